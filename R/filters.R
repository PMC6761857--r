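#' Default hard-filter thresholds
#'
#' A site is removed when an annotation that is present violates its
#' threshold: QD < 2, FS > 60, MQ < 40, QUAL < 30, MQRankSum < -12.5,
#' ReadPosRankSum < -8. Missing annotations never cause removal
#' (the standard hard-filtering convention). Comparisons are exactly as
#' stated: FS = 60 is retained, QD = 2 is retained.
#'
#' @return named list of threshold values.
#' @export
default_hard_filters <- function() {
  list(QD = 2, FS = 60, MQ = 40, QUAL = 30,
       MQRankSum = -12.5, ReadPosRankSum = -8)
}

# direction of each comparison: "lt" = removed when value < threshold,
# "gt" = removed when value > threshold
.filter_direction <- c(QD = "lt", FS = "gt", MQ = "lt", QUAL = "lt",
                       MQRankSum = "lt", ReadPosRankSum = "lt")

new_filter_report <- function() {
  data.table(stage = character(), n_in = integer(),
             n_removed = integer(), n_retained = integer())
}

# collapse a logical reason matrix to "name1,name2" strings (rowwise)
reasons_of <- function(mat) {
  if (nrow(mat) == 0) return(character())
  apply(mat, 1, function(r) paste(colnames(mat)[r], collapse = ","))
}

add_stage <- function(report, stage, n_in, n_removed) {
  rbind(report, data.table(stage = stage, n_in = as.integer(n_in),
                           n_removed = as.integer(n_removed),
                           n_retained = as.integer(n_in - n_removed)))
}

#' Apply GATK-style hard filters to a genotype matrix
#'
#' Evaluates the named site-level annotations (QD, FS, MQ, QUAL,
#' MQRankSum, ReadPosRankSum) against their thresholds. A record is
#' removed iff at least one annotation that is present violates its
#' threshold; absent (`NA`) annotations pass. Each removal records the
#' violated filter name(s).
#'
#' @param gm a [geno_matrix()] whose `sites` carry the INFO columns.
#' @param thresholds named list as returned by [default_hard_filters()].
#' @return list with elements `gm` (retained sites), `report` (one-row
#'   stage count table), `removed` (`data.table`: scaffold, pos, reasons).
#' @export
apply_hard_filters <- function(gm, thresholds = default_hard_filters()) {
  s <- gm$sites
  m <- nrow(s)
  fails <- matrix(FALSE, m, length(thresholds),
                  dimnames = list(NULL, names(thresholds)))
  for (f in names(thresholds)) {
    if (!f %in% names(.filter_direction))
      stop2("unknown hard filter '%s'", f)
    col <- if (f == "QUAL") "qual" else f
    v <- if (col %in% names(s)) s[[col]] else rep(NA_real_, m)
    if (!is.numeric(v) && !all(is.na(v))) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      if (is.na(bad_row)) bad_row <- 1L
      stop2("malformed INFO value in %s at %s:%d", f,
            s$scaffold[bad_row], s$pos[bad_row])
    }
    v <- suppressWarnings(as.numeric(v))
    bad <- if (.filter_direction[[f]] == "lt") v < thresholds[[f]]
           else v > thresholds[[f]]
    fails[, f] <- !is.na(bad) & bad
  }
  drop <- rowSums(fails) > 0
  removed <- data.table(
    scaffold = s$scaffold[drop], pos = s$pos[drop],
    reasons = reasons_of(fails[drop, , drop = FALSE]))
  list(gm = subset_sites(gm, !drop),
       report = add_stage(new_filter_report(), "hard_filters", m, sum(drop)),
       removed = removed)
}

#' Apply site-depth filters
#'
#' Two-pass depth filter: the mean and standard deviation of site-level
#' DP are computed over all input records first, then a record is retained
#' iff `DP >= min_dp` and `|DP - mean| <= sd_mult * sd`. Records without a
#' DP annotation are removed (reason `DP-missing`).
#'
#' @param gm a [geno_matrix()].
#' @param min_dp minimum site depth (default 5).
#' @param sd_mult standard-deviation multiplier (default 3).
#' @param per_sample_mean when `TRUE`, interpret the site DP divided by
#'   the sample count as the depth tested against `min_dp`. Off by
#'   default; the site-level reading is the primary contract.
#' @return list with `gm`, `report`, `removed` (scaffold, pos, reasons).
#' @export
apply_depth_filters <- function(gm, min_dp = 5, sd_mult = 3,
                                per_sample_mean = FALSE) {
  s <- gm$sites
  m <- nrow(s)
  dp <- as.numeric(s$DP %||% rep(NA_real_, m))
  if (per_sample_mean) dp <- dp / max(1L, n_samples(gm))
  missing_dp <- is.na(dp)
  mu <- mean(dp[!missing_dp])
  sig <- sd(dp[!missing_dp])
  if (is.na(sig)) sig <- 0  # single site: degenerate SD
  low <- !missing_dp & dp < min_dp
  out_band <- !missing_dp & abs(dp - mu) > sd_mult * sig
  drop <- missing_dp | low | out_band
  rr <- cbind(DP_missing = missing_dp[drop], DP_low = low[drop],
              DP_outlier = out_band[drop])
  reasons <- reasons_of(rr)
  list(gm = subset_sites(gm, !drop),
       report = add_stage(new_filter_report(), "depth_filters", m, sum(drop)),
       removed = data.table(scaffold = s$scaffold[drop], pos = s$pos[drop],
                            reasons = reasons),
       dp_mean = mu, dp_sd = sig)
}

#' Restrict to bi-allelic SNPs off excluded scaffolds
#'
#' Removes records on excluded scaffolds (by default the mitochondrial
#' scaffold NC_009849.1), indels (REF or ALT longer than one base) and
#' multi-allelic records (more than one ALT allele).
#'
#' @param gm a [geno_matrix()].
#' @param excluded_scaffolds character vector of scaffold names to drop.
#' @return list with `gm`, `report`, `removed`.
#' @export
restrict_sites <- function(gm, excluded_scaffolds = "NC_009849.1") {
  s <- gm$sites
  m <- nrow(s)
  on_excl <- s$scaffold %in% excluded_scaffolds
  multi <- grepl(",", s$alt, fixed = TRUE)
  indel <- nchar(s$ref) != 1L | (!multi & nchar(s$alt) != 1L)
  drop <- on_excl | multi | indel
  rr <- cbind(excluded_scaffold = on_excl[drop], multi_allelic = multi[drop],
              indel = indel[drop])
  reasons <- reasons_of(rr)
  list(gm = subset_sites(gm, !drop),
       report = add_stage(new_filter_report(), "restrict_sites", m, sum(drop)),
       removed = data.table(scaffold = s$scaffold[drop], pos = s$pos[drop],
                            reasons = reasons))
}

#' Transition/transversion ratio
#'
#' Classifies each bi-allelic REF/ALT pair as a transition (A<->G, C<->T)
#' or a transversion and returns their ratio. Symmetric in REF and ALT.
#'
#' @param gm a [geno_matrix()] of bi-allelic SNPs, or a two-column
#'   character matrix / data.frame of ref and alt alleles.
#' @return the Ts/Tv ratio (errors when there are no transversions,
#'   reporting both counts).
#' @export
compute_tstv <- function(gm) {
  if (inherits(gm, "geno_matrix")) {
    ref <- gm$sites$ref; alt <- gm$sites$alt
  } else {
    ref <- as.character(gm[[1]]); alt <- as.character(gm[[2]])
  }
  if (length(ref) == 0)
    stop2("Ts/Tv undefined: no variants (0 transitions, 0 transversions)")
  ok <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE)
  assert_that(all(ok), "compute_tstv requires bi-allelic SNPs")
  purine <- c("A", "G")
  is_ts <- (ref %in% purine) == (alt %in% purine)
  n_ts <- sum(is_ts); n_tv <- sum(!is_ts)
  if (n_tv == 0)
    stop2("Ts/Tv undefined: %d transitions, 0 transversions", n_ts)
  n_ts / n_tv
}

#' Intersect two call sets on site keys
#'
#' Set intersection of two genotype matrices on (scaffold, pos, ref, alt)
#' keys, mirroring a two-caller consensus where the surviving genotypes
#' are taken from the second call set.
#'
#' @param gm1,gm2 [geno_matrix()] objects from the two callers.
#' @return a [geno_matrix()]: the shared sites with `gm2`'s genotypes and
#'   annotations.
#' @export
intersect_callers <- function(gm1, gm2) {
  key1 <- paste(gm1$sites$scaffold, gm1$sites$pos, gm1$sites$ref,
                gm1$sites$alt, sep = ":")
  key2 <- paste(gm2$sites$scaffold, gm2$sites$pos, gm2$sites$ref,
                gm2$sites$alt, sep = ":")
  subset_sites(gm2, key2 %in% key1)
}

#' Full site-filtering cascade
#'
#' Runs [apply_hard_filters()], [apply_depth_filters()] and
#' [restrict_sites()] in order, computing the Ts/Tv ratio before and
#' after (on the bi-allelic SNP subset), and accumulates a per-stage
#' filter report.
#'
#' @param gm a [geno_matrix()].
#' @param thresholds hard-filter thresholds.
#' @param min_dp,sd_mult depth-filter parameters.
#' @param excluded_scaffolds scaffolds to drop entirely.
#' @return list with `gm` (surviving sites), `report` (stage table with
#'   attribute rows for every stage), `tstv_before`, `tstv_after`,
#'   `removed` (combined removal table with stage labels).
#' @export
filter_cascade <- function(gm, thresholds = default_hard_filters(),
                           min_dp = 5, sd_mult = 3,
                           excluded_scaffolds = "NC_009849.1") {
  tstv_before <- tryCatch(compute_tstv(snp_subset(gm)), error = function(e) NA_real_)
  st1 <- apply_hard_filters(gm, thresholds)
  st2 <- apply_depth_filters(st1$gm, min_dp, sd_mult)
  st3 <- restrict_sites(st2$gm, excluded_scaffolds)
  tstv_after <- tryCatch(compute_tstv(st3$gm), error = function(e) NA_real_)
  report <- rbind(st1$report, st2$report, st3$report)
  tag <- function(stage, rem) {
    if (nrow(rem) == 0)
      return(data.table(stage = character(), scaffold = character(),
                        pos = integer(), reasons = character()))
    data.table(stage = stage, rem)
  }
  removed <- rbind(tag("hard_filters", st1$removed),
                   tag("depth_filters", st2$removed),
                   tag("restrict_sites", st3$removed))
  list(gm = st3$gm, report = report, removed = removed,
       tstv_before = tstv_before, tstv_after = tstv_after)
}

# bi-allelic SNP rows only (for Ts/Tv on unfiltered input)
snp_subset <- function(gm) {
  keep <- nchar(gm$sites$ref) == 1 & nchar(gm$sites$alt) == 1 &
    !grepl(",", gm$sites$alt, fixed = TRUE)
  subset_sites(gm, keep)
}

#' Write a filter report as TSV
#' @param report stage-count table from the filtering operations.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  fwrite(report, path, sep = "\t")
  invisible(path)
}
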