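#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic cohort with the statistical structure the
#' downstream scans assume: a sparse diploid SNP panel over several
#' scaffolds, two or more populations diverged under the Balding-Nichols
#' model, optional implanted low-heterozygosity (sweep) regions and
#' high-differentiation regions, per-genotype missingness, and a fraction
#' of sites whose INFO annotations violate one named hard filter.
#'
#' @param seed integer seed; identical configurations (including the seed)
#'   produce byte-identical output files.
#' @param scaffolds named integer vector of scaffold lengths in bp.
#' @param snp_density expected SNPs per bp (uniform site-placement model).
#' @param populations named integer vector: diploid individuals per
#'   population.
#' @param F_divergence Balding-Nichols drift parameter in `[0, 1)`.
#' @param sweep_regions `data.frame` with columns `scaffold`, `start`,
#'   `end` (0-based half-open bp), `population` (a population name or
#'   `"all"`), `fixation_level` in `[0.5, 1]`; or `NULL`.
#' @param diff_regions `data.frame` with columns `scaffold`, `start`,
#'   `end`, `delta_freq` in `(0, 1]`; or `NULL`. Requires exactly two
#'   populations.
#' @param missing_rate per-genotype missingness probability in `[0, 1)`.
#' @param info_fail_fraction fraction of sites given INFO values violating
#'   one hard-filter threshold (cycled over QD, FS, MQ, QUAL, MQRankSum,
#'   ReadPosRankSum).
#' @param tstv expected transition/transversion ratio of the generated
#'   REF/ALT pairs.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       scaffolds = c(scaf1 = 1e6L),
                       snp_density = 1 / 2000,
                       populations = c(popA = 20L, popB = 20L),
                       F_divergence = 0,
                       sweep_regions = NULL,
                       diff_regions = NULL,
                       missing_rate = 0,
                       info_fail_fraction = 0,
                       tstv = 2.0) {
  assert_that(length(scaffolds) >= 1 && all(scaffolds > 0),
              "need at least one scaffold with positive length")
  assert_that(!is.null(names(scaffolds)) && !anyNA(names(scaffolds)),
              "scaffolds must be named")
  assert_that(length(populations) >= 1 && all(populations >= 1),
              "need at least one population with at least one individual")
  assert_that(F_divergence >= 0 && F_divergence < 1,
              "F_divergence must lie in [0, 1)")
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must lie in [0, 1)")
  assert_that(info_fail_fraction >= 0 && info_fail_fraction <= 1,
              "info_fail_fraction must lie in [0, 1]")
  chk_regions <- function(reg, cols, what) {
    if (is.null(reg)) return(NULL)
    reg <- data.table::as.data.table(reg)
    assert_that(all(cols %in% names(reg)), "%s needs columns %s",
                what, paste(cols, collapse = ", "))
    assert_that(all(reg$scaffold %in% names(scaffolds)),
                "%s references unknown scaffold", what)
    len <- scaffolds[reg$scaffold]
    assert_that(all(reg$start >= 0 & reg$end <= len & reg$start < reg$end),
                "%s intervals must lie within their scaffold", what)
    reg
  }
  sweep_regions <- chk_regions(
    sweep_regions, c("scaffold", "start", "end", "population",
                     "fixation_level"), "sweep_regions")
  if (!is.null(sweep_regions)) {
    assert_that(all(sweep_regions$fixation_level >= 0.5 &
                      sweep_regions$fixation_level <= 1),
                "fixation_level must lie in [0.5, 1]")
    assert_that(all(sweep_regions$population %in%
                      c("all", names(populations))),
                "sweep target population not in population list")
  }
  diff_regions <- chk_regions(
    diff_regions, c("scaffold", "start", "end", "delta_freq"),
    "diff_regions")
  if (!is.null(diff_regions)) {
    assert_that(length(populations) == 2,
                "diff_regions require exactly two populations")
    assert_that(all(diff_regions$delta_freq > 0 &
                      diff_regions$delta_freq <= 1),
                "delta_freq must lie in (0, 1]")
  }
  structure(
    list(seed = as.integer(seed), scaffolds = scaffolds,
         snp_density = snp_density, populations = populations,
         F_divergence = F_divergence, sweep_regions = sweep_regions,
         diff_regions = diff_regions, missing_rate = missing_rate,
         info_fail_fraction = info_fail_fraction, tstv = tstv),
    class = "sim_config"
  )
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population allele frequencies around an ancestral frequency
#' `p_anc` under the Balding-Nichols model: each population's frequency is
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so the mean is `p_anc` and the variance
#' is `F * p_anc * (1 - p_anc)`. With `F = 0` there is no drift and every
#' population receives `p_anc` exactly.
#'
#' @param p_anc ancestral allele frequency, strictly inside `(0, 1)`.
#' @param F drift/divergence parameter in `[0, 1)`.
#' @param n_pops number of populations to draw.
#' @return numeric vector of length `n_pops`.
#' @export
sample_bn_frequencies <- function(p_anc, F, n_pops) {
  assert_that(all(p_anc > 0 & p_anc < 1),
              "ancestral frequency must lie strictly in (0, 1): monomorphic site")
  assert_that(F >= 0 && F < 1, "F must lie in [0, 1)")
  if (F == 0) return(rep(p_anc, n_pops))
  shape <- (1 - F) / F
  rbeta(n_pops, p_anc * shape, (1 - p_anc) * shape)
}

#' Implant a selective sweep into per-site frequencies
#'
#' Forces every site inside `region` to a major-allele frequency of at
#' least `fixation_level`, leaving sites outside the region untouched.
#' The side of the frequency spectrum is preserved: sites whose current
#' frequency favours the alternate allele are driven towards 1, the rest
#' towards 0. The realised major-allele frequency is drawn uniformly from
#' `[fixation_level, 1]`.
#'
#' @param freqs numeric vector of per-site alternate-allele frequencies.
#' @param pos integer vector of 1-based site positions (same length).
#' @param region list or one-row data.frame with `start`, `end`
#'   (0-based half-open bp).
#' @param fixation_level minimum major-allele frequency in `[0.5, 1]`.
#' @param toward_alt optional logical vector (same length as `freqs`)
#'   naming the allele the sweep favours at each site; by default the
#'   currently more frequent allele. A sweep shared by several
#'   populations must favour the same allele in each, so the cohort
#'   generator passes the ancestral direction here.
#' @return modified copy of `freqs`.
#' @export
implant_sweep <- function(freqs, pos, region, fixation_level,
                          toward_alt = NULL) {
  assert_that(fixation_level >= 0.5 && fixation_level <= 1,
              "fixation_level must lie in [0.5, 1]")
  inside <- pos > region$start & pos <= region$end
  if (!any(inside)) {
    warning("sweep region contains no sites; nothing implanted")
    return(freqs)
  }
  if (is.null(toward_alt)) toward_alt <- freqs >= 0.5
  p_major <- runif(sum(inside), fixation_level, 1)
  freqs[inside] <- ifelse(toward_alt[inside], p_major, 1 - p_major)
  freqs
}

# Push the two populations' frequencies apart by delta at in-region sites,
# symmetric around the ancestral frequency (clamped so both stay in [0,1]).
implant_diff <- function(freq_mat, pos, region, delta) {
  inside <- pos > region$start & pos <= region$end
  if (!any(inside)) {
    warning("differentiation region contains no sites; nothing implanted")
    return(freq_mat)
  }
  centre <- pmin(pmax(rowMeans(freq_mat[inside, , drop = FALSE]),
                      delta / 2), 1 - delta / 2)
  freq_mat[inside, 1] <- centre + delta / 2
  freq_mat[inside, 2] <- centre - delta / 2
  freq_mat
}

# passing INFO ranges and just-past-threshold violations for hard filters
.info_pass_ranges <- list(
  QD = c(5, 30), FS = c(0, 10), MQ = c(45, 60),
  MQRankSum = c(-2, 2), ReadPosRankSum = c(-2, 2), QUAL = c(50, 500)
)
.info_fail_values <- c(
  QD = 1.9, FS = 60.5, MQ = 39.5, QUAL = 29.5,
  MQRankSum = -12.6, ReadPosRankSum = -8.5
)

#' Generate a synthetic cohort
#'
#' Draws a full synthetic cohort from a [sim_config()]: site positions
#' (uniform placement at the configured density), ancestral frequencies
#' (Uniform(0.05, 0.95) so every site segregates), Balding-Nichols
#' per-population frequencies, implanted sweep and differentiation
#' regions, Hardy-Weinberg binomial genotypes, missingness, REF/ALT base
#' pairs at the configured expected Ts/Tv, and INFO annotations where a
#' configured fraction of sites violates exactly one hard filter. A single
#' seeded RNG stream with a fixed draw order makes the output reproducible.
#'
#' When `outdir` is given, writes `cohort.vcf` (VCF v4.2),
#' `samples.tsv` (sample_id, population), `genes.gff3` (non-overlapping
#' synthetic gene models), `scaffolds.tsv` (name, length),
#' `truth_sweeps.bed`, `truth_diffs.bed` (0-based half-open) and
#' `truth_filter_fail.tsv`.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory; created if absent.
#' @return an object of class `sim_cohort`: list with elements `geno`
#'   (a [geno_matrix()]), `truth` (sweep/diff intervals, per-site
#'   ancestral and per-population frequencies, filter-violating sites),
#'   `config`, and `files` (paths, when written).
#' @export
generate_cohort <- function(config, outdir = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, generate_cohort_impl(config, outdir))
}

generate_cohort_impl <- function(config, outdir) {
  scafs <- config$scaffolds
  pops <- config$populations
  n_pop <- length(pops)
  pop_names <- names(pops)

  # 1. site positions: per scaffold, Binomial(L, density) sites placed
  #    uniformly without replacement
  sites_list <- lapply(names(scafs), function(sc) {
    L <- scafs[[sc]]
    n <- rbinom(1, L, min(1, config$snp_density))
    if (n == 0) return(NULL)
    data.table(scaffold = sc, pos = sort(sample.int(L, n)))
  })
  sites <- data.table::rbindlist(sites_list)
  assert_that(nrow(sites) > 0, "no sites generated; increase snp_density")
  m <- nrow(sites)

  # 2. ancestral frequencies: Uniform(0.05, 0.95), always segregating
  p_anc <- runif(m, 0.05, 0.95)

  # 3. REF/ALT pairs at expected Ts/Tv = config$tstv
  alleles <- draw_ref_alt(m, config$tstv)

  # 4. per-population frequencies under Balding-Nichols
  freq <- matrix(0, m, n_pop, dimnames = list(NULL, pop_names))
  if (config$F_divergence == 0) {
    freq[] <- p_anc
  } else {
    shape <- (1 - config$F_divergence) / config$F_divergence
    for (k in seq_len(n_pop))
      freq[, k] <- rbeta(m, p_anc * shape, (1 - p_anc) * shape)
  }

  # 5. sweeps (per target population, after drift)
  if (!is.null(config$sweep_regions)) {
    for (r in seq_len(nrow(config$sweep_regions))) {
      reg <- config$sweep_regions[r]
      on_scaf <- sites$scaffold == reg$scaffold
      targets <- if (reg$population == "all") pop_names else reg$population
      # shared direction: the sweep favours the ancestral major allele in
      # every target population
      toward <- p_anc[on_scaf] >= 0.5
      for (pn in targets) {
        freq[on_scaf, pn] <- implant_sweep(
          freq[on_scaf, pn], sites$pos[on_scaf],
          list(start = reg$start, end = reg$end), reg$fixation_level,
          toward_alt = toward)
      }
    }
  }

  # 6. differentiation regions (two populations)
  if (!is.null(config$diff_regions)) {
    for (r in seq_len(nrow(config$diff_regions))) {
      reg <- config$diff_regions[r]
      on_scaf <- sites$scaffold == reg$scaffold
      freq[on_scaf, ] <- implant_diff(
        freq[on_scaf, , drop = FALSE], sites$pos[on_scaf],
        list(start = reg$start, end = reg$end), reg$delta_freq)
    }
  }

  # 7. genotypes: Binomial(2, p_pop) per individual, HWE within population
  n_ind <- sum(pops)
  sample_ids <- unlist(lapply(pop_names, function(pn)
    sprintf("%s_%02d", pn, seq_len(pops[[pn]]))), use.names = FALSE)
  populations <- setNames(rep(pop_names, pops), sample_ids)
  geno <- matrix(NA_integer_, m, n_ind, dimnames = list(NULL, sample_ids))
  col <- 1L
  for (k in seq_len(n_pop)) {
    for (i in seq_len(pops[[k]])) {
      geno[, col] <- rbinom(m, 2L, freq[, k])
      col <- col + 1L
    }
  }

  # 8. missingness mask
  if (config$missing_rate > 0) {
    mask <- matrix(runif(m * n_ind) < config$missing_rate, m, n_ind)
    geno[mask] <- NA_integer_
  }

  # 9. INFO annotations: clean sites from passing ranges
  info <- data.table(
    QD = runif(m, .info_pass_ranges$QD[1], .info_pass_ranges$QD[2]),
    FS = runif(m, .info_pass_ranges$FS[1], .info_pass_ranges$FS[2]),
    MQ = runif(m, .info_pass_ranges$MQ[1], .info_pass_ranges$MQ[2]),
    MQRankSum = runif(m, .info_pass_ranges$MQRankSum[1],
                      .info_pass_ranges$MQRankSum[2]),
    ReadPosRankSum = runif(m, .info_pass_ranges$ReadPosRankSum[1],
                           .info_pass_ranges$ReadPosRankSum[2]),
    qual = runif(m, .info_pass_ranges$QUAL[1], .info_pass_ranges$QUAL[2]),
    DP = round(runif(m, 100, 300))
  )

  # 10. hard-filter violations: round(fraction * m) sites, filters cycled
  n_fail <- round(config$info_fail_fraction * m)
  fail_sites <- data.table(scaffold = character(), pos = integer(),
                           filter = character())
  if (n_fail > 0) {
    idx <- sort(sample.int(m, n_fail))
    filt <- rep_len(names(.info_fail_values), n_fail)
    for (j in seq_len(n_fail)) {
      f <- filt[j]
      if (f == "QUAL") info$qual[idx[j]] <- .info_fail_values[[f]]
      else data.table::set(info, idx[j], f, .info_fail_values[[f]])
    }
    fail_sites <- data.table(scaffold = sites$scaffold[idx],
                             pos = sites$pos[idx], filter = filt)
  }

  site_tab <- data.table(
    scaffold = sites$scaffold, pos = sites$pos,
    ref = alleles$ref, alt = alleles$alt, qual = info$qual,
    QD = info$QD, FS = info$FS, MQ = info$MQ,
    MQRankSum = info$MQRankSum, ReadPosRankSum = info$ReadPosRankSum,
    DP = as.integer(info$DP))

  gm <- geno_matrix(site_tab, geno, sample_ids, populations)

  # 11. synthetic gene models: non-overlapping, one per ~40 kb
  genes <- synth_genes(scafs)

  truth <- list(
    sweep_intervals = config$sweep_regions,
    diff_intervals = config$diff_regions,
    fail_sites = fail_sites,
    p_anc = p_anc,
    pop_freq = freq
  )
  out <- structure(list(geno = gm, truth = truth, genes = genes,
                        config = config, files = NULL),
                   class = "sim_cohort")
  if (!is.null(outdir)) out$files <- write_cohort(out, outdir)
  out
}

# REF/ALT pairs with P(transition) = tstv/(1+tstv)
draw_ref_alt <- function(m, tstv) {
  ts_pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  tv_pairs <- rbind(c("A", "C"), c("C", "A"), c("A", "T"), c("T", "A"),
                    c("C", "G"), c("G", "C"), c("G", "T"), c("T", "G"))
  is_ts <- runif(m) < tstv / (1 + tstv)
  pick_ts <- sample.int(nrow(ts_pairs), m, replace = TRUE)
  pick_tv <- sample.int(nrow(tv_pairs), m, replace = TRUE)
  ref <- ifelse(is_ts, ts_pairs[pick_ts, 1], tv_pairs[pick_tv, 1])
  alt <- ifelse(is_ts, ts_pairs[pick_ts, 2], tv_pairs[pick_tv, 2])
  list(ref = ref, alt = alt)
}

# deterministic synthetic gene models: gene of 2-15 kb every 40 kb
synth_genes <- function(scaffolds) {
  res <- lapply(names(scaffolds), function(sc) {
    L <- scaffolds[[sc]]
    starts <- seq(0L, max(0L, L - 1L), by = 40000L)
    lens <- round(runif(length(starts), 2000, 15000))
    ends <- pmin(starts + lens, L)
    keep <- ends > starts
    data.table(gene_id = sprintf("%s_g%03d", sc, seq_along(starts))[keep],
               scaffold = sc, start = starts[keep], end = as.integer(ends[keep]),
               strand = rep_len(c("+", "-"), sum(keep)))
  })
  data.table::rbindlist(res)
}
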