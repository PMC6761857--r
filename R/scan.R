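#' Sliding genomic windows
#'
#' Builds half-open windows `[start, start + size)` anchored at
#' coordinate 0 of every scaffold, advanced by `step`; the final windows
#' are truncated at the scaffold end. Defaults follow the common sweep
#' scan layout: 50-kb windows with a 25-kb step.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param size window size in bp (default 50000).
#' @param step window step in bp (default 25000).
#' @return `data.table` with columns `scaffold`, `start` (0-based,
#'   inclusive), `end` (exclusive), `window_id`.
#' @export
make_windows <- function(scaffold_lengths, size = 50000L, step = 25000L) {
  assert_that(size >= step && step > 0, "need size >= step > 0")
  assert_that(all(scaffold_lengths > 0), "scaffold lengths must be positive")
  res <- lapply(names(scaffold_lengths), function(sc) {
    L <- scaffold_lengths[[sc]]
    starts <- seq(0L, L - 1L, by = step)
    starts <- starts[starts < L]
    data.table(scaffold = sc, start = as.integer(starts),
               end = as.integer(pmin(starts + size, L)))
  })
  w <- data.table::rbindlist(res)
  w[, window_id := seq_len(.N)]
  w[]
}

# map each site to every window containing it (half-open windows,
# 1-based positions: window contains pos iff start < pos <= end)
assign_sites_to_windows <- function(sites, windows) {
  s <- data.table(scaffold = sites$scaffold, site_idx = seq_len(nrow(sites)),
                  s0 = sites$pos - 1L, s1 = sites$pos - 1L)
  w <- data.table(scaffold = windows$scaffold, window_id = windows$window_id,
                  s0 = windows$start, s1 = windows$end - 1L)
  data.table::setkey(w, scaffold, s0, s1)
  ov <- data.table::foverlaps(s, w, type = "within", nomatch = NULL)
  ov[, list(window_id, site_idx)]
}

#' Windowed pooled heterozygosity (Hp)
#'
#' For each window, sums the per-site major and minor observed allele
#' counts of the analysed cohort and computes
#' `Hp = 2 * S_maj * S_min / (S_maj + S_min)^2`. Sites contribute to
#' every window containing their position (overlapping windows
#' double-count by design); windows supported by fewer than `min_snps`
#' SNPs are discarded.
#'
#' @param gm a [geno_matrix()] restricted to the analysis cohort.
#' @param windows windows from [make_windows()].
#' @param min_snps minimum SNPs per retained window (default 2).
#' @return `data.table` with columns `scaffold`, `start`, `end`,
#'   `n_snps`, `sum_nmaj`, `sum_nmin`, `hp`.
#' @export
window_hp <- function(gm, windows, min_snps = 2L) {
  ac <- site_allele_counts(gm)
  ov <- assign_sites_to_windows(gm$sites, windows)
  ov[, c("n_maj", "n_min") := list(ac$n_maj[site_idx], ac$n_min[site_idx])]
  stat <- ov[, list(n_snps = .N, sum_nmaj = sum(n_maj),
                    sum_nmin = sum(n_min)), by = "window_id"]
  stat <- stat[n_snps >= min_snps]
  out <- windows[stat, on = "window_id"]
  out[, hp := 2 * as.numeric(sum_nmaj) * as.numeric(sum_nmin) /
        (as.numeric(sum_nmaj) + as.numeric(sum_nmin))^2]
  setorder(out, scaffold, start)
  out[]
}

#' Z-transform window statistics
#'
#' Median-centred Z-score: `Z = (x - median(x)) / sd(x)` with the sample
#' standard deviation (n - 1 denominator) over all retained windows.
#'
#' @param values numeric vector of per-window statistics.
#' @return numeric vector of Z-scores.
#' @export
z_transform <- function(values) {
  assert_that(length(values) >= 2, "need at least two windows to Z-transform")
  s <- sd(values)
  if (s == 0) stop2("degenerate distribution: zero standard deviation")
  (values - median(values)) / s
}

#' Empirical-tail significance threshold
#'
#' Linear-interpolation empirical quantile (order-statistic index
#' `h = q (n - 1) + 1`; the default quantile definition of R) at
#' `tail_fraction` for the lower tail or `1 - tail_fraction` for the
#' upper tail. Values at or beyond the threshold are significant.
#'
#' @param values numeric vector.
#' @param tail_fraction tail mass (default 0.001).
#' @param side `"lower"` or `"upper"`.
#' @return the threshold value.
#' @export
empirical_threshold <- function(values, tail_fraction = 0.001,
                                side = c("lower", "upper")) {
  side <- match.arg(side)
  assert_that(tail_fraction > 0 && tail_fraction < 0.5,
              "tail_fraction must lie in (0, 0.5)")
  if (length(values) < 1 / tail_fraction)
    warning(sprintf(
      "only %d values: fewer than one expected significant at tail %.4g",
      length(values), tail_fraction))
  q <- if (side == "lower") tail_fraction else 1 - tail_fraction
  unname(quantile(values, q, type = 7, names = FALSE))
}

#' Weir-Cockerham per-site variance components
#'
#' Computes the a (between-population), b (between-individual within
#' population) and c (within-individual) variance components of the
#' Weir-Cockerham Fst estimator for a bi-allelic site observed in two
#' populations, from diploid sample sizes `n1`, `n2`, alternate-allele
#' frequencies `p1`, `p2` and observed heterozygote fractions `h1`, `h2`.
#' All arguments vectorise over sites.
#'
#' With r = 2 populations: `nbar = (n1 + n2)/2`,
#' `nc = sum(n) - sum(n^2)/sum(n)`, `pbar = sum(n p)/sum(n)`,
#' `s2 = sum(n (p - pbar)^2) / ((r-1) nbar)`, `hbar = sum(n h)/sum(n)`,
#' and
#' \deqn{a = (nbar/nc) [s2 - (pbar(1-pbar) - s2/2 - hbar/4)/(nbar-1)]}
#' \deqn{b = (nbar/(nbar-1)) [pbar(1-pbar) - s2/2 - hbar (2 nbar - 1)/(4 nbar)]}
#' \deqn{c = hbar/2}
#'
#' Sites monomorphic across both cohorts return `(0, 0, 0)` and are
#' excluded from window sums downstream.
#'
#' @param n1,n2 called diploid individuals per population (must be >= 2).
#' @param p1,p2 alternate-allele sample frequencies.
#' @param h1,h2 observed heterozygote fractions.
#' @return `data.table` with columns `a`, `b`, `c`.
#' @export
fst_site_components <- function(n1, p1, h1, n2, p2, h2) {
  assert_that(all(n1 >= 2) && all(n2 >= 2),
              "need at least two called diploids in each population")
  r <- 2
  nsum <- n1 + n2
  nbar <- nsum / r
  nc <- nsum - (n1^2 + n2^2) / nsum
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  mono <- (pbar == 0 | pbar == 1) & hbar == 0
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  data.table(a = a, b = b, c = cc)
}

# per-site cohort summaries needed by the Fst components
cohort_site_summary <- function(gm, samples) {
  sub <- gm$geno[, samples, drop = FALSE]
  called <- !is.na(sub)
  n <- rowSums(called)
  p <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, rowSums(sub == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Windowed Weir-Cockerham Fst between two cohorts
#'
#' Per-site variance components from [fst_site_components()] are combined
#' per window as the weighted (ratio-of-sums) estimator
#' `Fst = sum(a) / sum(a + b + c)` over in-window sites. Sites with fewer
#' than two called diploids in either cohort, or monomorphic across both
#' cohorts, are excluded. Windows with fewer than `min_snps` contributing
#' SNPs, or a zero denominator, are dropped. Negative window values are
#' reported as computed.
#'
#' @param gm a [geno_matrix()] with a population map.
#' @param pop_a,pop_b the two population labels to contrast.
#' @param windows windows from [make_windows()].
#' @param min_snps minimum contributing SNPs per window (default 2).
#' @return `data.table` with columns `scaffold`, `start`, `end`,
#'   `n_snps`, `sum_a`, `sum_abc`, `fst`, plus attribute
#'   `"site_theta"` holding the per-site estimates for inspection.
#' @export
window_fst <- function(gm, pop_a, pop_b, windows, min_snps = 2L) {
  assert_that(!is.null(gm$populations), "population map required")
  sa <- gm$samples[gm$populations == pop_a]
  sb <- gm$samples[gm$populations == pop_b]
  assert_that(length(sa) > 0 && length(sb) > 0,
              "empty cohort: %s or %s", pop_a, pop_b)
  ca <- cohort_site_summary(gm, sa)
  cb <- cohort_site_summary(gm, sb)
  usable <- ca$n >= 2 & cb$n >= 2
  comp <- data.table(a = rep(NA_real_, n_sites(gm)), b = NA_real_,
                     c = NA_real_)
  if (any(usable)) {
    cmp <- fst_site_components(ca$n[usable], ca$p[usable], ca$h[usable],
                               cb$n[usable], cb$p[usable], cb$h[usable])
    comp[usable, c("a", "b", "c") := cmp]
  }
  # monomorphic-in-both sites contribute nothing
  mono <- usable & (comp$a == 0 & comp$b == 0 & comp$c == 0)
  contributing <- usable & !mono
  ov <- assign_sites_to_windows(gm$sites, windows)
  ov <- ov[contributing[site_idx]]
  ov[, c("a", "abc") := list(comp$a[site_idx],
                             comp$a[site_idx] + comp$b[site_idx] +
                               comp$c[site_idx])]
  stat <- ov[, list(n_snps = .N, sum_a = sum(a), sum_abc = sum(abc)),
             by = "window_id"]
  stat <- stat[n_snps >= min_snps]
  zero_den <- stat$sum_abc == 0
  if (any(zero_den)) {
    warning(sprintf("%d window(s) dropped: zero Fst denominator",
                    sum(zero_den)))
    stat <- stat[!zero_den]
  }
  out <- windows[stat, on = "window_id"]
  out[, fst := sum_a / sum_abc]
  setorder(out, scaffold, start)
  site_theta <- ifelse(contributing,
                       comp$a / (comp$a + comp$b + comp$c), NA_real_)
  data.table::setattr(out, "site_theta", site_theta)
  out[]
}

#' Merge overlapping significant windows into regions
#'
#' Same-scaffold windows sharing at least one bp are merged into maximal
#' regions; abutting windows (end equal to the next start under half-open
#' coordinates) are kept separate. Each region carries its member count
#' and the extreme statistic of its members (minimum for a lower-tail
#' scan, maximum for an upper-tail scan).
#'
#' @param windows `data.table` of significant windows with columns
#'   `scaffold`, `start`, `end` and a statistic column.
#' @param stat_col name of the statistic column (e.g. `"zhp"`, `"fst"`).
#' @param extreme `"min"` or `"max"`.
#' @return `data.table` with columns `scaffold`, `start`, `end`,
#'   `n_windows`, `extreme_stat`; disjoint and sorted.
#' @export
merge_significant <- function(windows, stat_col = "zhp",
                              extreme = c("min", "max")) {
  extreme <- match.arg(extreme)
  ef <- if (extreme == "min") min else max
  w <- data.table::as.data.table(windows)
  if (nrow(w) == 0)
    return(data.table(scaffold = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      extreme_stat = numeric()))
  setorder(w, scaffold, start, end)
  regions <- list()
  cur <- NULL
  for (i in seq_len(nrow(w))) {
    row <- w[i]
    if (is.null(cur) || row$scaffold != cur$scaffold ||
        row$start >= cur$end) {  # no shared bp: start < end required
      if (!is.null(cur)) regions[[length(regions) + 1L]] <- cur
      cur <- list(scaffold = row$scaffold, start = row$start, end = row$end,
                  n_windows = 1L, extreme_stat = row[[stat_col]])
    } else {
      cur$end <- max(cur$end, row$end)
      cur$n_windows <- cur$n_windows + 1L
      cur$extreme_stat <- ef(cur$extreme_stat, row[[stat_col]])
    }
  }
  regions[[length(regions) + 1L]] <- cur
  out <- data.table::rbindlist(regions)
  setorder(out, scaffold, start)
  out[]
}

#' Pooled-heterozygosity sweep scan
#'
#' End-to-end Hp scan of one cohort: windowed Hp, median-centred
#' Z-transform, lower-tail empirical threshold, and merging of
#' overlapping significant windows into candidate regions.
#'
#' @param gm a [geno_matrix()] restricted to the analysis cohort.
#' @param scaffold_lengths named integer vector.
#' @param size,step window geometry in bp.
#' @param tail_fraction lower-tail mass declared significant
#'   (default 0.001).
#' @param min_snps minimum SNPs per window (default 2).
#' @return list with `windows` (all retained windows with `hp`, `zhp`),
#'   `threshold` (realised ZHp cutoff), `significant` (windows at or
#'   below the cutoff), `regions` (merged).
#' @export
scan_hp <- function(gm, scaffold_lengths, size = 50000L, step = 25000L,
                    tail_fraction = 0.001, min_snps = 2L) {
  windows <- make_windows(scaffold_lengths, size, step)
  wh <- window_hp(gm, windows, min_snps)
  wh[, zhp := z_transform(hp)]
  thr <- empirical_threshold(wh$zhp, tail_fraction, "lower")
  sig <- wh[zhp <= thr]
  regions <- merge_significant(sig, "zhp", "min")
  list(windows = wh[], threshold = thr, significant = sig[],
       regions = regions)
}

#' Windowed Fst differentiation scan
#'
#' End-to-end Fst scan between two cohorts: windowed weighted
#' Weir-Cockerham Fst, upper-tail empirical threshold, and merged
#' significant regions.
#'
#' @inheritParams scan_hp
#' @param pop_a,pop_b population labels to contrast.
#' @return list with `windows`, `threshold` (realised Fst cutoff),
#'   `significant`, `regions`.
#' @export
scan_fst <- function(gm, pop_a, pop_b, scaffold_lengths, size = 50000L,
                     step = 25000L, tail_fraction = 0.001, min_snps = 2L) {
  windows <- make_windows(scaffold_lengths, size, step)
  wf <- window_fst(gm, pop_a, pop_b, windows, min_snps)
  thr <- empirical_threshold(wf$fst, tail_fraction, "upper")
  sig <- wf[fst >= thr]
  regions <- merge_significant(sig, "fst", "max")
  list(windows = wf[], threshold = thr, significant = sig[],
       regions = regions)
}
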