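#' Per-site minor allele frequency and call rate
#'
#' For each site: `call_rate` = non-missing genotypes / samples;
#' `p` = mean dosage / 2 over non-missing calls; `maf` = min(p, 1-p).
#'
#' @param gm a [geno_matrix()].
#' @return `data.table` with columns `maf`, `call_rate`, `p_alt`.
#'   Sites with no called genotypes raise an error.
#' @export
site_stats <- function(gm) {
  called <- !is.na(gm$geno)
  ncall <- rowSums(called)
  if (any(ncall == 0))
    stop2("site statistics undefined: %d site(s) with no called genotypes",
          sum(ncall == 0))
  p <- rowSums(gm$geno, na.rm = TRUE) / (2 * ncall)
  data.table(maf = pmin(p, 1 - p),
             call_rate = ncall / n_samples(gm),
             p_alt = p)
}

#' Marker-level QC: MAF and call-rate filtering
#'
#' Removes sites with `maf < maf_min` (when `apply_maf`) or
#' `call_rate < call_rate_min`; both comparisons are strict, so boundary
#' sites (MAF exactly 5%, call rate exactly 95%) are retained. Failures
#' are counted in three disjoint buckets (MAF only, call rate only, both)
#' to support the usual QC-breakdown table. `apply_maf = FALSE`
#' reproduces the pooled-heterozygosity dataset regime, where MAF
#' filtering is deliberately skipped because the Hp statistic is itself a
#' function of allele-frequency extremes.
#'
#' @param gm a [geno_matrix()].
#' @param maf_min MAF threshold (default 0.05).
#' @param call_rate_min call-rate threshold (default 0.95).
#' @param apply_maf apply the MAF criterion (default `TRUE`).
#' @return list with `gm` (retained), `report` (named counts:
#'   `n_in`, `removed_maf`, `removed_callrate`, `removed_both`, `n_out`),
#'   `kept` (logical index into the input sites).
#' @export
filter_snps <- function(gm, maf_min = 0.05, call_rate_min = 0.95,
                        apply_maf = TRUE) {
  st <- site_stats(gm)
  fail_maf <- apply_maf & st$maf < maf_min
  fail_cr <- st$call_rate < call_rate_min
  keep <- !(fail_maf | fail_cr)
  if (!any(keep)) stop2("marker QC removed every site")
  report <- list(
    n_in = nrow(st),
    removed_maf = sum(fail_maf & !fail_cr),
    removed_callrate = sum(fail_cr & !fail_maf),
    removed_both = sum(fail_maf & fail_cr),
    n_out = sum(keep))
  list(gm = subset_sites(gm, keep), report = report, kept = keep)
}

#' Composite genotypic LD between two dosage vectors
#'
#' Squared Pearson correlation of the dosage vectors over jointly
#' non-missing samples. Returns `NA` (treated as "not in LD") when fewer
#' than two joint observations exist or either vector has zero variance.
#'
#' @param d1,d2 integer dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
pairwise_r2 <- function(d1, d2) {
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 2) return(NA_real_)
  x <- d1[ok]; y <- d2[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Greedy sliding-window LD pruning
#'
#' PLINK-style `indep-pairwise` semantics: per scaffold, windows of
#' `window_snps` sites advanced by `step_snps`; within the current
#' window, while any kept pair has r-squared above `r2_max`, the member
#' with the lower MAF is removed (ties broken towards the later
#' position). On completion no surviving within-window pair exceeds the
#' threshold.
#'
#' @param gm a [geno_matrix()] sorted by position within scaffold.
#' @param window_snps window width in SNPs (default 50).
#' @param step_snps window advance in SNPs (default 10).
#' @param r2_max LD threshold (default 0.1).
#' @return list with `gm` (pruned), `kept` (logical index), `n_removed`.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 10, r2_max = 0.1) {
  st <- site_stats(gm)
  maf <- st$maf
  keep <- rep(TRUE, n_sites(gm))
  # windows are defined over the *surviving* sites, so removals shift the
  # window frames; iterate full passes until a fixed point is reached,
  # which guarantees the ld_audit post-condition on the output
  repeat {
    removed_this_pass <- FALSE
    idx_by_scaf <- split(which(keep), gm$sites$scaffold[keep])
    for (idx in idx_by_scaf) {
      ord <- idx[order(gm$sites$pos[idx])]
      n <- length(ord)
      if (n < 2) next
      starts <- unique(seq(1L, max(1L, n - 1L), by = step_snps))
      for (s0 in starts) {
        win <- ord[s0:min(n, s0 + window_snps - 1L)]
        r2m <- window_r2(gm$geno, win)
        w <- length(win)
        for (a in seq_len(w - 1L)) {
          if (!keep[win[a]]) next
          for (b in seq(a + 1L, w)) {
            if (!keep[win[b]]) next
            r2 <- r2m[a, b]
            if (!is.na(r2) && r2 > r2_max) {
              keep[ld_victim(win[a], win[b], maf, gm$sites$pos)] <- FALSE
              removed_this_pass <- TRUE
            }
          }
        }
      }
    }
    if (!removed_this_pass) break
  }
  list(gm = subset_sites(gm, keep), kept = keep, n_removed = sum(!keep))
}

# squared pairwise correlation of the dosage rows in `win`, over jointly
# non-missing samples; zero-variance pairs give NA
window_r2 <- function(geno, win) {
  suppressWarnings(
    stats::cor(t(geno[win, , drop = FALSE]),
               use = "pairwise.complete.obs")^2)
}

# prune victim: lower MAF; tie -> later position
ld_victim <- function(i, j, maf, pos) {
  if (maf[i] < maf[j]) return(i)
  if (maf[j] < maf[i]) return(j)
  if (pos[i] >= pos[j]) i else j
}

#' Audit the LD-pruning post-condition
#'
#' Exhaustively rechecks that no surviving pair within any sliding window
#' exceeds the r-squared threshold.
#'
#' @inheritParams ld_prune
#' @return `TRUE` when the contract holds, otherwise a `data.table` of
#'   violating pairs.
#' @export
ld_audit <- function(gm, window_snps = 50, step_snps = 10, r2_max = 0.1) {
  bad <- list()
  idx_by_scaf <- split(seq_len(n_sites(gm)), gm$sites$scaffold)
  for (idx in idx_by_scaf) {
    ord <- idx[order(gm$sites$pos[idx])]
    n <- length(ord)
    starts <- unique(c(seq(1L, max(1L, n - 1L), by = step_snps)))
    for (s0 in starts) {
      win <- ord[s0:min(n, s0 + window_snps - 1L)]
      if (length(win) < 2) next
      r2m <- window_r2(gm$geno, win)
      hits <- which(upper.tri(r2m) & !is.na(r2m) & r2m > r2_max,
                    arr.ind = TRUE)
      if (nrow(hits))
        bad[[length(bad) + 1L]] <- data.table(
          i = win[hits[, 1]], j = win[hits[, 2]],
          r2 = r2m[hits])
    }
  }
  if (length(bad) == 0) TRUE else data.table::rbindlist(bad)
}

#' Pairwise identity-by-state matrix
#'
#' `IBS(j,k) = 1 - sum_i |x_ij - x_ik| / (2 L_jk)` over the `L_jk` sites
#' called in both samples.
#'
#' @param gm a [geno_matrix()].
#' @return list with `ibs` (symmetric matrix, diagonal 1) and `n_joint`
#'   (jointly called site counts).
#' @export
ibs_matrix <- function(gm) {
  X <- gm$geno
  M <- !is.na(X)
  A <- list(
    (X == 0L & M) * 1,
    (X == 1L & M) * 1,
    (X == 2L & M) * 1)
  # sum over sites of |xi - xj| decomposed by dosage-class cross products
  d01 <- crossprod(A[[1]], A[[2]]); d12 <- crossprod(A[[2]], A[[3]])
  d02 <- crossprod(A[[1]], A[[3]])
  absdiff <- (d01 + t(d01)) + (d12 + t(d12)) + 2 * (d02 + t(d02))
  L <- crossprod(M * 1)
  ibs <- 1 - absdiff / (2 * L)
  diag(ibs) <- 1
  dimnames(ibs) <- list(gm$samples, gm$samples)
  list(ibs = ibs, n_joint = L)
}

#' Sample-level QC: call rate and IBS duplicates
#'
#' Flags samples whose genotyping call rate falls below
#' `call_rate_min`, and for every pair with IBS at or above `ibs_max`
#' (near-duplicates) lists the pair member with the lower call rate for
#' removal. Pairs with no jointly called sites are skipped with a
#' warning.
#'
#' @param gm a [geno_matrix()].
#' @param call_rate_min per-sample call-rate threshold (default 0.95).
#' @param ibs_max IBS duplicate threshold (default 0.90; flagging uses
#'   `>=`).
#' @return `data.table` with columns `sample`, `reason`, `value`
#'   (empty when all samples pass).
#' @export
sample_qc <- function(gm, call_rate_min = 0.95, ibs_max = 0.90) {
  assert_that(n_samples(gm) >= 2, "sample QC needs at least two samples")
  cr <- colMeans(!is.na(gm$geno))
  out <- data.table(sample = character(), reason = character(),
                    value = numeric())
  low <- which(cr < call_rate_min)
  if (length(low))
    out <- rbind(out, data.table(sample = gm$samples[low],
                                 reason = "call_rate", value = cr[low]))
  im <- ibs_matrix(gm)
  if (any(im$n_joint[upper.tri(im$n_joint)] == 0))
    warning("sample pair(s) with no jointly called sites skipped in IBS check")
  pairs <- which(upper.tri(im$ibs) & im$ibs >= ibs_max & im$n_joint > 0,
                 arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      j <- pairs[r, 1]; k <- pairs[r, 2]
      victim <- if (cr[j] <= cr[k]) j else k
      out <- rbind(out, data.table(sample = gm$samples[victim],
                                   reason = "ibs_duplicate",
                                   value = im$ibs[j, k]))
    }
  }
  unique(out)
}
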