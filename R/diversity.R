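#' Per-sample observed heterozygosity
#'
#' Fraction of a sample's called sites that are heterozygous
#' (dosage 1).
#'
#' @param gm a [geno_matrix()].
#' @return named numeric vector over samples. Errors when a sample has no
#'   called sites.
#' @export
observed_heterozygosity <- function(gm) {
  called <- !is.na(gm$geno)
  n_called <- colSums(called)
  if (any(n_called == 0))
    stop2("observed heterozygosity undefined for sample(s): %s",
          paste(gm$samples[n_called == 0], collapse = ", "))
  het <- colSums(gm$geno == 1L, na.rm = TRUE)
  setNames(het / n_called, gm$samples)
}

#' Per-sample inbreeding coefficient
#'
#' Moment estimator of the within-individual inbreeding coefficient from
#' observed versus expected homozygosity (the estimator popularised by
#' GenABEL's `hom` function):
#' `F_j = (O_hom_j - E_hom_j) / (L_j - E_hom_j)` with
#' `E_hom_j = sum over the sample's called sites of (1 - 2 p_i (1 - p_i))`,
#' where `p_i` is the pooled alternate-allele frequency of site `i`
#' computed over the analysis cohort.
#'
#' @param gm a [geno_matrix()].
#' @param p optional externally supplied per-site allele frequencies; by
#'   default pooled frequencies over all samples of `gm`.
#' @return named numeric vector of inbreeding estimates; `NA` (with a
#'   warning) for samples whose denominator is zero.
#' @export
inbreeding_f <- function(gm, p = NULL) {
  called <- !is.na(gm$geno)
  if (is.null(p)) p <- site_stats(gm)$p_alt
  exp_hom_site <- 1 - 2 * p * (1 - p)
  o_hom <- colSums(gm$geno != 1L, na.rm = TRUE)
  e_hom <- colSums(called * exp_hom_site)
  L <- colSums(called)
  denom <- L - e_hom
  f <- ifelse(denom == 0, NA_real_, (o_hom - e_hom) / denom)
  if (anyNA(f))
    warning(sprintf("inbreeding F undefined for sample(s): %s",
                    paste(gm$samples[is.na(f)], collapse = ", ")))
  setNames(f, gm$samples)
}

#' Cohort diversity summary
#'
#' Per-sample observed heterozygosity and inbreeding, with per-population
#' means and standard deviations.
#'
#' @param gm a [geno_matrix()] carrying a population map.
#' @return list with `per_sample` (`data.table`: sample, population, het,
#'   f) and `per_population` (mean/sd of both).
#' @export
diversity_summary <- function(gm) {
  het <- observed_heterozygosity(gm)
  f <- inbreeding_f(gm)
  per_sample <- data.table(
    sample = gm$samples,
    population = if (is.null(gm$populations)) NA_character_
                 else unname(gm$populations),
    het = unname(het), f = unname(f))
  per_population <- per_sample[, list(
    n = .N, het_mean = mean(het), het_sd = sd(het),
    f_mean = mean(f), f_sd = sd(f)), by = "population"]
  list(per_sample = per_sample, per_population = per_population)
}

#' SNP-based relatedness (unadjusted Ajk)
#'
#' The unadjusted genetic-relationship estimator of Yang et al. as
#' implemented by PLINK's `--make-rel`:
#' off-diagonal
#' `A_jk = (1/N) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' and diagonal
#' `A_jj = 1 + (1/N) sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`,
#' where sums run over sites called in both samples (for a pair) or in
#' the sample (diagonal), and sites with `p_i` of 0 or 1 are excluded.
#' Around 0 for unrelated pairs and 1 for self-comparison; pairs above
#' the conventional 0.025 threshold are considered related.
#'
#' @param gm a [geno_matrix()].
#' @param p optional per-site allele frequencies (default: pooled).
#' @param threshold relatedness call threshold (default 0.025).
#' @return list with `ajk` (symmetric matrix), `n_sites` (contributing
#'   site counts per pair), `related_pairs` (`data.table` of off-diagonal
#'   pairs exceeding `threshold`).
#' @export
relatedness_ajk <- function(gm, p = NULL, threshold = 0.025) {
  if (is.null(p)) p <- site_stats(gm)$p_alt
  poly <- p > 0 & p < 1
  if (!any(poly)) stop2("no polymorphic sites for relatedness")
  X <- gm$geno[poly, , drop = FALSE]
  pp <- p[poly]
  M <- !is.na(X)
  denom <- 2 * pp * (1 - pp)
  Z <- (X - 2 * pp) / sqrt(denom)
  Z[!M] <- 0
  num <- crossprod(Z)
  N <- crossprod(M * 1)
  if (any(N[upper.tri(N)] == 0))
    warning("sample pair(s) with no contributing sites: Ajk undefined (NA)")
  ajk <- num / N
  # diagonal by the self-variant formula
  diag_terms <- (X^2 - (1 + 2 * pp) * X + 2 * pp^2) / denom
  diag_terms[!M] <- 0
  diag(ajk) <- 1 + colSums(diag_terms) / diag(N)
  dimnames(ajk) <- list(gm$samples, gm$samples)
  hits <- which(upper.tri(ajk) & !is.na(ajk) & ajk > threshold,
                arr.ind = TRUE)
  related <- data.table(
    sample1 = gm$samples[hits[, 1]], sample2 = gm$samples[hits[, 2]],
    ajk = ajk[hits])
  list(ajk = ajk, n_sites = N, related_pairs = related,
       threshold = threshold)
}

#' Evanno delta-K from clustering log-likelihoods
#'
#' Post-processes replicate log-likelihoods of a model-based clustering
#' run over successive K values (e.g. ADMIXTURE): the second-order rate
#' of change `|L''(K)| = |L'(K+1) - L'(K)|` with `L'(K) = L(K) - L(K-1)`,
#' scaled by the replicate standard deviation: `deltaK = |L''(K)| / sd(L(K))`.
#' The optimum is the interior K maximising deltaK.
#'
#' @param likelihoods `data.frame` with columns `K` and `loglik` (one row
#'   per replicate), or a named list of per-K replicate vectors.
#' @return list with `table` (`data.table`: K, n_rep, mean_l, sd_l,
#'   l_prime, l_doubleprime_abs, delta_k) and `optimum_k`.
#' @export
evanno_delta_k <- function(likelihoods) {
  if (is.list(likelihoods) && !is.data.frame(likelihoods)) {
    likelihoods <- data.table(
      K = rep(as.integer(names(likelihoods)),
              lengths(likelihoods)),
      loglik = unlist(likelihoods, use.names = FALSE))
  }
  lk <- data.table::as.data.table(likelihoods)
  assert_that(all(c("K", "loglik") %in% names(lk)),
              "likelihoods need columns K and loglik")
  tab <- lk[, list(n_rep = .N, mean_l = mean(loglik),
                   sd_l = sd(loglik)), by = "K"]
  setorder(tab, K)
  assert_that(nrow(tab) >= 3, "need at least 3 consecutive K values")
  assert_that(all(diff(tab$K) == 1), "K values must be consecutive")
  n <- nrow(tab)
  lp <- c(NA, diff(tab$mean_l))                       # L'(K), K >= 2
  lpp <- c(NA, abs(diff(lp)[-1]), NA)                 # |L''(K)|, interior K
  dk <- lpp / tab$sd_l
  if (any(!is.na(lpp) & tab$sd_l == 0))
    warning("sd(L(K)) = 0: deltaK undefined at K = ",
            paste(tab$K[!is.na(lpp) & tab$sd_l == 0], collapse = ", "))
  dk[!is.na(dk) & is.infinite(dk)] <- NA
  tab[, c("l_prime", "l_doubleprime_abs", "delta_k") := list(lp, lpp, dk)]
  optimum <- if (all(is.na(dk))) NA_integer_
             else tab$K[which.max(ifelse(is.na(dk), -Inf, dk))]
  list(table = tab[], optimum_k = optimum)
}
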