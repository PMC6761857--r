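#' Genotype matrix container
#'
#' The central data structure of the package: a set of variant sites with
#' their VCF-level annotations, together with a sites-by-samples matrix of
#' alternate-allele dosages and a sample-to-population map.
#'
#' @param sites a `data.table` with at least columns `scaffold` (character),
#'   `pos` (integer, 1-based), `ref`, `alt` (character; `alt` may hold a
#'   comma-separated list for multi-allelic records). Optional columns:
#'   `qual`, `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `DP`.
#' @param geno integer matrix, `nrow(sites)` rows by `length(samples)`
#'   columns, holding alternate-allele dosages in `{0, 1, 2}` with `NA`
#'   for missing genotypes.
#' @param samples character vector of sample identifiers (column order of
#'   `geno`).
#' @param populations named character vector mapping each sample id to a
#'   population label; may be `NULL` when no map is available.
#'
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, geno, samples, populations = NULL) {
  sites <- data.table::as.data.table(sites)
  assert_that(all(c("scaffold", "pos", "ref", "alt") %in% names(sites)),
              "sites must have columns scaffold, pos, ref, alt")
  geno <- as.matrix(geno)
  assert_that(nrow(geno) == nrow(sites),
              "geno has %d rows but sites has %d", nrow(geno), nrow(sites))
  assert_that(ncol(geno) == length(samples),
              "geno has %d columns but %d samples given",
              ncol(geno), length(samples))
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  assert_that(!any(bad), "dosages must be 0, 1, 2 or NA")
  storage.mode(geno) <- "integer"
  colnames(geno) <- samples
  if (!is.null(populations)) {
    assert_that(all(samples %in% names(populations)),
                "populations map does not cover all samples")
    populations <- populations[samples]
  }
  structure(
    list(sites = sites, geno = geno, samples = samples,
         populations = populations),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d sites x %d samples (%d scaffolds)\n",
              n_sites(x), n_samples(x), length(unique(x$sites$scaffold))))
  if (!is.null(x$populations)) {
    tab <- table(x$populations)
    cat("populations:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a `geno_matrix`.
#' @return integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site index or by sample id
#'
#' @param gm a `geno_matrix`.
#' @param idx integer or logical index into the site rows.
#' @return a new `geno_matrix`.
#' @export
subset_sites <- function(gm, idx) {
  geno_matrix(gm$sites[idx], gm$geno[idx, , drop = FALSE],
              gm$samples, gm$populations)
}

#' @rdname subset_sites
#' @param ids character vector of sample ids (or a population name present
#'   in the population map) to retain.
#' @export
subset_samples <- function(gm, ids) {
  if (length(ids) == 1 && !is.null(gm$populations) &&
      !(ids %in% gm$samples) && ids %in% gm$populations) {
    ids <- gm$samples[gm$populations == ids]
  }
  assert_that(all(ids %in% gm$samples), "unknown sample id(s): %s",
              paste(setdiff(ids, gm$samples), collapse = ", "))
  keep <- match(ids, gm$samples)
  geno_matrix(gm$sites, gm$geno[, keep, drop = FALSE],
              gm$samples[keep], gm$populations)
}

#' Per-site observed allele counts
#'
#' Counts alternate and total called alleles per site over non-missing
#' genotypes, and derives major/minor allele counts as used by the pooled
#' heterozygosity statistic.
#'
#' @param gm a `geno_matrix`.
#' @return a `data.table` with columns `alt_count`, `total`, `n_called`,
#'   `n_maj`, `n_min`, `p_alt` (alternate-allele frequency; `NaN` when no
#'   calls).
#' @export
site_allele_counts <- function(gm) {
  called <- !is.na(gm$geno)
  alt <- rowSums(gm$geno, na.rm = TRUE)
  ncall <- rowSums(called)
  tot <- 2L * ncall
  data.table(
    alt_count = as.integer(alt),
    total = as.integer(tot),
    n_called = as.integer(ncall),
    n_maj = as.integer(pmax(alt, tot - alt)),
    n_min = as.integer(pmin(alt, tot - alt)),
    p_alt = alt / tot
  )
}
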