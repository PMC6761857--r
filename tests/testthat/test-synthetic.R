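test_that("Balding-Nichols frequencies: no-drift limit and moments", {
  expect_equal(sample_bn_frequencies(0.3, 0, 4), rep(0.3, 4))
  expect_error(sample_bn_frequencies(0, 0.2, 2), "monomorphic")
  expect_error(sample_bn_frequencies(1, 0.2, 2), "monomorphic")

  set.seed(42)
  draws <- sample_bn_frequencies(0.5, 0.2, 10000)
  expect_true(all(draws >= 0 & draws <= 1))
  # Beta mean = p_anc, variance = F p (1 - p)
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  expect_lt(abs(var(draws) - 0.05) / 0.05, 0.2)
})

test_that("implant_sweep drives in-region sites to the major allele", {
  set.seed(1)
  pos <- seq(100L, 100000L, by = 100L)
  freqs <- runif(length(pos), 0.05, 0.95)
  region <- list(start = 20000L, end = 40000L)

  out <- implant_sweep(freqs, pos, region, 1.0)
  inside <- pos > region$start & pos <= region$end
  expect_true(all(out[inside] %in% c(0, 1)))  # monomorphic, Hp = 0
  expect_identical(out[!inside], freqs[!inside])

  out95 <- implant_sweep(freqs, pos, region, 0.95)
  maj <- pmax(out95[inside], 1 - out95[inside])
  expect_true(all(maj >= 0.95))
  expect_lte(mean(2 * out95[inside] * (1 - out95[inside])),
             2 * 0.95 * 0.05)

  expect_warning(
    implant_sweep(freqs, pos, list(start = 990000L, end = 999000L), 0.9),
    "no sites")
  expect_error(implant_sweep(freqs, pos, region, 0.3), "fixation_level")
})

test_that("sim_config validates intervals and parameters", {
  expect_error(sim_config(scaffolds = c(s1 = 0L)), "positive")
  expect_error(sim_config(F_divergence = 1), "F_divergence")
  expect_error(sim_config(populations = integer()), "population")
  expect_error(
    sim_config(scaffolds = c(s1 = 1000L),
               sweep_regions = data.frame(scaffold = "s1", start = 500,
                                          end = 2000, population = "all",
                                          fixation_level = 0.9)),
    "within their scaffold")
  expect_error(
    sim_config(scaffolds = c(s1 = 10000L), populations = c(only = 10L),
               diff_regions = data.frame(scaffold = "s1", start = 0,
                                         end = 5000, delta_freq = 0.5)),
    "two populations")
})

test_that("generate_cohort: call rate, INFO failure counting, structure", {
  cfg <- sim_config(seed = 11, scaffolds = c(s1 = 2e6L),
                    snp_density = 1 / 2000,
                    populations = c(popA = 10L, popB = 10L),
                    missing_rate = 0, info_fail_fraction = 0.1)
  co <- generate_cohort(cfg)
  gm <- co$geno
  m <- n_sites(gm)

  # missing_rate = 0 -> every genotype called
  expect_false(anyNA(gm$geno))
  expect_true(all(site_stats(gm)$call_rate == 1))

  # ~10% of sites flagged, one named filter each, +-1 site rounding
  expect_lte(abs(nrow(co$truth$fail_sites) - 0.1 * m), 1)
  expect_true(all(co$truth$fail_sites$filter %in%
                    c("QD", "FS", "MQ", "QUAL", "MQRankSum",
                      "ReadPosRankSum")))

  # per-population frequencies are valid and sites live on the scaffold
  expect_true(all(co$truth$pop_freq >= 0 & co$truth$pop_freq <= 1))
  expect_true(all(gm$sites$pos >= 1 & gm$sites$pos <= 2e6))
  expect_true(!is.unsorted(gm$sites$pos))
})

test_that("identical configs give byte-identical output files", {
  cfg <- sim_config(seed = 5, scaffolds = c(s1 = 3e5L, s2 = 2e5L),
                    snp_density = 1 / 1000,
                    populations = c(popA = 6L, popB = 6L),
                    F_divergence = 0.05, missing_rate = 0.1,
                    info_fail_fraction = 0.05)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # different seed changes the VCF
  d3 <- withr::local_tempdir()
  cfg2 <- sim_config(seed = 6, scaffolds = c(s1 = 3e5L, s2 = 2e5L),
                     snp_density = 1 / 1000,
                     populations = c(popA = 6L, popB = 6L),
                     F_divergence = 0.05, missing_rate = 0.1,
                     info_fail_fraction = 0.05)
  generate_cohort(cfg2, d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
    unname(tools::md5sum(file.path(d3, "cohort.vcf")))))
})

test_that("pooled sample frequency converges to the generating frequency", {
  # |p_hat - p| <= 3 binomial SE for nearly all sites as n grows
  cfg <- sim_config(seed = 21, scaffolds = c(s1 = 1e6L),
                    snp_density = 1 / 1000,
                    populations = c(popA = 150L), F_divergence = 0)
  co <- generate_cohort(cfg)
  p <- co$truth$pop_freq[, 1]
  st <- site_stats(co$geno)
  se <- sqrt(p * (1 - p) / (2 * 150))
  frac_within <- mean(abs(st$p_alt - p) <= 3 * se)
  expect_gt(frac_within, 0.99)
})

test_that("HWE null: mean per-sample inbreeding near zero", {
  cfg <- sim_config(seed = 31, scaffolds = c(s1 = 2e6L),
                    snp_density = 1 / 1000,
                    populations = c(popA = 200L), F_divergence = 0)
  co <- generate_cohort(cfg)
  expect_gt(n_sites(co$geno), 1500)
  f <- inbreeding_f(co$geno)
  expect_lt(abs(mean(f)), 0.05)
})

test_that("sweep and differentiation regions shape the frequencies", {
  sweeps <- data.frame(scaffold = "s1", start = 100000, end = 300000,
                       population = "popA", fixation_level = 0.98)
  diffs <- data.frame(scaffold = "s1", start = 600000, end = 800000,
                      delta_freq = 0.8)
  cfg <- sim_config(seed = 41, scaffolds = c(s1 = 1e6L),
                    snp_density = 1 / 1000,
                    populations = c(popA = 15L, popB = 15L),
                    sweep_regions = sweeps, diff_regions = diffs)
  co <- generate_cohort(cfg)
  pos <- co$geno$sites$pos
  fr <- co$truth$pop_freq
  in_sweep <- pos > 100000 & pos <= 300000
  in_diff <- pos > 600000 & pos <= 800000
  expect_true(all(pmax(fr[in_sweep, "popA"],
                       1 - fr[in_sweep, "popA"]) >= 0.98))
  expect_true(all(abs(fr[in_diff, "popA"] - fr[in_diff, "popB"]) >=
                    0.8 - 1e-12))
})
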