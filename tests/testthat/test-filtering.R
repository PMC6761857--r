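test_that("hard filters: boundary semantics exactly as stated", {
  # one failing record per filter, plus exact-boundary records that pass
  gm <- make_gm(matrix(1L, 9, 4),
                QD = c(1.9, 10, 10, 10, 10, 10, 2.0, 10, 10),
                FS = c(5, 60.5, 5, 5, 5, 5, 5, 60.0, 5),
                MQ = c(50, 50, 39.9, 50, 50, 50, 50, 50, 40.0),
                qual = c(100, 100, 100, 29.9, 100, 100, 100, 100, 30.0),
                MQRankSum = c(0, 0, 0, 0, -12.6, 0, 0, 0, -12.5),
                ReadPosRankSum = c(0, 0, 0, 0, 0, -8.1, 0, 0, -8.0))
  res <- apply_hard_filters(gm)
  expect_identical(res$removed$pos, gm$sites$pos[1:6])
  expect_identical(res$removed$reasons,
                   c("QD", "FS", "MQ", "QUAL", "MQRankSum",
                     "ReadPosRankSum"))
  expect_identical(n_sites(res$gm), 3L)  # all boundary records retained
  expect_identical(res$report$n_in, 9L)
  expect_identical(res$report$n_removed + res$report$n_retained,
                   res$report$n_in)
})

test_that("missing INFO annotations never cause removal", {
  gm <- make_gm(matrix(1L, 3, 2), QD = c(NA, 10, 1.0), FS = NA,
                MQ = NA, MQRankSum = NA, ReadPosRankSum = NA)
  res <- apply_hard_filters(gm)
  expect_identical(res$removed$pos, gm$sites$pos[3])
  expect_identical(n_sites(res$gm), 2L)

  # malformed (non-numeric) INFO values error with record context
  gm_bad <- make_gm(matrix(1L, 2, 2))
  gm_bad$sites$FS <- c("5.0", "oops")
  expect_error(apply_hard_filters(gm_bad), "malformed INFO.*s1:200")
})

test_that("hard filters are record-local and idempotent", {
  set.seed(9)
  gm <- random_gm(200, 5)
  gm$sites$QD <- runif(200, 0, 10)          # mixture of pass and fail
  gm$sites$FS <- runif(200, 50, 70)
  res1 <- apply_hard_filters(gm)
  # order-insensitivity: shuffle rows, same removal set
  perm <- sample(200)
  res2 <- apply_hard_filters(subset_sites(gm, perm))
  expect_setequal(paste(res1$removed$scaffold, res1$removed$pos),
                  paste(res2$removed$scaffold, res2$removed$pos))
  # idempotence: re-applying removes nothing
  res3 <- apply_hard_filters(res1$gm)
  expect_identical(res3$report$n_removed, 0L)
})

test_that("depth filter: two-pass mean/SD semantics", {
  # DP = {10,10,10,10,4}: mean 8.8, sd 2.683; DP=4 fails DP >= 5 only
  gm <- make_gm(matrix(1L, 5, 2), DP = c(10, 10, 10, 10, 4))
  res <- apply_depth_filters(gm)
  expect_identical(n_sites(res$gm), 4L)
  expect_identical(res$removed$reasons, "DP_low")
  expect_equal(res$dp_mean, 8.8)
  expect_equal(res$dp_sd, sd(c(10, 10, 10, 10, 4)))

  # degenerate SD: all DP equal -> all retained
  gm2 <- make_gm(matrix(1L, 4, 2), DP = 20)
  expect_identical(n_sites(apply_depth_filters(gm2)$gm), 4L)

  # an extreme outlier among many equal values exceeds mean + 3 sd
  dp <- c(rep(10, 999), 1000)
  mu <- mean(dp); sig <- sd(dp)
  stopifnot(1000 > mu + 3 * sig)  # oracle on the constructed vector
  gm3 <- make_gm(matrix(1L, 1000, 2), DP = dp)
  res3 <- apply_depth_filters(gm3)
  expect_identical(n_sites(res3$gm), 999L)
  expect_identical(res3$removed$reasons, "DP_outlier")

  # missing DP removed with its own reason
  gm4 <- make_gm(matrix(1L, 3, 2), DP = c(100, NA, 100))
  res4 <- apply_depth_filters(gm4)
  expect_identical(res4$removed$reasons, "DP_missing")
})

test_that("restrict_sites drops excluded scaffolds, indels, multi-allelics", {
  gm <- make_gm(matrix(1L, 4, 2),
                scaffold = c("NC_009849.1", "s1", "s1", "s1"),
                ref = c("A", "A", "AT", "A"),
                alt = c("G", "T,G", "A", "C"))
  res <- restrict_sites(gm)
  expect_identical(n_sites(res$gm), 1L)
  expect_identical(res$gm$sites$alt, "C")
  expect_identical(res$removed$reasons,
                   c("excluded_scaffold", "multi_allelic", "indel"))
})

test_that("Ts/Tv classification and error cases", {
  pairs <- data.frame(ref = c("A", "C", "G", "A", "T", "G"),
                      alt = c("G", "T", "A", "C", "A", "C"))
  expect_equal(compute_tstv(pairs), 1.0)  # 3 Ts, 3 Tv
  pairs2 <- data.frame(ref = c("A", "G", "C", "T", "A", "C"),
                       alt = c("G", "A", "T", "C", "T", "G"))
  expect_equal(compute_tstv(pairs2), 2.0)
  expect_error(compute_tstv(data.frame(ref = character(),
                                       alt = character())), "no variants")
  expect_error(compute_tstv(data.frame(ref = "A", alt = "G")),
               "0 transversions")
})

test_that("caller intersection keeps shared keys with second caller's data", {
  gm1 <- make_gm(matrix(0L, 3, 2), pos = c(100L, 200L, 300L),
                 ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  gm2 <- make_gm(matrix(2L, 3, 2), pos = c(200L, 300L, 400L),
                 ref = c("C", "G", "T"), alt = c("T", "A", "C"))
  res <- intersect_callers(gm1, gm2)
  expect_identical(res$sites$pos, c(200L, 300L))
  expect_true(all(res$geno == 2L))  # genotypes from the second call set
})

test_that("cascade removals equal the simulator's truth set exactly", {
  cfg <- sim_config(seed = 17, scaffolds = c(s1 = 1e6L),
                    snp_density = 1 / 1000,
                    populations = c(popA = 8L, popB = 8L),
                    info_fail_fraction = 0.08)
  co <- generate_cohort(cfg)
  fc <- filter_cascade(co$geno)
  expect_setequal(paste(fc$removed$scaffold, fc$removed$pos),
                  paste(co$truth$fail_sites$scaffold,
                        co$truth$fail_sites$pos))
  # reasons match the violated filter recorded in truth
  key <- function(d) d[order(d$pos)]
  rm_ord <- key(fc$removed)
  tr_ord <- key(co$truth$fail_sites)
  expect_identical(rm_ord$reasons, tr_ord$filter)
  # stage conservation at every stage
  expect_true(all(fc$report$n_in ==
                    fc$report$n_removed + fc$report$n_retained))
  # Ts/Tv close to the configured expectation of 2
  expect_gt(fc$tstv_after, 1.6)
  expect_lt(fc$tstv_after, 2.5)
})
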