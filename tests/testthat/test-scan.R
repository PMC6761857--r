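test_that("make_windows enumerates the stated layout", {
  w <- make_windows(c(s = 120000L))
  expect_equal(w$start, c(0, 25000, 50000, 75000, 100000))
  expect_equal(w$end, c(50000, 75000, 100000, 120000, 120000))

  w2 <- make_windows(c(s = 50000L))
  expect_equal(w2$start, c(0, 25000))
  expect_equal(w2$end, c(50000, 50000))

  w3 <- make_windows(c(s = 10000L))
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$end, 10000L)

  expect_error(make_windows(c(s = 0L)), "positive")
  expect_error(make_windows(c(s = 1e5L), size = 10, step = 20), "size >= step")
})

test_that("window_hp: printed-formula hand check and boundary rules", {
  # per-site (n_maj, n_min) = (18,2), (15,5), (12,8) over 10 diploids:
  # Hp = 2 * 45 * 15 / 60^2 = 0.375
  g <- rbind(c(1L, 1L, rep(0L, 8)),
             c(2L, 2L, 1L, rep(0L, 7)),
             c(2L, 2L, 2L, 1L, 1L, rep(0L, 5)))
  gm <- make_gm(g, pos = c(1000L, 2000L, 3000L))
  w <- make_windows(c(s1 = 50000L), 50000L, 25000L)
  res <- window_hp(gm, w)
  expect_equal(nrow(res), 1L)  # second window [25k,50k) has 0 SNPs
  expect_identical(res$sum_nmaj, 45L)
  expect_identical(res$sum_nmin, 15L)
  expect_equal(res$hp, 0.375)

  # balanced counts -> maximum 0.5; monomorphic window -> 0
  g2 <- rbind(rep(1L, 10), rep(1L, 10),
              rep(0L, 10), rep(0L, 10))
  gm2 <- make_gm(g2, pos = c(1000L, 2000L, 30000L, 40000L))
  res2 <- window_hp(gm2, make_windows(c(s1 = 25000L), 25000L, 25000L))
  expect_equal(res2$hp, 0.5)
  gm3 <- make_gm(g2[3:4, , drop = FALSE], pos = c(1000L, 2000L))
  res3 <- window_hp(gm3, make_windows(c(s1 = 25000L), 25000L, 25000L))
  expect_equal(res3$hp, 0)

  # single-SNP windows discarded
  gm4 <- make_gm(rbind(rep(1L, 10)), pos = 1000L)
  expect_equal(nrow(window_hp(gm4, make_windows(c(s1 = 25000L)))), 0L)

  # a site belongs to every window containing it (double counting)
  gm5 <- make_gm(rbind(rep(1L, 4), rep(1L, 4)), pos = c(30000L, 40000L))
  res5 <- window_hp(gm5, make_windows(c(s1 = 75000L)))
  expect_equal(res5$start, c(0, 25000))  # windows [0,50k) and [25k,75k)
})

test_that("Hp is bounded and label-swap invariant", {
  set.seed(14)
  gm <- random_gm(400, 25, missing_rate = 0.1)
  w <- make_windows(c(s1 = 40000L), 5000L, 2500L)
  res <- window_hp(gm, w)
  expect_true(all(res$hp >= 0 & res$hp <= 0.5))
  flipped <- gm
  flipped$geno <- 2L - gm$geno
  expect_equal(window_hp(flipped, w)$hp, res$hp)
})

test_that("z_transform: median-centred sample-SD Z-score", {
  z <- z_transform(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(z[1], (0.1 - 0.3) / sd(c(0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_equal(round(z[1], 4), -1.2649)
  expect_equal(z[3], 0)  # value at the median
  # monotone map preserves ordering
  expect_identical(order(z), order(c(0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_error(z_transform(rep(1, 5)), "zero standard deviation")
  expect_error(z_transform(0.5), "at least two")
})

test_that("empirical_threshold: interpolated quantile and contracts", {
  vals <- 0:999
  expect_equal(empirical_threshold(vals, 0.001, "lower"), 0.999)
  expect_equal(empirical_threshold(vals, 0.001, "upper"),
               quantile(vals, 0.999, type = 7, names = FALSE))
  expect_equal(suppressWarnings(
    empirical_threshold(rep(3.3, 10), 0.01, "lower")), 3.3)
  expect_warning(empirical_threshold(1:10, 0.001), "fewer than one")

  # declared-significant fraction never exceeds tail + 1/n
  set.seed(15)
  for (n in c(500, 2000)) {
    x <- rnorm(n)
    thr <- suppressWarnings(empirical_threshold(x, 0.001, "lower"))
    expect_lte(mean(x <= thr), 0.001 + 1 / n)
  }
})

test_that("Fst site components match an independent transcription", {
  # fixed difference: theta = 1
  cmp <- fst_site_components(10, 1, 0, 10, 0, 0)
  expect_equal(with(cmp, a / (a + b + c)), 1)

  # identical populations: non-positive numerator over a grid
  grid <- expand.grid(p = c(0.1, 0.3, 0.5, 0.7), h = c(0, 0.2, 0.5))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; h <- min(grid$h[i], 2 * min(p, 1 - p))
    cmp <- fst_site_components(12, p, h, 12, p, h)
    expect_lte(cmp$a, 1e-12)
  }

  # random draws against the scalar oracle transcription
  set.seed(16)
  for (i in 1:100) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    p1 <- runif(1); p2 <- runif(1)
    h1 <- runif(1, 0, 2 * min(p1, 1 - p1))
    h2 <- runif(1, 0, 2 * min(p2, 1 - p2))
    got <- fst_site_components(n1, p1, h1, n2, p2, h2)
    want <- wc_oracle(n1, p1, h1, n2, p2, h2)
    expect_equal(unname(unlist(got)), unname(want), tolerance = 1e-12)
  }

  expect_error(fst_site_components(1, 0.5, 0.5, 10, 0.5, 0.5),
               "at least two")
})

test_that("window_fst: fixed difference, null, and drift recovery", {
  # 10 fixed-difference sites in one window -> weighted Fst = 1
  pops <- setNames(rep(c("a", "b"), each = 10), sprintf("S%02d", 1:20))
  g <- matrix(c(rep(0L, 10), rep(2L, 10)), 10, 20, byrow = TRUE)
  gm <- make_gm(g, pos = seq(1000L, 10000L, by = 1000L),
                populations = pops)
  w <- make_windows(c(s1 = 25000L), 25000L, 25000L)
  res <- window_fst(gm, "a", "b", w)
  expect_equal(res$fst, 1.0)

  # identical source populations: window Fst small (null simulation)
  set.seed(18)
  pops2 <- setNames(rep(c("a", "b"), each = 30), sprintf("S%02d", 1:60))
  p <- runif(50, 0.1, 0.9)
  g2 <- matrix(rbinom(50 * 60, 2, rep(p, 60)), 50, 60)
  gm2 <- make_gm(g2, pos = seq_len(50) * 400L, populations = pops2)
  res2 <- window_fst(gm2, "a", "b", make_windows(c(s1 = 20000L),
                                                 20000L, 20000L))
  expect_lte(res2$fst, 0.02)

  # Balding-Nichols drift: estimator recovers the generating F
  cfg <- sim_config(seed = 19, scaffolds = c(s1 = 2e6L),
                    snp_density = 1 / 1000,
                    populations = c(a = 30L, b = 30L), F_divergence = 0.2)
  co <- generate_cohort(cfg)
  big <- make_windows(c(s1 = 2e6L), 2e6L, 2e6L)
  res3 <- window_fst(co$geno, "a", "b", big)
  expect_lt(abs(res3$fst - 0.2), 0.05)
})

test_that("merge_significant: interval union under half-open semantics", {
  w <- data.table::data.table(
    scaffold = "s1", start = c(0L, 25000L, 100000L),
    end = c(50000L, 75000L, 150000L), zhp = c(-3, -2.6, -2.8))
  r <- merge_significant(w, "zhp", "min")
  expect_equal(r$start, c(0, 100000))
  expect_equal(r$end, c(75000, 150000))
  expect_equal(r$extreme_stat, c(-3, -2.8))
  expect_equal(r$n_windows, c(2L, 1L))

  # abutting windows are NOT merged
  w2 <- data.table::data.table(scaffold = "s1", start = c(0L, 50000L),
                               end = c(50000L, 100000L), zhp = c(-3, -2.5))
  expect_equal(nrow(merge_significant(w2)), 2L)

  # single window -> identical region
  w3 <- data.table::data.table(scaffold = "s2", start = 0L, end = 50000L,
                               fst = 0.4)
  r3 <- merge_significant(w3, "fst", "max")
  expect_equal(r3$start, 0L)
  expect_equal(r3$end, 50000L)
  expect_equal(r3$extreme_stat, 0.4)

  # same coordinates on different scaffolds stay separate
  w4 <- data.table::data.table(scaffold = c("s1", "s2"),
                               start = c(0L, 0L), end = c(50000L, 50000L),
                               zhp = c(-3, -3))
  expect_equal(nrow(merge_significant(w4)), 2L)

  # regions in a result set are disjoint and sorted
  set.seed(20)
  starts <- sort(sample(seq(0L, 5e5L, by = 25000L), 12))
  w5 <- data.table::data.table(scaffold = "s1", start = starts,
                               end = starts + 50000L,
                               zhp = runif(12, -4, -2))
  r5 <- merge_significant(w5)
  expect_true(all(diff(r5$start) > 0))
  expect_true(all(r5$start[-1] >= r5$end[-nrow(r5)]))
})

test_that("scan_hp recovers implanted sweeps on a simulated scaffold", {
  sweeps <- data.frame(
    scaffold = "s1", start = c(400000, 1500000), end = c(600000, 1700000),
    population = "all", fixation_level = 0.99)
  cfg <- sim_config(seed = 23, scaffolds = c(s1 = 3e6L),
                    snp_density = 1 / 500,
                    populations = c(popA = 30L), sweep_regions = sweeps)
  co <- generate_cohort(cfg)
  res <- scan_hp(co$geno, cfg$scaffolds, tail_fraction = 0.05)
  hit <- function(s, e) any(res$regions$start < e & res$regions$end > s)
  expect_true(hit(400000, 600000))
  expect_true(hit(1500000, 1700000))
})
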