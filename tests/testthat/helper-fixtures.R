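# fixture builders shared across test files; everything is generated in
# code so no binary data ships with the package

# geno_matrix from a dosage matrix (sites x samples); site metadata filled
# with clean passing INFO values unless overridden
make_gm <- function(dosage, scaffold = "s1", pos = NULL, populations = NULL,
                    ref = "A", alt = "G", qual = 100, QD = 10, FS = 5,
                    MQ = 50, MQRankSum = 0, ReadPosRankSum = 0, DP = 200) {
  dosage <- as.matrix(dosage)
  m <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  samples <- colnames(dosage)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(dosage)))
  sites <- data.table::data.table(
    scaffold = rep_len(scaffold, m), pos = as.integer(pos),
    ref = rep_len(ref, m), alt = rep_len(alt, m),
    qual = as.numeric(rep_len(qual, m)), QD = as.numeric(rep_len(QD, m)),
    FS = as.numeric(rep_len(FS, m)), MQ = as.numeric(rep_len(MQ, m)),
    MQRankSum = as.numeric(rep_len(MQRankSum, m)),
    ReadPosRankSum = as.numeric(rep_len(ReadPosRankSum, m)),
    DP = as.numeric(rep_len(DP, m)))
  geno_matrix(sites, dosage, samples, populations)
}

# random HWE genotype matrix at given allele frequencies (no structure)
random_gm <- function(n_sites, n_samples, p = NULL, seed = 1,
                      missing_rate = 0, populations = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(n_sites, 0.05, 0.95)
  g <- matrix(stats::rbinom(n_sites * n_samples, 2,
                            rep(p, n_samples)), n_sites, n_samples)
  if (missing_rate > 0)
    g[matrix(runif(length(g)) < missing_rate, n_sites, n_samples)] <- NA
  make_gm(g, populations = populations)
}

# the 12-record toy VCF of the filter-cascade acceptance check:
# one record violating each of the six hard filters, one mtDNA record,
# one indel, one tri-allelic record, and three clean records
write_toy_vcf <- function(path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=scafA,length=100000>",
    "##contig=<ID=NC_009849.1,length=16000>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"mr\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"rp\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB")
  info_clean <- "QD=10.0;FS=5.0;MQ=50.0;MQRankSum=0.0;ReadPosRankSum=0.0;DP=200"
  rec <- function(chrom, pos, ref, alt, qual, info, gt1 = "0/1", gt2 = "0/0")
    paste(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT", gt1, gt2,
          sep = "\t")
  body <- c(
    rec("scafA", 100, "A", "G", 100,
        "QD=1.9;FS=5.0;MQ=50.0;MQRankSum=0.0;ReadPosRankSum=0.0;DP=200"),
    rec("scafA", 200, "C", "T", 100,
        "QD=10.0;FS=60.5;MQ=50.0;MQRankSum=0.0;ReadPosRankSum=0.0;DP=200"),
    rec("scafA", 300, "G", "A", 100,
        "QD=10.0;FS=5.0;MQ=39.5;MQRankSum=0.0;ReadPosRankSum=0.0;DP=200"),
    rec("scafA", 400, "T", "C", 29.5, info_clean),
    rec("scafA", 500, "A", "C", 100,
        "QD=10.0;FS=5.0;MQ=50.0;MQRankSum=-12.6;ReadPosRankSum=0.0;DP=200"),
    rec("scafA", 600, "A", "T", 100,
        "QD=10.0;FS=5.0;MQ=50.0;MQRankSum=0.0;ReadPosRankSum=-8.5;DP=200"),
    rec("NC_009849.1", 700, "A", "G", 100, info_clean),
    rec("scafA", 800, "AT", "A", 100, info_clean),
    rec("scafA", 900, "A", "T,G", 100, info_clean, "1/2", "0/1"),
    rec("scafA", 1000, "A", "G", 100, info_clean),
    rec("scafA", 1100, "C", "T", 100, info_clean),
    rec("scafA", 1200, "G", "C", 100, info_clean, "1/1", "0/1"))
  writeLines(c(hdr, body), path)
  path
}

# literal re-transcription of the two-population Weir-Cockerham variance
# components, written independently of fst_site_components (scalar, no
# vectorisation, follows the algebra step by step)
wc_oracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

# brute-force windowed Hp: direct per-window recount, no shared code with
# window_hp
brute_force_hp <- function(gm, windows, min_snps = 2) {
  res <- list()
  for (i in seq_len(nrow(windows))) {
    w <- windows[i]
    idx <- which(gm$sites$scaffold == w$scaffold &
                   gm$sites$pos - 1 >= w$start & gm$sites$pos - 1 < w$end)
    if (length(idx) < min_snps) next
    smaj <- 0; smin <- 0
    for (k in idx) {
      g <- gm$geno[k, ]
      alt <- sum(g, na.rm = TRUE)
      tot <- 2 * sum(!is.na(g))
      smaj <- smaj + max(alt, tot - alt)
      smin <- smin + min(alt, tot - alt)
    }
    res[[length(res) + 1]] <- data.table::data.table(
      scaffold = w$scaffold, start = w$start, end = w$end,
      n_snps = length(idx), hp = 2 * smaj * smin / (smaj + smin)^2)
  }
  data.table::rbindlist(res)
}
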