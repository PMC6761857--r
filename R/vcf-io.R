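#' Write a genotype matrix as VCF v4.2
#'
#' Serialises a [geno_matrix()] to an uncompressed VCF v4.2 text file with
#' INFO fields QD, FS, MQ, MQRankSum, ReadPosRankSum and DP and a GT-only
#' FORMAT. Numeric fields use fixed-format rendering so identical inputs
#' give byte-identical files.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @param scaffold_lengths optional named integer vector used to emit
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, scaffold_lengths = NULL) {
  s <- gm$sites
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    if (!is.null(scaffold_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(scaffold_lengths),
              as.integer(scaffold_lengths)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  num <- function(x) ifelse(is.na(x), ".", fmt_num(x, 2L))
  info <- sprintf("QD=%s;FS=%s;MQ=%s;MQRankSum=%s;ReadPosRankSum=%s;DP=%s",
                  num(s$QD), num(s$FS), num(s$MQ), num(s$MQRankSum),
                  num(s$ReadPosRankSum),
                  ifelse(is.na(s$DP), ".", as.character(as.integer(s$DP))))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", n_sites(gm), n_samples(gm))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[gm$geno[ok] + 1L]
  body <- paste(s$scaffold, s$pos, ".", s$ref, s$alt, num(s$qual), "PASS",
                info, "GT", sep = "\t")
  if (ncol(gt) > 0)
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "wb")  # binary mode: fixed \n line endings
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (plain or bgzipped) with `VariantAnnotation::readVcf` and
#' converts it to a [geno_matrix()]. Diploid GT calls are converted to
#' alternate-allele dosage; genotypes carrying any allele other than 0/1
#' (e.g. at multi-allelic records) and missing calls become `NA`. INFO
#' fields QD, FS, MQ, MQRankSum, ReadPosRankSum, DP are retained when
#' present.
#'
#' @param path VCF file.
#' @param sample_map optional path to a two-column TSV (`sample_id`,
#'   `population`) or a named character vector.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, sample_map = NULL) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  alt_str <- vapply(as(alt, "CharacterList"), paste, "", collapse = ",")
  info <- VariantAnnotation::info(vcf)
  grab <- function(key) {
    if (key %in% names(info)) {
      v <- info[[key]]
      if (is.list(v) || methods::is(v, "List"))
        v <- vapply(v, function(e) if (length(e)) e[[1]] else NA_real_, 0)
      as.numeric(v)
    } else rep(NA_real_, length(vcf))
  }
  sites <- data.table(
    scaffold = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt_str,
    qual = as.numeric(rr$QUAL),
    QD = grab("QD"), FS = grab("FS"), MQ = grab("MQ"),
    MQRankSum = grab("MQRankSum"), ReadPosRankSum = grab("ReadPosRankSum"),
    DP = grab("DP"))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) gt <- matrix(character(), nrow(sites), 0)
  geno <- gt_to_dosage(gt)
  samples <- colnames(gt) %||% character()
  populations <- NULL
  if (!is.null(sample_map)) {
    populations <- if (is.character(sample_map) && length(sample_map) == 1 &&
                       file.exists(sample_map))
      read_sample_map(sample_map) else sample_map
  }
  geno_matrix(sites, geno, samples, populations)
}

# "0/1"-style calls to dosage; anything non-biallelic or missing -> NA
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt))
  if (length(gt)) {
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
    hit <- match(gt, names(map))
    d[] <- unname(map[hit])
  }
  d
}

#' Read / write a sample-to-population map
#'
#' Two-column headered TSV: `sample_id`, `population`.
#'
#' @param path TSV file.
#' @return named character vector (population keyed by sample id).
#' @export
read_sample_map <- function(path) {
  tab <- fread(path, header = TRUE, sep = "\t",
               colClasses = list(character = 1:2))
  assert_that(all(c("sample_id", "population") %in% names(tab)),
              "sample map must have columns sample_id, population")
  assert_that(!anyDuplicated(tab$sample_id),
              "duplicate sample_id in sample map")
  setNames(tab$population, tab$sample_id)
}

#' @rdname read_sample_map
#' @param populations named character vector (names = sample ids).
#' @export
write_sample_map <- function(populations, path) {
  fwrite(data.table(sample_id = names(populations),
                    population = unname(populations)),
         path, sep = "\t")
  invisible(path)
}

# GFF3 writer for synthetic gene tables (0-based half-open in memory,
# 1-based inclusive on disk)
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsweepscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$scaffold, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id, genes$gene_id))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# BED writer (0-based half-open, as in memory)
write_bed <- function(dt, path, name_col = NULL, score_col = NULL) {
  out <- data.table(dt$scaffold, dt$start, dt$end)
  if (!is.null(name_col)) out <- cbind(out, dt[[name_col]])
  if (!is.null(score_col)) out <- cbind(out, fmt_num(dt[[score_col]], 4L))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# write all files of a simulated cohort; returns the path manifest
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  files <- list(
    vcf = p("cohort.vcf"), samples = p("samples.tsv"),
    genes = p("genes.gff3"), scaffolds = p("scaffolds.tsv"),
    sweeps = p("truth_sweeps.bed"), diffs = p("truth_diffs.bed"),
    filter_fail = p("truth_filter_fail.tsv"))
  write_vcf(cohort$geno, files$vcf, cohort$config$scaffolds)
  write_sample_map(cohort$geno$populations, files$samples)
  write_gff3(cohort$genes, files$genes)
  fwrite(data.table(scaffold = names(cohort$config$scaffolds),
                    length = as.integer(cohort$config$scaffolds)),
         files$scaffolds, sep = "\t")
  tr <- cohort$truth
  if (!is.null(tr$sweep_intervals))
    write_bed(tr$sweep_intervals, files$sweeps, name_col = "population")
  else write_bed(data.table(scaffold = character(), start = integer(),
                            end = integer()), files$sweeps)
  if (!is.null(tr$diff_intervals))
    write_bed(tr$diff_intervals, files$diffs, score_col = "delta_freq")
  else write_bed(data.table(scaffold = character(), start = integer(),
                            end = integer()), files$diffs)
  fwrite(tr$fail_sites, files$filter_fail, sep = "\t")
  files
}

#' Read scaffold lengths from a two-column TSV
#'
#' Accepts either a headered TSV with columns `scaffold`, `length` or a
#' headerless FASTA-index-style file whose first two columns are name and
#' length.
#'
#' @param path TSV file.
#' @return named integer vector.
#' @export
read_scaffold_lengths <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("scaffold", first, fixed = TRUE)
  tab <- fread(path, header = has_header, sep = "\t")
  setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
}
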