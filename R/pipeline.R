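#' Pipeline run configuration
#'
#' Collects every threshold of the pipeline with its standard default:
#' hard filters (QD 2, FS 60, MQ 40, QUAL 30, MQRankSum -12.5,
#' ReadPosRankSum -8), depth filter (DP >= 5, within 3 SD), marker QC
#' (MAF 5%, call rate 95%), LD pruning (50 SNPs / step 10 / r2 0.1),
#' sample QC (call rate 95%, IBS 90%), windows (50 kb / 25 kb step),
#' empirical tails (0.1%), and the relatedness threshold (0.025).
#'
#' @param input list with file paths: `vcf`, `samples`, `genes`,
#'   `scaffolds`; or `NULL` when `simulate` is given.
#' @param simulate a [sim_config()] (the cohort is generated in
#'   `outdir/sim`); or `NULL` when `input` is given.
#' @param hp_cohorts named list of population-name vectors defining the
#'   cohorts scanned with Hp; the special value `"all"` means every
#'   sample.
#' @param fst_pops length-2 character vector of population labels for the
#'   Fst contrast, or `NULL` to skip.
#' @param outdir output directory.
#' @param seed integer seed for the run.
#' @param params named list overriding individual defaults (see
#'   `pipeline_defaults()`).
#' @return object of class `run_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            hp_cohorts = list(all = "all"),
                            fst_pops = NULL, outdir = tempfile("sweepscan_"),
                            seed = 1L, params = list()) {
  assert_that(xor(is.null(input), is.null(simulate)),
              "provide exactly one of input or simulate")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(params), names(defaults))
  assert_that(length(unknown) == 0, "unknown parameter(s): %s",
              paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(input = input, simulate = simulate,
                 hp_cohorts = hp_cohorts, fst_pops = fst_pops,
                 outdir = outdir, seed = as.integer(seed),
                 params = defaults),
            class = "run_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    hard_filters = default_hard_filters(),
    min_dp = 5, dp_sd_mult = 3,
    excluded_scaffolds = "NC_009849.1",
    maf_min = 0.05, call_rate_min = 0.95,
    ld_window = 50, ld_step = 10, ld_r2_max = 0.1,
    sample_call_rate_min = 0.95, ibs_max = 0.90,
    window_size = 50000L, window_step = 25000L,
    hp_tail = 0.001, fst_tail = 0.001, min_snps_window = 2L,
    relatedness_threshold = 0.025,
    run_ld_prune = TRUE, run_diversity = TRUE)
}

#' Run the full pipeline
#'
#' Executes the stages in their canonical order: data acquisition
#' (simulation or file input), site-filter cascade, sample QC, diversity
#' statistics on the MAF-filtered LD-pruned panel, pooled-heterozygosity
#' scans per cohort on the MAF-unfiltered panel, windowed Fst between the
#' two configured populations, and gene annotation of candidate regions.
#' Writes per-stage TSV outputs plus a machine-readable `report.json`
#' under `config$outdir` and returns the report.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly identical to the JSON on
#'   disk.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  p <- config$params
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, parameters = p, stages = list())

  # --- stage: data ---------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- generate_cohort(config$simulate, file.path(outdir, "sim"))
    gm <- sim$geno
    genes <- sim$genes
    scaffold_lengths <- config$simulate$scaffolds
    report$stages$data <- list(source = "simulated",
                               n_sites = n_sites(gm),
                               n_samples = n_samples(gm))
  } else {
    inp <- config$input
    gm <- read_vcf(inp$vcf, inp$samples)
    genes <- if (!is.null(inp$genes)) load_genes(inp$genes) else NULL
    scaffold_lengths <- read_scaffold_lengths(inp$scaffolds)
    report$stages$data <- list(source = "files",
                               n_sites = n_sites(gm),
                               n_samples = n_samples(gm))
  }
  pops_used <- unique(c(unlist(config$hp_cohorts), config$fst_pops))
  pops_used <- setdiff(pops_used, "all")
  missing_pops <- setdiff(pops_used, unique(gm$populations))
  assert_that(length(missing_pops) == 0,
              "population(s) not in sample map: %s",
              paste(missing_pops, collapse = ", "))

  # --- stage: site filters -------------------------------------------
  fc <- filter_cascade(gm, p$hard_filters, p$min_dp, p$dp_sd_mult,
                       p$excluded_scaffolds)
  gm <- fc$gm
  write_filter_report(fc$report, file.path(outdir, "filter_report.tsv"))
  report$stages$site_filters <- list(
    report = as.list(split(fc$report$n_removed, fc$report$stage)),
    n_retained = n_sites(gm),
    tstv_before = fc$tstv_before, tstv_after = fc$tstv_after)

  # --- stage: sample QC ----------------------------------------------
  sq <- sample_qc(gm, p$sample_call_rate_min, p$ibs_max)
  if (nrow(sq) > 0) gm <- subset_samples(gm, setdiff(gm$samples, sq$sample))
  report$stages$sample_qc <- list(
    failed_samples = as.list(setNames(sq$reason, sq$sample)),
    n_samples_retained = n_samples(gm))

  # --- stage: diversity (MAF-filtered, LD-pruned panel) --------------
  if (isTRUE(p$run_diversity)) {
    qc <- filter_snps(gm, p$maf_min, p$call_rate_min, apply_maf = TRUE)
    gm_div <- qc$gm
    n_ld_removed <- 0L
    if (isTRUE(p$run_ld_prune)) {
      pr <- ld_prune(gm_div, p$ld_window, p$ld_step, p$ld_r2_max)
      gm_div <- pr$gm
      n_ld_removed <- pr$n_removed
    }
    div <- diversity_summary(gm_div)
    rel <- relatedness_ajk(gm_div, threshold = p$relatedness_threshold)
    fwrite(div$per_sample, file.path(outdir, "diversity_per_sample.tsv"),
           sep = "\t")
    fwrite(data.table(sample = rownames(rel$ajk), rel$ajk),
           file.path(outdir, "relatedness_ajk.tsv"), sep = "\t")
    report$stages$diversity <- list(
      marker_qc = qc$report, n_ld_removed = n_ld_removed,
      n_sites_panel = n_sites(gm_div),
      per_population = lapply(seq_len(nrow(div$per_population)), function(i)
        as.list(div$per_population[i])),
      n_related_pairs = nrow(rel$related_pairs))
  }

  # --- stage: Hp scans (call-rate-only panel per cohort) -------------
  hp_out <- list()
  for (cname in names(config$hp_cohorts)) {
    members <- config$hp_cohorts[[cname]]
    gm_c <- if (identical(members, "all")) gm else
      subset_samples(gm, gm$samples[gm$populations %in% members])
    qc_c <- filter_snps(gm_c, apply_maf = FALSE,
                        call_rate_min = p$call_rate_min)
    scan <- scan_hp(qc_c$gm, scaffold_lengths, p$window_size,
                    p$window_step, p$hp_tail, p$min_snps_window)
    pref <- file.path(outdir, paste0("hp_", cname))
    fwrite(scan$windows, paste0(pref, "_windows.tsv"), sep = "\t")
    write_bed(scan$regions, paste0(pref, "_regions.bed"),
              score_col = "extreme_stat")
    ann <- if (!is.null(genes) && nrow(genes))
      intersect_regions_genes(scan$regions, genes) else NULL
    bg <- if (!is.null(ann)) background_genes(scan$windows, genes) else NULL
    if (!is.null(ann)) {
      writeLines(ann$genes, paste0(pref, "_genes.txt"))
      writeLines(bg, paste0(pref, "_background_genes.txt"))
    }
    hp_out[[cname]] <- list(
      n_sites_panel = n_sites(qc_c$gm),
      n_windows = nrow(scan$windows),
      zhp_threshold = scan$threshold,
      n_significant_windows = nrow(scan$significant),
      n_regions = nrow(scan$regions),
      n_genes = if (is.null(ann)) NA_integer_ else ann$n_unique_genes,
      n_regions_with_genes = if (is.null(ann)) NA_integer_
                             else ann$n_regions_with_genes,
      n_background_genes = if (is.null(bg)) NA_integer_ else length(bg))
  }
  report$stages$hp_scans <- hp_out

  # --- stage: Fst scan ------------------------------------------------
  if (!is.null(config$fst_pops)) {
    qc_f <- filter_snps(gm, apply_maf = FALSE,
                        call_rate_min = p$call_rate_min)
    scan <- scan_fst(qc_f$gm, config$fst_pops[1], config$fst_pops[2],
                     scaffold_lengths, p$window_size, p$window_step,
                     p$fst_tail, p$min_snps_window)
    pref <- file.path(outdir, "fst")
    fwrite(scan$windows, paste0(pref, "_windows.tsv"), sep = "\t")
    write_bed(scan$regions, paste0(pref, "_regions.bed"),
              score_col = "extreme_stat")
    ann <- if (!is.null(genes) && nrow(genes))
      intersect_regions_genes(scan$regions, genes) else NULL
    if (!is.null(ann)) writeLines(ann$genes, paste0(pref, "_genes.txt"))
    report$stages$fst <- list(
      pops = config$fst_pops,
      n_sites_panel = n_sites(qc_f$gm),
      n_windows = nrow(scan$windows),
      fst_threshold = scan$threshold,
      n_significant_windows = nrow(scan$significant),
      n_regions = nrow(scan$regions),
      n_genes = if (is.null(ann)) NA_integer_ else ann$n_unique_genes)
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
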