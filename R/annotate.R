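#' Load gene features from GFF3 or BED
#'
#' Reads gene-type features from a GFF3 file (1-based inclusive on disk)
#' or intervals from a BED file (0-based half-open) and converts them to
#' the package's internal 0-based half-open convention. Features are
#' sorted by (scaffold, start); duplicated gene identifiers are rejected.
#'
#' @param path annotation file; format chosen by extension (`.gff`,
#'   `.gff3` or `.bed`) unless `format` is given.
#' @param format `"gff3"`, `"bed"` or `NULL` (auto).
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return `data.table` with columns `gene_id`, `scaffold`, `start`
#'   (0-based), `end` (exclusive), `strand`.
#' @export
load_genes <- function(path, format = NULL, feature_type = "gene") {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
              else if (ext == "bed") "bed"
              else stop2("cannot infer annotation format from '%s'", path)
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature_type]
    if (length(gr) == 0) {
      warning("no gene features loaded from ", path)
      return(data.table(gene_id = character(), scaffold = character(),
                        start = integer(), end = integer(),
                        strand = character()))
    }
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids) || anyNA(ids))
      stop2("GFF3 gene features must carry an ID (or Name) attribute")
    genes <- data.table(
      gene_id = as.character(ids),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- gr$name
    if (is.null(ids))
      ids <- sprintf("interval_%05d", seq_along(gr))
    genes <- data.table(
      gene_id = as.character(ids),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # import.bed converts to 1-based
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  }
  if (nrow(genes) == 0) {
    warning("no gene features loaded from ", path)
    return(genes)
  }
  assert_that(all(genes$end > genes$start),
              "gene with end <= start after coordinate conversion")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  assert_that(length(dup) == 0, "duplicated gene_id(s): %s",
              paste(unique(dup), collapse = ", "))
  setorder(genes, scaffold, start)
  genes[]
}

# internal half-open intervals -> GRanges (1-based inclusive)
intervals_to_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$scaffold,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end))
}

#' Intersect candidate regions with gene features
#'
#' Reports a gene for a region iff they share at least one bp (half-open
#' interval semantics, matching the default of bedtools intersect).
#'
#' @param regions `data.table` with `scaffold`, `start`, `end` (0-based
#'   half-open), e.g. from [merge_significant()].
#' @param genes gene table from [load_genes()].
#' @return list with `pairs` (`data.table`: region index, region
#'   coordinates, gene_id), `genes` (unique overlapping gene ids),
#'   `n_regions_with_genes`, `n_unique_genes`, and
#'   `per_region_gene_counts`.
#' @export
intersect_regions_genes <- function(regions, genes) {
  regions <- data.table::as.data.table(regions)
  empty <- data.table(region_idx = integer(), scaffold = character(),
                      start = integer(), end = integer(),
                      gene_id = character())
  if (nrow(regions) == 0 || nrow(genes) == 0)
    return(list(pairs = empty, genes = character(),
                n_regions_with_genes = 0L, n_unique_genes = 0L,
                per_region_gene_counts = integer(nrow(regions))))
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(regions),
                                      intervals_to_granges(genes))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pairs <- data.table(region_idx = qi,
                      scaffold = regions$scaffold[qi],
                      start = regions$start[qi], end = regions$end[qi],
                      gene_id = genes$gene_id[si])
  setorder(pairs, scaffold, start, gene_id)
  counts <- tabulate(qi, nbins = nrow(regions))
  list(pairs = pairs,
       genes = sort(unique(pairs$gene_id)),
       n_regions_with_genes = sum(counts > 0),
       n_unique_genes = length(unique(pairs$gene_id)),
       per_region_gene_counts = counts)
}

#' Background gene set over all tested windows
#'
#' Unique genes overlapping at least one window retained in the scan
#' (pre-significance). Because every significant window is a tested
#' window, the significant gene set is always contained in this
#' background set.
#'
#' @param all_windows `data.table` of all retained scan windows
#'   (`scaffold`, `start`, `end`).
#' @param genes gene table from [load_genes()].
#' @return sorted character vector of gene ids.
#' @export
background_genes <- function(all_windows, genes) {
  intersect_regions_genes(all_windows, genes)$genes
}
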