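#' Filter genes for TCR analysis
#'
#' Retains genes that do not overlap any other annotated gene
#' (strand-agnostic interval intersection against the full annotation,
#' including genes that themselves fail other filters) and are at least
#' `min_length` bp long. An expression filter (`rpkm > min_rpkm`) is
#' applied last when requested; genes lacking an expression value are
#' then excluded with a message.
#'
#' @param genes A `GRanges` of all annotated genes with `gene_id` and
#'   (optionally) `rpkm`.
#' @param min_length Minimum gene length in bp (default 1000).
#' @param require_nonoverlapping Drop genes overlapping any other gene
#'   (default `TRUE`).
#' @param min_rpkm Optional expression threshold; genes must satisfy
#'   `rpkm > min_rpkm` strictly.
#' @return The filtered `GRanges`.
#' @export
filter_genes <- function(genes, min_length = 1000L,
                         require_nonoverlapping = TRUE, min_rpkm = NULL) {
  keep <- GenomicRanges::width(genes) >= min_length
  if (require_nonoverlapping)
    keep <- keep & !overlaps_any_other(genes)
  out <- genes[keep]
  if (!is.null(min_rpkm)) {
    no_expr <- is.na(out$rpkm)
    if (any(no_expr))
      message(sum(no_expr), " gene(s) without expression values excluded")
    out <- out[!no_expr & !is.na(out$rpkm)]
    out <- out[out$rpkm > min_rpkm]
  }
  out
}

#' Assign reads to the transcribed or non-transcribed strand
#'
#' An excision-product read derives from the strand that was incised, so a
#' read antisense to the gene (opposite the annotated mRNA strand) reports
#' repair of the transcribed/template strand (TS); a read on the gene's
#' own strand reports the non-transcribed/coding strand (NTS).
#'
#' @param read_strand,gene_strand Character vectors of `"+"`/`"-"`
#'   (recycled).
#' @return Character vector of `"TS"`/`"NTS"`.
#' @export
assign_strand <- function(read_strand, gene_strand) {
  ifelse(as.character(read_strand) != as.character(gene_strand), "TS", "NTS")
}

# Plus-orientation bin index (0..149) of a 1-based midpoint relative to a
# gene [gstart, gend]: 25 upstream 80-bp flank bins, 100 body bins with
# floor-based edges (final base clamps to body bin 99), 25 downstream
# flank bins. NA outside gene +/- 2kb.
plus_bin_index <- function(m1, gstart, gend) {
  len <- gend - gstart + 1L
  idx <- rep(NA_integer_, length(m1))
  up <- m1 < gstart & m1 >= gstart - 2000L
  idx[up] <- (m1[up] - gstart[up] + 2000L) %/% 80L
  body <- m1 >= gstart & m1 <= gend
  idx[body] <- 25L + pmin((100L * (m1[body] - gstart[body])) %/% len[body], 99L)
  down <- m1 > gend & m1 <= gend + 2000L
  idx[down] <- 125L + (m1[down] - gend[down] - 1L) %/% 80L
  idx
}

# 1-based midpoint of read intervals under the BED-convention rule
# floor((start0 + end0)/2).
read_midpoint1 <- function(reads) {
  (GenomicRanges::start(reads) - 1L + GenomicRanges::end(reads)) %/% 2L + 1L
}

#' Unit-gene TS/NTS meta-profile
#'
#' Scales every retained gene to a common 150-bin axis — 25 upstream 2-kb
#' flank bins (80 bp each), 100 gene-body bins (length/100 bp each) and 25
#' downstream flank bins — oriented 5' to 3' along transcription (bin 1 is
#' always 2 kb upstream of the TSS). Each read is assigned to exactly one
#' bin by its midpoint; per-gene per-bin
#' `RPKM = count * 1e9 / (bin_bp * total_mapped_reads)`; the profile is
#' the arithmetic mean over genes, accumulated separately for TS and NTS
#' reads. Flank bins lying beyond a chromosome end are recorded as missing
#' and excluded from the mean; flank regions overlapping a neighbouring
#' retained gene's region are counted for both genes and tallied.
#'
#' @param reads A `GRanges` of mapped reads.
#' @param genes Filtered genes (see [filter_genes()]).
#' @param total_mapped_reads Library size used for RPKM (defaults to
#'   `length(reads)`).
#' @return An object of class `xr_unit_gene_profile`: `ts`/`nts` mean
#'   vectors (length 150), per-gene matrices `ts_mat`/`nts_mat`,
#'   `n_genes`, per-bin contributing-gene counts, and a
#'   `flank_double_counted` tally.
#' @export
unit_gene_profile <- function(reads, genes, total_mapped_reads = length(reads)) {
  if (length(genes) == 0L) stop("no genes after filtering", call. = FALSE)
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0", call. = FALSE)
  counts <- bin_read_counts(reads, genes)
  n_genes <- length(genes)
  len <- GenomicRanges::width(genes)
  bin_bp <- matrix(80, nrow = n_genes, ncol = 150)
  bin_bp[, 26:125] <- matrix(rep(len / 100, 100), nrow = n_genes)

  build <- function(cls) {
    mat <- matrix(0, nrow = n_genes, ncol = 150)
    sub <- counts$tab[counts$tab$cls == cls, ]
    mat[cbind(sub$gene, sub$bin + 1L)] <- sub$N
    mat <- mat * 1e9 / (bin_bp * total_mapped_reads)
    mat[counts$missing_bins] <- NA_real_
    mat
  }
  ts_mat <- build("TS"); nts_mat <- build("NTS")
  structure(list(
    ts = colMeans(ts_mat, na.rm = TRUE),
    nts = colMeans(nts_mat, na.rm = TRUE),
    ts_mat = ts_mat, nts_mat = nts_mat,
    n_genes = n_genes,
    genes_per_bin = colSums(!counts$missing_bins),
    flank_double_counted = counts$flank_double_counted,
    total_mapped_reads = total_mapped_reads),
    class = "xr_unit_gene_profile")
}

# Midpoint-in-bin counts for reads over gene +/- 2kb regions.
bin_read_counts <- function(reads, genes) {
  m1 <- read_midpoint1(reads)
  mid <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                IRanges::IRanges(m1, width = 1L),
                                strand = GenomicRanges::strand(reads))
  regions <- suppressWarnings(GenomicRanges::resize(
    genes, GenomicRanges::width(genes) + 4000L, fix = "center"))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(mid, regions, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits); g <- S4Vectors::subjectHits(hits)
  gstart <- GenomicRanges::start(genes)[g]
  gend <- GenomicRanges::end(genes)[g]
  gstrand <- as.character(GenomicRanges::strand(genes))[g]
  bin_plus <- plus_bin_index(m1[q], gstart, gend)
  bin <- ifelse(gstrand == "-", 149L - bin_plus, bin_plus)
  cls <- assign_strand(as.character(GenomicRanges::strand(reads))[q], gstrand)
  tab <- data.table::as.data.table(
    data.frame(gene = g, bin = bin, cls = cls))[, .N, by = c("gene", "bin", "cls")]
  data.table::setDF(tab)  # plain data.frame: avoids NSE scoping downstream

  # flank bins beyond chromosome ends are missing, not zero
  chrom_len <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomicRanges::seqnames(genes))]
  missing_bins <- matrix(FALSE, nrow = length(genes), ncol = 150)
  for (i in seq_along(genes)) {
    s <- GenomicRanges::start(genes)[i]; e <- GenomicRanges::end(genes)[i]
    up_edges <- s - 2000L + 80L * (0:24)          # bin start coords, left flank
    up_ok <- up_edges >= 1L
    down_edges <- e + 80L * (1:25)                # bin end coords, right flank
    down_ok <- is.na(chrom_len[i]) | down_edges <= chrom_len[i]
    miss_plus <- c(!up_ok, rep(FALSE, 100), !down_ok)
    if (as.character(GenomicRanges::strand(genes))[i] == "-")
      miss_plus <- rev(miss_plus)
    missing_bins[i, ] <- miss_plus
  }
  n_multi <- sum(table(q) > 1L)
  list(tab = tab, missing_bins = missing_bins, flank_double_counted = n_multi)
}

#' @export
print.xr_unit_gene_profile <- function(x, ...) {
  cat(sprintf("xr_unit_gene_profile: %d genes, %d mapped reads\n",
              x$n_genes, x$total_mapped_reads))
  cat(sprintf("  body means: TS %.3g, NTS %.3g (TS/NTS %.3f)\n",
              mean(x$ts[26:125], na.rm = TRUE),
              mean(x$nts[26:125], na.rm = TRUE),
              body_ts_nts_ratio(x)))
  invisible(x)
}

#' Gene-body TS/NTS repair ratio of a unit-gene profile
#'
#' Ratio of means over the 100 gene-body bins (not a mean of per-bin
#' ratios, so near-zero bins cannot dominate).
#'
#' @param profile An `xr_unit_gene_profile`.
#' @return The dimensionless ratio; `NA` if the NTS body mean is zero.
#' @export
body_ts_nts_ratio <- function(profile) {
  stopifnot(inherits(profile, "xr_unit_gene_profile"))
  ts <- mean(profile$ts[26:125], na.rm = TRUE)
  nts <- mean(profile$nts[26:125], na.rm = TRUE)
  if (!is.finite(nts) || nts == 0) return(NA_real_)
  ts / nts
}

#' Per-gene Log2(TS/NTS) from gene-body read counts
#'
#' Counts reads whose midpoints fall inside each gene body, split by
#' strand class, and reports `log2((ts + c)/(nts + c))` with pseudocount
#' `c`. Computed over every supplied gene — the genome-wide Log2(TS/NTS)
#' distribution uses all annotated genes, unfiltered.
#'
#' @param reads A `GRanges` of mapped reads.
#' @param genes A `GRanges` of genes.
#' @param pseudocount Pseudocount `c > 0` (default 1).
#' @return A `data.frame` with `gene_id`, `ts_count`, `nts_count`,
#'   `length`, `log2_ratio`.
#' @export
log2_ts_nts_per_gene <- function(reads, genes, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  m1 <- read_midpoint1(reads)
  mid <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                                IRanges::IRanges(m1, width = 1L))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(mid, genes, ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits); g <- S4Vectors::subjectHits(hits)
  cls <- assign_strand(as.character(GenomicRanges::strand(reads))[q],
                       as.character(GenomicRanges::strand(genes))[g])
  ts <- tabulate(g[cls == "TS"], nbins = length(genes))
  nts <- tabulate(g[cls == "NTS"], nbins = length(genes))
  data.frame(gene_id = genes$gene_id,
             ts_count = ts, nts_count = nts,
             length = GenomicRanges::width(genes),
             log2_ratio = log2((ts + pseudocount) / (nts + pseudocount)),
             stringsAsFactors = FALSE)
}

#' TCR time-course as mean Log2(TS/NTS)
#'
#' Summarizes a series of XR-seq samples against one shared filtered gene
#' set: per sample, the mean of per-gene `log2((TS + c)/(NTS + c))` over
#' the filtered genes. Using a single gene set for every time point is the
#' comparability contract; times must be strictly increasing.
#'
#' @param samples Named or unnamed list; each element is
#'   `list(time = <numeric>, reads = <GRanges>)`.
#' @param genes The shared filtered gene set.
#' @param pseudocount Pseudocount for the per-gene ratios.
#' @return A `data.frame` with `time`, `mean_log2_ts_nts`, `n_genes`,
#'   ordered by time.
#' @export
tcr_timecourse <- function(samples, genes, pseudocount = 1) {
  times <- vapply(samples, function(s) as.numeric(s$time), numeric(1))
  if (anyDuplicated(times) || is.unsorted(sort(times), strictly = TRUE))
    stop("sample times must be unique", call. = FALSE)
  ord <- order(times)
  rows <- lapply(samples[ord], function(s) {
    per_gene <- log2_ts_nts_per_gene(s$reads, genes, pseudocount)
    data.frame(time = as.numeric(s$time),
               mean_log2_ts_nts = mean(per_gene$log2_ratio),
               n_genes = nrow(per_gene))
  })
  do.call(rbind, rows)
}

#' Export TCR results as TSV
#'
#' @param profile An `xr_unit_gene_profile`.
#' @param path Output TSV.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "xr_unit_gene_profile"))
  utils::write.table(
    data.frame(bin = 1:150,
               region = rep(c("upstream", "body", "downstream"), c(25, 100, 25)),
               ts_mean = profile$ts, nts_mean = profile$nts,
               n_genes = profile$genes_per_bin),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
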