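#' Place annotated genes on a synthetic genome
#'
#' Places `n_genes` genes: regular isolated genes of length
#' `gene_length_range`, a configurable number of sub-1-kb genes (which fail
#' the minimum-length gene filter), and a configurable number of antisense
#' overlapping gene pairs (which fail the non-overlap filter). Loci are
#' separated by at least `intergenic_min` bases; strands are assigned at
#' random; per-gene expression is drawn from `config$expression_law`.
#'
#' @param genome A [Biostrings::DNAStringSet] from [make_genome()].
#' @param config An [sim_config()] object.
#' @return A [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `rpkm` and `class` (`"regular"`, `"short"` or `"overlap"`).
#' @export
place_genes <- function(genome, config) {
  stopifnot(inherits(config, "xr_sim_config"))
  set.seed(config$seed + 1L)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (config$n_genes == 0L)
    return(empty_gene_set(genome))

  n_regular <- config$n_genes - config$n_short_genes - 2L * config$n_overlap_pairs
  # locus = footprint reserved on the genome; pairs reserve one joint locus
  locus_kind <- c(rep("regular", n_regular),
                  rep("short", config$n_short_genes),
                  rep("pair", config$n_overlap_pairs))

  occupied <- lapply(chrom_len, function(...) IRanges::IRanges())
  rows <- vector("list", length(locus_kind))
  max_attempts <- 200L * length(locus_kind) + 1000L
  attempts <- 0L
  gr_min <- config$gene_length_range[1]
  gr_max <- config$gene_length_range[2]

  for (i in seq_along(locus_kind)) {
    kind <- locus_kind[i]
    if (kind == "regular") {
      len <- sample(gr_min:gr_max, 1L)
      width <- len
    } else if (kind == "short") {
      len <- sample(300:999, 1L)
      width <- len
    } else {
      len1 <- sample(gr_min:gr_max, 1L)
      len2 <- sample(gr_min:gr_max, 1L)
      offset <- len1 %/% 2L   # second gene starts halfway into the first
      width <- max(len1, offset + len2)
    }
    placed <- FALSE
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", length(locus_kind), " gene loci with ",
             "intergenic_min = ", config$intergenic_min,
             " on a ", sum(chrom_len), " bp genome: genome too small",
             call. = FALSE)
      chrom <- sample(names(chrom_len), 1L, prob = chrom_len)
      if (chrom_len[chrom] < width + 2L) next
      start <- sample.int(chrom_len[chrom] - width + 1L, 1L)
      cand <- IRanges::IRanges(start = max(1L, start - config$intergenic_min),
                               end = min(chrom_len[chrom],
                                         start + width - 1L + config$intergenic_min))
      if (length(IRanges::findOverlaps(cand, occupied[[chrom]])) > 0L) next
      occupied[[chrom]] <- c(occupied[[chrom]],
                             IRanges::IRanges(start, width = width))
      strand1 <- sample(c("+", "-"), 1L)
      if (kind == "pair") {
        rows[[i]] <- data.frame(
          chrom = chrom,
          start = c(start, start + len1 %/% 2L),
          width = c(len1, len2),
          strand = c(strand1, setdiff(c("+", "-"), strand1)),
          class = "overlap")
      } else {
        rows[[i]] <- data.frame(chrom = chrom, start = start, width = len,
                                strand = strand1, class = kind)
      }
      placed <- TRUE
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start, width = tab$width),
    strand = tab$strand,
    seqlengths = chrom_len)
  gr$gene_id <- sprintf("gene%03d", seq_along(gr))
  gr$rpkm <- sample_expression(config$expression_law, length(gr))
  gr$class <- tab$class
  sort(gr, ignore.strand = TRUE)
}

sample_expression <- function(law, n) {
  switch(law$dist,
    lognormal = stats::rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
    constant = rep(law$value, n),
    stop("unknown expression law: ", law$dist, call. = FALSE))
}

empty_gene_set <- function(genome) {
  gr <- GenomicRanges::GRanges(
    seqlengths = stats::setNames(Biostrings::width(genome), names(genome)))
  gr$gene_id <- character(0)
  gr$rpkm <- numeric(0)
  gr$class <- character(0)
  gr
}

#' Flag genes that overlap any other annotated gene
#'
#' Strand-agnostic interval intersection against the full annotation.
#'
#' @param genes A `GRanges` of genes.
#' @return Logical vector, `TRUE` where a gene overlaps at least one other.
#' @export
overlaps_any_other <- function(genes) {
  GenomicRanges::countOverlaps(genes, genes, ignore.strand = TRUE) > 1L
}
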