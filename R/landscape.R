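#' Expected damage-site density along the unit gene
#'
#' Counts damage-motif occurrences (e.g. GG for cisplatin-d(GpG); TT, TC,
#' CT, CC for UV photoproducts) per unit-gene bin, per strand class, on
#' the same 150-bin layout as [unit_gene_profile()]. Both strands are
#' scanned — a GG on the minus strand appears as CC on the plus-strand
#' reference — and each occurrence is assigned to the bin of its 5' base
#' and to TS or NTS by which strand carries it relative to the gene.
#' Values are mean motif sites per bp per gene. This sequence-only
#' expectation explains composition-driven structure in repair profiles,
#' such as reduced cisplatin repair at A-T-rich TSS/TES regions where the
#' GpG dinucleotide needed for adduct formation is rare.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param genes Filtered genes (see [filter_genes()]).
#' @param motifs Character vector of fixed-length motifs over A/C/G/T.
#' @return An object of class `xr_site_density_profile` with `ts`/`nts`
#'   mean density vectors (sites per bp), per-gene matrices, `n_genes`
#'   and the motif set.
#' @export
site_density_profile <- function(genome, genes, motifs) {
  if (length(motifs) == 0L) stop("empty motif set", call. = FALSE)
  if (!all(grepl("^[ACGT]+$", motifs)))
    stop("motifs must be fixed strings over A/C/G/T", call. = FALSE)
  if (length(genes) == 0L) stop("no genes after filtering", call. = FALSE)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))

  occ <- list()
  for (chrom in names(genome)) {
    for (m in motifs) {
      w <- nchar(m)
      plus <- Biostrings::start(Biostrings::matchPattern(m, genome[[chrom]]))
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
      minus <- Biostrings::start(Biostrings::matchPattern(rc, genome[[chrom]]))
      pos <- c(plus, minus + w - 1L)            # 5' base on the carrying strand
      if (length(pos) == 0L) next
      occ[[length(occ) + 1L]] <- data.frame(
        chrom = chrom, pos = pos,
        strand = rep(c("+", "-"), c(length(plus), length(minus))),
        stringsAsFactors = FALSE)
    }
  }
  occ <- do.call(rbind, occ)
  if (is.null(occ))
    occ <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0))
  sites <- GenomicRanges::GRanges(occ$chrom, IRanges::IRanges(occ$pos, width = 1L),
                                  strand = occ$strand, seqlengths = chrom_len)
  counts <- bin_read_counts(sites, genes)
  n_genes <- length(genes)
  len <- GenomicRanges::width(genes)
  bin_bp <- matrix(80, nrow = n_genes, ncol = 150)
  bin_bp[, 26:125] <- matrix(rep(len / 100, 100), nrow = n_genes)
  build <- function(cls) {
    mat <- matrix(0, nrow = n_genes, ncol = 150)
    sub <- counts$tab[counts$tab$cls == cls, ]
    mat[cbind(sub$gene, sub$bin + 1L)] <- sub$N
    mat <- mat / bin_bp
    mat[counts$missing_bins] <- NA_real_
    mat
  }
  ts_mat <- build("TS"); nts_mat <- build("NTS")
  structure(list(
    ts = colMeans(ts_mat, na.rm = TRUE),
    nts = colMeans(nts_mat, na.rm = TRUE),
    ts_mat = ts_mat, nts_mat = nts_mat,
    n_genes = n_genes, motifs = motifs),
    class = "xr_site_density_profile")
}

#' @export
print.xr_site_density_profile <- function(x, ...) {
  cat(sprintf("xr_site_density_profile: motifs {%s}, %d genes\n",
              paste(x$motifs, collapse = ", "), x$n_genes))
  cat(sprintf("  body means (sites/bp): TS %.4f, NTS %.4f\n",
              mean(x$ts[26:125], na.rm = TRUE),
              mean(x$nts[26:125], na.rm = TRUE)))
  invisible(x)
}

#' Observed repair over expected damage-site density
#'
#' Elementwise ratio of a repair unit-gene profile to the sequence-derived
#' site-density profile on the same 150-bin layout, per strand class.
#' Separates repair-driven structure from composition-driven structure: a
#' profile whose dips track motif scarcity flattens after this
#' normalization. Bins with zero (or missing) expected density are
#' reported as missing, never infinite.
#'
#' @param repair An `xr_unit_gene_profile`.
#' @param expected An `xr_site_density_profile`.
#' @return A `data.frame` with `bin`, `region`, `ts_ratio`, `nts_ratio`.
#' @export
observed_over_expected <- function(repair, expected) {
  stopifnot(inherits(repair, "xr_unit_gene_profile"),
            inherits(expected, "xr_site_density_profile"))
  if (length(repair$ts) != length(expected$ts))
    stop("bin layouts differ between repair and expected profiles",
         call. = FALSE)
  ratio <- function(obs, exp) {
    out <- obs / exp
    out[!is.finite(out) | exp == 0] <- NA_real_
    out
  }
  data.frame(bin = 1:150,
             region = rep(c("upstream", "body", "downstream"), c(25, 100, 25)),
             ts_ratio = ratio(repair$ts, expected$ts),
             nts_ratio = ratio(repair$nts, expected$nts))
}

#' @rdname write_profile_tsv
#' @param density An `xr_site_density_profile`.
#' @export
write_site_density_tsv <- function(density, path) {
  stopifnot(inherits(density, "xr_site_density_profile"))
  utils::write.table(
    data.frame(bin = 1:150,
               region = rep(c("upstream", "body", "downstream"), c(25, 100, 25)),
               ts_sites_per_bp = density$ts, nts_sites_per_bp = density$nts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
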