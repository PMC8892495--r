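#' Simulate XR-seq excision-product reads with ground truth
#'
#' Generates stranded excision-product reads carrying one lesion each,
#' placed at damage motifs (GG for cisplatin; TT/TC/CT/CC dipyrimidines for
#' UV photoproducts) with the dual-incision register of the repair
#' nuclease, plus a configurable fraction of background (non-damage)
#' fragments. Transcription-coupled repair is emulated by up-weighting
#' motif sites that lie inside annotated gene bodies on the template
#' strand (the strand opposite the gene's annotated strand) by
#' `1 + (tcr_factor - 1) * f(rpkm)`, where `f` is linear in RPKM and
#' saturates at the gene set's 95th expression percentile.
#'
#' Incision register (read-local, 1-based from the 5' end): for cisplatin
#' the lesion's 5' base sits at position `L - 7` of an `L`-mer, leaving
#' `L - 8` nucleotides 5' of it and 6 nucleotides 3' of the lesion; for UV
#' photoproducts the register is an even mixture of `L - 8` and `L - 7`,
#' which reproduces both the 3-position enrichment window (20-22 of a
#' 28-mer) and the major 5' offset of 19 nt together with the 6-nt 3'
#' offset.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param genes A `GRanges` of genes with `gene_id` and `rpkm` metadata
#'   (from [place_genes()] or [read_annotation()]).
#' @param config An [sim_config()] object.
#' @return A list with elements `reads` (a `GRanges`, names = read ids,
#'   metadata column `seq` holding the lesion-strand sequence) and `truth`
#'   (a `data.frame`; `start`/`end` use the 0-based half-open BED
#'   convention, `lesion_positions` are read-local 1-based, empty for
#'   background reads).
#' @export
simulate_excision_reads <- function(genome, genes, config) {
  stopifnot(inherits(config, "xr_sim_config"))
  set.seed(config$seed + 2L)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  lens <- as.integer(names(config$length_weights))
  min_register <- min(lens) - 8L
  if (min_register < 1L)
    stop("incision geometry error: length ", min(lens),
         " nt is too short for a ", min(lens) - 8L,
         " nt 5' register", call. = FALSE)

  n_background <- round(config$background_fraction * config$n_reads)
  n_damage <- config$n_reads - n_background

  damage <- NULL
  if (n_damage > 0L) {
    sites <- enumerate_damage_sites(genome, config)
    if (nrow(sites) == 0L)
      stop("no damage motif sites found on either strand", call. = FALSE)
    sites$weight <- sites$motif_weight *
      tcr_site_multiplier(sites, genes, config$tcr_factor)
    damage <- sample_damage_reads(sites, chrom_len, config, n_damage)
  }
  background <- NULL
  if (n_background > 0L)
    background <- sample_background_reads(chrom_len, config, n_background)

  tab <- rbind(damage, background)
  if (is.null(tab) || nrow(tab) == 0L)
    stop("n_reads must be positive", call. = FALSE)
  tab$read_id <- sprintf("read%07d", seq_len(nrow(tab)))

  reads <- GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start1, end = tab$end1),
    strand = tab$strand,
    seqlengths = chrom_len)
  names(reads) <- tab$read_id
  reads$seq <- as.character(extract_stranded_seqs(genome, reads))

  truth <- data.frame(
    read_id = tab$read_id,
    chrom = tab$chrom,
    start = tab$start1 - 1L,          # BED convention: 0-based half-open
    end = tab$end1,
    strand = tab$strand,
    lesion_positions = ifelse(tab$is_background, "",
                              paste(tab$register, tab$register + 1L, sep = ",")),
    damage_type = ifelse(tab$is_background, "", config$damage_type),
    source_gene = truth_source_gene(tab, genes, chrom_len),
    is_background = tab$is_background,
    stringsAsFactors = FALSE)

  list(reads = reads, truth = truth)
}

# All damage-motif occurrences on both strands. `g5` is the 1-based genomic
# coordinate of the lesion's 5'-most base *on the lesion strand*: for a
# 2-mer at plus-strand positions [p, p+1] that is p on "+" and p+1 on "-".
enumerate_damage_sites <- function(genome, config) {
  motifs <- damage_motifs(config)
  out <- vector("list", 2L * length(motifs) * length(genome))
  k <- 0L
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (m in names(motifs)) {
      plus <- Biostrings::start(Biostrings::matchPattern(m, subject))
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
      minus <- Biostrings::start(Biostrings::matchPattern(rc, subject))
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        chrom = chrom, g5 = plus, strand = "+", motif = m,
        motif_weight = motifs[[m]])
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        chrom = chrom, g5 = minus + 1L, strand = "-", motif = m,
        motif_weight = motifs[[m]])
    }
  }
  data.table::rbindlist(out[seq_len(k)])
}

# Per-site TCR weight: sites on the template strand inside a gene body get
# 1 + (tcr_factor - 1) * min(rpkm, q95)/q95; elsewhere 1. Template strand
# is the strand opposite the gene's annotated strand.
tcr_site_multiplier <- function(sites, genes, tcr_factor) {
  mult <- rep(1, nrow(sites))
  if (length(genes) == 0L || tcr_factor == 1) return(mult)
  q95 <- stats::quantile(genes$rpkm, 0.95, names = FALSE)
  if (!is.finite(q95) || q95 <= 0) return(mult)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$g5, width = 1L),
                                    strand = sites$strand)
  hits <- GenomicRanges::findOverlaps(site_gr, genes, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  template <- sites$strand[q] != as.character(GenomicRanges::strand(genes))[s]
  q <- q[template]; s <- s[template]
  e <- pmin(genes$rpkm[s], q95) / q95
  m <- 1 + (tcr_factor - 1) * e
  # a site under several genes takes the strongest enhancement
  agg <- tapply(m, q, max)
  mult[as.integer(names(agg))] <- pmax(mult[as.integer(names(agg))], agg)
  mult
}

sample_damage_reads <- function(sites, chrom_len, config, n) {
  lens <- as.integer(names(config$length_weights))
  uv <- config$damage_type != "CISPLATIN"
  pieces <- list(); got <- 0L; guard <- 0L
  while (got < n) {
    guard <- guard + 1L
    if (guard > 50L)
      stop("failed to place requested damage reads inside chromosome bounds",
           call. = FALSE)
    take <- ceiling((n - got) * 1.05) + 100L
    idx <- sample.int(nrow(sites), take, replace = TRUE, prob = sites$weight)
    L <- sample(lens, take, replace = TRUE, prob = config$length_weights)
    register <- if (uv) L - sample(c(8L, 7L), take, replace = TRUE) else L - 7L
    chrom <- sites$chrom[idx]; g5 <- sites$g5[idx]; strand <- sites$strand[idx]
    plus <- strand == "+"
    start1 <- ifelse(plus, g5 - (register - 1L), g5 + (register - 1L) - L + 1L)
    end1 <- start1 + L - 1L
    ok <- start1 >= 1L & end1 <= chrom_len[chrom]
    piece <- data.frame(chrom = chrom, start1 = start1, end1 = end1,
                        strand = strand, register = register,
                        is_background = FALSE,
                        stringsAsFactors = FALSE)[ok, , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- piece
    got <- got + nrow(piece)
  }
  out <- do.call(rbind, pieces)[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_background_reads <- function(chrom_len, config, n) {
  lens <- as.integer(names(config$length_weights))
  L <- sample(lens, n, replace = TRUE, prob = config$length_weights)
  chrom <- sample(names(chrom_len), n, replace = TRUE, prob = chrom_len)
  start1 <- floor(stats::runif(n) * (chrom_len[chrom] - L)) + 1L
  data.frame(chrom = chrom, start1 = as.integer(start1),
             end1 = as.integer(start1 + L - 1L),
             strand = sample(c("+", "-"), n, replace = TRUE),
             register = NA_integer_, is_background = TRUE,
             stringsAsFactors = FALSE)
}

# Gene whose body contains the lesion's genomic position (NA for
# background or intergenic lesions; first gene on ties).
truth_source_gene <- function(tab, genes, chrom_len) {
  src <- rep(NA_character_, nrow(tab))
  dmg <- which(!tab$is_background)
  if (length(dmg) == 0L || length(genes) == 0L) return(src)
  g5 <- ifelse(tab$strand[dmg] == "+",
               tab$start1[dmg] + tab$register[dmg] - 1L,
               tab$end1[dmg] - tab$register[dmg] + 1L)
  les <- GenomicRanges::GRanges(tab$chrom[dmg],
                                IRanges::IRanges(g5, width = 1L),
                                seqlengths = chrom_len)
  hits <- GenomicRanges::findOverlaps(les, genes, ignore.strand = TRUE,
                                      select = "first")
  src[dmg] <- ifelse(is.na(hits), NA_character_, genes$gene_id[hits])
  src
}

#' Extract read sequences in read-strand orientation
#'
#' Slices each read's interval from its chromosome and reverse-complements
#' minus-strand reads, so that sequences read 5' to 3' on the strand the
#' read derives from.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param reads A `GRanges` of read intervals with strand.
#' @return A [Biostrings::DNAStringSet] parallel to `reads`.
#' @export
extract_stranded_seqs <- function(genome, reads) {
  out <- Biostrings::DNAStringSet(rep("", length(reads)))
  for (chrom in unique(as.character(GenomicRanges::seqnames(reads)))) {
    if (!chrom %in% names(genome))
      stop("chromosome '", chrom, "' not present in the genome", call. = FALSE)
    i <- which(as.character(GenomicRanges::seqnames(reads)) == chrom)
    at <- IRanges::IRanges(GenomicRanges::start(reads)[i],
                           GenomicRanges::end(reads)[i])
    out[i] <- Biostrings::extractAt(genome[[chrom]], at)
  }
  minus <- as.character(GenomicRanges::strand(reads)) == "-"
  if (any(minus)) out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- names(reads)
  out
}
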