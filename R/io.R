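#' Read and write genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that enforce unique record names and
#' uppercase sequence storage. Gzipped files are handled transparently.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  # keep the leading word of each header, as aligners do
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate FASTA headers: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "),
         call. = FALSE)
  if (any(Biostrings::width(genome) == 0))
    stop("empty FASTA record(s)", call. = FALSE)
  # DNAStringSet normalizes case on construction; force for safety
  Biostrings::DNAStringSet(toupper(genome))
}

#' @rdname read_fasta
#' @param genome A [Biostrings::DNAStringSet].
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read gene annotation as a stranded GeneSet
#'
#' Imports BED12 or GFF3 through `rtracklayer`. GFF3 1-based closed
#' coordinates are converted to the internal convention on import; BED
#' 0-based half-open likewise. Genes with undefined strand are rejected:
#' strand is essential for calling TS/NTS repair.
#'
#' @param path Annotation file (optionally gzipped).
#' @param dialect `"BED12"` or `"GFF3"`.
#' @return A `GRanges` with metadata columns `gene_id` and `rpkm`
#'   (`NA` until joined with [join_expression()]).
#' @export
read_annotation <- function(path, dialect = c("BED12", "GFF3")) {
  dialect <- match.arg(dialect)
  if (dialect == "BED12") {
    gr <- rtracklayer::import(path, format = "bed")
    gr$gene_id <- gr$name
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "gene"]
    gr$gene_id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  }
  if (any(is.na(gr$gene_id)) || anyDuplicated(gr$gene_id))
    stop("gene records must carry unique identifiers", call. = FALSE)
  if (any(as.character(GenomicRanges::strand(gr)) == "*"))
    stop("gene(s) with undefined strand: ",
         paste(utils::head(gr$gene_id[
           as.character(GenomicRanges::strand(gr)) == "*"], 5), collapse = ", "),
         "; strand is required to resolve TS/NTS", call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  keep <- intersect(c("gene_id", "rpkm", "class"), colnames(mc))
  S4Vectors::mcols(gr) <- mc[, keep, drop = FALSE]
  if (is.null(gr$rpkm)) gr$rpkm <- NA_real_
  gr
}

#' Write genes as BED12 or GFF3
#'
#' Single-block BED12 records (thickStart/thickEnd unused, set to the gene
#' span) or GFF3 `gene` features carrying `ID`.
#'
#' @param genes A `GRanges` with `gene_id`.
#' @param path Output file.
#' @export
write_genes_bed12 <- function(genes, path) {
  gr <- granges_only(genes)
  gr$name <- genes$gene_id
  gr$thick <- IRanges::ranges(gr)
  gr$blocks <- methods::as(IRanges::IRanges(1L, GenomicRanges::width(gr)),
                           "IRangesList")
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_genes_bed12
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- granges_only(genes)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$source <- "xrseqr"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

granges_only <- function(gr) {
  out <- GenomicRanges::granges(gr)
  names(out) <- NULL
  out
}

#' Read/write a per-gene expression table
#'
#' Two-column TSV: `gene_id`, `rpkm`.
#'
#' @param path TSV path (optionally gzipped).
#' @return `read_expression`: a `data.frame` with `gene_id`, `rpkm`.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rpkm") %in% colnames(tab)))
    stop("expression table must have columns gene_id and rpkm", call. = FALSE)
  tab
}

#' @rdname read_expression
#' @param genes A `GRanges` with `gene_id` and `rpkm`.
#' @export
write_expression <- function(genes, path) {
  utils::write.table(
    data.frame(gene_id = genes$gene_id, rpkm = genes$rpkm),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join expression values onto a gene set
#'
#' @param genes A `GRanges` with `gene_id`.
#' @param expression A `data.frame` from [read_expression()].
#' @return `genes` with its `rpkm` column filled (`NA` where no expression
#'   record exists; such genes are dropped, with a message, by expression
#'   filters downstream).
#' @export
join_expression <- function(genes, expression) {
  genes$rpkm <- expression$rpkm[match(genes$gene_id, expression$gene_id)]
  genes
}

#' Read mapped excision-product reads from BED6
#'
#' Extracts each read's sequence from the named strand of the supplied
#' genome (reverse complement for minus-strand reads). Reads on missing
#' chromosomes are an error; reads outside chromosome bounds are rejected
#' and tallied in `S4Vectors::metadata(reads)$n_rejected`.
#'
#' @param path BED6 path (optionally gzipped).
#' @param genome A [Biostrings::DNAStringSet].
#' @return A `GRanges` with metadata column `seq`.
#' @export
read_reads_bed <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bed")
  chroms <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing) > 0)
    stop("read(s) on chromosome(s) absent from the genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  oob <- GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > lens[chroms]
  n_rejected <- sum(oob)
  if (n_rejected > 0) {
    message(n_rejected, " read(s) outside chromosome bounds rejected")
    gr <- gr[!oob]
  }
  if (!is.null(gr$name) && !anyDuplicated(gr$name) && !any(is.na(gr$name)))
    names(gr) <- gr$name
  GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
  gr$seq <- as.character(extract_stranded_seqs(genome, gr))
  S4Vectors::metadata(gr)$n_rejected <- n_rejected
  gr
}

#' Write reads as BED6 (+ companion FASTA)
#'
#' @param reads A `GRanges` with metadata column `seq`.
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  gr <- granges_only(reads)
  gr$name <- names(reads)
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
write_reads_fasta <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- names(reads)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read/write the simulation truth table
#'
#' @param truth Truth `data.frame` from [simulate_excision_reads()].
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(lesion_positions = "character"))
}

#' Toy-scale unique exact-match read mapper
#'
#' Reports a read if and only if its sequence (or reverse complement)
#' occurs at exactly one genomic locus; multi-locus and zero-locus reads
#' are dropped and tallied. String search uses a precompiled dictionary
#' ([Biostrings::PDict]) per read length. Intended for small synthetic
#' genomes: genomes above `max_genome_bp` are refused with a pointer to a
#' real aligner.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param seqs A named [Biostrings::DNAStringSet] (or named character
#'   vector) of read sequences, each at least 20 nt.
#' @param max_genome_bp Refusal cap (default 10 Mb).
#' @return A `GRanges` of uniquely mapped reads with metadata column `seq`
#'   (read-strand orientation); drop tallies in
#'   `S4Vectors::metadata()$drops` (`unmapped`, `multi`).
#' @export
map_reads_exact <- function(genome, seqs, max_genome_bp = 1e7) {
  if (sum(Biostrings::width(genome)) > max_genome_bp)
    stop("genome exceeds ", max_genome_bp, " bp; this exact-match mapper is ",
         "for toy genomes only - use a real aligner (e.g. bowtie2/bwa) and ",
         "supply uniquely mapped reads as BED", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("read%07d", seq_along(seqs))
  if (any(Biostrings::width(seqs) < 20L))
    stop("reads shorter than 20 nt are not mappable here", call. = FALSE)

  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  widths <- Biostrings::width(seqs)
  hit_list <- list()
  counts <- integer(length(seqs))
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    for (orient in c("+", "-")) {
      pats <- if (orient == "+") seqs[idx] else
        Biostrings::reverseComplement(seqs[idx])
      pd <- Biostrings::PDict(pats)
      for (chrom in names(genome)) {
        mi <- Biostrings::matchPDict(pd, genome[[chrom]])
        n <- S4Vectors::elementNROWS(mi)
        counts[idx] <- counts[idx] + n
        if (sum(n) > 0L) {
          ir <- unlist(mi)
          hit_list[[length(hit_list) + 1L]] <- data.frame(
            read = idx[rep.int(seq_along(n), n)],
            chrom = chrom,
            start = IRanges::start(ir),
            end = IRanges::end(ir),
            strand = orient,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  unique_reads <- which(counts == 1L)
  drops <- c(unmapped = sum(counts == 0L), multi = sum(counts > 1L))
  hits <- do.call(rbind, hit_list)
  hits <- hits[hits$read %in% unique_reads, , drop = FALSE]
  hits <- hits[order(hits$read), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = hits$chrom,
    ranges = IRanges::IRanges(hits$start, hits$end),
    strand = hits$strand,
    seqlengths = chrom_len)
  names(gr) <- names(seqs)[hits$read]
  gr$seq <- as.character(seqs[hits$read])
  S4Vectors::metadata(gr)$drops <- drops
  gr
}
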