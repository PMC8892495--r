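#' Run the synthetic-data generator and write its file set
#'
#' Writes genome FASTA, gene annotation (BED12 and GFF3), expression TSV,
#' reads BED6 plus a companion read-sequence FASTA, the ground-truth TSV
#' and an effective-config YAML into `out_dir`. Re-running the emitted
#' config reproduces the outputs bit-identically.
#'
#' @param config An [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `genome`, `genes`, `reads`, `truth` and
#'   the output `paths`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "xr_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(config)
  genes <- place_genes(genome, config)
  sim <- simulate_excision_reads(genome, genes, config)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    genes_bed = file.path(out_dir, "genes.bed"),
    genes_gff3 = file.path(out_dir, "genes.gff3"),
    expression = file.path(out_dir, "expression.tsv"),
    reads_bed = file.path(out_dir, "reads.bed"),
    reads_fasta = file.path(out_dir, "reads.fa"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "effective_config.yaml"))
  write_fasta(genome, paths$genome)
  write_genes_bed12(genes, paths$genes_bed)
  write_genes_gff3(genes, paths$genes_gff3)
  write_expression(genes, paths$expression)
  write_reads_bed(sim$reads, paths$reads_bed)
  write_reads_fasta(sim$reads, paths$reads_fasta)
  write_truth_tsv(sim$truth, paths$truth)
  write_effective_config(config, paths$config)
  invisible(list(genome = genome, genes = genes, reads = sim$reads,
                 truth = sim$truth, paths = paths))
}

write_effective_config <- function(config, path) {
  x <- unclass(config)
  x$length_weights <- as.list(x$length_weights)
  x$dipyrimidine_weights <- as.list(x$dipyrimidine_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load a simulation config from an effective-config YAML
#'
#' @param path YAML written by [run_simulate()].
#' @return An [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(
    genome_length = x$genome_length, n_chromosomes = x$n_chromosomes,
    gc_content = x$gc_content, n_genes = x$n_genes,
    n_short_genes = x$n_short_genes, n_overlap_pairs = x$n_overlap_pairs,
    gene_length_range = unlist(x$gene_length_range),
    intergenic_min = x$intergenic_min, expression_law = x$expression_law,
    damage_type = x$damage_type, n_reads = x$n_reads,
    tcr_factor = x$tcr_factor, length_weights = unlist(x$length_weights),
    dipyrimidine_weights = unlist(x$dipyrimidine_weights),
    background_fraction = x$background_fraction, seed = x$seed)
}

#' Profile excision products: lengths, base frequencies, incision geometry
#'
#' Computes the length distribution, the position-frequency matrix at the
#' modal (or requested) length, the damage-base enriched window with both
#' incision offsets, and the damage-signature verdict; writes TSVs, a
#' plain-text geometry report and figure files into `out_dir`.
#'
#' @param reads A `GRanges` with `seq` (from [read_reads_bed()] or
#'   [map_reads_exact()]).
#' @param genome A [Biostrings::DNAStringSet] (background composition).
#' @param damage_type `"CPD"`, `"SIX_FOUR"` or `"CISPLATIN"`.
#' @param out_dir Output directory.
#' @param L Read length for the frequency matrix. Defaults to 28 nt — the
#'   length at which excision products are conventionally characterized —
#'   falling back to the modal length when too few 28-mers are present.
#' @param min_ratio Enrichment threshold (default 1.5).
#' @param min_reads Minimum reads of length `L` (default 500).
#' @return Invisibly, a list with `lengths`, `pfm`, `window`, `geometry`,
#'   `signature`.
#' @export
run_profile <- function(reads, genome, damage_type, out_dir, L = NULL,
                        min_ratio = 1.5, min_reads = 500L) {
  if (length(reads) == 0L) stop("empty read set", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ld <- length_distribution(reads)
  if (is.null(L)) {
    n28 <- sum(GenomicRanges::width(reads) == 28L)
    L <- if (n28 >= min_reads) 28L else ld$mode
  }
  pfm <- position_frequency_matrix(reads, L, min_reads = min_reads)
  bg <- base_composition(genome)
  bases <- damage_bases(damage_type)
  window <- enriched_window(pfm, bases, bg, min_ratio)
  geometry <- infer_incision_offsets(window, L)
  signature <- damage_signature_score(pfm, bases, bg, min_ratio)

  write_length_tsv(ld, file.path(out_dir, "length_distribution.tsv"))
  write_pfm_tsv(pfm, file.path(out_dir, sprintf("pfm_%dnt.tsv", L)))
  report <- file.path(out_dir, "geometry_report.txt")
  writeLines(c(
    sprintf("damage_type\t%s", damage_type),
    sprintf("read_length\t%d", L),
    sprintf("n_reads\t%d", pfm$n_reads),
    sprintf("enriched_window\t%s",
            if (length(window)) paste(window, collapse = "-") else "none"),
    sprintf("five_prime_offset\t%s", geometry$five_prime_offset),
    sprintf("three_prime_offset\t%s", geometry$three_prime_offset),
    sprintf("three_prime_rank\t%s", geometry$three_prime_rank),
    sprintf("signature_score\t%.4f", signature$score),
    sprintf("signature_verdict\t%s", signature$verdict)), report)
  save_plot(plot_length_distribution(ld),
            file.path(out_dir, "length_distribution.pdf"))
  save_plot(plot_pfm(pfm), file.path(out_dir, sprintf("pfm_%dnt.pdf", L)))
  invisible(list(lengths = ld, pfm = pfm, window = window,
                 geometry = geometry, signature = signature))
}

#' Run the TCR analysis: filters, unit-gene profile, per-gene ratios
#'
#' Applies the gene filters (non-overlapping, >= 1 kb, optional
#' `rpkm > min_rpkm`), builds the unit-gene TS/NTS meta-profile and the
#' per-gene Log2(TS/NTS) table over all annotated genes, and writes TSVs
#' plus the meta-profile figure into `out_dir`.
#'
#' @param reads A `GRanges` of mapped reads.
#' @param genes A `GRanges` of all annotated genes (with `rpkm` joined if
#'   `min_rpkm` is used).
#' @param out_dir Output directory.
#' @param min_length,min_rpkm Gene filters (see [filter_genes()]).
#' @param pseudocount For per-gene Log2(TS/NTS).
#' @return Invisibly, a list with `filtered_genes`, `profile`,
#'   `body_ratio`, `per_gene`.
#' @export
run_tcr <- function(reads, genes, out_dir, min_length = 1000L,
                    min_rpkm = NULL, pseudocount = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(min_rpkm) && all(is.na(genes$rpkm)))
    stop("min_rpkm set but no expression values are joined to the genes",
         call. = FALSE)
  filtered <- filter_genes(genes, min_length = min_length,
                           require_nonoverlapping = TRUE, min_rpkm = min_rpkm)
  profile <- unit_gene_profile(reads, filtered,
                               total_mapped_reads = length(reads))
  per_gene <- log2_ts_nts_per_gene(reads, genes, pseudocount)
  write_profile_tsv(profile, file.path(out_dir, "unit_gene_profile.tsv"))
  utils::write.table(per_gene, file.path(out_dir, "log2_ts_nts_per_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ratio <- body_ts_nts_ratio(profile)
  writeLines(c(sprintf("n_genes_filtered\t%d", length(filtered)),
               sprintf("body_ts_nts_ratio\t%.4f", ratio),
               sprintf("mean_log2_ts_nts_all_genes\t%.4f",
                       mean(per_gene$log2_ratio))),
             file.path(out_dir, "tcr_report.txt"))
  save_plot(plot_unit_gene_profile(profile),
            file.path(out_dir, "unit_gene_profile.pdf"))
  invisible(list(filtered_genes = filtered, profile = profile,
                 body_ratio = ratio, per_gene = per_gene))
}

#' Run the damage-landscape analysis
#'
#' Builds the sequence-derived expected damage-site density on the
#' unit-gene layout and, when a repair profile is supplied, the
#' observed-over-expected ratio; writes TSVs and the overlay figure.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param genes Filtered genes.
#' @param damage_type Damage type, selects the motif set (GG or the four
#'   dipyrimidines).
#' @param out_dir Output directory.
#' @param repair_profile Optional `xr_unit_gene_profile`.
#' @return Invisibly, a list with `density` and (optionally) `ratio`.
#' @export
run_landscape <- function(genome, genes, damage_type, out_dir,
                          repair_profile = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  motifs <- if (damage_type == "CISPLATIN") "GG" else c("TT", "TC", "CT", "CC")
  density <- site_density_profile(genome, genes, motifs)
  write_site_density_tsv(density, file.path(out_dir, "site_density.tsv"))
  out <- list(density = density)
  if (!is.null(repair_profile)) {
    ratio <- observed_over_expected(repair_profile, density)
    utils::write.table(ratio, file.path(out_dir, "observed_over_expected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    save_plot(plot_landscape_overlay(repair_profile, density),
              file.path(out_dir, "landscape_overlay.pdf"))
    out$ratio <- ratio
  }
  invisible(out)
}

save_plot <- function(p, path, width = 6, height = 4) {
  grDevices::pdf(NULL)  # guard against spawning a default device
  on.exit(grDevices::dev.off(), add = TRUE)
  suppressMessages(ggplot2::ggsave(path, p, width = width, height = height))
  invisible(path)
}
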