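#' Simulation configuration for synthetic XR-seq data
#'
#' Bundles and validates every parameter of the synthetic-data generator:
#' genome composition, gene placement, expression law, damage chemistry,
#' excision-length law, transcription-coupled repair (TCR) strength and
#' background (non-damage) fragment fraction. All downstream randomness
#' flows from the single `seed`.
#'
#' @param genome_length Total genome size in bases (split across
#'   `n_chromosomes`). Must be >= 10000.
#' @param n_chromosomes Number of chromosomes.
#' @param gc_content Target GC fraction, strictly between 0 and 1.
#' @param n_genes Total number of genes to place, including the short and
#'   overlapping ones below.
#' @param n_short_genes How many genes shorter than 1 kb to place (these
#'   exercise the minimum-length gene filter).
#' @param n_overlap_pairs How many antisense overlapping gene pairs to place
#'   (each pair contributes two genes; these exercise the overlap filter).
#' @param gene_length_range Length range (bases) for regular genes,
#'   `c(min, max)` with `min >= 1000`.
#' @param intergenic_min Minimum gap in bases between placed gene loci.
#' @param expression_law Either `list(dist = "lognormal", meanlog, sdlog)`
#'   (RPKM-like units) or `list(dist = "constant", value)` for uniform
#'   expression across genes.
#' @param damage_type One of `"CPD"`, `"SIX_FOUR"`, `"CISPLATIN"`. UV
#'   photoproducts (CPD, (6-4)PP) form at dipyrimidines; cisplatin-d(GpG)
#'   adducts form at GG.
#' @param n_reads Number of excision-product reads to simulate.
#' @param tcr_factor Template-strand repair enhancement (dimensionless,
#'   >= 0). 1 means no TCR (strand-symmetric in expectation); the default 2
#'   matches the gene-body TS/NTS ratio observed for cisplatin adducts.
#' @param length_weights Named numeric vector mapping excision-product
#'   length (nt, support within 24..32) to probability; must sum to 1.
#'   Defaults peak at 27 nt for UV photoproducts and 28 nt for cisplatin.
#' @param dipyrimidine_weights Named weights over the four dipyrimidines
#'   (TT, TC, CT, CC) for UV damage placement; TT-heaviest by default.
#'   Ignored for cisplatin.
#' @param background_fraction Fraction of reads that are background
#'   (non-damage) fragments in `[0, 1]`. `1` emulates the repair-null
#'   (XPC-knockout-like) condition in which all captured fragments are
#'   shearing background with no lesion.
#' @param seed Integer seed controlling all randomness.
#'
#' @return An object of class `xr_sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(damage_type = "CISPLATIN", n_reads = 1000, seed = 1)
#' cfg$length_weights
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chromosomes = 2,
                       gc_content = 0.43,
                       n_genes = 50,
                       n_short_genes = 0,
                       n_overlap_pairs = 0,
                       gene_length_range = c(1000L, 8000L),
                       intergenic_min = 5000,
                       expression_law = list(dist = "lognormal",
                                             meanlog = 3, sdlog = 1),
                       damage_type = c("CPD", "SIX_FOUR", "CISPLATIN"),
                       n_reads = 1e5,
                       tcr_factor = 2,
                       length_weights = NULL,
                       dipyrimidine_weights = c(TT = 0.50, TC = 0.25,
                                                CT = 0.15, CC = 0.10),
                       background_fraction = 0.05,
                       seed = 1L) {
  damage_type <- match.arg(damage_type)
  if (!is.numeric(genome_length) || genome_length < 10000)
    stop("genome_length must be >= 10000 bases", call. = FALSE)
  if (gc_content <= 0 || gc_content >= 1)
    stop("gc_content must be strictly between 0 and 1", call. = FALSE)
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1", call. = FALSE)
  if (n_genes < 0 || n_short_genes < 0 || n_overlap_pairs < 0)
    stop("gene counts must be non-negative", call. = FALSE)
  if (n_short_genes + 2L * n_overlap_pairs > n_genes)
    stop("n_short_genes + 2*n_overlap_pairs exceeds n_genes", call. = FALSE)
  if (length(gene_length_range) != 2 || gene_length_range[1] < 1000 ||
      diff(gene_length_range) < 0)
    stop("gene_length_range must be c(min, max) with min >= 1000", call. = FALSE)
  if (background_fraction < 0 || background_fraction > 1)
    stop("background_fraction must be in [0, 1]", call. = FALSE)
  if (tcr_factor < 0) stop("tcr_factor must be >= 0", call. = FALSE)
  if (is.null(length_weights))
    length_weights <- default_length_weights(damage_type)
  lw <- validate_length_weights(length_weights)
  dw <- dipyrimidine_weights
  if (damage_type != "CISPLATIN") {
    if (!setequal(names(dw), c("TT", "TC", "CT", "CC")) || any(dw < 0) ||
        sum(dw) <= 0)
      stop("dipyrimidine_weights must be non-negative weights named TT, TC, CT, CC",
           call. = FALSE)
    dw <- dw[c("TT", "TC", "CT", "CC")] / sum(dw)
  }
  structure(list(
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    gc_content = gc_content,
    n_genes = as.integer(n_genes),
    n_short_genes = as.integer(n_short_genes),
    n_overlap_pairs = as.integer(n_overlap_pairs),
    gene_length_range = as.integer(gene_length_range),
    intergenic_min = as.integer(intergenic_min),
    expression_law = expression_law,
    damage_type = damage_type,
    n_reads = as.integer(n_reads),
    tcr_factor = tcr_factor,
    length_weights = lw,
    dipyrimidine_weights = dw,
    background_fraction = background_fraction,
    seed = as.integer(seed)
  ), class = "xr_sim_config")
}

#' Default excision-product length law per damage type
#'
#' Support 24..32 nt with 26-29-mers predominating; modal length 27 nt for
#' UV photoproducts and 28 nt for cisplatin adducts.
#'
#' @param damage_type `"CPD"`, `"SIX_FOUR"` or `"CISPLATIN"`.
#' @return Named probability vector over lengths 24..32.
#' @export
default_length_weights <- function(damage_type) {
  w <- switch(damage_type,
    CPD = ,
    SIX_FOUR = c(0.02, 0.06, 0.17, 0.26, 0.22, 0.14, 0.07, 0.04, 0.02),
    CISPLATIN = c(0.02, 0.04, 0.10, 0.22, 0.26, 0.19, 0.10, 0.05, 0.02),
    stop("unknown damage_type: ", damage_type, call. = FALSE))
  names(w) <- as.character(24:32)
  w
}

validate_length_weights <- function(lw) {
  if (is.null(names(lw)) || anyNA(suppressWarnings(as.integer(names(lw)))))
    stop("length_weights must be named by integer length", call. = FALSE)
  lens <- as.integer(names(lw))
  if (any(lens < 24L) || any(lens > 32L))
    stop("length_weights support must lie within [24, 32] nt", call. = FALSE)
  if (any(lw < 0)) stop("length_weights must be non-negative", call. = FALSE)
  if (abs(sum(lw) - 1) > 1e-9)
    stop("length_weights must sum to 1 (within 1e-9)", call. = FALSE)
  lw[order(lens)]
}

#' @export
print.xr_sim_config <- function(x, ...) {
  cat("xr_sim_config\n")
  cat(sprintf("  genome: %g bp over %d chromosome(s), GC %.2f\n",
              x$genome_length, x$n_chromosomes, x$gc_content))
  cat(sprintf("  genes: %d (%d short, %d antisense overlapping pairs)\n",
              x$n_genes, x$n_short_genes, x$n_overlap_pairs))
  cat(sprintf("  damage: %s, %d reads, tcr_factor %.2f, background %.2f\n",
              x$damage_type, x$n_reads, x$tcr_factor, x$background_fraction))
  cat(sprintf("  length law: mode %s nt; seed %d\n",
              names(x$length_weights)[which.max(x$length_weights)], x$seed))
  invisible(x)
}

# Damage motifs on the lesion strand, as 2-mers.
damage_motifs <- function(config) {
  if (config$damage_type == "CISPLATIN") c(GG = 1) else config$dipyrimidine_weights
}

# Single bases whose enrichment marks the lesion in a frequency matrix.
#' Damage-marking bases for a damage type
#'
#' `"CISPLATIN"` lesions sit at GG, so G marks them; UV photoproducts sit at
#' dipyrimidines, so C and T mark them.
#'
#' @param damage_type `"CPD"`, `"SIX_FOUR"` or `"CISPLATIN"`.
#' @return Character vector of bases.
#' @export
damage_bases <- function(damage_type) {
  if (damage_type == "CISPLATIN") "G" else c("C", "T")
}
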