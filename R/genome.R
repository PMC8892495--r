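#' Generate a random genome
#'
#' Samples chromosome sequences i.i.d. from the base composition implied by
#' `gc_content` (G and C each at `gc/2`, A and T each at `(1-gc)/2`),
#' splitting `genome_length` evenly across `n_chromosomes`. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A [Biostrings::DNAStringSet] named `chr1`, `chr2`, ...
#' @examples
#' g <- make_genome(sim_config(genome_length = 1e4, n_reads = 0, seed = 7))
#' Biostrings::width(g)
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "xr_sim_config"))
  set.seed(config$seed)
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  per_chrom <- distribute_evenly(config$genome_length, config$n_chromosomes)
  seqs <- vapply(per_chrom, function(len) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_along(genome))
  genome
}

distribute_evenly <- function(total, k) {
  base <- floor(total / k)
  out <- rep(base, k)
  out[seq_len(total - base * k)] <- base + 1
  as.integer(out)
}

#' Genome-wide single-base composition
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named frequency vector over A, C, G, T summing to 1 (N and other
#'   ambiguity codes are excluded from the denominator).
#' @export
base_composition <- function(genome) {
  counts <- colSums(Biostrings::letterFrequency(genome, c("A", "C", "G", "T")))
  counts / sum(counts)
}

#' GC fraction of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(genome) {
  comp <- base_composition(genome)
  unname(comp["G"] + comp["C"])
}
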