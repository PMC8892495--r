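# Shared simulation fixtures, built once per test run and memoized.
# All fixtures use fixed seeds so expected values frozen in the tests are
# reproducible.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# UV (CPD) run at the generator's defaults; ~50k 28-mers among 230k reads.
fx_cpd <- function() fx("cpd", function() {
  cfg <- sim_config(damage_type = "CPD", n_reads = 230000L, seed = 101L)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  sim <- simulate_excision_reads(genome, genes, cfg)
  list(cfg = cfg, genome = genome, genes = genes,
       reads = sim$reads, truth = sim$truth)
})

# Cisplatin run at the defaults; geometry fixture.
fx_cis <- function() fx("cis", function() {
  cfg <- sim_config(damage_type = "CISPLATIN", n_reads = 200000L, seed = 102L)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  sim <- simulate_excision_reads(genome, genes, cfg)
  list(cfg = cfg, genome = genome, genes = genes,
       reads = sim$reads, truth = sim$truth)
})

# Cisplatin TCR run: default tcr_factor = 2, uniform expression,
# 50 non-overlapping genes >= 1 kb, 500k reads.
fx_cis_tcr <- function() fx("cis_tcr", function() {
  cfg <- sim_config(damage_type = "CISPLATIN", n_reads = 500000L,
                    expression_law = list(dist = "constant", value = 50),
                    seed = 103L)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  sim <- simulate_excision_reads(genome, genes, cfg)
  list(cfg = cfg, genome = genome, genes = genes,
       reads = sim$reads, truth = sim$truth)
})

# Strand-symmetric cisplatin run (tcr_factor = 1, no background):
# lesions fall uniformly over motif sites.
fx_sym <- function() fx("sym", function() {
  cfg <- sim_config(damage_type = "CISPLATIN", n_reads = 500000L,
                    tcr_factor = 1, background_fraction = 0, seed = 104L)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  sim <- simulate_excision_reads(genome, genes, cfg)
  list(cfg = cfg, genome = genome, genes = genes,
       reads = sim$reads, truth = sim$truth)
})

# Repair-null condition: every fragment is background.
fx_bg <- function() fx("bg", function() {
  cfg <- sim_config(genome_length = 4e5, n_genes = 10L, damage_type = "CPD",
                    n_reads = 30000L, background_fraction = 1, seed = 105L)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  sim <- simulate_excision_reads(genome, genes, cfg)
  list(cfg = cfg, genome = genome, genes = genes,
       reads = sim$reads, truth = sim$truth)
})

# Uniform-repair run (tcr_factor = 1, no background) on a genome whose
# TSS/TES regions were rewritten A-T rich, so the damage-site landscape has
# real compositional structure (GG scarcity at gene ends) for the repair
# profile to track.
fx_atrich <- function() fx("atrich", function() {
  cfg <- sim_config(damage_type = "CISPLATIN", n_reads = 400000L,
                    tcr_factor = 1, background_fraction = 0, seed = 111L)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  set.seed(112L)
  for (i in seq_along(genes)) {
    chrom <- as.character(GenomicRanges::seqnames(genes))[i]
    len <- length(genome[[chrom]])
    for (anchor in c(GenomicRanges::start(genes)[i],
                     GenomicRanges::end(genes)[i])) {
      s <- max(1L, anchor - 500L); e <- min(len, anchor + 500L)
      block <- paste(sample(c("A", "T", "C", "G"), e - s + 1L, replace = TRUE,
                            prob = c(0.46, 0.46, 0.04, 0.04)), collapse = "")
      genome[[chrom]] <- Biostrings::replaceAt(
        genome[[chrom]], IRanges::IRanges(s, e), block)
    }
  }
  sim <- simulate_excision_reads(genome, genes, cfg)
  list(cfg = cfg, genome = genome, genes = genes,
       reads = sim$reads, truth = sim$truth)
})

# Brute-force pairwise overlap oracle, independent of GenomicRanges.
brute_force_overlaps <- function(genes) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                   start = GenomicRanges::start(genes),
                   end = GenomicRanges::end(genes))
  n <- nrow(df)
  out <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && df$chrom[i] == df$chrom[j] &&
        df$start[i] <= df$end[j] && df$start[j] <= df$end[i]) {
      out[i] <- TRUE
      break
    }
  }
  out
}

# Lesion-strand dinucleotide at the truth register of each damage read.
truth_lesion_dinucs <- function(sim) {
  tr <- sim$truth[!sim$truth$is_background, ]
  p <- as.integer(sub(",.*", "", tr$lesion_positions))
  seqs <- sim$reads$seq[match(tr$read_id, names(sim$reads))]
  substr(seqs, p, p + 1L)
}

# A tiny deterministic GRanges gene set on a 100 kb single chromosome.
toy_genes <- function(starts, widths, strands, chrom_len = 100000L,
                      rpkm = NULL) {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(starts, width = widths),
                               strand = strands,
                               seqlengths = c(chr1 = chrom_len))
  gr$gene_id <- sprintf("g%02d", seq_along(gr))
  gr$rpkm <- if (is.null(rpkm)) rep(50, length(gr)) else rpkm
  gr$class <- "regular"
  gr
}

toy_reads <- function(starts, widths, strands, chrom_len = 100000L) {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(starts, width = widths),
                               strand = strands,
                               seqlengths = c(chr1 = chrom_len))
  names(gr) <- sprintf("r%04d", seq_along(gr))
  gr
}
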