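test_that("sim_config validates its inputs", {
  expect_error(sim_config(gc_content = 0), "gc_content")
  expect_error(sim_config(genome_length = 500), "genome_length")
  expect_error(sim_config(background_fraction = 1.2), "background_fraction")
  expect_error(sim_config(length_weights = c(`23` = 1)), "\\[24, 32\\]")
  expect_error(sim_config(length_weights = c(`26` = 0.5, `27` = 0.6)),
               "sum to 1")
  expect_error(sim_config(n_genes = 3, n_overlap_pairs = 2), "exceeds")
  expect_error(sim_config(damage_type = "OXIDATIVE"))
  lw <- sim_config(damage_type = "CISPLATIN")$length_weights
  expect_equal(sum(lw), 1, tolerance = 1e-12)
  expect_equal(names(lw)[which.max(lw)], "28")
})

test_that("make_genome hits the target composition and is deterministic", {
  cfg <- sim_config(genome_length = 2e5, n_chromosomes = 3, gc_content = 0.43,
                    seed = 7)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(length(g1), 3L)
  expect_equal(sum(Biostrings::width(g1)), 2e5)
  expect_lt(abs(gc_fraction(g1) - 0.43), 0.02)
})

test_that("place_genes emits the requested mix and filter-oracle counts agree", {
  cfg <- sim_config(genome_length = 2e6, n_genes = 50, n_short_genes = 5,
                    n_overlap_pairs = 2, seed = 21)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  expect_equal(length(genes), 50L)
  expect_equal(sum(genes$class == "short"), 5L)
  expect_equal(sum(genes$class == "overlap"), 4L)
  # brute-force oracle: 50 - 5 short - 4 overlapping = 41 pass the filters
  bf <- brute_force_overlaps(genes)
  pass <- !bf & GenomicRanges::width(genes) >= 1000L
  expect_equal(sum(pass), 41L)
  expect_identical(overlaps_any_other(genes), bf)
  # both members of each antisense pair are flagged and antisense
  ov <- genes[genes$class == "overlap"]
  expect_true(all(overlaps_any_other(genes)[genes$class == "overlap"]))
  expect_setequal(as.character(GenomicRanges::strand(ov)), c("+", "-"))
})

test_that("place_genes handles the degenerate and impossible cases", {
  cfg0 <- sim_config(n_genes = 0, seed = 1)
  expect_length(place_genes(make_genome(cfg0), cfg0), 0L)
  cfg_big <- sim_config(genome_length = 2e4, n_genes = 40, seed = 1)
  expect_error(place_genes(make_genome(cfg_big), cfg_big), "too small")
})

test_that("lesions sit on the damage motif at the incision register", {
  cis <- fx_cis()
  expect_true(all(truth_lesion_dinucs(cis) == "GG"))
  # cisplatin register: 5' base at L-7, so an L-mer has L-8 nt 5' and 6 nt 3'
  tr <- cis$truth[!cis$truth$is_background, ]
  p <- as.integer(sub(",.*", "", tr$lesion_positions))
  L <- tr$end - tr$start
  expect_true(all(p == L - 7L))
  expect_true(all((L - (p + 1L)) == 6L))

  cpd <- fx_cpd()
  expect_true(all(truth_lesion_dinucs(cpd) %in% c("TT", "TC", "CT", "CC")))
  tr <- cpd$truth[!cpd$truth$is_background, ]
  p <- as.integer(sub(",.*", "", tr$lesion_positions))
  L <- tr$end - tr$start
  expect_true(all(p %in% c(L - 8L, L - 7L)))
  # even register mixture
  expect_lt(abs(mean(p == L - 8L) - 0.5), 0.01)
})

test_that("truth coordinates reproduce emitted read sequences exactly", {
  cpd <- fx_cpd()
  idx <- seq(1, nrow(cpd$truth), by = 23)   # thinned: strand-aware re-extraction
  tr <- cpd$truth[idx, ]
  gr <- GenomicRanges::GRanges(tr$chrom,
                               IRanges::IRanges(tr$start + 1L, tr$end),
                               strand = tr$strand)
  re <- as.character(extract_stranded_seqs(cpd$genome, gr))
  expect_identical(unname(re), unname(cpd$reads$seq[idx]))
})

test_that("sampled lengths follow the configured length law", {
  cfg <- sim_config(damage_type = "CISPLATIN", n_reads = 50000L, seed = 110)
  genome <- make_genome(cfg)
  sim <- simulate_excision_reads(genome, place_genes(genome, cfg), cfg)
  obs <- table(factor(GenomicRanges::width(sim$reads), levels = 24:32))
  p <- stats::chisq.test(obs, p = cfg$length_weights)$p.value
  expect_gt(p, 0.01)
})

test_that("background_fraction = 1 yields lesion-free background fragments", {
  bg <- fx_bg()
  expect_true(all(bg$truth$is_background))
  expect_true(all(bg$truth$lesion_positions == ""))
  expect_true(all(is.na(bg$truth$source_gene)))
})

test_that("tcr_factor = 1 is strand-symmetric and doubling it doubles TS/NTS", {
  sym <- fx_sym()
  per <- log2_ts_nts_per_gene(sym$reads, filter_genes(sym$genes))
  expect_lt(abs(mean(per$log2_ratio)), 0.05)
  # doubled enhancement at constant expression: per-gene TS/NTS doubles
  cfg4 <- sim_config(damage_type = "CISPLATIN", n_reads = 200000L,
                     tcr_factor = 4, background_fraction = 0,
                     expression_law = list(dist = "constant", value = 50),
                     seed = 106L)
  cfg2 <- cfg4; cfg2$tcr_factor <- 2
  genome <- make_genome(cfg4)
  genes <- place_genes(genome, cfg4)
  r4 <- simulate_excision_reads(genome, genes, cfg4)$reads
  r2 <- simulate_excision_reads(genome, genes, cfg2)$reads
  ratio_of <- function(reads) {
    per <- log2_ts_nts_per_gene(reads, filter_genes(genes), pseudocount = 1)
    sum(per$ts_count) / sum(per$nts_count)
  }
  expect_equal(ratio_of(r4) / ratio_of(r2), 2, tolerance = 0.1)
})

test_that("the generator is deterministic for a fixed seed", {
  cfg <- sim_config(genome_length = 1e5, n_genes = 5, n_reads = 2000, seed = 33)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  s1 <- simulate_excision_reads(genome, genes, cfg)
  s2 <- simulate_excision_reads(genome, genes, cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$reads$seq, s2$reads$seq)
})
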