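# Hand-built frequency matrix helper: columns are base-frequency vectors.
pfm_from_cols <- function(cols) {
  m <- do.call(cbind, cols)
  rownames(m) <- c("A", "C", "G", "T")
  colnames(m) <- as.character(seq_len(ncol(m)))
  structure(list(matrix = m, L = ncol(m), n_reads = 1000L), class = "xr_pfm")
}
unif_col <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("length_distribution summarizes counts, mode and median", {
  ld <- length_distribution(c(28L, 28L, 27L, 29L))
  expect_equal(sum(ld$fraction), 1)
  expect_equal(ld$mode, 28L)
  expect_equal(ld$median, 28L)

  # mode ties break toward the smaller length
  expect_equal(length_distribution(c(26L, 26L, 29L, 29L))$mode, 26L)
  # median is the 50th-percentile length on the count CDF
  expect_equal(length_distribution(c(24L, 25L, 26L, 27L))$median, 25L)

  single <- length_distribution(rep(28L, 10))
  expect_equal(unname(single$fraction), 1)
  expect_error(length_distribution(integer(0)), "empty")
})

test_that("position_frequency_matrix normalizes columns without pseudocounts", {
  pfm <- position_frequency_matrix(rep(strrep("A", 28), 600), 28,
                                   min_reads = 500)
  expect_true(all(pfm$matrix["A", ] == 1))
  expect_true(all(abs(colSums(pfm$matrix) - 1) < 1e-9))
  expect_error(position_frequency_matrix(rep(strrep("A", 28), 100), 28),
               "min_reads")

  cis <- fx_cis()
  pfm <- position_frequency_matrix(cis$reads, 28)
  expect_true(all(abs(colSums(pfm$matrix) - 1) < 1e-9))
  # G frequency is maximal at the platination dinucleotide, positions 21-22
  top2 <- order(pfm$matrix["G", ], decreasing = TRUE)[1:2]
  expect_setequal(top2, c(21L, 22L))
})

test_that("enriched_window finds the lesion window and handles nulls and ties", {
  spike <- unif_col; spike["G"] <- 0.9; spike[c("A", "C", "T")] <- 0.1 / 3
  cols <- rep(list(unif_col), 15); cols[[10]] <- spike
  expect_equal(enriched_window(pfm_from_cols(cols), "G", unif_col, 1.5),
               c(10L, 10L))

  flat <- pfm_from_cols(rep(list(unif_col), 15))
  expect_length(enriched_window(flat, "G", unif_col, 1.5), 0L)

  # two single-position runs tie: the 3'-most wins
  cols2 <- rep(list(unif_col), 15); cols2[[4]] <- spike; cols2[[12]] <- spike
  expect_equal(enriched_window(pfm_from_cols(cols2), "G", unif_col, 1.5),
               c(12L, 12L))
})

test_that("windows and offsets recover the simulated incision geometry", {
  cis <- fx_cis()
  bg <- base_composition(cis$genome)
  pfm <- position_frequency_matrix(cis$reads, 28)
  w <- enriched_window(pfm, damage_bases("CISPLATIN"), bg)
  expect_equal(w, c(21L, 22L))
  geo <- infer_incision_offsets(w, 28)
  expect_equal(geo$five_prime_offset, 20L)
  expect_equal(geo$three_prime_offset, 6L)

  cpd <- fx_cpd()
  bg <- base_composition(cpd$genome)
  pfm <- position_frequency_matrix(cpd$reads, 28)
  w <- enriched_window(pfm, damage_bases("CPD"), bg)
  expect_equal(w, c(20L, 22L))
  geo <- infer_incision_offsets(w, 28)
  expect_equal(geo$five_prime_offset, 19L)
  expect_equal(geo$three_prime_offset, 6L)
  expect_equal(geo$three_prime_rank, 7L)

  # window detection uses frequencies, so it is read-count invariant
  pfm_sub <- position_frequency_matrix(cpd$reads[seq_len(60000)], 28)
  expect_equal(enriched_window(pfm_sub, damage_bases("CPD"), bg), w)
})

test_that("infer_incision_offsets arithmetic and degenerate windows", {
  expect_equal(infer_incision_offsets(c(20, 22), 28)$five_prime_offset, 19L)
  full <- infer_incision_offsets(c(1, 28), 28)
  expect_equal(full$five_prime_offset, 0L)
  expect_equal(full$three_prime_offset, 0L)
  undef <- infer_incision_offsets(integer(0), 28)
  expect_true(is.na(undef$five_prime_offset))
  expect_length(undef$enriched_window, 0L)
})

test_that("damage signature separates repair-proficient from null samples", {
  cpd <- fx_cpd()
  sig <- damage_signature_score(position_frequency_matrix(cpd$reads, 28),
                                damage_bases("CPD"),
                                base_composition(cpd$genome))
  expect_equal(sig$verdict, "present")

  bgrun <- fx_bg()
  sig0 <- damage_signature_score(position_frequency_matrix(bgrun$reads, 28),
                                 damage_bases("CPD"),
                                 base_composition(bgrun$genome))
  expect_equal(sig0$verdict, "absent")
  expect_lt(sig0$score, 1.1)

  # score decreases strictly as the lesion fraction falls
  scores <- vapply(c(0, 0.5, 1), function(bf) {
    cfg <- sim_config(genome_length = 4e5, n_genes = 10, damage_type = "CPD",
                      n_reads = 30000, background_fraction = bf, seed = 107)
    genome <- make_genome(cfg)
    sim <- simulate_excision_reads(genome, place_genes(genome, cfg), cfg)
    damage_signature_score(position_frequency_matrix(sim$reads, 28),
                           damage_bases("CPD"),
                           base_composition(genome))$score
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("the dominant window dinucleotide tracks the motif law", {
  cpd <- fx_cpd()
  pfm <- position_frequency_matrix(cpd$reads, 28)
  w <- enriched_window(pfm, damage_bases("CPD"), base_composition(cpd$genome))
  seqs <- cpd$reads$seq[GenomicRanges::width(cpd$reads) == 28]
  dinucs <- unlist(lapply(w[1]:(w[2] - 1L), function(p) substr(seqs, p, p + 1L)))
  top <- names(sort(table(dinucs), decreasing = TRUE))[1]
  expect_equal(top, "TT")  # TT carries the heaviest weight in the default law
})
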