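test_that("filter_genes applies length, overlap and expression rules", {
  # 999 bp isolated gene excluded, 1000 bp retained (half-open length)
  genes <- toy_genes(c(1001, 20001, 50001, 52001), c(999, 1000, 3000, 3000),
                     c("+", "+", "+", "-"))
  kept <- filter_genes(genes)
  expect_setequal(kept$gene_id, c("g02"))
  # g03/g04 form an antisense overlapping pair: both excluded
  expect_false(any(c("g03", "g04") %in% kept$gene_id))

  # overlap is tested against ALL genes, including short ones
  genes2 <- toy_genes(c(1001, 1500), c(3000, 500), c("+", "-"))
  expect_length(filter_genes(genes2), 0L)

  # expression filter is applied last and drops NA-expression genes
  genes3 <- toy_genes(c(1001, 20001, 40001), c(2000, 2000, 2000),
                      c("+", "+", "-"), rpkm = c(5, 50, NA))
  expect_message(kept3 <- filter_genes(genes3, min_rpkm = 10), "without expression")
  expect_equal(kept3$gene_id, "g02")
})

test_that("assign_strand implements the template-strand definition", {
  expect_equal(assign_strand("-", "+"), "TS")
  expect_equal(assign_strand("+", "+"), "NTS")
  expect_equal(assign_strand("-", "-"), "NTS")
  expect_equal(assign_strand("+", "-"), "TS")
})

test_that("TS/NTS counts track the simulated enhancement factor", {
  cfg <- sim_config(genome_length = 1e6, n_genes = 20, n_reads = 100000,
                    damage_type = "CISPLATIN", tcr_factor = 4,
                    background_fraction = 0,
                    expression_law = list(dist = "constant", value = 50),
                    seed = 108)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  per <- log2_ts_nts_per_gene(simulate_excision_reads(genome, genes, cfg)$reads,
                              filter_genes(genes))
  expect_equal(sum(per$ts_count) / sum(per$nts_count), 4, tolerance = 0.1)
})

test_that("a single body read lands in exactly one bin with the hand RPKM", {
  genes <- toy_genes(10001, 4000, "+")
  reads <- toy_reads(11001, 28, "+")   # midpoint 11014, body offset 1013
  prof <- unit_gene_profile(reads, genes, total_mapped_reads = 1)
  nz <- which(prof$nts > 0)
  expect_length(nz, 1L)
  # body bin floor(100 * 1013 / 4000) = 25 -> profile bin 26 + 25
  expect_equal(nz, 25L + 25L + 1L)
  # RPKM = 1 read * 1e9 / (bin_bp 40 * total 1)
  expect_equal(prof$nts[nz], 1e9 / 40)
  expect_true(all(prof$ts == 0))
})

test_that("minus-strand genes are profiled 5' to 3' along transcription", {
  # same locus, read 100 bp after the TSS of a minus-strand gene
  genes <- toy_genes(10001, 4000, "-")          # TSS at 14000
  reads <- toy_reads(13888, 28, "-")            # midpoint 13901, offset 99 from TSS
  prof <- unit_gene_profile(reads, genes, total_mapped_reads = 1)
  nz <- which(prof$nts > 0)
  expect_equal(nz, 25L + floor(100 * (14000 - 13901) / 4000) + 1L)
  # an upstream read (beyond the TSS in genomic +) maps to the upstream flank
  up <- toy_reads(14100, 28, "+")               # 113 bp upstream of TSS, TS class
  prof_up <- unit_gene_profile(up, genes, total_mapped_reads = 1)
  expect_equal(which(prof_up$ts > 0), 24L)      # flank bin 25 - floor(113/80)
})

test_that("read midpoints are conserved across unit-gene bins", {
  cis <- fx_cis_tcr()
  filtered <- filter_genes(cis$genes)
  counts <- xrseqr:::bin_read_counts(cis$reads, filtered)
  # brute-force oracle on plain coordinate arithmetic
  m1 <- (GenomicRanges::start(cis$reads) - 1L +
           GenomicRanges::end(cis$reads)) %/% 2L + 1L
  chrom <- as.character(GenomicRanges::seqnames(cis$reads))
  total <- 0L
  for (i in seq_along(filtered)) {
    inside <- chrom == as.character(GenomicRanges::seqnames(filtered))[i] &
      m1 >= GenomicRanges::start(filtered)[i] - 2000L &
      m1 <= GenomicRanges::end(filtered)[i] + 2000L
    total <- total + sum(inside)
  }
  expect_equal(sum(counts$tab$N), total)
})

test_that("flipping every gene strand swaps TS and NTS profiles exactly", {
  cis <- fx_cis_tcr()
  filtered <- filter_genes(cis$genes)
  prof <- unit_gene_profile(cis$reads, filtered)
  flipped <- filtered
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(filtered)) == "+", "-", "+")
  prof_f <- unit_gene_profile(cis$reads, flipped)
  # flipping also reverses the unit-gene orientation
  expect_equal(prof$ts, rev(prof_f$nts))
  expect_equal(prof$nts, rev(prof_f$ts))
})

test_that("body_ts_nts_ratio is a ratio of body-bin means", {
  prof <- structure(list(ts = rep(2, 150), nts = rep(1, 150)),
                    class = "xr_unit_gene_profile")
  expect_equal(body_ts_nts_ratio(prof), 2)
  prof0 <- structure(list(ts = rep(1, 150), nts = rep(0, 150)),
                     class = "xr_unit_gene_profile")
  expect_true(is.na(body_ts_nts_ratio(prof0)))

  sym <- fx_sym()
  ratio <- body_ts_nts_ratio(unit_gene_profile(sym$reads,
                                               filter_genes(sym$genes)))
  expect_equal(ratio, 1, tolerance = 0.1)
})

test_that("per-gene Log2(TS/NTS) uses gene-body midpoints and a pseudocount", {
  genes <- toy_genes(10001, 4000, "+")
  reads <- toy_reads(rep(11001, 46), 28, rep(c("-", "+"), c(31, 15)))
  per <- log2_ts_nts_per_gene(reads, genes, pseudocount = 1)
  expect_equal(per$ts_count, 31L)
  expect_equal(per$nts_count, 15L)
  expect_equal(per$log2_ratio, 1)   # log2(32/16)

  empty <- log2_ts_nts_per_gene(toy_reads(90000, 28, "+"), genes)
  expect_equal(empty$log2_ratio, 0) # pseudocount identity at ts = nts = 0
})

test_that("tcr_timecourse orders samples and tracks the enhancement", {
  cfg <- sim_config(genome_length = 2e6, n_genes = 50, n_reads = 100000,
                    damage_type = "CPD", background_fraction = 0,
                    expression_law = list(dist = "constant", value = 50),
                    seed = 109)
  genome <- make_genome(cfg)
  genes <- place_genes(genome, cfg)
  reads_at <- function(f) {
    c2 <- cfg; c2$tcr_factor <- f
    simulate_excision_reads(genome, genes, c2)$reads
  }
  filtered <- filter_genes(genes)
  tc <- tcr_timecourse(list(list(time = 0.5, reads = reads_at(1)),
                            list(time = 2, reads = reads_at(4)),
                            list(time = 1, reads = reads_at(2))), filtered)
  expect_equal(tc$time, c(0.5, 1, 2))
  expect_true(all(diff(tc$mean_log2_ts_nts) > 0))
  # constant enhancement of 2 gives a flat curve at ~log2(2) = 1
  flat <- tcr_timecourse(list(list(time = 1, reads = reads_at(2))), filtered)
  expect_equal(flat$mean_log2_ts_nts, 1, tolerance = 0.1)
  expect_error(
    tcr_timecourse(list(list(time = 1, reads = reads_at(1)),
                        list(time = 1, reads = reads_at(2))), filtered),
    "unique")
})
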