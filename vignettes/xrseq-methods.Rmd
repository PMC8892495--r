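---
title: "Excision-repair simulation and TCR analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excision-repair simulation and TCR analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrseqr)
```

## The measurement being modelled

Nucleotide excision repair removes bulky DNA lesions by making two nicks
that bracket the lesion and releasing a short single-stranded oligomer —
24–32 nt in eukaryotes. XR-seq captures and sequences these excision
products, so each mapped read is direct evidence that a specific strand at
a specific locus was repaired. Two families of questions follow:

* **Product chemistry and geometry.** What is the length distribution of
  the excision products, where does the lesion sit within them, and hence
  where did the 5′ and 3′ incisions fall relative to the lesion?
* **Transcription-coupled repair (TCR).** Is repair faster on the
  template (transcribed) strand of genes than on the coding
  (non-transcribed) strand, and how does that asymmetry depend on
  expression and time?

`xrseqr` implements both analyses for strand-aware mapped reads, and —
because genome-scale truth is unobservable in real data — a synthetic-data
generator with full ground truth, so that every stage of the pipeline is
verifiable by parameter recovery.

## The generator

`sim_config()` bundles the generative model. For each non-background read:

1. **Lesion site.** A damage motif occurrence is sampled genome-wide on
   either strand: `GG` for cisplatin-d(GpG) adducts, a dipyrimidine
   (`TT`, `TC`, `CT`, `CC`) for UV photoproducts. The dipyrimidine weights
   default to TT-heaviest (0.50/0.25/0.15/0.10), reflecting the relative
   propensity of CPD formation.
2. **TCR weighting.** A site inside an annotated gene body on the
   template strand (the strand opposite the annotated mRNA strand) has
   its sampling weight multiplied by
   \(w = 1 + (f - 1)\,\min(r, q_{95})/q_{95}\), where \(f\) is
   `tcr_factor`, \(r\) the gene's RPKM and \(q_{95}\) the 95th expression
   percentile of the gene set. The affine form is deliberate: at
   \(f = 1\) the generator is exactly strand-symmetric whatever the
   expression values, under uniform expression the enhancement is exactly
   \(f\), and the response is monotone and saturating in expression. The
   saturating-linear expression link is a modelling choice — only a
   positive association between transcription and TCR is established —
   and is exposed in the configuration. The default \(f = 2\) matches the
   gene-body TS/NTS ratio of ~2 observed for cisplatin adducts.
3. **Length.** The product length \(L\) is drawn from `length_weights`,
   defaulting to laws supported on 24–32 nt with 26–29-mers
   predominating and a mode of 27 nt (UV) or 28 nt (cisplatin).
4. **Incision register.** The lesion's 5′ base is placed at read-local
   position \(L-7\) for cisplatin (so a 28-mer carries the GG at
   positions 21–22: 20 nt 5′ of the lesion and 6 nt 3′ of it). For UV
   photoproducts the register is an even mixture of \(L-8\) and \(L-7\).
   A two-base lesion cannot occupy a three-position enrichment window
   from a single register; the even mixture is the smallest model that
   reproduces both the 20–22 window of 28-mers and the canonical offsets
   (19 nt 5′, 6 nt 3′) simultaneously.
5. **Sequence.** The read sequence is extracted from the lesion strand
   (reverse complement for minus-strand lesions), so lesion positions in
   the truth table always point at the motif in the emitted sequence.

Background reads — uniform genomic fragments with the same length law on
a random strand — model shearing products that carry no lesion. The
default `background_fraction` of 0.05 represents the residual
non-specific fraction of a repair-proficient library; setting it to 1
reproduces a repair-null (XPC-knockout-like) sample in which *all*
ligation products are background, and the damage-signature verdict flips
to "absent". One lesion per read is assumed and products do not degrade,
consistent with the low degradation of excision products in fly samples.

Genes are placed with a minimum intergenic gap (default 5 kb), random
strands and lognormal RPKM (meanlog 3, sdlog 1 — median ~20, a realistic
spread for expressed genes). The generator can also deliberately place
sub-1-kb genes and antisense overlapping pairs; these exist to exercise
the gene filters, which must exclude them.

What the generator does *not* emulate: chromatin and nucleosome
structure, sequencing error, PCR duplicates, mappability variation,
continuous repair kinetics (time-courses are independent samples with
varying `tcr_factor`), and lesion-context effects beyond the dinucleotide
motif. Passing tests therefore demonstrate correctness of the analytical
machinery, not robustness to every artefact of real libraries.

## Incision-geometry inference

`position_frequency_matrix()` tabulates base frequencies by read-local
position (5′ end = position 1) for reads of one length, with no
pseudocounts. `enriched_window()` then finds the maximal contiguous run
of positions where the damage-marking bases (G for cisplatin; C+T for UV)
are enriched over the genome background, and
`infer_incision_offsets()` converts the window \([a, b]\) of an
\(L\)-mer into the incision offsets: \(a - 1\) nucleotides 5′ of the
lesion and \(L - b\) nucleotides 3′ of it.

Two numerical choices deserve comment.

* **Enrichment is judged on the odds scale**:
  \(\mathrm{odds}(p)/\mathrm{odds}(p_0) \ge\) `min_ratio` (default 1.5),
  where \(p_0\) is the background frequency of the damage bases. The
  pyrimidine background is exactly 0.5 on any strand-symmetric genome,
  and under the even UV register mixture the window's edge positions have
  expected frequency 0.75 — precisely 1.5 × 0.5 — so a linear
  fold-change threshold of 1.5 sits on a knife edge and cannot call the
  full window reliably. The odds ratio at those edges is 3.0 versus a
  background of 1.0, giving a clean margin while still returning an
  empty window for background-only input. `damage_signature_score()`
  keeps the simple linear maximum fold-change, which is well separated at
  the window's centre; its verdict operationalizes the wild-type versus
  repair-null contrast.
* **Both 3′ counting conventions are reported.** The literature counts
  the lesion either by nucleotides strictly 3′ of it (6 nt for a 28-mer
  window ending at 22) or by the inclusive rank of the 3′-most enriched
  position from the 3′ end (7 for the same window). `infer_incision_offsets()`
  returns both (`three_prime_offset`, `three_prime_rank`) to avoid
  off-by-one confusion.

Ties in window length resolve to the 3′-most run, since the incision
geometry places lesions 3′-of-centre. The background is the genome-wide
single-base composition (configurable), matching the visual baseline of
per-position frequency plots and requiring no extra inputs. Product
characterization defaults to 28-mers — the conventional length for these
plots — falling back to the modal length when 28-mers are scarce.

## Unit-gene TS/NTS analysis

Genes retained for meta-profiles must not overlap any other annotated
gene (strand-agnostic, tested against the full annotation, including
genes that themselves fail other filters) and must be at least 1 kb long;
an `rpkm > 10` filter is applied when expression-conditioned profiles are
wanted. Short genes are excluded because damage may distribute
inhomogeneously between strands over short ranges; overlapping antisense
pairs confound TS/NTS labels — in an overlap, strong TCR of one gene
manifests as apparent NTS repair of the other.

Each retained gene maps to a 150-bin axis: 25 upstream flank bins (80 bp
each, 2 kb), 100 gene-body bins (length/100 bp each), 25 downstream
flank bins, always oriented 5′→3′ along transcription. Reads are
assigned to exactly one bin by their midpoint
(\(\lfloor(start+end)/2\rfloor\) in 0-based half-open coordinates) — a
point rule avoids double counting and is robust for 24–32-nt reads
against bins of ≥ 80 bp (body bins of very short genes approach 10 bp,
where the ~7 bp offset between a read's midpoint and its lesion becomes
visible; this is a known resolution limit). Bin values are
\(\mathrm{RPKM} = n \cdot 10^9 / (\ell_{bin} \cdot N)\) with \(\ell_{bin}\)
the per-bin width in bp and \(N\) the library size; per-bin length
normalization is required because body bins differ in width across
genes. The profile is the arithmetic mean over genes, TS and NTS
accumulated separately; a read is TS for a gene iff its strand is
opposite the gene's. Genes not divisible by 100 use floor-based bin
edges with the final base clamped to bin 100. Flank bins beyond a
chromosome end are missing (excluded from the mean, not zero-filled);
flank regions overlapping a neighbouring retained gene are counted for
both genes and tallied.

`body_ts_nts_ratio()` is the ratio of body-bin means (not the mean of
per-bin ratios, which near-empty bins would destabilize). Per-gene
`log2((TS + c)/(NTS + c))` uses pseudocount \(c = 1\) so ratios stay
finite for silent genes; the genome-wide distribution is computed over
*all* annotated genes, unfiltered. The time-course summary is the mean
of per-gene log2 ratios over one shared filtered gene set — averaging
per-gene ratios rather than taking log2 of summed counts keeps highly
covered genes from dominating; both are defensible, this one is the
documented choice. Sensitivity to \(c\) is mild for covered genes
(counts ≫ 1) and largest for near-silent genes, which the expression
filter removes from profile analyses anyway.

## Sequence-derived damage landscape

`site_density_profile()` counts damage-motif occurrences per unit-gene
bin (assigned to the 5′ base's bin; negligible at ≥ 80-bp bins) per
strand class, as sites per bp averaged over genes. This is the expected
damage landscape under uniform per-site damage probability — a
dinucleotide-only model, matching the GpG argument for cisplatin; no
context weighting is attempted. `observed_over_expected()` divides the
repair profile by it, reporting missing values where the expectation is
zero. Repair dips at TSS/TES over A-T–rich regions, where GG
dinucleotides are scarce, flatten under this normalization — separating
composition-driven from repair-driven structure. Note that on a
homogeneous i.i.d. genome the expected profile is flat and the
observed/expected comparison is uninformative (both vectors are noise
around a constant); the test suite therefore exercises this module on
genomes with A-T–rich blocks rewritten around gene boundaries.

## Mapping and formats

BED6 is the native mapped-read interchange; BED12/GFF3 carry gene
models, TSV carries expression and truth tables, and all parsers reject
malformed records (undefined gene strand, out-of-bounds reads, duplicate
FASTA headers) rather than coercing them, tallying rejects.
`map_reads_exact()` exists so the synthetic path needs no external
aligner: a read is reported iff it matches exactly one locus on either
strand, and the implementation (a precompiled pattern dictionary per
read length) is intended for ≤ 10 Mb toy genomes — larger genomes are
refused with a pointer to a real aligner. Real-data users supply
uniquely mapped reads produced by their own alignment standard; no
alignment parameters or deduplication policy are imposed here.

## Problem sizes and determinism

All randomness flows from the single `seed` in `sim_config()` (module
seeds are derived deterministically from it), so identical configurations
reproduce outputs bit-identically; `run_simulate()` writes an
effective-config YAML that can be re-run to prove it. The packaged
analyses are sized for a desk-scale study — 2 Mb genomes, 50 genes,
0.1–0.5 M reads — at which the length-law χ² test is well powered
(n ≥ 50,000), incision offsets are recovered exactly (positions are
discrete), and the gene-body TS/NTS ratio recovers the configured
enhancement within ~5% (the default 5% background fraction dilutes a
factor of 2.0 to ≈ 1.95, and sampling noise at 500 k reads adds ~2%).

## Known limitations

* Incision offsets are aggregate geometry; per-read lesion coordinates
  are not called for real data.
* The TCR-versus-expression link is a modelling choice beyond the
  established positive association; recovered `tcr_factor` values are
  interpretable only relative to the chosen link.
* Flank profiles of closely spaced genes double-count reads (tallied);
  meta-profiles near chromosome ends lose flank bins.
* The landscape module's dinucleotide model ignores wider sequence
  context and transcription-complex occlusion at TSS/TES, which real
  data may superimpose on the compositional signal.
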