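---
title: "Models and methods behind polymeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polymeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`polymeth` compares whole-genome bisulfite sequencing (WGBS) methylomes
between genotypes of an allopolyploid plant — typically a reference
genotype, a test genotype derived from it by genome separation or merger,
and a "restored" genotype in which the change has been reversed. Around
that core it provides the companion analyses such a study needs: annotation
of differentially methylated regions (DMRs) to genes and transposable
elements (TEs), metagene profiles, TE absence-variant calling from
resequencing read pairs, and homoeolog dyad/triad identification across the
A, B and D subgenomes. Every stage runs on seeded synthetic data with
planted ground truth, so the whole pipeline is testable offline.

Inputs are standard formats: Bismark-style per-cytosine count reports,
FASTA genomes, GFF3/BED annotations, SAM alignments, and 12-column tabular
CDS alignment hits. Internally, intervals follow the Bioconductor 1-based
closed convention (`GRanges`); 0-based formats (BED) are converted only at
the file boundary.

# Methylcytosine calling

Incomplete bisulfite conversion leaves a fraction $\varepsilon$ of truly
unmethylated cytosines reading as methylated, so raw methylated counts
cannot be taken at face value. For a cytosine with $n_{mC}$ methylated of
$n$ total reads, `call_methylcytosines()` computes the one-sided upper
binomial tail

$$p = P(X \ge n_{mC}), \qquad X \sim \mathrm{Binomial}(n, \varepsilon),$$

and calls a methylcytosine when $p < 10^{-5}$ (strict inequality). The test
is one-sided because its purpose is to detect methylation *above* chemical
noise. $\varepsilon$ defaults to 0.005, consistent with a conversion rate
above 99%; in practice it should be estimated from an unmethylated control
(e.g. chloroplast DNA) and passed in. Cytosines with fewer than 3 reads are
not callable. Only cytosines covered by at least 3 reads in *all* compared
genotypes enter comparative analyses (`coverage_filter()`), so every
comparison uses the same sites.

Methylation levels are always count-pooled proportions
$\mathrm{mC} / (\mathrm{mC} + \mathrm{non\text{-}mC})$ over a region, never
means of per-cytosine ratios. Genome-scale summaries use 1-Mb windows
(`genome_bins()`); empty bins are flagged undefined rather than zero.

# Windowed DMR detection

`dmr_scan()` tiles each chromosome with non-overlapping 200-bp windows and
pools counts per window and per sequence context (CG, CHG, CHH; H = A, C
or T). Although such scans are often described as "sliding windows", the
step equals the width here: overlapping tiles would double-count DMRs and
undermine the independence assumptions of the multiple-testing correction.
The step is configurable for users who want overlap.

A window is kept when both genotypes have at least 16 (CG), 16 (CHG) or 64
(CHH) reads pooled over its context cytosines — CHH sites are several-fold
denser, hence the higher bar. Each kept window's 2x2 count table
$[[\mathrm{mC}_{ref}, \mathrm{u}_{ref}], [\mathrm{mC}_{test},
\mathrm{u}_{test}]]$ is tested with a two-sided Fisher exact test (both
hyper- and hypomethylation are of interest, so one-sidedness would
presuppose a direction). The implementation enumerates the hypergeometric
point probabilities directly, vectorized over windows, using the customary
rule that the two-sided $p$ sums all tables whose probability does not
exceed the observed one (within a $1 + 10^{-7}$ relative tolerance); tests
cross-check it against `stats::fisher.test` and against a binomial-
coefficient enumeration. A window with a zero margin has a single-point
support and $p = 1$ by convention.

P-values are corrected per context with Benjamini–Hochberg (the field
default for genome-wide window scans; Bonferroni is available). A window
becomes a DMR when

* $p_{adj} < 0.05$ (strict), and
* $|\Delta| > 0.5 / 0.3 / 0.1$ for CG/CHG/CHH (strict), with
  $\Delta = \mathrm{level}_{test} - \mathrm{level}_{ref}$.

The per-context effect floors reflect the dynamic range of each context:
CG methylation in plants is near-saturated (~0.8 genome-wide), CHG
intermediate, CHH low (~0.04), so a fixed absolute floor would be either
toothless or unreachable. The two gates are deliberately independent: at
high depth, biologically negligible shifts are statistically overwhelming,
and the effect-size gate is what rejects them. `direction` is `hypo` when
the test genotype lost methylation.

Adjacent significant windows are *not* merged by default — DMR counts are
window counts, which keeps them comparable across runs; merging is a
post-processing choice left to the user.

## Restoration analysis

For a series reference → test → restored (e.g. extracted tetraploid vs
natural hexaploid vs resynthesized hexaploid wheat), `restoration_analysis()`
asks, for each test-vs-reference DMR, whether the restored genotype
reverted it. "Reverted to the original level" is operationalized
symmetrically to the original call: the restored-vs-test comparison on the
same window must itself pass the full DMR rule (coverage, $p_{adj}$,
effect floor) in the opposite direction. A level-based rule without a
significance gate was the alternative; the significance-based rule was
chosen because it inherits the caller's error control instead of inventing
a second, looser criterion. Windows without adequate coverage in the
restored genotype are `NA` and excluded from restored-fraction
denominators.

`dmr_overlap()` counts same-context, ≥1-bp interval overlaps between two
DMR sets, reporting the fraction of each set matched.

# Annotation and enrichment

`assign_dmr_features()` gives each DMR exactly one category with precedence
exon > intron > upstream > downstream > intergenic; body overlap is the
stronger annotation claim, so it wins over flanks. Introns are inferred as
gaps between consecutive exons when not annotated. Upstream/downstream
windows and promoters default to 2,000 bp, strand-aware — the same span as
the metagene flanks, chosen for internal consistency since no universal
promoter length exists for wheat; both are configurable.
TE-overlapping DMRs are tallied by TE length class in left-closed kb bins
0–1, 1–2, 2–4, 4–8, >8 kb (`assign_te_classes()`). For homoeolog pairs,
`homoeolog_dmr_classes()` reports whether a promoter DMR hits one or both
members of each dyad.

`hypergeom_enrich()` is a generic overrepresentation test: for a selection
of $n$ ids from a background of $N$ with $K$ category members, it reports
the upper tail $P(X \ge k)$ of the hypergeometric distribution, flagged at
$p < 0.05$. Category labels are plain two-column tables, so GO slims or TE
superfamilies plug in without an ontology engine (ontology traversal is
out of scope).

# Metagene and meta-TE profiles

`meta_profile()` length-normalizes each feature body into 60 equal windows
and adds fixed flanks — 2,000 bp for genes, 500 bp for TEs — split into 20
windows per side, giving a conventional 100-window vector. Minus-strand
features are orientation-flipped before binning. Aggregation across
features is count pooling, consistent with the level formula above
(mean-of-feature-levels would weight a sparse feature equally with a dense
one); features shorter than 60 bp are excluded and counted. Windows
without any covered cytosine are `NA`, not zero.

# TE absence variants

A reference-annotated TE that is missing from a query genotype leaves a
characteristic alignment signature when the query's reads are mapped to
the reference: read pairs whose mates flank the locus appear with inflated
separation, reads crossing the deletion junction align as split reads, and
the TE interior receives no coverage. `call_te_absence()` implements the
corresponding rule chain:

1. *Evidence* (`extract_evidence()`): discordant pairs and split reads
   whose aligned parts are separated by more than 2 kb (strict), measured
   end-of-left-part to start-of-right-part; the spanned interval is that
   gap. Records below mapping quality 20 are ignored.
2. *Candidates* (`candidate_tes()`): a single evidence interval must span
   at least 80% of the TE. The single-best-evidence rule (rather than a
   union over reads) is the conservative reading of "a read spanning";
   the union is available by option.
3. *Depth* (`depth_criterion()`): mean per-base depth inside the spanned
   part of the TE must be strictly below 10% of the mean over the 2-kb
   flanks (both sides averaged, truncated at chromosome ends; one-sided at
   an edge). Mean rather than median depth is used; at the shallow depths
   where this caller operates the two are close and the mean is exactly
   recountable in tests.
4. *Confirmation* (`confirm_with_reference_reads()`): optionally, at least
   80% of the TE's bases must be covered by reads of the TE-carrying
   genotype, establishing that the reference annotation is real sequence
   rather than an assembly artifact.

# Homoeolog dyads and triads

CDSs of each subgenome pair are assumed to have been aligned reciprocally
(BLASTN-style tables). `filter_hits()` keeps hits with e-value ≤ 1e-10,
identity strictly above 90%, and aligned length strictly above 60% of
*both* CDS lengths; multi-HSP pairs are reduced to the single best HSP
first (HSP chaining would need arbitrary collinearity rules and is not
attempted). `reciprocal_best()` forms a dyad when each gene is the other's
unique best hit — best by bitscore, then identity; a query whose top two
hits tie on both has no unique best and forms no dyad, which is what makes
one-to-many homologies drop out rather than being resolved arbitrarily.
`build_triads()` intersects the three pairwise dyad sets; one-to-one dyads
guarantee each gene appears in at most one triad.

# The synthetic-data generator

`simulate_methylomes()` emulates the three-genotype WGBS design:

* random genome (uniform base composition), genes with 1–4 exons and TEs
  (0.4–10 kb, log-uniform) placed in non-overlapping slots;
* per-cytosine true levels from context baselines CG 0.80, CHG 0.60,
  CHH 0.04 — typical plant genome-wide values on the saturated CG /
  intermediate CHG / sparse CHH pattern;
* planted DMRs on 200-bp window tiles (so window-level truth is
  unambiguous; multi-tile DMRs can be built by lowering `window_width`),
  with per-context effect sizes defaulting to 0.6/0.4/0.2; CG and CHG
  changes default to hypomethylation, CHH to hypermethylation because a
  0.04 baseline cannot lose 0.2;
* a restored genotype reverting a configurable fraction (default 0.5) of
  planted tiles to the reference level;
* observed counts: depth $\sim$ Poisson(8.8) — the coverage regime of a
  typical hexaploid-wheat WGBS study — and methylated reads $\sim$
  Binomial(depth, $\ell(1 - \varepsilon') + \varepsilon(1 - \ell)$) with
  non-conversion $\varepsilon = 0.005$ and methylated-read failure
  $\varepsilon' = 0$ by default. The one-parameter error model matches
  what a conversion-rate QC measures.

`simulate_read_pairs()` draws fragments uniformly from the query genome
(the reference minus absent TEs) and reports them in reference
coordinates, producing discordant pairs, split reads (primary +
supplementary SAM records) and empty TE interiors exactly as an aligner
would see them. Fragment length is Normal(1500, 150) truncated at ±3 sd,
as in a size-selected library; the long insert lets even a 1-kb TE
deletion exceed the 2-kb separation rule. `simulate_cds_hits()` builds
reciprocal hit tables for 50-triad designs plus decoys that each violate
exactly one dyad criterion (identity 85–90%, length 40–58%,
non-reciprocal best, tied one-to-many).

What the generator does *not* emulate: sequencing error and quality
strings, PCR duplicates, mappability variation, context-dependent coverage
bias, chimeric/nested TEs, and subgenome homoeologous mapping ambiguity.
Passing recovery tests therefore demonstrates the correctness of the
statistical machinery under its stated model, not robustness to alignment
artifacts in real wheat data.

# Problem sizes and numerical choices

The shipped tests exercise the scan at 10,000–30,000 windows (1–6 Mb of
genome across up to three chromosomes, three genotypes), 200 planted DMRs,
100 TEs with 20 planted absences at 20-fold depth, and 50-triad designs —
sizes chosen so the full suite runs comfortably on a laptop while keeping
per-context counts large enough for tight recovery bounds. Exact-test
implementations are verified against brute-force enumeration to 1e-10
(Fisher) and 1e-12 (binomial, hypergeometric). Ties, zero margins, empty
bins, uncovered windows and chromosome-edge flanks all have declared
behaviors (p = 1, `NA`-not-zero, exclusion, truncation respectively), each
pinned by a test.

All randomness flows from explicit seeds; there are no unseeded entry
points, and `run_pipeline()` writes a versioned summary JSON that is
byte-identical across reruns of the same config and seed.

# Known limitations

* The caller tests windows marginally; it does not borrow strength across
  neighboring windows (no smoothing, no HMM), so single-window power at
  low depth is the binding constraint.
* Effect floors and coverage gates are tuned for plant methylomes with
  near-saturated CG methylation; other kingdoms need different defaults.
* The TE caller detects absence only (reference-present variants); TE
  insertions relative to the reference are out of scope.
* Promoter length, flank spans and the BH correction are conventions, not
  estimates; results near those boundaries should be read accordingly.
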