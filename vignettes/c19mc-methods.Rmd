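---
title: "Methods: p53-box landscapes, TC/TI stratification, and coverage-gap fusion inference around C19MC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: p53-box landscapes, TC/TI stratification, and coverage-gap fusion inference around C19MC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c19mctools)
```

## The scientific setting

The chromosome 19 microRNA cluster (C19MC, chr19q13.42, 46 miRNAs over
~96 kb) is normally placenta-restricted but oncogenically overexpressed in a
subset of hepatocellular carcinomas. That subset is marked by cancer-testis
antigen expression and by tumours whose p53 is transcriptionally
*incompetent* (TI) — p53-induced output genes silent, p53-repressed mitotic
genes high. This package implements, as reusable and tested code, four desk
analyses around that biology:

1. **Motif landscape** — scan a genomic window for reverse-complement
   palindromic p53 response-element boxes (CDKN1A/GADD45 consensus
   sub-elements, "CP"/"GP" boxes) and Sp1 zinc/nickel boxes, and summarise
   their distribution relative to the cluster region.
2. **TC/TI stratification** — classify an expression cohort with a 30-gene
   signature (20 p53-induced, 10 p53-repressed) and compare C19MC miRNA load
   between groups nonparametrically.
3. **Expression screen** — split a cohort by cumulative C19MC load,
   log10-transform, and correlate ligand mRNAs against cluster miRNAs with a
   significance mask and hierarchically clustered ordering.
4. **Fusion-gap inference** — call a focal deletion as a zero-coverage run in
   RNA-seq depth joining two genes' introns, decompose a junction amplicon
   into flank matches plus a non-templated linker, and compute the expected
   PCR product size across the rearrangement.

A synthetic-data generator with planted ground truth replaces the original
tumour-cohort (TCGA-style) and cell-line inputs, so every stage runs and is
validated offline.

## Coordinate conventions

All genomic intervals — motif hits, coverage tracks, gaps, exons, deletion
intervals — are **0-based, half-open** internally, the BED/bedGraph
convention. This makes the printed-breakpoint arithmetic exact: a deletion
between breakpoints 7,501,000 and 7,577,371 spans
`7,577,371 − 7,501,000 = 76,371` bases. Printed reports (`print()` methods)
use 1-based inclusive coordinates, the genome-browser style. We accept that
this differs from the 1-based closed convention of the Bioconductor range
containers; the bedGraph reader/writer converts at the boundary.

## Palindrome and box scanning

A *reverse-complement palindrome* is a DNA string equal to its own reverse
complement; over ACGT such strings are necessarily even-length (a central
base would have to complement itself). This dyad symmetry underlies p53
dimer/tetramer binding. The shipped box catalogue contains the CDKN1A
palindromic sub-elements (CP box-1: `CCCGGG` ⊂ `GCCCGGGC`; CP box-2:
`ACATGT` ⊂ `CAACATGTTG`), the GADD45 sub-elements (`ACATGT`, `GCATGC` ⊂
`AGCATGCT`), and an Sp1 zinc box (`GGGGCGGGG`, the canonical GC-box).

Numerical/policy choices, each of which is tested:

* **Nested hits are all reported.** The 6-mer inside an 8-mer palindrome is
  a distinct biological element (a shorter box a p53 dimer could engage), so
  deduplication is not performed by default.
* **N policy.** Any N inside a candidate window blocks the match, even when
  the box carries a mismatch allowance — a conservative rule that avoids
  phantom palindromes in masked sequence.
* **The "7-mer GP box" rule.** A 7-mer over ACGT cannot itself be a
  reverse-complement palindrome. We implement the 7-mer GP element
  explicitly as: 7-mer windows matching the first or last 7 bases of
  `AGCATGCT` with at most one mismatch (`GP-7mer-L`, `GP-7mer-R`,
  `max_mismatches = 1`). The rule is a documented, configurable reading of
  an ambiguous definition; users can drop or replace those probes.
* **Sp1 nickel box.** There is no universally agreed nickel-preference Sp1
  sequence; the catalogue ships a configurable slot (`sp1_ni=`) with no
  default truth rather than inventing one.
* **Strands.** Palindromic boxes are strand-symmetric and scanned once
  (verified: hit sets identical with `both_strands` on/off); non-palindromic
  boxes are additionally scanned as their reverse complement and reported in
  window-forward coordinates.

Pattern matching inside `find_box_hits()` is delegated to
`Biostrings::matchPattern()` (IUPAC-aware, with mismatch budget); the
palindrome enumerator is a vectorised dyad-symmetry check written here. Both
are validated against an exhaustive substring oracle on random sequences.

Percent coordinates are the linear map putting the window start at 0 and end
at 100 — the convention used to draw binding-site maps of the 200 kb region
(chr19:54,100,000–54,300,000 around the ~96 kb cluster). The landscape
summary assigns each hit to inside / left-flank / right-flank by its start
coordinate; the three counts partition the hits by construction.

## The synthetic cohort generator

`simulate_expression_cohort()` draws each feature's `log2(x+1)` value as
Gaussian: baseline level uniform on [3, 10] log2 units, noise sd
`noise_sd`. Group structure is planted on the log2 scale and the matrices
are emitted on the linear scale (`2^L − 1`, clamped at 0):

* half the samples (rounding down) are labelled TI;
* induced signature genes shift **down** and repressed genes **up** by
  `effect_size_delta` in TI samples;
* cluster miRNAs shift up by `c19mc_shift` in TI samples;
* the first ligand's log2 signal is `mu + noise_sd·(ρ·S + sqrt(1−ρ²)·ε)`
  where `S` is the standardized log2 cumulative-cluster load — a Gaussian
  copula giving population correlation ρ between ligand and cluster load on
  the log scale.

Defaults are the study conditions the generator emulates: 183 samples (the
integrated-cluster tumour subset size), `effect_size_delta = 2`,
`c19mc_shift = 2`, `ligand_rho = 0.8`, `noise_sd = 0.5`, and mean coverage
`depth_lambda = 30`; the planted ligand is named *IFNG* to mirror the
screen's intended discovery. Where the underlying study does not state a
generative value (baseline levels, noise law), the log-Gaussian choice is a
conventional stand-in for log-scale expression data, chosen once — it is
**not** an inference about the real data's noise. Consequences for
interpretation: passing tests show the *pipeline* recovers planted structure
at realistic effect sizes; they do not show that real tumour cohorts carry
that structure. Real count overdispersion, batch effects, and miRNA/mRNA
normalisation artefacts are deliberately not simulated.

Default feature identifiers are transparent placeholders: 46
`C19MC-miR-xx` members, `LIG-xxx` background ligands, and a 30-gene
signature stand-in assembled from canonical p53 targets (CDKN1A, MDM2, BAX,
…) and mitotic genes repressed downstream of p53 (CCNB1, PLK1, FOXM1, …).
The study's actual signature genes are supplementary material, so the
signature file remains a required input for real analyses
(`read_signature_file()`).

## TC/TI stratification

Features are standardized as `z = (log2(x+1) − mean) / sd_pop` with the
*population* sd (divisor n), the convention under which two samples at
{0, 3} give z = {−1, +1}; zero-variance features become all-0 and are
flagged. The per-sample activity score is

```
score(s) = mean(z of induced genes) − mean(z of repressed genes)
```

so transcription-competent samples score high. The original two-group choice
was made by visual inspection of a clustered heatmap; we make it
reproducible in two documented ways, recorded in `method_record`:

* `cluster` (default): Ward-linkage (`ward.D2`) hierarchical clustering on
  Euclidean distances over the z-scored signature genes, cut at k = 2; the
  cluster with the higher mean induced-gene z is TC. (Whether the original
  clustering used Euclidean or correlation distance is unstated; Euclidean
  with Ward is the common heatmap default and is fixed here.)
* `threshold`: TC iff score ≥ 0 — a deterministic fallback that needs no
  clustering and is useful for single-sample application.

At the default generator conditions (Δ = 2, sd = 0.5, n = 100) label
recovery exceeds 95% over 50 seeds, and accuracy is non-decreasing in the
effect size over Δ ∈ {0, 0.5, 1, 2}.

## Group comparison statistics

`mann_whitney_u()` computes U from midranks. With combined n ≤ 12 and no
ties the two-sided p is exact by enumerating all rank assignments and
counting `|U − n_a·n_b/2|` at least as extreme; otherwise the tie-corrected
normal approximation is used **without** continuity correction, so U at its
null mean yields p = 1 (identical groups give p = 1 under either route).
The exact route is verified against full enumeration and against
`stats::wilcox.test` in the tests; the implementation itself never calls
either. `boxwhisker_stats()` fixes the percentile convention to linear
interpolation (type 7) and defines outliers as values strictly outside
[p10, p90] — the 10–90-percentile box-whisker style.

## The correlation screen

The cohort is split into high/low thirds by cumulative cluster load
(`split_high_low`, top-n/bottom-n with n = 61 for the 183-sample design;
how the original threshold was chosen is unstated, so n per group is the
exposed parameter, with boundary ties broken lexicographically by sample id
and recorded). Values are `log10(x + 1)` (pseudocount 1 by default: zeros
exist in miRNA-seq and the original handling is unstated). The screen then
computes all ligand × miRNA Pearson correlations (Spearman via flag), with
two-sided p from the t transform `t = r·sqrt((n−2)/(1−r²))`; cells with
p ≥ α = 0.05 are masked — the "insignificant cells are white" convention —
with no multiple-testing correction by default (a Benjamini–Hochberg option
exists but is off, mirroring the original display). The significance test
behind the original mask is not named in the source material; the t-based
test is this package's documented choice. Rows and columns are ordered by
average-linkage hierarchical clustering on correlation distance (1 − r)
between correlation profiles, with the clustering's deterministic leaf
order; degenerate shapes (< 3 rows) fall back to the identity order.
Ligands are ranked by mean r across miRNAs. Under the null the masked
fraction is calibrated to α (checked at n = 122 over 50 seeds), and the
planted ρ = 0.8 ligand ranks first in ≥ 95/100 seeds.

`delta_delta_ct()` is the standard comparative-Ct relative quantification,
`2^−ΔΔCt` after normalizing target to reference (e.g. a miRNA to RNU6B).

## Coverage-gap fusion inference

`find_coverage_gaps()` reports maximal runs of depth ≤ `max_depth`
(default 0) of length ≥ `min_span_bp`. The default minimum span of 10 kb
separates focal deletions from splicing-scale gaps: the motivating event is
76 kb, while spliced-out introns of a single expressed gene are typically
shorter, and — more decisively — RNA-seq coverage gaps *within one gene* are
expected from splicing regardless of length. `assign_gap_to_genes()`
therefore emits a fusion call only when the two breakpoints fall in introns
of two *different* genes; single-gene gaps are annotated "possible
splicing", and exonic or intergenic breakpoints never produce a fusion
call. Intron indices are counted in transcription order (reversed relative
to genomic order on the minus strand), matching how "the intron between
exons 3 and 4" is described for a minus-strand gene.

With Poisson(30) background and `max_depth = 0`, false gaps of ≥ 1 kb are
essentially impossible (each base is non-zero with probability
1 − e^−30), and the tests observe none across seeds; planted breakpoints
are recovered exactly because zero-runs are deterministic given the plant.

`decompose_junction()` splits a junction read into
`left match | linker | right match` with the **left-maximal** convention:
the left match is the longest junction prefix matching the left flank, then
the right match is the longest suffix of the remainder matching the right
flank. When microhomology at the boundary would let the right match extend
into the left match, the decomposition is reported left-maximally and
flagged `ambiguous` rather than silently choosing — the split point is then
a convention, not a sequence fact. The three segment lengths always sum to
the junction length.

`expected_amplicon_size()` is the template arithmetic across a deletion:
`(gap_start − fwd_primer_start) + linker + (rev_primer_end − gap_end)`. At
the printed breakpoint and primer coordinates with a 12-nt linker this gives
241 bp. The originally observed band was ~425 bp; since the printed
breakpoints are explicitly approximate ("~"), the two numbers cannot be
reconciled from coordinates alone, and the fusion report surfaces the
discrepancy instead of resolving it. `example_fusion_models()` ships
*schematic* exon layouts (synthetic coordinates) whose only commitment is
the breakpoint containment structure — FXR2-like intron 7 and TP53-like
intron 3 — for tests and demonstrations.

## Problem sizes and determinism

All simulations in the tests and drivers are sized for interactive use: the
landscape scan uses a 200 kb window (the real region's size), cohorts are
16–183 samples, calibration suites use 50–100 seeds, and coverage tracks
180 kb (placed at the true chr17 offset rather than simulating the
chromosome). Every generator takes an explicit seed and restores the
caller's RNG state; a fixed configuration reproduces fixtures byte for
byte.

## Known limitations

* The scanners are exact-match/mismatch-count tools; no position-weight
  matrices, conservation, or chromatin-state integration.
* The cohort generator is log-Gaussian and i.i.d. across features; no
  count noise, no feature-feature correlation beyond the planted couplings.
* Read-level simulation (FASTQ/alignment) is out of scope; coverage is
  simulated per base directly.
* The high/low split and the 30-gene signature are parameters, not shipped
  truths, for real-data use.

## A worked miniature

```{r worked}
cfg <- sim_config(seed = 42, n_samples = 60)
cohort <- simulate_expression_cohort(cfg)
part <- partition_tc_ti(cohort$mrna, default_gene_signature())
table(part$labels, cohort$labels)

totals <- cumulative_cluster_expression(cohort$mirna, default_c19mc_members())
mann_whitney_u(totals[part$labels == "TI"], totals[part$labels == "TC"])$p

sim <- simulate_coverage_with_deletion(20000, c(5000, 17000), 30, seed = 1)
find_coverage_gaps(sim$track, max_depth = 0, min_span_bp = 1000)
```
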