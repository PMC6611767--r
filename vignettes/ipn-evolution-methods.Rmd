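---
title: "Methods: multi-region evolution analysis of pulmonary nodules"
author: "IPNevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region evolution analysis of pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IPNevolve)
```

# Scope and data model

`IPNevolve` analyses multi-region somatic variant tables from resected
pulmonary nodules spanning four ordered histologic stages — AAH
(preneoplasia), AIS (preinvasive), MIA and invasive ADC. The unit of
analysis is the **lesion**, sampled in one or more **regions**; each
region carries its somatic calls (a MAF-like table), an estimated
purity, and optionally per-bin tumor/normal coverage and heterozygous
site B-allele frequencies (BAFs). Coordinates are 1-based and closed
throughout; locus identity is the exact (chrom, pos, ref, alt) tuple.
Trinucleotide context travels with each call as a 41-nt window centred
on the variant, so no reference genome is needed at analysis time.

Upstream alignment, the individual variant callers, annotation and
purity estimation are out of scope: caller labels, LOD scores and
purities are *inputs*.

# Variant QC

FFPE material produces non-recurrent, low-VAF (usually < 10%),
low-LOD C>T/G>A deamination artifacts. The filter cascade therefore
combines per-call evidence thresholds with a raised LOD floor and
caller concordance:

* SNVs: tumor VAF ≥ 0.05, normal VAF ≤ 0.01, tumor depth ≥ 20×,
  normal depth ≥ 10×, LOD **strictly** > 10, and detection by ≥ 2
  independent callers.
* Indels: tumor depth **strictly** > 15, normal depth **strictly** > 6,
  ≥ 4 supporting reads, same VAF bounds; caller concordance is not
  required (the indel caller family is disjoint from the SNV callers).

Boundary semantics are deliberate and tested: thresholds phrased as
strict inequalities stay strict, "at least/minimum" thresholds are
inclusive. A locus that passes in one region of a lesion is
**force-called** in the sibling regions at relaxed evidence
(VAF ≥ 0.01 and ≥ 2 alt reads): multi-region sampling of one lesion
shares its mutation loci, and sub-threshold signal at an
already-validated locus is information, not noise.

Sample-level QC reports the C>T/G>A transition fraction overall and
stratified at VAF 10%; a sample whose overall fraction strictly exceeds
0.5625 (the top-5% boundary of a frozen-tissue lung adenocarcinoma
reference cohort) is flagged. Flagging annotates rather than deletes:
exclusion is a pipeline decision, recorded in the exclusion log.

Mutation burden counts the union of passing loci across regions, both
raw and per Mb (default denominator 36 Mb, a configurable exome target
size). Two conservative recomputations — dropping private subclonal
mutations (seen in exactly one region and labelled subclonal) and
dropping all transitions — bound the possible effect of residual
artifacts; both can only lower the burden.

# Mutational signatures and APOBEC enrichment

Spectra use the standard 96 pyrimidine-centred trinucleotide channels
(purine-reference calls are reverse-complemented; the channel order is
the lexicographic "A[C>A]A" … "T[T>G]T"). Deconstruction minimises the
Euclidean distance between the normalised spectrum and a non-negative
mixture of reference signatures (non-negative least squares via
`pracma::lsqnonneg`), then iteratively removes signatures with weight
< 0.06 and refits — the convention of established deconstruction tools,
which suppresses spurious small exposures. Lesions with fewer than 100
SNVs are not evaluated (small spectra overfit); the fit is
scale-invariant by construction.

The package ships **no curated biological reference**:
`syntheticSignatures()` generates a clearly-labelled synthetic,
well-separated, column-stochastic matrix used by the simulator and the
recovery tests, and `readSignatureMatrix()` accepts any user-supplied
96 × K reference (e.g. a COSMIC subset) in TSV form.

APOBEC activity is scored at the TCW motif (W = A/T):
`E = (tcw_mut / tcw_ctx) / (c_mut / c_ctx)`, counting mutated motifs
against motif opportunity in the ±20-nt windows of the mutated sites,
both strands. Using the travelling 41-nt windows (rather than a
genome-wide normaliser) keeps the score self-contained; this choice is
documented, not asserted to be numerically identical to genome-wide
variants of the score. A one-sided Fisher test of motif excess is
reported alongside but not used for filtering. Lesions with < 10 SNVs
are not scored. A small upward bias (~7% at the null) arises because
the mutated site always sits at the centre of its own window; the
recovery tests budget for it.

# Copy number and allelic imbalance

Per-bin log2 ratios adjust tumor and normal counts for total mapped
reads, with a 0.5 pseudocount for empty bins. Segmentation is circular
binary segmentation: recursive splitting at the maximal circular
two-sample statistic, a split being accepted when its permutation
p-value (default 1000 permutations, early-terminated once rejection is
certain) falls below α = 0.01; segments narrower than 3 bins merge into
the neighbour with the closer mean. The bin-weighted mean of segment
means equals the global mean to 1e-9 — a conservation invariant under
test.

Two log2 thresholds coexist deliberately and are separate parameters:
**±2** screens genes for high-amplitude events (gene calls use the
length-weighted mean of overlapping segments), while **0.3** defines
the per-bin gain/loss frequencies aggregated by stage (gain strictly
> 0.3, loss ≤ −0.3). Recurrence significance testing (GISTIC-style) is
out of scope; the frequency aggregation is the recurrence summary.

Allelic imbalance uses a two-state hidden Markov model on the folded
BAF `|BAF − 0.5|`: a balanced state centred at 0 and an imbalanced
state centred at 0.1 (Gaussian emissions, sd 0.03 — the typical folded
noise scale at exome depth; switch probability 0.001). Maximal Viterbi
runs of ≥ 10 imbalanced sites become events. This is an **unphased
simplification** of haplotype-based imbalance callers with the same
event semantics (contiguous imbalanced runs); it trades the power of
phasing for zero external dependencies. Event counts are reported per
region, and per lesion as the maximum over regions (the source of the
per-lesion convention is not settled; both are available).

# Clonality

For each mutation, multiplicity is
`m = round(VAF/p · (p·CN + 2(1−p)))` clipped to [1, CN], and
`CCF = VAF · (p·CN + 2(1−p)) / (p·m)`; CN defaults to 2 where no
segment overlaps. The 95% interval maps the Jeffreys
Beta(alt + 0.5, depth − alt + 0.5) interval on VAF through the same
linear transform, with boundary adjustments at alt = 0 and alt = depth
so the interval always brackets the point estimate. A mutation is
**clonal** iff the interval overlaps 1 — the identical downstream rule
used by posterior-sampling clonality callers, with a closed-form
interval replacing MCMC; this is a stated simplification, exact in the
binomial limit the simulator generates. CCFs above 1 are retained
internally (they flag multiplicity misestimation) and clipped at 1.5
for reporting.

Across regions the conservative conjunction applies: lesion-clonal
means present in **every** region and interval-clonal in every region
where measured. Lesions with < 10 union mutations are not evaluated.
An optional binomial-mixture EM over k = 1..6 clusters, selected by
BIC with quantile-spread seeded initialisation, stands in for
Dirichlet-process clustering when a discrete clonal structure is
wanted.

# Phylogenetics

Per patient (or lesion), a binary presence matrix over regions plus an
all-zero `NORMAL` germline row feeds Hamming distances, neighbor
joining (`ape::nj`, negative branches clamped to 0) and Wagner
parsimony. Parsimony scoring is an in-package Fitch pass on binary
characters (free reversals; with germline rooting reversals are never
optimal in practice), with exhaustive topology enumeration up to 8
leaves (ties broken by lexicographic Newick string) and an NJ-seeded
NNI search beyond; `phangorn`'s independent implementation
cross-checks the scores in the test suite. Branch lengths are the
parsimony changes assigned per edge by the top-down pass (root state 0
at `NORMAL`), so lengths sum exactly to the score. Trunk mutations are
the columns present in every region; their proportion is the
early-event fraction compared across stages.

# Risk scoring and statistics

The Brock logistic model is implemented exactly as printed, including
the centring constants (age − 62, (size/10)^−0.5 − 1.58113883,
count − 4) and the −6.7892 intercept, so a 62-year-old with a single
4 mm baseline nodule and count 4 evaluates to the intercept
(probability ≈ 0.112%). The categorical coefficients (sex, family
history, emphysema, nodule type, upper lobe, spiculation) are **not**
part of this package's claims: they are additive log-odds inputs the
caller supplies from the original publication.

Group comparisons delegate to the standard R implementations:
Kruskal–Wallis with tie correction, one-sided Wilcoxon rank-sum (exact
for small tie-free samples), Tukey HSD, and the Cochran–Armitage trend
test. The smoker/non-smoker gene comparisons are reproduced by the
one-sided hypergeometric (Fisher) tail: the source labels these
"chi-square" but the printed p-values (0.283, 0.073, 0.092) match the
exact tail, so both the exact test and the label's test are available
and the exact tail is what the reproduction targets use.

# The synthetic cohort generator

The simulator exists so every downstream stage is testable against
ground truth — the real cohort is controlled-access. Its defaults
encode the emulated study conditions; they are fixed study parameters,
not tuning knobs:

* **Design**: 2–3 regions per lesion, negative-binomial depth
  (mean 150×, matching the emulated sequencing design; dispersion 10),
  purity uniform on 0.4–0.8 (the macrodissection floor of 40% diseased
  cells to ~80% realistic ceiling).
* **Burden**: Poisson per-lesion means rising 40 → 80 → 140 → 200
  across AAH → AIS → MIA → ADC, giving the progressive single-nucleotide
  gradient at realistic per-Mb scales.
* **Clonal architecture**: clone trees with 2–5 clones. AAH uses the
  *diversify* regime (subclones with region-specific home territories,
  occasionally private to one region); AIS/MIA/ADC use the *sweep*
  regime (founder exclusive fraction ≥ 0.9 everywhere — a completed
  selective sweep). The founder mutation share rises 0.30 → 0.55 →
  0.60 → 0.70. Together these produce the rising clonal-proportion and
  trunk-proportion gradients with the AAH-versus-later contrast
  dominating, and a plateau across the later stages — the same shape
  the real cohort shows.
* **Reads**: alt counts are binomial at the expected VAF
  `p·m·CCF / (p·CN + 2(1−p))`; LOD is ~2 per alt read so that
  well-supported variants clear the LOD > 10 floor and marginal ones do
  not; 2–5 concordant callers per true variant.
* **FFPE artifacts**: Poisson per region (default 10), C>T/G>A only,
  VAF = 0.1·Beta(1.5, 3.5) (all < 10%, mode ≈ 2–3%), LOD uniform on
  (2, 10), single caller, never recurrent across regions. All flagged
  in truth.
* **Chromosomal events**: a synthetic 4-chromosome, 1-Mb-binned genome;
  copy-number segments (5–15 bins, mostly |log2| 0.4–1.2 with 10%
  high-amplitude ≥ 2.2) at stage rates 0.2/1.5/2.5/3.5 per lesion — few
  in AAH, prevalent later (the demarcated chromosomal transition); AI
  blocks of 25–50 heterozygous sites at folded deviation 0.15 at stage
  rates 0.3/1/4/6 — the steep AIS→MIA rise.
* **Determinism**: every lesion draws from its own substream derived
  from the master seed, so cohorts are byte-reproducible and stable
  under changes elsewhere.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: germline haplotypes and phasing
(the AI caller is tested against its own unphased generative model),
mapping/alignment artifacts, context-dependent sequencing error,
subclonal copy number, purity estimation error (purity is passed
through exactly), and real signature profiles (the synthetic reference
is well-separated by construction; real signature sets are more
collinear and recovery is correspondingly harder).

# Numerical choices and degenerate inputs

Zero-depth calls fail depth rules without division errors; empty call
tables propagate as empty results; all-identical groups give H = 0,
p = 1; zero-margin contingency tables give p = 1; a constant log2
series yields one segment; fewer BAF sites than the minimum run length
yields no events; clustering on identical CCFs returns k = 1. The EM
uses a 1e-8 log-likelihood convergence tolerance and 200-iteration cap;
CBS permutation tests early-terminate once rejection is impossible.

# Problem sizes in the shipped tests

The test and acceptance runs use 100-bin CBS problems, 200–600-site BAF
series, 1000-mutation signature draws (50 seeds), 30-mutation × 3-CCF ×
50-seed recovery grids, and a 20-lesion-per-stage cohort (~80 lesions,
~9,000 true mutations) for the gradient reproduction — sizes chosen so
the full suite runs in minutes on one CPU while keeping every
statistical check comfortably powered.

# Known limitations

The AI caller's sensitivity is tied to the folded-deviation scale of
its emission model; imbalance much weaker than the 0.1 state centre
(high-purity-diluted events) needs the deviation parameter lowered.
The closed-form CCF interval ignores purity and copy-number
uncertainty. The forced-calling rescue requires the locus to appear in
the sibling region's table (a pileup surrogate); loci absent from the
table are treated as absent. Exhaustive parsimony is capped at 8
leaves (10,395 topologies); beyond that the NNI heuristic makes no
optimality guarantee.
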