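---
title: "Discovering and characterizing drug-induced transcriptional modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and characterizing drug-induced transcriptional modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codimr)
```

## The model

A drug-treatment expression compendium is a genes × treatments matrix of
z-scores: how strongly each gene responds to each drug treatment relative
to background. The working assumption of this package is that the
biologically meaningful structure in such a matrix is *modular*: subsets
of genes respond coherently (up or down) to subsets of drugs, while the
remainder of the matrix is noise. A module is therefore a bicluster — a
gene set with signed scores plus the drug/treatment set that regulates it
— and modules found independently in several systems and matched across
them (CODIMs) are the units we trust for downstream inference.

### ISA: scoring, thresholding, fixed points

The Iterative Signature Algorithm alternates between the two sides of the
bicluster. Given the row-standardized matrix `E_G` (each gene's profile
has mean 0, s.d. 1) and the column-standardized `E_C`, and a current
signed gene vector `g`:

1. condition scores `c = E_Gᵀ g / ‖g‖₁`; keep conditions with
   `|c_j| > t_drug · sd(c)`, zero the rest;
2. gene scores `g = E_C c / ‖c‖₁`; keep genes with
   `|g_i| > t_gene · sd(g)`.

The s.d. in each thresholding step is taken over the *full* score vector
at that iteration, not over current members, so the threshold adapts to
how concentrated the signal is. Membership is signed: up- and
down-regulated genes coexist in one module, which matters for real
modules with inverse expression patterns (e.g. the two arms of a
cell-cycle response). Iteration stops when the Pearson correlation of
consecutive gene-score vectors exceeds `1 − eps` for two consecutive
iterations (`eps = 1e-2`), the gene or condition set empties, or
`max_iter` is reached; only converged runs yield modules. A converged
module is (approximately) a fixed point: re-feeding it as its own seed
reproduces the same membership.

These conventions — L1 normalization of the propagated vector, sd over
the full score vector, the correlation convergence rule, seeds of
`max(5, 1%)` random genes with +1 signs — are pinned so that runs are
exactly reproducible; they follow the conventions established by the
standard ISA implementations.

### The threshold sweep and why it needs cleanup

No single threshold pair is right for all modules: strong compact modules
surface at high thresholds, weaker or broader ones only at lower
thresholds. `isa_sweep()` therefore runs `n_seeds` random seeds for every
pair on a grid — gene thresholds 5 to 2, drug thresholds 4 to 1 (4 to 2
for liver-style data), steps of 0.2. The grids are enumerated in
ascending order; since a module found at a high threshold is a strict
member-subset (a truncation) of its lower-threshold variant, ascending
order makes the *least truncated* variant of each module the first one
encountered within a priority band (see below). The sweep output is
massively redundant by construction and goes through four filters:

1. **Robustness**: a module's signature strength (geometric mean of its
   gene- and condition-side projections, unit-normalized) must exceed the
   best strength obtained by running ISA at the same thresholds on a
   fully permuted copy of the matrix. The permutation scrambles the raw
   matrix once and re-standardizes, so the null input is internally
   consistent; permuting `E_G` and `E_C` independently would destroy the
   fixed-point structure and make the null vacuous.
2. **Constitutive filter**: modules whose genes are strongly coexpressed
   in *untreated* samples (≥ 10% of gene pairs with r > 0.6) reflect
   intrinsic cellular programs — cell-cycle phase, ribosome biogenesis —
   not drug responses, and are removed. Pairs with undefined correlation
   or genes missing from the untreated matrix count as not coexpressed
   (conservative: missing evidence never removes a module).
3. **Size filter**: at least 20 genes and 5 drugs (10 for liver data,
   where dose/time profiles of one drug are collapsed to the drug level
   before counting).
4. **Prioritized redundancy removal**: modules are stably sorted by
   threshold band — gene thresholds in 4–3 before 5–3.2 before 2.8–2 for
   cell lines (3–2 before 5–3.2 for liver), then drug thresholds 3–2
   before 4–3.2 before 1.8–1 — to preferentially retain medium-sized
   modules. Walking that order, a module is dropped if its signed
   membership-score vector correlates (absolute value) above 0.3 with an
   already-kept module, and in a second pass if its gene overlap with a
   kept module reaches hypergeometric P < 1e-5. Score vectors are laid
   out over the full gene universe (zeros for non-members): over the
   union of two member sets, disjoint modules would be exactly
   anti-correlated and the filter would degenerate. The absolute value
   makes sign-flipped duplicates (ISA converges to both signs of one
   attractor) redundant, as they should be.

### Conservation across datasets

Catalogs from two datasets are compared in the intersection of their gene
universes, after translating liver genes through a one-to-one orthology
map. Every module pair gets an upper-tail hypergeometric overlap P;
BH-FDR is applied per dataset pair (each pair is reported as its own
comparison); links with q < 0.01 are significant. A link is a *reciprocal
best hit* when each module is the other's minimum-P partner (ties: larger
overlap, then lexicographic id). CODIMs are the connected components of
the RBH graph over cell-line modules, with gene and drug sets the unions
over members; liver RBHs annotate a CODIM as cross-species conserved but
contribute no members, because the liver system differs in gene space,
drugs, and physiology. Drug overlaps of linked cell-line modules get a
one-sided Fisher test over the shared drug universe (liver is refused —
too few drugs in common for a meaningful drug-overlap comparison).

The conservation permutation test asks whether the *number* of modules
with a significant RBH partner exceeds chance: each module of the first
catalog has its gene set replaced by a uniform random set of the same
size from that catalog's universe, the count is recomputed, and the
p-value is the add-one empirical tail `(1 + #{null ≥ obs})/(1 + n_perm)`
— with 999 permutations the minimum attainable P is exactly 0.001. The
membership permutation (rather than permuting the expression matrix and
re-running discovery) is a declared, cheap stand-in that preserves module
sizes and the partner catalog.

### Functional coherence and drug-set enrichment

Coherence of a gene set against an association network is the fraction of
its gene pairs linked in the network (self-relations excluded), compared
with 1000 random gene sets of the same size drawn from the *expression*
universe — not from network nodes only; genes absent from the network
contribute no edges. This choice keeps the null aligned with how modules
arise (from expression data, with the network as a lookup) and makes the
test slightly conservative for modules of well-studied genes. Networks
are pre-filtered to score > 0.4 and coexpression-channel edges are
excluded, since coexpression evidence is methodologically circular here.
Duplicate channel edges for one pair combine by maximum score.

Drug-set enrichment is a one-sided Fisher test per annotation term
(terms with fewer than five drugs in the universe are dropped first),
BH-FDR within each category, significance at q < 0.1 — except chemical
fragments at q < 0.01, because the fragment category is much larger and
its terms heavily overlap. Repositioning candidates inside a module are
its drugs *not* annotated with the target term whose maximum Tanimoto
similarity (|a∧b|/|a∨b| on 1024-bit fingerprints) to any annotated module
drug is below 0.5: same transcriptional context, novel chemistry.

### Dose–response validation

The experimental follow-up of a repositioning prediction produces
concentration/response curves. Raw signal is converted to percent via the
plate's high/low controls (values outside [0, 100] are kept; the
constrained asymptotes absorb them), then fit by least squares to the
two-parameter log-logistic `f(x) = 100/(1 + exp(b(ln x − ln e)))` with
bottom 0% and top 100%; `e` is the IC50. The optimizer is
Levenberg–Marquardt with multi-start: five log-spaced midpoint
initializations across the dosed range, two slope starts, best RSS wins;
the convergence flag requires both optimizer success and a small
gradient norm, so an all-flat curve yields a flagged non-fit rather than
an error. Binding IC50s convert to inhibition constants via Cheng–
Prusoff `Ki = IC50/(1 + L/Kd)` (the radioligand concentration and Kd are
required inputs — they are assay properties no fit can recover), and hits
classify as confirmed below 15 µM, ambiguous below 50 µM, else disproved.

## What the synthetic data emulate — and what they do not

`generate_compendium()` emulates the statistical skeleton of multi-system
drug screens: independent Gaussian background (s.d. `noise_sd`), planted
biclusters as mean shifts of `effect_size` s.d. with per-gene signs,
modules shared across declared datasets, a liver-like dataset restricted
to an orthologous ~40% of the gene space with several dose/time profiles
per drug treated as independent experiments, untreated companion
matrices, and — for constitutive modules — a shared latent factor in the
untreated samples with loading 2, giving pairwise correlations around
0.8, well above the 0.6 filter cutoff. Raw mode adds baselines, batch
offsets, replicates, control samples, present calls and missing values so
the preprocessing branch (quantile normalization → imputation →
max-variance probe collapse → regularized z-scores → replicate averaging
→ ortholog restriction) can be exercised end to end.

What passing tests on these data show: the algorithmic chain recovers
exactly what was planted, removes what should be removed, and its tests
are calibrated under the null. What they do *not* show: performance under
correlated noise, batch effects confounded with treatment, heavy-tailed
responses, partially overlapping modules of very different strengths, or
annotation catalogs with realistic term dependence — real compendia are
harder than this generator in all those ways.

A dimensioning constraint worth knowing: sd-based condition thresholds
cannot isolate a module covering a large fraction of all treatments — as
the planted fraction approaches half, the score distribution becomes
symmetric-bimodal and the threshold rises with the signal itself.
Realistic screens profile many more drugs than any one module covers
(~10% or less); the demo's liver dataset therefore uses 80 drugs with a
12-drug conserved module (~15% of conditions), near the edge of the
detectable regime on purpose.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gene_thresholds` | 5→2 by 0.2 | gene stringency grid (units: s.d. of gene scores) |
| `drug_thresholds` | 4→1 (liver 4→2) by 0.2 | condition stringency grid |
| `n_seeds` | 2000 (desk); demo runs use 30–100 | random restarts per threshold pair; full-compendium analyses want 20 000 or more, but planted-module recovery on synthetic data saturates below 100 |
| `eps`, `max_iter` | 1e-2, 100 | convergence tolerance / cap |
| `constitutive_pair_fraction`, `constitutive_r` | 0.10, 0.60 | untreated-coexpression removal rule |
| `min_genes`, `min_drugs` | 20, 5 (liver 10) | size floor |
| `redundancy_corr`, `overlap_p_cut` | 0.3, 1e-5 | redundancy removal |
| `q_gene`, `q_drug` | 0.01 | FDR cutoffs for cross-dataset links |
| `n_perm`, `n_random` | 999, 1000 | permutation counts (min P = 1/(n+1)) |
| coherence `min_score` | 0.4 | association-network confidence cutoff |
| enrichment `q_cut` | 0.1 (fragments 0.01) | per-category FDR cutoffs |
| Tanimoto `max_sim` | 0.5 | structural-novelty cutoff for repositioning |
| Ki thresholds | 15 µM, 50 µM | confirmed / ambiguous hit bounds |

## Numerical and degenerate-input choices

- All enrichment-style tests are one-sided (over-representation); the
  Fisher test is computed through the identical upper-tail hypergeometric
  parametrization, and the two functions are exhaustively checked to
  agree.
- Empirical p-values use the add-one rule, so P = 0 never occurs and
  "P ≤ 1/(n+1)" is a meaningful statement of maximality.
- The BH procedure is the FDR correction throughout.
- Probe-collapse ties (equal variance) break by lexicographic probe id;
  best-hit ties break by smaller P, larger overlap, then lexicographic
  module id — all total orders, so results are permutation-stable.
- The missing-value rule is strict ">10%": a probe at exactly 10% missing
  is kept.
- The regularized z-score adds the 0.1 quantile of all per-gene s.d.
  values to each denominator; constant genes get finite (zero) z-scores.
  The s.d. is computed over all samples, treated and control, before
  replicate averaging, so averaging shrinks noise without rescaling the
  per-gene signal.
- Replicate selection maximizes mean pairwise cross-system correlation —
  exhaustively up to 64 combinations, then greedy coordinate ascent
  seeded from the best single pair (exact at realistic replicate counts).
- Single-column quantile normalization warns and returns its input.
- All randomness flows from one integer seed through named per-stage
  substreams (`stage_seed`), so any stage can be re-run in isolation and
  a full pipeline run is byte-reproducible; output writers use fixed
  numeric formatting and the run manifest contains no timestamps.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the study at desk scale,
chosen so recovery is saturated while a laptop CPU finishes comfortably:
cell lines of 1500 genes × 120 drugs, a liver set of ~600 orthologs × 80
drugs × 3 profiles, 30 ISA seeds per threshold pair on the full grids,
999 conservation permutations and 1000 coherence randomizations;
calibration checks use 400 coherence trials and 100 enrichment
catalogs; dose–response recovery uses 8 semilog doses and 200 noise
replicates. The discovery stage is O(genes × drugs × n_seeds) per
threshold pair and parallelizes trivially over datasets if needed.

## Known limitations

- ISA finds axis-aligned mean-shift biclusters; purely sign-mixed *drug*
  patterns within one module (condition scores near zero on average) can
  cancel and be missed.
- The conservation permutation preserves module sizes but not gene-gene
  correlation inside modules; its null is mildly liberal for datasets
  with heavy intrinsic coexpression.
- Batch correction for cell-line-style input is out of scope: the package
  expects batch-adjusted z-scores on that branch as input.
- Fragment generation and fingerprinting are accepted as inputs
  (`fingerprints` matrix, `fragment` catalog category); no cheminformatics
  engine is bundled.
- The annotation of a CODIM tests its union drug set against the union
  cell-line drug universe; per-dataset testing is available by running
  `enrich_terms()` on the member modules directly.
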