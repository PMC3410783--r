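---
title: "Methods: integrated miRNA-mRNA analysis of hyperoxic lung injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA-mRNA analysis of hyperoxic lung injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxymir)
```

`oxymir` reimplements, as composable tested functions, the analysis chain
of a two-platform expression study of hyperoxia-induced neonatal lung
injury: mRNA arrays and TaqMan low-density miRNA arrays profiled across a
postnatal time course, integrated through anti-correlation and target
prediction. This vignette is the package's account of the underlying
methods: the models, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, and the judgment calls made
where the procedure admitted more than one reading.

## Study design and contrasts

The emulated design has five cells: room-air (RA) animals at postnatal
days P1, P14 and P29, and oxygen-exposed (O2) animals at P14 and P29.
There is no P1-O2 cell. The defaults are 2 RA and 3 O2 replicates per
cell — 12 samples. Three pairwise contrasts carry all the biology:

* **A** — P29-RA vs P14-RA: normal late alveolar development;
* **B** — P14-O2 vs P14-RA: the early hyperoxia response;
* **C** — P29-O2 vs P29-RA: the late (established-injury) response.

## miRNA quantification

Raw CT values from a 384-well TaqMan array are processed in three steps.

1. **Ceiling** (`apply_ct_ceiling()`): any CT above 35 cycles, and any
   undetected well, is set to 35. This is the standard TLDA convention;
   35 cycles is the practical single-copy detection limit, and clamping
   keeps undetectable wells from contributing spurious dynamic range.
2. **ΔCT** (`normalize_delta_ct()`): per sample, each miRNA's CT minus the
   U6 small nuclear RNA CT. ΔCT is a log2-scale abundance (negated:
   greater ΔCT = lower expression), which is why
   `delta_ct_to_expression()` feeds `-ΔCT` into the differential-
   expression machinery so "up" keeps its usual meaning.
3. **Copies per cell** (`ct_to_copy_number()`):
   `10^((40 − CT)/3.34) / 22`. The slope of 3.34 cycles per decade is
   near-ideal PCR efficiency (`10^(1/3.34) ≈ 1.993` per cycle), and the
   divisor 22 folds in the assumption of 30 pg total RNA per cell. The
   30 pg figure is carried as metadata only — changing it without
   changing the divisor would have no effect, which is why
   `quant_constants()` treats 22 as the operative constant.

**Detection** is not standardised on this platform; the rule here
(`detect_expressed()`) is a declared convention: a miRNA is detected if
its CT is strictly below the ceiling in at least `min_fraction`
(default 0.5) of the samples of at least one design cell. The 0.5 default
tolerates one dropout in a triplicate cell while excluding rows that only
ever sit at the ceiling. One open point in the source procedure is whether
ΔCT used raw or clamped values for CTs between 35 and 40; this
implementation applies the ceiling first, so ΔCT has a hard detectability
floor of `35 − CT_U6`.

## mRNA preprocessing

Inputs are probe-set-level log2 intensities. `quantile_normalize()`
applies the across-array core of standard array preprocessing: every
column is mapped onto the mean of the column-wise order statistics, with
ties given the mean of their tied ranks' reference values (deterministic,
idempotent). The probe-level background-convolution model of full RMA is
deliberately out of scope — the package starts from summarised values.

`filter_low_expression()` drops probes whose *maximum* over all samples is
below `min_log2` (default 5.0, in the lower quarter of the typical 4–12
log2 array range). The max-based rule operationalises "low at every time
point": a probe high in even one cell is kept, since it can still drive a
contrast. No threshold was stated in the source procedure, so the value is
exposed in the pipeline config rather than hard-coded.

## Differential expression

`fit_cell_means()` fits, per probe, the cell-means parameterisation of the
two-factor model. Because the layout is incomplete (no P1-O2), a full
factorial decomposition with interaction is not estimable over the whole
design; the cell-means form is, and group comparisons within a two-way
ANOVA of such a layout reduce exactly to pooled-variance contrasts on cell
means. The residual variance pools across all five cells
(df = N − 5 = 7 at the default design), and `test_contrasts()` computes
`t = (m₁ − m₂) / √(s²(1/n₁ + 1/n₂))` with a two-sided p per contrast.
Probes with zero residual variance are flagged degenerate and excluded
from inference rather than producing p = 0. No variance moderation or
shrinkage is applied: with planted-truth simulations the exact t reference
distribution is what makes calibration testable, and the t-test's
uniform-null behaviour is verified in the test suite.

Fold changes use the reciprocal-negative convention
(`signed_fold_change()`): `2^d` for up, `−2^(−d)` for down, magnitude
always ≥ 1, so a "fold change > |2|" gate is literally
`abs(signed_fc) > 2`.

Multiple testing is Benjamini–Hochberg within each contrast group.
`bh_p_cutoff()` reports the largest order statistic passing the step-up
condition — the raw-p threshold whose selection set equals `q ≤ FDR`.
This is the mechanism by which an FDR gate gets reported as a
dataset-specific raw-p statement ("to p < 0.018" on one platform,
"p < 0.027" on the other, in the study this emulates); the equivalence is
asserted exactly on 1000 random p-vectors in the tests. Defaults follow
the emulated study: fold-change cutoff |2| for mRNA, |4| for miRNA,
FDR 0.05.

### Patterns

`classify_patterns()` gives every significant probe exactly one
cross-contrast label. Hyperoxia membership takes precedence: a probe
significant in B or C is classified by its B/C membership and sign
(mRNA: 3/4 B-only, 5/6 shared, 7/8 C-only); only probes significant in A
alone get the developmental labels (mRNA 1/2). The miRNA numbering
follows that platform's printed convention (1 = A-down, 2 = A-up, …,
6 = C-only up); it has no slots for C-only-down or shared-down miRNAs
because the emulated study observed essentially none (all but one
responsive miRNA rose). Those combinations, and B/C sign conflicts, go to
an explicit `"discordant"` bucket — auditable, never silently dropped.

## Target integration

The pairing heuristic is set logic on significance calls, not correlation
coefficients: within each hyperoxia group, every up-miRNA is paired with
every down-mRNA probe of the same group (`candidate_pairs()`), and a pair
survives if the probe's gene is among that miRNA's predicted targets in
the database (`intersect_predictions()`). Same-group co-occurrence
(rather than pooling all of B∪C) is the declared reading of
"simultaneously"; the `groups` argument makes the pooled variant a
one-line change. Counting follows the two scales real reports use:
`n_pairs` counts distinct (miRNA, probe) pairs pooled over groups, while
`unique_mrnas` counts genes — several probes can interrogate one gene, so
the two differ by design. Probes missing from the probe→gene map are
dropped and counted (`n_unmapped`), mirroring how identifier conversion
loses transcripts silently in practice. `cross_database_overlap()` is
plain set intersection of the gene-level target sets of two databases.

## Enrichment

`enrich_terms()` is the one-sided hypergeometric over-representation test:
`p = P(X ≥ k)` for overlap `k` between the gene list and a term within a
reference universe (the full array's gene complement, when available). No
EASE-style score deflation and no term-level multiple-testing correction
are applied — the emulated workflow filters at nominal p < 0.05 and ranks
the survivors by overlap count (`top_terms()`, ties broken by smaller p
then term id, truncated at 10). A BH column can be added with
`bh_adjust()` by callers who want it.

`compare_term_enrichment()` implements the two-list comparison: each term
gets the spread of its two −log10 p values, defined as their population
standard deviation `|x − y| / 2`. Any positive multiple of `|x − y|`
induces the same ranking, so the constant is a recorded convention, not a
modelling choice.

## qPCR quantification

`delta_delta_ct()` is plain `2^−ΔΔCT` — invariant to global CT shifts,
equal to 1 when treated and control ΔCT agree. Efficiency correction is
deliberately not applied to fold changes; `fit_standard_curve()` reports
the efficiency (`10^(−1/slope) − 1`, flagged outside [70%, 130%]) as QC,
and `absolute_quantify()` inverts the fitted line. Replicate CTs should be
averaged arithmetically before ΔΔCT, the standard convention.

## The synthetic generator

`simulate_study()` produces every input with planted structure, so each
stage has an oracle:

* **Baselines**: per-probe means uniform on 4–12 log2 units — wide enough
  to exercise the low-expression filter without modelling a chip.
* **Effects**: planted probes are shifted ±`effect_log2` in the cells
  that make them differential in exactly one group. Group-A plants shift
  *both* P29 cells (a developmental change present under both
  treatments): shifting P29-RA alone would leak an opposite-sign effect
  into contrast C, so orthogonal placement is what makes per-group
  recovery interpretable. Shared B∩C plants (for the "common" patterns)
  are requested explicitly via `n_shared_bc`; the three per-group sets
  are disjoint.
* **Noise**: i.i.d. Gaussian on the log2 scale, matching the t-test's
  assumptions so calibration and recovery results are interpretable. The
  source study reports no replicate-level variance estimate, so
  `noise_sd` is a free parameter; the default 0.25 log2 units is a
  typical within-group array sd, chosen once.
* **CT values**: `u6_ct + baseline ΔCT − effect + noise`, with one cycle
  per two-fold change — the same ideal-efficiency assumption the
  copy-number formula's base `10^(1/3.34) ≈ 2` encodes. A configurable
  fraction of *non-planted* miRNAs is forced above the ceiling in every
  sample (planted rows are never overwritten, keeping ground-truth counts
  exact). The default miRNA effect of 3 log2 units reflects the platform:
  miRNA inductions in this model are large (tens to hundreds-fold), and
  the |4| fold gate presumes them.
* **Edges and databases**: each up-planted miRNA in B/C receives planted
  target genes among the down-planted probes of the same group;
  prediction databases contain each true edge with probability
  `1 − miss_rate` plus per-miRNA decoys. Two databases generated with
  different seeds/miss rates emulate the partially-overlapping-databases
  situation that motivates the cross-database overlap statistic.
* **Annotation**: random gene sets plus one planted term whose members are
  preferentially drawn (bias factor) when composing a biased list.

What the generator does **not** emulate: probe-level CEL structure,
intensity-dependent (heteroscedastic) array noise, correlated probes,
assay-specific PCR efficiencies, sequence-based target prediction, or the
GO graph. Passing tests therefore demonstrate that the *procedures* are
implemented correctly and are calibrated under their stated assumptions —
not that the pipeline's thresholds are optimal for any particular real
dataset.

## Numerical choices and degenerate inputs

* Quantile-normalisation ties: mean of tied ranks' reference values;
  idempotent to 1e−12.
* Zero residual variance: flagged, p = NA, excluded from selection.
* `bh_p_cutoff` with nothing passing: returns 0 (empty selection).
* Undetected CT markers accepted: empty field, `NA`, `Undetermined`.
* Copy-number round trip is exact to machine precision over CT ∈ [10, 40].
* Seeds: one top-level seed per run; stage seeds derived by a fixed
  integer map, all below 2³¹.

## Problem sizes

The shipped demo and the verification scripts use 2000 probes × 12
samples, 300 miRNAs, and 20–50 Monte-Carlo replicates per property —
sizes at which per-group effects of 2.5 log2 units over sd 0.25 give
essentially complete power, so recovery rates isolate logic errors rather
than power limits, while keeping a full run in seconds.

## Known limitations

* No variance moderation: at 2 replicates per RA cell the pooled t-test
  is exact but not powerful; limma-style shrinkage would change the
  calibration guarantees tested here and is deliberately out of scope.
* The detection rule and the low-expression threshold are declared
  conventions, not estimates of the emulated study's (unstated) ones.
* Per-contrast BH (three separate families) is one defensible reading of
  "adjusted by FDR" per group; a pooled-family variant would give
  different derived cutoffs.
* The enrichment test ignores term overlap structure and the GO
  hierarchy; fuzzy functional clustering of terms is out of scope.
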