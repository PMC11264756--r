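---
title: "Methods behind saltscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind saltscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltscreen)
```

`saltscreen` implements a complete desk pipeline for salt-performance
screening of a crop variety panel: JIP-test extraction from fast
chlorophyll-a fluorescence transients, the salt performance index and its
reduction-factor machinery, the group statistics used to letter such
figures, SSR diversity with a Shannon-information partition of molecular
variance, protein physicochemical characterisation, and relative expression
by the 2^-ddCt method. This vignette explains each model, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The JIP test

A dark-adapted leaf exposed to saturating light produces the polyphasic
O-J-I-P fluorescence rise between about 10 µs and 1 s. The JIP test reduces
the curve to marks — F0 at 50 µs (the origin, photochemical traps open),
F300 at 300 µs, FJ at 2 ms (the J step) and FM at the transient's maximum —
and derives

* `FV/FM = (FM - F0) / FM`, the maximum potential quantum efficiency of
  photosystem II;
* `M0 = 4 (F300 - F0) / (FM - F0)`, the approximated initial slope (per ms)
  of relative variable fluorescence;
* `VJ = (FJ - F0) / (FM - F0)`, the relative variable fluorescence at 2 ms;
* the performance index on absorption basis,
  `PIabs = [1 - F0/FM] / (M0/VJ) × (FM - F0)/F0 × (1 - VJ)/VJ`.

Two readings of the PIabs middle term circulate in print; the
dimensionally consistent reaction-centre term `(FM - F0)/F0` is the
default (`variant = "standard"`), and the literal anomalous form
`(FM/F0)/F0` is available as `variant = "as_printed"` so either can be
reproduced. The variant used is recorded in every output row.

Numerical choices:

* **Mark times are configurable** (`t_f0`, `t_f300`, `t_fj`; defaults
  50 µs, 300 µs, 2 ms). Some descriptions quote "50 ms" for the origin
  mark; on a 10 µs–1 s acquisition that reading is expressible here but is
  not the default, which follows standard JIP-test practice.
* **Interpolation is linear in log10(time)** because OJIP acquisitions are
  log-spaced; linear-in-time interpolation overshoots badly between
  decade-spaced samples.
* **FM is the global maximum** of the curve, not F(1 s), tolerating
  transients that peak before the end of acquisition.
* **No smoothing by default**; a 3-point running median (`smooth = TRUE`)
  is available for noisy curves.
* Degenerate curves (FM = F0) and marks outside the acquired range raise
  errors rather than extrapolating.

A caveat worth knowing: algebra reduces the standard PIabs to
`(FM - F0)^2 (FM - FJ) / (4 FM F0 (F300 - F0))`, so PIabs decreases with
rising F0 only while `F0 < F300/2`. Real transients sit comfortably inside
that regime, and the package's property tests exercise it there; outside
it the index is still computed faithfully but is no longer monotone in F0.

## Relative values, reduction factors and the SPI

Screening compares a medium-salinity platform (8 dS/m) against a
low-salinity control platform (4 dS/m) at three growth stages (`leaf3`,
`boot`, `flowering`) with six replicates per cell. For each
variety × stage × parameter cell the **relative value** is the
medium-platform mean over the low-platform mean. The **reduction factor**
is the relative value at leaf 3 over the relative value at flowering — a
decline magnitude under progressive salinity (RF > 1 means decline).

The **salt performance index** is `SPI = log10(A) + n·log10(B)`, with A
the marker's relative value at leaf 3, B at late flowering, and n an
integer weight expressing that a late decline is n times as consequential
as an early one. The log base is 10 by default (`base` argument) —
consistent with the drought-factor-index lineage this construction
follows.

Open design points and how they were resolved:

* **Marker selection** (`select_marker`): among parameters whose decline
  is significant and of consistent sign in at least a configurable
  fraction of varieties (default all of them), the one with the largest
  mean RF wins; ties break by the larger fraction of significant
  varieties, then lexicographically, so the result cannot depend on input
  order. `n = max(1, round(mean RF))` — a mean RF of 2.3 gives n = 2;
  no published rounding rule exists, so nearest-integer is used.
* **"Significant reduction"** is a per-variety one-way contrast of
  replicate-level relative values (each medium replicate divided by its
  cell's low-platform mean) at leaf 3 versus flowering, at p ≤ 0.01.
  The choice of test behind published reduction factors is not documented
  anywhere we know of; an ANOVA contrast on relative replicates is the
  least-assumption option and runs through the same `one_way_anova` used
  everywhere else.
* **Means, not replicates, enter A and B**: relative values are ratios of
  cell means, matching how relative means are conventionally reported.
* **Unbalanced cells** are used with a warning; cells with fewer than 3
  replicates are excluded from significance testing (their RF is still
  reported with `significant = NA`).

`spi_correlations` reports Pearson r, R² and two-sided p for SPI against
the flowering-stage relative marker value and against dry-matter gain
(medium/low dry mass). These are descriptive correlations on the data
given; the package makes no claim that SPI predicts field yield beyond
them.

## Group statistics

`one_way_anova` wraps the classical between/within decomposition
(`stats::aov`), defaulting to the screening's p ≤ 0.01 judgement level.
`duncan_mrt` implements Duncan's multiple range test: ordered means are
compared over spans of p consecutive means against critical ranges
`R_p = q(1 - alpha_p; p, df_error) · sqrt(MSE/n)` with Duncan's protection
level `alpha_p = 1 - (1 - alpha)^(p-1)`; studentized-range quantiles come
from `stats::qtukey` (no table lookups). The protection rule — any pair
inside a non-significant span is itself non-significant — is applied
exhaustively, and letters come from the insert-and-absorb compact
letter display, so the letters can never contradict the pairwise
decisions. Unbalanced groups fall back to the harmonic mean n with a
warning. Alpha defaults to 0.05 for post-hoc lettering and 0.01 for the
ANOVA judgement, the two levels used in this kind of screening.
`correlation_matrix` gives pairwise Pearson r/R²/p and excludes constant
columns with a flag.

No mixed models or repeated-measures structure are fitted: stages are
handled by separate contrasts, which is how the screening design treats
them.

## SSR diversity and the Shannon partition of molecular variance

Genotypes are diploid band-score calls ("a/b", top/bottom band) per
variety × SSR locus; a presence/absence band matrix can be converted with
`bands_to_genotypes` (two scored bands → heterozygote, one → homozygote,
none → missing, more than two → error). Missing calls are excluded
locus-wise, matching frequency-based estimators. Per locus:
`He = 1 - Σp²` (gene diversity) and
`PIC = 1 - Σp² - Σ_{i<j} 2 p_i² p_j²`, with `PIC ≤ He` always and both 0
exactly when monomorphic.

`shannon_amova` partitions, per locus, the pooled allelic Shannon entropy
(natural log — required so that `2·N·I` is a G statistic with the usual
chi-square behaviour, N being allele copies) into the size-weighted mean
within-population entropy plus the among-population mutual information.
G statistics are summed over loci, so `G_total = G_among + G_within`
holds to machine precision. Because published tables of this kind report
variance components alongside G statistics, the components come from a
standard two-level AMOVA on pairwise allele-mismatch distances (0, 1 or 2
mismatching allele copies per locus under best matching of the two
diploid calls), with `df_among = k - 1`, `df_within = N - k`, and the
usual n0 correction for unequal population sizes. Variation proportions
are computed from the package's own components — published tables
occasionally print proportions that disagree slightly with their own
components, and recomputation is the defensible choice.

P values are permutational: individuals are reassigned to populations
with sizes fixed; `p_among` is the fraction of permutations whose among
G statistic reaches the observed one, and `p_within` the fraction whose
within variance component is at most the observed one (population
structure depletes the within share, so small observed values are the
extreme ones). Both use the +1/(permutations + 1) correction and are
reproducible given `seed`. The default is 999 permutations; 1000 is
conventional for published tables.

`evanno_delta_k` implements the usual post-processing of clustering
log-probabilities, `ΔK = |L(K+1) - 2L(K) + L(K-1)| / sd(L(K))` on
replicate means; the MCMC clustering itself is out of scope. ΔK is
undefined at boundary K and where the replicate spread is zero (flagged).

## Protein physicochemical properties

`protein_properties` mirrors the usual characterisation-table columns:
length, average molecular weight (average residue masses plus one water;
additive up to a water), isoelectric point, GRAVY (mean Kyte–Doolittle
hydropathy), Ikai's aliphatic index (`X_A + 2.9 X_V + 3.9 (X_I + X_L)` on
mole percentages) and Guruprasad's instability index (`(10/L) Σ DIWV`
over consecutive dipeptides). The pI solves net charge = 0 by bisection
on [0, 14] to 1e-3 pH, with Henderson–Hasselbalch charges over the
termini and D, E, C, Y, H, K, R. The Bjellqvist/ExPASy pKa set is the
default because the reported column sets of such tables match
ExPASy-style output; the EMBOSS set is selectable (`pka = "emboss"`).
Exact reproduction of any particular web calculator's rounding is not
promised. Sequences with ambiguous residues are flagged at read time and
refused by the pI and instability calculators rather than silently
guessed. Homology search, domain detection and subcellular-localisation
prediction are out of scope.

## Relative expression

`ddct` computes `dCt = Ct_target - Ct_reference` within each condition
(replicates averaged arithmetically first), `ddCt = dCt_treated -
dCt_control` and fold = `2^-ddCt`, with amplification efficiency fixed at
2 (no efficiency correction) and a propagated SD reported for information
only. Fold changes are invariant to plate shifts (adding a constant to
every Ct of a condition) and invert exactly under condition swap.
`expression_clustering` orders the matrix by average-linkage clustering
on Euclidean distances of log2 folds, the conventional heatmap layout.

## What the synthetic data emulates — and what it does not

The generators provide every input format with known ground truth so the
whole pipeline is testable without instrument data.

* `simulate_transient` builds the OJIP rise phenomenologically as a sum
  of three saturating exponentials (phase weights summing to 1; time
  constants 0.5, 10 and 100 ms) between F0 and FM, sampled log-uniformly
  with the mark times included exactly, plus optional Gaussian noise.
  This is sufficient to exercise mark extraction and the JIP algebra; it
  is **not** a photochemical ODE model, and it does not reproduce the
  I-step shoulder shapes, light-intensity dependence or instrument
  artefacts of real fluorometers.
* `simulate_panel` plants per-parameter, per-stage medium/low
  depressions. The defaults are the study conditions of this kind of
  screening: 18 varieties, six replicates, a marker (PIabs) depression
  profile 0.90/0.60/0.39 across stages — a planted reduction factor of
  2.31, the design point for selecting n = 2 — milder declines for A,
  ETR, NPQ and FV/FM in that order, 5% replicate noise (a typical
  fluorometry CV), a variety tolerance spread of 0.15 on the log scale,
  and a dry-matter gain correlated with the planted SPI at 0.8, the
  design point for the observed R² near 0.6–0.8. Real panels add
  year effects, spatial structure and genotype × stage interactions that
  this generator deliberately omits, so green tests show the machinery
  recovers planted structure — not that any particular field panel
  behaves this way.
* `simulate_genotypes` draws ancestral allele frequencies from a flat
  Dirichlet and population frequencies from the Balding–Nichols model
  (Dirichlet with parameters `p(1-F)/F`), chosen because it plants a
  closed-form differentiation level; 2–5 alleles per locus matches
  observed SSR panels. At FST = 0 all populations share the ancestral
  frequencies exactly, giving a clean panmictic null for type-I-error
  checks.
* `simulate_proteins` and `simulate_ct` give uniform random peptides and
  Ct tables whose planted fold changes round-trip exactly at zero noise.

Every generator is deterministic given its seed and regenerates
byte-identically.

## Problem sizes used in the shipped checks

The package's own end-to-end checks use 500 noiseless transients for the
mark round trip, 200 random 3–6-group datasets for the Duncan oracle, 300
panmictic datasets (2 populations × 9 individuals × 30 loci, 200
permutations each) for the AMOVA type-I control with a further 4 × 50
datasets for the planted-FST ordering, 50 panels for the SPI recovery
summaries and 100 random 50-mers for the pI grid check — sizes at which
the Monte-Carlo summaries are stable to well within the tolerances they
are compared at.

## Known limitations

* The AMOVA degrees of freedom follow the general convention
  (`k - 1`, `N - k`); published tables sometimes reflect data-specific
  exclusions that cannot be reconstructed from the table alone, so no
  special-case df logic is included.
* Duncan's test is implemented for one-way layouts only, as used here.
* The pI model treats pKa values as sequence-independent; conformational
  effects are out of scope, as in all ProtParam-style calculators.
* The SPI machinery assumes both platforms were measured at the same
  stages; it does not impute missing platform × stage cells.
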