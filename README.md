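# saltscreen

Quantitative salt-stress screening of crop variety panels from fast
chlorophyll-a fluorescence, growth-stage trials, SSR genotypes, protein
sequences and qPCR data — for plant physiologists and breeders who need a
reproducible desk pipeline from raw transients to a ranked panel.

## What it computes

**JIP test.** From an O-J-I-P fluorescence transient (10 µs – 1 s) the
package reads the marks F₀ (50 µs), F₃₀₀ (300 µs), F_J (2 ms) and F_M
(curve maximum) and derives

- F_V/F_M = (F_M − F₀)/F_M
- M₀ = 4(F₃₀₀ − F₀)/(F_M − F₀),  V_J = (F_J − F₀)/(F_M − F₀)
- PI_ABS = [1 − F₀/F_M]/(M₀/V_J) × (F_M − F₀)/F₀ × (1 − V_J)/V_J

**Salt performance index.** With relative values (medium-salinity mean /
low-salinity mean) per variety × stage, reduction factors
RF = rel(leaf 3)/rel(flowering), and a data-selected marker parameter with
integer weight n = round(mean RF):

SPI = log₁₀ A + n · log₁₀ B

where A and B are the marker's relative values at leaf 3 and late
flowering. Pearson correlations of SPI with the relative marker value and
with dry-matter gain quantify how well the index tracks biomass
performance.

**Group statistics.** One-way ANOVA (p ≤ 0.01 screening convention),
Duncan's multiple range test with protection levels
α_p = 1 − (1 − α)^(p−1) and a compact letter display, and Pearson
correlation matrices.

**SSR diversity and Shannon AMOVA.** Allele frequencies, observed
heterozygosity, gene diversity He = 1 − Σp², PIC = 1 − Σp² − Σ 2p_i²p_j²,
and a Shannon-information partition of molecular variance: per-locus
entropy splits into within-population and among-population (mutual
information) components, 2N·I forms chi-square G statistics
(G_total = G_among + G_within exactly), variance components come from a
two-level AMOVA on allele-mismatch distances, and P values from
permutation of individuals across populations. Evanno ΔK post-processing
of clustering log-probabilities is included.

**Protein properties.** ProtParam-style length, average molecular weight,
isoelectric point (Bjellqvist pKa set, bisection), GRAVY, aliphatic index
and instability index from FASTA input.

**Expression.** 2^−ΔΔCt fold changes with a reference gene (EF1 by
default) and hierarchical ordering for heatmap display.

**Synthetic data.** Every input format can be simulated with known ground
truth (OJIP kinetics, stage panels with planted depressions, island-model
genotypes with planted F_ST, random peptides, Ct tables with planted
folds), so the full pipeline is testable end to end.

## Worked example

```r
library(saltscreen)

## JIP test on a synthetic transient
tr <- simulate_transient(F0 = 500, FM = 2500, seed = 1)
m  <- extract_marks(tr)
m
#> JIP marks (a.u.):
#>        F0      F300        FJ        FM
#>  598.3550  970.1192 1598.3664 2499.9818
fv_fm(m); pi_abs(m)
#> [1] 0.7606562
#> [1] 1.465678

## SPI on an 18-variety panel planted at the study conditions
panel <- simulate_panel(seed = 42)
rel   <- relative_values(panel)
sel   <- select_marker(reduction_factors(panel))
sel$parameter; sel$n
#> [1] "PIabs"
#> [1] 2
sp <- spi(rel, sel$parameter, sel$n)
spi_correlations(sp, rel, dm = dm_gain(panel), marker = sel$parameter)
#> SPI correlations (Pearson):
#>   vs relative marker     r = 0.990  R^2 = 0.980  p = 5.51e-15  (n = 18)
#>   vs dry-matter gain     r = 0.729  R^2 = 0.532  p = 0.000594  (n = 18)

## Shannon AMOVA on island-model genotypes (planted FST = 0.2)
sim <- simulate_genotypes(n_pops = 2, n_per_pop = 9, n_loci = 30,
                          fst = 0.2, seed = 7)
shannon_amova(sim$genotypes, sim$populations, permutations = 999, seed = 1)
#> Shannon statistics of molecular variance (2 populations, 999 permutations)
#>  source df       G variance   pct     p
#>   among  1  332.47    4.307  27.8 0.001
#>  within 16 1584.35   11.181  72.2 0.001
#>   total 17 1916.82   15.488 100.0    NA
```

The fluorescence marks sit on the simulated rise (F₀ near 600 a.u. because
the J phase has already begun moving by 50 µs), F_V/F_M ≈ 0.76 is a
healthy dark-adapted leaf, and the marker selection recovers the planted
design: PI_ABS declines about 2.2-fold more at flowering than at leaf 3,
so n = 2. The SPI tracks the flowering-stage PI_ABS almost perfectly by
construction and correlates with dry-matter gain at R² ≈ 0.5 for this
single panel draw. In the AMOVA, 28% of allelic variance lies among the
two planted populations and the permutation test is maximally significant
at 999 permutations.

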