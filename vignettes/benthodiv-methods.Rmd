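---
title: "Methods: models, defaults and design choices in benthodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in benthodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`benthodiv` implements the downstream statistics of a paired DNA/RNA 16S
rRNA zOTU survey of deep-sea sediments along a latitudinal ocean transect.
This vignette is the package's own account of the science: the statistical
procedures and their assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, and the design choices
made where more than one defensible option existed.

## The analytical setting

Each of nine stations contributes two sequencing libraries: one from 16S
rRNA genes (the entire archaeal community) and one from reverse-transcribed
transcripts (the potentially active community). Libraries have very unequal
depths — including RNA libraries so shallow (down to ~50 reads) that they
cannot be used at all — and the two fractions were extracted with different
kits, so **DNA and RNA arms are never pooled in any statistical model**.
The covariates are a small, strongly inter-correlated set: latitude, water
depth, summed chlorophyll in the top 500 m of the water column (the
primary-production proxy), silicic acid, nitrate, TOC, and the sediment
contents of Fe~2~O~3~, MnO~2~ and S. Ammonium and phosphate are excluded by
default (below quantification limits in the motivating setting); a flag
restores them.

With n = 9 stations per arm, every inference here lives in the small-n
regime. That drives most of the design: permutation tests instead of
asymptotics, exact Spearman null distributions, and rarefaction repeated
many times so that no conclusion hinges on one random subsample.

## Alpha diversity

`rarefy_counts()` subsamples each library **without replacement** to a fixed
depth (a multivariate hypergeometric draw), so a taxon with `N_i` of `N`
reads keeps its exact finite-population moments. `alpha_profile()` repeats
this `iterations = 100` times (the study protocol), computes richness,
Shannon `H'` (natural log; base is a parameter but nats are canonical — the
plausible per-sample values of 5–6 at richness 500–900 are only consistent
with nats) and Faith's PD per iteration, and averages.

Faith's PD is **root-inclusive**: the sum of branch lengths over every
branch with at least one present descendant, after pruning the tree to the
table's zOTU set. This matches `picante::pd(..., include.root = TRUE)`,
which the test suite uses as an independent oracle. PD is computed through
the same branch-incidence matrix as UniFrac, which keeps the 100-iteration
loop fast.

Coverage uses the Michaelis–Menten saturation model `y = d·x/(e + x)`:
`d` (asymptote, richness units) estimates the total richness a sample would
reach with unbounded effort, `e` (half-saturation, reads) the effort needed
to see half of it, and `coverage = 100 · S_obs / d`. The fit is plain least
squares (Levenberg–Marquardt), started from `d₀ = max(y)` and `e₀ = x` at
the response closest to `d₀/2`; a constant response is reported as
non-converged rather than guessed at, and coverage above 100% (observed
richness exceeding the fitted asymptote) is returned with a warning, never
silently clamped.

Two denominators were genuinely open:

* **Per-sample coverage** defaults to one MM fit on the *mean* analytic
  rarefaction curve across iterations (`coverage_method = "mean_curve"`);
  fitting per iteration and averaging coverages afterwards is available as
  `"per_iteration"`. The two differ only through fit nonlinearity and agree
  closely on saturating curves; the mean-curve option is the default because
  it estimates the curve first (where the averaging is exact) and fits once.
* **Transect-level recovered fraction** uses the MM asymptote of the
  sample-based accumulation curve (`species_accumulation()`, the exact
  combinatorial form), i.e. the expected fraction of the zOTU pool recovered
  by the survey as a whole.

## Beta diversity

The four dissimilarities are authored from first principles and
cross-checked against `vegan::vegdist` and `phyloseq::UniFrac` in the tests:

* weighted Bray–Curtis `Σ|x−y| / Σ(x+y)` — abundance-driven, dominated by
  the major community members;
* unweighted (binary, Sørensen) Bray–Curtis `(A+B−2J)/(A+B)` — the rare
  biosphere weighs as much as the dominants by construction;
* weighted UniFrac, the *normalised* form
  `Σ l_b|p_b−q_b| / Σ l_b(p_b+q_b)` over branch-descendant read fractions
  (the GUniFrac `d_1`, α = 1 convention); the raw unnormalised variant is
  deliberately not offered;
* unweighted UniFrac `Σ l_b|[p_b>0]−[q_b>0]| / Σ l_b[p_b>0 ∨ q_b>0]`.

UniFrac depends only on within-sample proportions, so the distance functions
never rarefy internally — rarefaction is the caller's job, which is exactly
what the repeated-rarefaction PERMANOVA exploits. Zero-length branches are
legal and contribute nothing; any root edge is outside the branch set; a
basal polytomy is accepted as the root. Trees may carry tips absent from
the count table (pruned lazily), but every counted zOTU must map to exactly
one tip.

## PERMANOVA with repeated rarefaction

`gower_center()` forms `G = C(−D∘D/2)C`; its trace is the total sum of
squares (Huygens identity). For one covariate with hat matrix `H`,
`pseudo_f()` returns `F = (tr(HGH)/df_m)/(tr((I−H)G(I−H))/df_r)` and
`R² = tr(HGH)/tr(G)`. Because `G` is double-centred these traces reduce to
`sum(G * H)`, and permuting the covariate equals permuting `H`'s rows and
columns — one cheap elementwise product per permutation.

Significance comes from free permutation of the covariate (single-factor
design, no strata). The **epsilon correction** counts permuted statistics
within `ε = √(machine precision) · max(1, |F_obs|)` of the observed value as
exceedances, so floating-point ties can never make the test anti-conservative.

A rarefied table is one random realisation, so `permanova_rarefied()`
re-rarefies `R = 999` times (child seed per round, derived deterministically
from the global seed) and pools:

```
p = (1 + Σ_r #{F_{r,k} ≥ F_r − ε_r}) / (1 + R·K)
```

with fresh permutations per round by default. Two alternatives were open and
both are implemented: permutations can be drawn once and reused across
rounds (`reuse_permutations = TRUE`), and the pooling rule is isolated in
one place so it can be swapped. Pooling per-round exceedance counts is the
default because it is equivalent to averaging per-round p-values with a
single continuity correction, keeps `p ≥ 1/(1 + R·K) > 0`, and with `R = 1`
collapses *exactly* to the single-table test (a tested identity). Reported
`F` and `R²` are means over rounds; the full per-round trace is retained.

One covariate per model: the screens test each property separately, so no
sequential (type-I) decomposition is needed. Significance is declared at
`p ≤ 0.05` with **no multiple-testing correction by default** — mirroring
the analytical convention the package reproduces — and a Benjamini–Hochberg
option exists but is off.

`beta_env_screen()` shares its `R` rarefactions (and the four distance
matrices per rarefaction) across all properties and measures of one
fraction; permutation draws stay fresh per (round, property). This changes
nothing statistically — each cell still sees `R` independent rarefactions —
and avoids rebuilding identical distance matrices dozens of times.

## Spearman machinery

`spearman_test()` wraps `stats::cor.test`: midranks for ties, and the exact
permutation null of the rank statistic when `n ≤ 9` and the data are
tie-free (the regime of a 9-station transect), otherwise the t-approximation
`t = ρ√((n−2)/(1−ρ²))`. The exact branch is verified against full
enumeration of the 4! relabelings in the tests, and the two branches agree
to within 0.02 at n = 9 for |ρ| ≤ 0.6. Missing covariate values are handled
pairwise-complete everywhere; a PERMANOVA drops samples with NA in the
tested covariate only.

## The synthetic transect generator

The generator exists so that every inference stage has a recoverable ground
truth. Its defaults are the study conditions, chosen once:

| parameter | default | meaning |
|---|---|---|
| `n_stations` | 9 | transect stations (27°S–59°N after sorting) |
| `n_otus` | 300 | zOTU pool (a scaled stand-in for the ~1,469 of a full survey) |
| `depth_range` | 5,000–18,000 | log-uniform library depths, reads |
| `rna_low_depth` | 50 | one forced sub-threshold RNA library (station 2) |
| `effect_size_chl` | 0.65 | chlorophyll slope, log-abundance per SD of chlorophyll |
| `rna_mg2_boost` | 40 | RNA enrichment of the designated clade |
| `mg2_baseline` | 0.003 | DNA-fraction share of that clade |
| `dispersion` | 200 | Dirichlet-multinomial concentration |
| `null_property` | MnO₂ | covariate generated independent of composition |

Covariates come from a Gaussian copula whose target Spearman structure
(converted via `r = 2·sin(πρ/6)`) encodes a productivity/latitude block —
chlorophyll, latitude, silicic acid, nitrate, TOC — plus a depth–Fe~2~O~3~
association; marginals are mapped onto the transect's ranges (chlorophyll
41.9–122.9 mg/m³, depth 3,258–5,909 m, latitude −27°…59°, TOC ≈0.6% with a
single 1.3% value at the northernmost station). MnO₂ is the planted null:
independent of the other covariates *and* of composition, so every screen
has a row that must stay at chance.

Compositions are `softmax(base + effect_size_chl · z_chl · loading)` with
per-zOTU loadings evolved as Brownian motion along the tree, so
phylogenetically close zOTUs respond alike and UniFrac and Bray–Curtis react
differently to the same gradient. Counts are Dirichlet-multinomial
(overdispersed, so rarefaction replicates vary realistically). The
designated "Marine-Group-II-like" clade (~2.5% of tips) is pinned at 0.3% of
every DNA composition and boosted 40-fold in RNA — reproducing the
entire-vs-active contrast (≈0.3–0.6% vs ≈10%) at the level the motivating
observations support; its share is deliberately flat along the gradient,
since the contrast is a fraction effect, not a gradient effect.

`effect_size_chl = 0.65` was calibrated once, before any acceptance test was
written, so that the repeated-rarefaction PERMANOVA attributes ≈40% of the
weighted Bray–Curtis variance of the DNA arm to chlorophyll (mean R² = 0.41
over 30 seeds; R² saturates near 0.56 for slopes above ~1.4 because with
n = 9 the null expectation of R² is already ~1/8). It has not been revisited.

What the generator does **not** emulate: real taxonomic structure and
taxonomy strings, chimeras or any read-level artefacts, depth-dependent
sequencing error, spatial autocorrelation beyond the covariate copula, and
Tax4Fun2 internals (the synthetic functional table is a noisy non-negative
linear readout of composition, present only so the functional screen has a
target). Passing tests therefore demonstrate the *statistics* are correct
and calibrated — type-I error, power, estimator identities — not that any
particular biological result generalises.

## Numerical choices and degenerate inputs

* Rarefaction uses index subsampling of the expanded read vector; marginals
  are exactly hypergeometric (tested against the closed form).
* All child seeds derive from the global seed through a fixed affine
  congruence (`derive_seed()`), keeping every replicate reproducible and
  below 2³¹.
* The MM fit runs to relative tolerance 1e-10 with box constraints `d, e > 0`;
  non-convergence is a first-class result, and downstream coverage refuses a
  non-converged fit.
* An all-zero sample is an error for Shannon and UniFrac (undefined), PD 0
  for Faith's PD, and an error for Bray–Curtis only when *both* samples are
  empty.
* Samples identical up to a positive scale factor are at weighted-UniFrac
  distance 0; presence-identical samples are at unweighted distance 0.
* A constant covariate is a rank-deficient design and errors immediately;
  a constant alpha index inside a screen becomes an NA row with a note.

## Problem sizes

The package's own test and acceptance runs use the generator's default
scale: 300 zOTUs, 9 + 9 libraries, `R = 50` rarefactions × `K = 99`
permutations for replicate ensembles (200 null and 100 effect transects),
and `R = 100` × `K = 199` for single-dataset analyses; the full-protocol
`R = K = 999` defaults remain the production setting. These sizes were
chosen as the smallest at which the binomial confidence bands on type-I
error and power are informative.

## Known limitations

* Single-covariate models only; sequential multi-term PERMANOVA,
  dispersion tests (PERMDISP) and db-RDA are out of scope.
* The exact Spearman branch requires tie-free data; midrank t-approximation
  otherwise, which is crude below n ≈ 6 with heavy ties.
* Generalized UniFrac at other α, variance-adjusted UniFrac, and
  Aitchison-geometry distances are not provided.
* The pooled repeated-rarefaction p-value treats rounds as exchangeable
  replicates of the same hypothesis; it is a calibrated summary (verified by
  simulation), not an exact test.
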