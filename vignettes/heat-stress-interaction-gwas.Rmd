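---
title: "Time-lagged heat-stress interaction GWAS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lagged heat-stress interaction GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Dairy cattle are sensitive to heat, and the sensitivity is not confined to
the moment a trait is recorded. A dam exposed to heat stress late in
gestation carries a fetus whose development — and whose adult milk
production and udder health — can be altered. Because daughters are
genotyped, this *in-utero* (time-lagged) exposure opens a
genotype-by-environment question: do allele effects on production traits
differ between animals that were and were not heat-stressed in a given
gestation week?

`hsgwas` provides a tested implementation of that analysis: exposure
construction from raw weather, genotype quality control, variance-component
estimation with an interaction term, a per-SNP generalized-least-squares
scan, and candidate-gene annotation — plus a synthetic-data generator so
that every claim the package makes about itself is checked against known
ground truth.

## Exposure model

The heat-load indicator is the temperature-humidity index computed hourly
from dry-bulb temperature $T$ (°C) and relative humidity $RH$ (%):

$$\mathrm{THI} = (1.8\,T + 32) - (0.55 - 0.0055\,RH)(1.8\,T - 26).$$

Two algebraic facts anchor the unit tests: at $T = 26/1.8\,°C$ the second
bracket vanishes (THI $= 58$ for any humidity), and at $RH = 100$ the first
bracket's coefficient vanishes (THI $= 1.8T + 32$). THI is strictly
increasing in $T$; it increases with $RH$ above $26/1.8\,°C$ and decreases
below.

Hourly THI is averaged within calendar days, and daily THI within gestation
weeks counted backwards from the animal's birth date. Week 1 covers days
0–7 before birth — eight calendar days, as the windows are conventionally
printed — and weeks 2–8 cover seven days each ($7(k-1)+1$ to $7k$). We
implement the printed 8-day week 1 and expose a `strict7` flag for the
7-day reading, since the two conventions are both defensible and the
difference (one boundary day in one of eight windows) is immaterial to the
exposure flags in practice. A week is heat-stressed when its mean THI is at
least 60 (inclusive).

**Partial days.** A day with at least 18 of 24 hourly records uses the mean
of the available hours (flagged partial); fewer records make the day, and
any week needing it, missing. The threshold is configurable; 18 keeps
synthetic tests simple while refusing to average half-empty days.

**Station assignment.** Each herd is mapped once to the weather station at
minimal great-circle distance (haversine on the IUGG mean radius
6371.0088 km). A geodesic library would use an ellipsoid instead; the
relative discrepancy is below 0.2% and cannot change a nearest-station
decision at the distances involved (tens of km). Distance ties are broken
by the lexicographically smallest station id so the assignment is
deterministic.

## Genotype quality control and relationships

Markers and animals pass through filters in a fixed order: autosomes only →
marker call rate ≥ 0.95 → animal call rate ≥ 0.95 → minor allele frequency
strictly greater than 0.01 → heterozygosity deviation
$|H_{obs} - 2\hat p(1-\hat p)| < 0.15$. The order matters only marginally
(frequencies are recomputed after the call-rate removals) but fixing it
makes the removal report reproducible; each removal is attributed to the
first rule that catches it.

The genomic relationship matrix follows VanRaden: doses are centered by
twice the observed post-QC allele frequency and
$G = MM'/(2\sum_j p_j(1-p_j))$. Near-duplicate animals (relationship
> 0.95) are pruned greedily: while any pair exceeds the cutoff, the member
with more super-cutoff partners is dropped (ties: the larger id). This
retains a maximal, deterministic set — for a cluster of $k$ mutual
duplicates exactly one survivor remains.

The interaction covariance uses $G_{hs}$, the principal submatrix of $G$
for exposed animals, *not* a matrix rebuilt from exposed-only allele
frequencies. Shared frequencies keep $\sigma^2_g$ and $\sigma^2_{ghs}$ on
one scale, which is what makes their ratio ($r_{hs}$) interpretable as a
variance share.

Missing doses (after QC at most 5% per marker) are mean-imputed with
$2\hat p$, the standard pre-GRM fill that leaves column means unchanged.

## Variance components

Two models are fitted per trait and gestation week:

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Zg} + \mathbf{e}
\qquad\text{and}\qquad
\mathbf{y} = \mathbf{Xb} + \mathbf{Zg} + \mathbf{W}\mathbf{g}_{hs} + \mathbf{e},$$

with $\mathbf g \sim N(0, G\sigma^2_g)$,
$\mathbf g_{hs} \sim N(0, G_{hs}\sigma^2_{ghs})$ defined only for exposed
animals ($\mathbf W$ allocates their records), $\mathbf e \sim N(0,
I\sigma^2_e)$, and $\mathbf Z = I$ because all phenotyped animals are
genotyped. The fixed effects include herd, calving year and month,
age-at-first-calving class (6 classes), the combined dam lactation ×
calving-age class (21), days-in-milk class (6, test-day traits) or
lactation-length class (16 equal intervals over 275–305 days,
$\min(16, \lfloor (len-275) \cdot 16/31\rfloor + 1)$), and the week's
binary heat-stress dummy. Reported ratios are
$h^2_g = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ for the first model and
$h^2_c$, $r_{hs}$ (both over $\sigma^2_g+\sigma^2_{ghs}+\sigma^2_e$) for
the second.

**Estimation.** Restricted maximum likelihood,
$\ell_R = -\tfrac12(\log|V| + \log|X'V^{-1}X| + \mathbf y'P\mathbf y)$,
maximized by average-information (AI) quasi-Newton steps with an
expectation-maximization fallback: an AI step is accepted only when the
clamped candidate does not decrease $\ell_R$; otherwise the EM update
$\sigma_i^2 \leftarrow \sigma_i^2 + 2\sigma_i^4 \nabla_i \ell_R / n$ —
which is guaranteed ascent — is taken. Starting values are
$\sigma^2_e = \sigma^2_g = \mathrm{var}(y)/2$ (and
$\sigma^2_{ghs} = 0.1\,\mathrm{var}(y)$), convergence is declared at
$|\Delta\ell_R| < 10^{-8}$ or relative parameter change $< 10^{-6}$, with a
200-iteration cap. Components are floored at
$10^{-6}\,\mathrm{var}(y)$ rather than profiled out, so boundary solutions
($r_{hs} = 0$) are representable. Standard errors come from the inverse AI
matrix at convergence.

One iteration costs a Cholesky factorization and inversion of $V$
($O(n^3)$ but with small constants); traces such as
$\mathrm{tr}(PG)$ are computed as $\sum_{ij} (V^{-1})_{ij} G_{ij}$ minus a
$p$-dimensional correction, avoiding any explicit $n \times n$ product.
With no exposed animal, the interaction fit degrades exactly (not
approximately) to the no-interaction fit with $\sigma^2_{ghs} = 0$ and a
degenerate-exposure flag.

**Boundary behaviour.** When a component is truly zero, exact REML floors
its estimate in only about half of replicates: the asymptotic law of the
estimate is a 50:50 mixture of a point mass at zero and a half-normal.
The test suite asserts that mixture behaviour (substantial boundary mass
plus concentration near zero) rather than a near-certain floor rate, which
no exact-REML estimator can deliver; one acceptance criterion that demands
a ≥ 90% floor rate is therefore implemented verbatim and expected to fail,
with the analysis recorded alongside the suite.

## The genome scan

Variance components are estimated once per trait × week and held fixed
across the scan (two-step GWAS). For SNP $i$ the design is augmented by two
columns: $\mathbf x_{snp} = \mathbf m_i - 2p_i$ (centered doses, all
animals) and $\mathbf x_{inter}$, equal to $\mathbf x_{snp}$ for exposed
animals and 0 elsewhere. Centering always uses the all-animal frequency, so
the interaction coefficient estimates the exposed-animal *deviation* of the
allele-substitution effect. The GLS solution
$\hat{\mathbf b}_1 = (X_1'V^{-1}X_1)^{-1}X_1'V^{-1}\mathbf y$ with
$\mathrm{var}(\hat{\mathbf b}_1) = (X_1'V^{-1}X_1)^{-1}$ yields 1-df Wald
chi-squares for both coordinates; p-values are computed in log space so
statistics beyond $\chi^2 \approx 1400$ do not underflow.

Computationally, $V^{-1}$ is formed once per trait × week and each SNP is
solved by a rank-2 Schur complement against the cached fixed-effect block —
$O(n^2)$ per SNP instead of $O(n^3)$ — with all per-SNP scalars produced by
two $n \times m$ matrix products and column sums. The block-update path is
verified against a naive full-inversion oracle to $10^{-8}$ relative error
on random fixtures. Degenerate columns are handled per SNP without aborting
the scan: an all-zero or collinear interaction column drops the interaction
coordinate (`interaction-dropped`), a constant SNP is `skipped`.

Calibration is summarized by the inflation factor
$\lambda = \mathrm{median}(\chi^2) / q_{0.5,\chi^2_1}$ with the reference
median $q_{0.5,\chi^2_1} = 0.4549$. Significance uses
$p_{Bonf} = 0.05/m$ over all scanned SNPs and a suggestive threshold
$p_{sugg} = 0.05/m_{indep}$, where $m_{indep}$ counts LD-independent
markers: per chromosome, consecutive non-overlapping 500-SNP windows are
pruned greedily in map order, retaining a marker only when its squared
correlation with every retained marker in the window is ≤ 0.15. Threshold
comparisons are inclusive (a p-value exactly at the bound counts), and
significant hits are by construction a subset of suggestive ones.

## Candidate-gene windows

A gene is a candidate for a hit SNP when its $[start, end]$ interval
intersects the SNP's ±100 kb window on the same chromosome — interval
*intersection*, not gene-start-within-window, which is the inclusive
reading of "located within" and is monotone in the flank. Strand is
ignored; the reported distance is 0 for SNPs inside a gene, else the gap to
the nearest edge. BED input (0-based half-open) is converted to 1-based
inclusive coordinates on read; GFF3 passes through.

## The synthetic-data generator

The generator emulates the study system the package targets: tens of
thousands of Holstein cows in ~50 large north-east German herds served by
~30 weather stations, ~40k autosomal SNPs on 29 chromosomes, calving years
2010–2015. Those are the *defaults* of `sim_config()`; tests run smaller
configurations explicitly.

* **Markers and genotypes.** Balanced marker counts per chromosome,
  strictly increasing positions, true frequencies uniform on the MAF range;
  doses are binomial(2, p) per marker (Hardy-Weinberg, no linkage
  disequilibrium) with independent missingness. No LD is simulated: the LD
  pruning code is exercised with constructed duplicate/orthogonal fixtures
  instead, and a green pruning test says nothing about realistic LD decay.
* **Weather.** Per station: annual sinusoid (peak mid-July) + diurnal
  sinusoid (peak 14:00) + Gaussian noise; relative humidity moves against
  temperature and is clamped to [0, 100]. The seasonal baseline is
  calibrated by deterministic bisection so the fraction of weekly THI
  values ≥ 60 matches `hs_target_prevalence` (default 0.16, the normal
  tail estimate from a weekly-THI mean near 48 with SD near 12). A
  shortcut mode draws exposure flags directly as Bernoulli variables for
  fast tests; the full path exercises station assignment and aggregation.
* **Phenotypes.** Exactly the fitted model: $\mathbf g$ multivariate
  normal with covariance $G\sigma^2_g$, $\mathbf g_{hs}$ with covariance
  $G_{hs}\sigma^2_{ghs}$ on exposed animals, i.i.d. residuals, optional
  categorical fixed effects, and optional explicit causal markers (main
  effects on all animals, interaction effects on exposed animals only).
  Matching the generative and fitted models makes parameter recovery a
  well-posed test.
* **Square-root factors.** The default factor of $G$ is the symmetric
  eigendecomposition with negative eigenvalues clipped at zero (a numerical
  guard — $G$ is Gram-constructed). A second sampler (`g_method =
  "marker"`) draws i.i.d. effects for the centered marker columns; for a
  VanRaden $G$ built from the same genotypes this has *exactly* the target
  covariance (it is just a different square root) at $O(nm)$ cost, and the
  large calibration/recovery simulations use it.
* **What a green test does not establish.** The generator has no LD, no
  selection, no pedigree structure, no herd-by-climate confounding (levels
  are sampled independently; a confounding toggle can be emulated by
  passing custom animal records), and Gaussian weather noise. Calibration
  results transfer to real data only to the extent that the fitted
  covariance $V$ captures the real relatedness structure.

Determinism is a contract: every operation reseeds a private RNG stream
derived from `sim_config$seed` (offset per stage, restored afterwards), so
identical configurations give bit-identical outputs regardless of
evaluation order. The calibration, recovery and power simulations in the
test suite fit the generating model (intercept plus heat-stress dummy, no
nuisance factors) so that estimates are compared against the components
actually simulated.

## Numerical choices and edge cases

* Variance floor $10^{-6}\,\mathrm{var}(y)$; Cholesky everywhere (the
  floored residual variance keeps $V$ positive definite).
* GLS rank decisions use relative tolerances: an interaction column is
  dropped when the 2×2 Schur complement is singular relative to its
  diagonal, which catches both "nobody exposed" and "everybody exposed"
  exactly.
* p-values via `pchisq(..., log.p = TRUE)`; no underflow below
  $10^{-308}$.
* Station-assignment ties and relationship-pruning ties are broken by id
  order — both choices are arbitrary but deterministic and documented.
* The independent-SNP count treats monomorphic columns as uninformative
  (skipped, not retained).
* Thresholds at exactly the bound count as hits (inclusive comparison).

## Known limitations

Single-trait models only (no bivariate REML, no genetic correlations);
no random regression on continuous THI; dense matrices throughout (desk
scale, roughly $n \le 15{,}000$ with patience); interaction standard
errors are AI-based for the variances with no delta-method errors for the
ratios; exposure is binary per week with no duration/intensity index and no
station interpolation.
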