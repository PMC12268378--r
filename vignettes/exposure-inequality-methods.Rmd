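---
title: "Methods: county-level air-pollution exposure and its spatial inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: county-level air-pollution exposure and its spatial inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

airineq quantifies two distinct dimensions of air pollution at the county
level — how much pollution the population is exposed to, and how unevenly
that pollution is distributed inside each county — and then asks which
urban-form, socio-economic and environmental characteristics explain each
dimension. This vignette documents the statistical machinery, the choices
behind every tunable parameter, and what the synthetic testbed does and does
not establish about real data.

## The two outcome indices

**Population-weighted air pollution exposure (APE).** For a county with
pixels $i = 1, \dots, M$ carrying population $P_i$ and decay-adjusted
concentration $C_i^d$,

$$\mathrm{APE} = \frac{\sum_{i=1}^M P_i \, C_i^d}{\sum_{i=1}^M P_i},$$

in the concentration's units (µg/m³). The decay adjustment replaces each
pixel's concentration by a kernel-weighted mean of pixels whose centers lie
within a buffer distance (default 1 km on a 1-km grid), so a pixel's
effective concentration reflects nearby sources. The functional form of the
decay is a genuine modelling choice: we use a uniform kernel by default —
on a 1-km grid the 1-km buffer is the pixel plus its four rook neighbours —
and expose an inverse-distance kernel behind `kernel = "idw"`. With a
uniform (or any linear) kernel, decaying each pollutant and then summing
equals decaying the summed field, so the order of decay and pollutant
summation does not matter. Counties whose population is entirely zero have
no defined APE; they are flagged and reported as missing, never as zero.

The *combined* indicator is the cell-wise sum of the PM1, PM2.5 and PM10
surfaces, used as the headline exposure variable throughout; each fraction
is also reported separately.

**Spatial Gini index (SGI).** Over the $N$ pixels of one county with values
$x_i$ and a binary contiguity matrix $w_{ij}$,

$$\mathrm{SGI} = \frac{\sum_i \sum_j w_{ij}\,\lvert x_i - x_j\rvert}
                      {2 N^2 \bar{x}}.$$

Contiguity is rook (shared edge) by default, queen behind an option. With
complete weights ($w_{ij} = 1$ for all $i \neq j$) the statistic reduces to
the classical Gini coefficient, and for any binary $w$ it is bounded above
by the classical Gini, since the numerator sums over a subset of pairs.
It is invariant to rescaling all $x_i$ — doubling every concentration
changes nothing — and a county whose pixels are all equal scores exactly 0.
Single-pixel counties score 0 by convention.

One scaling property deserves emphasis: with binary contiguity weights the
numerator holds only $\mathcal{O}(N)$ adjacent pairs while the denominator
grows as $N^2$, so at fixed spatial roughness the SGI shrinks roughly like
$1/N$ with pixel count. Absolute SGI magnitudes are therefore comparable
only across counties of similar size and are much smaller than classical
Gini values; all the package's analyses use the SGI cross-sectionally,
where only relative variation matters. The per-pixel formulation (pixels as
sub-units, one SGI per county) is the default; `x = "pop_weighted"`
computes the same statistic on $P_i C_i^d$, the inequality of *exposure*
rather than of concentration, and both can be reported.

**Dissimilarity index (DI).** Income segregation within a county with
tracts $i$,

$$\mathrm{DI} = \tfrac{1}{2} \sum_i \left|\frac{P_i}{P} -
\frac{Q_i}{Q}\right|,$$

with $P_i$ the tract's low-income population ("low income" meaning below
the regional median income), $Q_i$ its total population, and $P, Q$ the
county totals. DI is 0 when every tract holds the county-wide low-income
share. Note a property of this variant (which compares the low-income group
against the *total* population rather than against the complementary
group): complete segregation — all low-income residents packed into tracts
holding nobody else — yields $\mathrm{DI} = 1 - P/Q$, which approaches 1
only when the low-income group is a small minority. The package implements
the formula exactly as defined and its tests assert this attainable
maximum, not a nominal 1. Counties with no low-income residents have no
defined DI and are flagged.

## Urban-form indicators

**Urban centrality index (UCI).** With tract POI shares $k_i$ (counts
normalized to proportions; raw counts would make the $1/N$ reference
meaningless) and the matrix $D$ of tract-centroid Euclidean distances:

- local coefficient $\mathrm{LC} = \tfrac12 \sum_i |k_i - 1/N|
  \in [0, (N-1)/N]$, the unevenness of the POI distribution;
- separation value $V = k^\top D\, k$, small when POIs concentrate, large
  when they split across mutually distant tracts;
- $V_{\max} = \max_{k \in \Delta} k^\top D\, k$ over the probability
  simplex. A point mass gives $V = 0$, the *minimum* of the quadratic form,
  so "the maximum possible value of $V$" cannot be a single central
  location; we implement the true maximum. Every Karush–Kuhn–Tucker point
  of the maximization lies on a face of the simplex and solves
  $D_S k \propto \mathbf{1}$ on its support $S$, so for up to 12 tracts we
  enumerate all supports and solve exactly; above 12 we run projected
  gradient ascent from deterministic multi-starts (uniform, plus two-point
  splits on the ten farthest pairs). The result always dominates the best
  two-point split $\max_{ij} D_{ij}/2$. A worked caution: on an equilateral
  triangle with side $d$, $V = d\,(1 - \sum_i k_i^2)$ is maximized by the
  uniform allocation at $2d/3$, not by a pairwise split at $d/2$ — another
  reason to compute the true maximum rather than guess a configuration.
- proximity index $\mathrm{PI} = 1 - V / V_{\max} \in [0, 1]$, and
  $\mathrm{UCI} = \mathrm{LC} \times \mathrm{PI}$.

Single-tract counties have $V_{\max} = 0$; PI is defined as 1 there by
convention and flagged. Counties without POIs have no defined UCI. Regular
tract layouts share a single cached $V_{\max}$ evaluation, since their
distance matrices coincide.

**Densities.** POI, road and population densities are plain counts (or
totals) divided by county area in km². Road "segments" are taken as given
counts of uniform-length segments.

**Conversion pressure index (CPI).** The fuzzy sum (probabilistic OR) of
the projected human-modification layer and the development-suitability
index, $1 - (1 - \mathrm{HM})(1 - \mathrm{DSI}) \in [0, 1]$: commutative,
monotone in each argument, absorbing at 1. Only the combination operator is
in scope; both ingredients are synthetic inputs here.

## Driver analysis

The per-county analysis table holds the combined APE and SGI plus 12
indicators: road density, POI density, UCI, population density, GDP, income
segregation (DI), CPI, MAT (°C), MAP (mm), NDVI, SAP (hPa), VC (m²/s).
Counties with any undefined metric are dropped and named in a message.

**Log transform.** GDP, POI density, population density, MAP, SAP and VC
span orders of magnitude and are natural-log transformed; the other columns
are untouched. Zeros (possible in sparse POI counts) are shifted by half
the column's smallest positive value before the log, with a warning —
a documented, data-scaled offset rather than an arbitrary +1.

**Bivariate OLS.** Each indicator is regressed against APE and against SGI
one at a time (`lm` underneath), reporting the slope, exact $R^2$,
two-sided slope p-value, and a 90% confidence interval — the conventional
interval for this screen. No multiple-testing correction is applied, and no
multivariable or spatial regression is attempted; the screen is
descriptive.

**PCA.** The 12 indicators (never APE or SGI, which are reserved as
regression targets) are z-scored and the correlation matrix
eigen-decomposed. Mixed units make covariance-PCA meaningless here.
The sign convention — each component's largest-magnitude loading is made
positive — removes the eigenvector sign ambiguity so that component
regressions have reproducible slopes. PC1 and PC2 scores are then regressed
on APE and SGI with the same bivariate machinery.

## Partial-correlation networks

For a chosen target (APE or SGI) plus the 12 indicators, the Pearson
correlation matrix $S$ of the standardized columns feeds an
$\ell_1$-penalized Gaussian maximum-likelihood precision estimate
(graphical lasso), solved by block coordinate descent with warm starts
along a penalty path; off-diagonal entries only are penalized, and each fit
stops when the duality gap falls below $10^{-4}$ (at most 1000 sweeps). The
path holds 100 log-spaced penalties from $\lambda_{\max}$ — the largest
absolute off-diagonal correlation, the smallest penalty yielding the empty
graph — down to $0.01\,\lambda_{\max}$. The model is selected by the
extended Bayesian information criterion,

$$\mathrm{EBIC}(\lambda) = -2\,\ell(\hat\Theta_\lambda) + E \log n +
4\,E\,\gamma \log p,$$

with $E$ the selected edge count, $\gamma = 0.5$ (the conventional
default), and $\ell$ the Gaussian log-likelihood of the regularized
precision. $\gamma = 0$ recovers the BIC, and increasing $\gamma$ never
adds edges. Edge presence is the *structural zero pattern* of the selected
precision — entries whose lasso coefficients are exactly zero — not a
threshold on partial-correlation magnitudes; reported edge weights are
$\mathrm{pcor}_{ij} = -\hat\Theta_{ij} / \sqrt{\hat\Theta_{ii}
\hat\Theta_{jj}}$. In the unpenalized limit these match partial
correlations from direct matrix inversion, which the tests verify to
$10^{-3}$; the solver's solutions were also cross-checked against an
independent graphical-lasso implementation during development.

A behaviour worth knowing: when true partial correlations are strong, the
lasso's shrinkage bias on the true edges leaves residual dependence that
EBIC sometimes prefers to absorb in weak spurious edges, so the selected
graph can slightly over-connect even at $\gamma = 0.5$. Sparsistency — the
regime where absent edges are reliably excluded — holds for weak-to-modest
signals. The package's structure-recovery tests therefore check full edge
detection on a strong chain graph and shortcut exclusion on a weak one.

**Centrality.** Node strength is $\sum_j |\mathrm{pcor}_{ij}|$; expected
influence is the signed sum. **Bootstrap stability** runs $B \ge 100$
case-resampling replicates (refitting the entire path each time) for
per-edge inclusion frequencies, plus case-dropping at proportions 0.1, 0.2
and 0.3 — $\lceil B/3 \rceil$ replicates each — correlating each
replicate's strength vector with the full-sample one. Replicates that
produce a constant column are redrawn up to 10 times. Everything is
deterministic given the seed.

## The synthetic province

The generator builds a complete study region with *planted, recoverable
structure*, so every stage of the pipeline can be validated end to end
without any external data.

**Geometry.** A rectangular lattice of square counties (default 10 × 10
counties of 8 km at 1-km cells, 9 tracts each in a 3 × 3 subdivision).
The regular geometry keeps adjacency and packing limits analytic — which
the exact tests need — at the cost of realism in shapes; 100 counties of
64 km² each keep a full Monte-Carlo replicate cheap while leaving enough
pixels per county for a meaningful within-county statistic.

**Latent design.** Two independent county-level factors, each a smooth
Gaussian field over the county lattice (exponential covariance, range 2.5
county widths — urbanization and economic geography vary regionally, not
i.i.d. across neighbouring counties):

- **F1, development density**: scales population level (county multiplier
  $e^{0.5 F_1}$ on log-normal per-cell marks), sharpens the within-county
  population and POI centrality kernels, and drives MAT (loading 0.7);
- **F2, economic activity and segregation**: drives GDP per capita, CPI's
  ingredients, road supply, the county's income-segregation level, and the
  county's *within-county concentration dispersion* (loading 0.7).

**Concentration surfaces.** All three pollutants share one unit-variance
Gaussian random field $Z$ with exponential covariance (range 10 km;
Cholesky for grids up to 1024 cells, circulant-embedding FFT above, with
negative embedding eigenvalues clamped at zero). The surface is
$\mathrm{level}_p \cdot \exp(s_c Z - s_c^2/2)$ with base levels
21 / 33 / 54 µg/m³ for PM1 / PM2.5 / PM10 — magnitudes typical of annual
means in southeastern China — so cell-wise ordering PM1 < PM2.5 < PM10
holds exactly. The per-county log-scale dispersion $s_c$ is drawn in
[0.05, 0.35] from F2, *independently of the county's mean level*: this
independent control is what lets exposure level and spatial inequality
decouple, so the testbed can exhibit high-APE/low-SGI and
low-APE/high-SGI counties simultaneously.

**Planted covariate effects.** County log-mean concentration is tilted by
$\exp(\eta)$ with $\eta_c = \sum_k \beta_k z_k(c) + \varepsilon_c$,
$\varepsilon_c \sim N(0, 0.1)$, default
$\beta = \{+0.3\ \text{pop density}, +0.3\ \text{MAT}, -0.3\ \text{NDVI}\}$
per covariate standard deviation. The tilt is interpolated bilinearly
between county centers rather than applied as a per-county step: a real
concentration surface carries no discontinuities at administrative
boundaries, and a step tilt would leak neighbouring counties' levels into
the within-county roughness through the decay kernel, mechanically coupling
SGI to neighbours' APE.

**Income, POIs, roads.** Each county's low-income share (centered on one
half, since "low income" is below the regional median) is allocated across
tracts as a mixture of exact proportionality (weight $1 - s$) and packing
into the fewest tracts (weight $s$), with the county's $s$ scaled from the
global `segregation_level` by F2; allocations are real-valued so that
`segregation_level = 0` yields DI exactly 0. POI counts are Poisson with
county rates proportional to population *times a log-normal per-capita
supply factor* (SD 0.35) — without it POI density would be a near-copy of
population density and their partial correlations unidentifiable — and
positions mix a uniform component with a Gaussian cluster at the county
center. Road counts are proportional to population with an F2 multiplier
and log-normal noise. Environmental covariates (MAT, MAP, NDVI, SAP, VC)
are smooth county-level fields with field-typical means and spreads
(19 ± 2 °C, 1400 ± 250 mm, 0.65 ± 0.05, 1000 ± 8 hPa, 3.3 ± 0.3 m²/s).

**Determinism.** Every stream (field, population, income, POIs,
covariates, tilt noise, factors) derives its own sub-seed from the master
seed, so adding a stream never perturbs the others, and a fixed seed
reproduces the entire province byte for byte.

**What the generator does not emulate.** Real coastline or county shapes;
measurement error of satellite-derived concentration products; temporal
structure (annual means are taken as given); tract-level population
heterogeneity beyond the kernel; any calibration to a particular province's
absolute magnitudes. Synthetic SGI values are small (the $1/N$ scaling
above at 64 pixels per county); only their cross-sectional variation is
meaningful. Passing the planted-recovery tests shows the *pipeline*
recovers known structure at realistic noise levels — it does not validate
any substantive claim about a real region.

## Problem sizes and numerical choices

The test suite and the acceptance script run on the default 10 × 10-county
province (n = 100 counties, 6 400 cells per surface). Recovery rates use
100 seeds for the OLS sign screen and 50 seeds for the PCA-alignment and
network-edge checks; decoupling uses 20 seeds; these sizes give stable
proportions while keeping a full run in minutes on one core. Other
numerics: raster/polygon zonal assignment is by cell center (unambiguous
and partition-preserving on a tessellation); adjacency ties are impossible
on a lattice; the glasso duality-gap tolerance is $10^{-4}$; $V_{\max}$ is
exact to machine precision up to 12 tracts and verified against a refined
simplex grid search to $10^{-4}$ on random instances; the circulant
embedding clamps negative eigenvalues (the approximation is checked by a
correlogram test against $e^{-1}$ at one range). Degenerate inputs —
zero-population counties, counties without POIs, all-nodata fields,
single-pixel counties, counties without low-income residents — are flagged
explicitly rather than silently dropped or zeroed.

## Known limitations

- The SGI's $1/N$ pixel-count scaling makes absolute values incomparable
  across differently sized counties; only cross-sectional variation among
  similar counties is interpretable.
- The decay kernel's form (uniform vs inverse-distance) is a modelling
  choice the data cannot arbitrate at one buffer width; both are exposed.
- EBIC-glasso edge sets can over-connect under strong dependence (see
  above); bootstrap edge frequencies are the more robust evidence.
- Bivariate OLS screens ignore spatial autocorrelation among counties, so
  p-values are optimistic when indicators are spatially smooth; the
  package reports them as the conventional screen but the networks and PCA
  are the intended inferential summary.
- The synthetic province's regular geometry understates the variance of
  area-dependent statistics relative to real, irregular counties.
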