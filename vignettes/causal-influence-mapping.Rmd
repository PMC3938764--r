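---
title: "Causal influence mapping of cell migration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal influence mapping of cell migration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellwiring)
```

## The scientific problem

Migrating cells are heterogeneous: at any moment, two genetically identical
cells in one dish differ in speed, shape, and in the organization of the
macromolecular machines that drive motility — cell–matrix adhesion
complexes (CMACs: focal adhesions, focal complexes, nascent adhesions) and
the F-actin cytoskeleton. `cellwiring` exploits that natural heterogeneity,
resolved in time, to ask a *directional* question that correlation cannot
answer: which organizational features of the migration machinery causally
influence migration speed, and which are themselves driven by it?

The causal notion used throughout is Granger causality: a background
feature X Granger-causes a response feature Y if past values of X, *in the
presence of* past values of Y, improve the prediction of present Y. No
perturbation is required; each experimental condition yields its own
directed, signed wiring diagram, and comparing diagrams across conditions
exposes *plasticity* of the wiring (edges lost, gained, or sign-inverted).

The pipeline starts from object tables (tracked cells with polygon
outlines; tracked CMACs with areas, axes and per-channel intensities at a
fixed 5-minute frame interval) — not from images. Everything upstream
(acquisition, filtering, segmentation) is out of scope.

## Pipeline and models

### Tracking and parsing

Detections are linked frame-to-frame by greedy mutual nearest-neighbor
assignment with a 2 µm displacement gate; candidate links are consumed in
order of increasing distance, ties broken toward smaller object ids.
Parsing then removes records whose fitted-ellipse minor axis is below one
pixel (0.21 µm, a guard against aberrant form factors), removes CMAC
tracks observed at a single time point (noise control), and flags tracks
touching the first or final frame as censored so that lifetime aggregates
never include incomplete lifetimes.

### Intensities

CMAC intensities are corrected for local background (corrected mean = raw
pixel mean − local background; corrected total = corrected mean × area;
negative values clamp to zero and are flagged) and then standardized per
channel and experimental repeat by the median corrected mean intensity of
*reference-condition* CMACs with area in 0.15–0.2 µm² — a size window
populated enough to give a stable median yet above the resolution limit,
so that area is unambiguous. This makes intensities comparable across
repeats with different detector gains.

### Feature catalogs

Each CMAC-frame yields 29 instantaneous features (morphology, dynamics,
corrected intensities, localization relative to the parent cell, and the
Pearson colocalization of the paired per-pixel EGFP-Paxillin /
RubyRed-LifeAct intensities). Each cell-frame yields 88 features: 6
polygon-morphology features (area; perimeter; compactness
$P^2/(4\pi A) \ge 1$, higher = less round; second-moment axes), the CMAC
count, 80 population aggregates (Mean, Median, Sum, SD and IDR — the
interdecile range $q_{90}-q_{10}$ — of 16 base CMAC features over the
CMACs present in the frame), and one behavioral feature, Instantaneous
Cell Speed (ICS): the displacement of the spline-smoothed centroid per
frame interval, in µm/min. The 87 non-speed features are the
*organizational* features. The catalogs are pinned: tests assert exactly
88 and 29 entries and the presence of every feature name used in the
analyses.

Two completions were genuinely open and are package conventions: the exact
composition of the 88/29 manifests (we cross 16 base CMAC features with
the five aggregators and add the cell-scale features, keeping every name
the analyses use), and the reading of IDR as the interdecile range. The
standardized distance of a CMAC to the cell edge is
$s = d_{\mathrm{edge}} / (d_{\mathrm{edge}} + d_{\mathrm{centre}})$ with
$d_{\mathrm{centre}}$ the distance to the polygon's center of area: $s=0$
on the boundary, $s=1$ at the center, well defined for any simple polygon.

Trajectory smoothing uses cubic smoothing splines with the penalty chosen
by generalized cross-validation (overridable via `spar`); tracks shorter
than 8 frames fall back to raw positions. Net intensity change is defined
on consecutive frames only; the first frame of a track has a missing
change value.

### Normalization and stationarity

The regression machinery assumes approximately Gaussian residuals, so
every feature is Box-Cox transformed with an individually tuned power:
$\lambda$ maximizes the profile likelihood on the grid $[-3, 3]$ in steps
of 0.01; a positivity shift of $-\min(x) + \varepsilon$ is applied and
recorded when needed, and the output is standardized to zero mean, unit
variance. Normalizability is screened by an Anderson–Darling test at
$\alpha = 0.01$; failing features are listed and excluded, with a
`keep` override standing in for the manual supervision step that a purely
automated screen cannot reproduce. Note the screen is advisory for the
causal stage: the transform is monotone either way, and with tens of
thousands of pooled observations a formal normality test will reject
visually unremarkable distributions.

Stationarity is verified (not enforced) with an augmented Dickey-Fuller
test per cell track — constant-only regression, augmentation order by AIC,
finite-sample critical values from the standard response-surface
coefficients — calling a feature stationary when the unit root is rejected
at the 5% level in at least 80% of tested tracks (configurable). The ADF
machinery is implemented in-package.

### Subpopulation structure and comparison

Organizational state is summarized by PCA (SVD of the centered matrix;
the retained dimension defaults to the smallest count reaching 85%
variance, configurable because different analyses legitimately retain
different counts). Subpopulations are found by fitting full-covariance
Gaussian mixtures with EM for $K = 2..8$, 10 random-seeded restarts per
$K$, selecting $K$ by AIC with the full free-parameter count
$k = (K-1) + Kd + Kd(d+1)/2$ (a groups-only penalty $k = K$ is available
by flag), and refitting the final assignment with 100 restarts.

Three numerical choices matter here. (1) *Random seeding* is implemented
as distance-weighted sampling of observations as initial means: still
random — relieving the locking effect of deterministic initialization —
but avoiding seedings that place two components in one well-separated
cluster, which trap EM in poor optima. (2) The mixture likelihood is
unbounded: a component collapsing onto a handful of points drives its
covariance toward singularity and the log-likelihood toward infinity.
Such solutions are spurious maxima, not models; a fit is flagged
`degenerate` when any component holds fewer than $d+1$ effective
observations or has a covariance eigenvalue below $10^{-4}$ times the
mean feature variance, and model selection rejects degenerate fits.
Without this guard, best-of-restarts AIC selection systematically
overestimates $K$. (3) Singular covariances arising transiently during EM
are ridge-regularized ($10^{-6}$) and flagged; convergence is declared at
a log-likelihood change below $10^{-8}$ or 500 iterations. The E/M loop is
compiled code (RcppArmadillo); the R wrapper owns seeding and AIC
accounting.

Subpopulations are compared with canonical variate analysis (eigenvectors
of $W^{-1}B$; groups smaller than $d+2$ trigger a PCA reduction, flagged),
pairwise Mahalanobis distances on the pooled within-group covariance,
single-linkage clustering of group means (Euclidean metric), MANOVA with
Wilks' $\Lambda = \det W / \det(B+W)$ and Bartlett's $\chi^2$
approximation, two-sample Kolmogorov-Smirnov tests decided against the
asymptotic critical value at the 5% level, and fixed-bandwidth Gaussian
KDE (evaluated by exact kernel sums so the grid density integrates to 1
within $10^{-6}$).

### Feature selection

Two independent rankings identify organizational features associated with
ICS. First, cells are stratified into ICS quintiles; the slowest (S1,
1–20%) and fastest (S5, 81–100%) are separated by two-group CVA and
features ranked by |loading| on the first canonical vector. Second, the
elastic net (mixing parameter $\alpha = 0.5$ by default — there is no
canonical value, so it is surfaced in the configuration; 100
log-spaced penalties, decreasing) regresses ICS on all organizational
features; at each path iteration the adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-p-1)$ is computed from the elastic-net residuals
with $p$ the support size (no refit — the path itself is the model being
judged), the optimum is the iteration maximizing adjusted $R^2$, and
features are ranked by |coefficient| there. The elastic net is chosen for
its grouping effect on multicollinear features. A global Spearman map
(pairwise-complete, average ranks) summarizes undirected associations.

### Granger causality

For a response Y and background X, the pooled design stacks, over every
cell track, rows regressing $Y_t$ on an intercept, $Y_{t-1..p_y}$ and
$X_{t-1..p_x}$; as older lags enter, younger lags are always retained, and
lags never cross track, condition or repeat boundaries (a track of length
$T$ contributes $T - \max(p_y, p_x)$ rows). Model A (restricted) drops the
X lags but keeps the same rows. The Granger-Sargent test of the RSS
reduction is applied in F-form,

$$\mathrm{GS} = \frac{(\mathrm{RSS}_A - \mathrm{RSS}_B)/p_x}
                     {\mathrm{RSS}_B/(N - 1 - p_y - p_x)}
  \sim F(p_x,\; N - 1 - p_y - p_x),$$

with an asymptotic $\chi^2$ form behind a flag. The test is computed once
on the pooled model (not aggregated over per-cell fits), matching the
pooled auto-regression framing; contemporaneous (lag-0) X terms are never
included — causality rests on past information only.

The full analysis evaluates the 10×10 grid of lag combinations
$(p_x, p_y) \in \{1..10\}^2$: adjusted-$R^2$ surfaces, p-values binned at
0.05/0.01/0.001/0.0001, a sign (by default the sign of the panel-level
Spearman correlation between X and Y, mirroring the blue/negative,
red/positive display convention; the sign of the summed X-lag coefficients
is available by flag), and the response autocorrelation sequence at lags
0..10 (1 at lag 0). No multiple-testing correction is applied across the
grid — robustness is handled at the edge level instead: an edge X→Y is
declared only when (a) ≥60% of grid cells are significant at 0.05, (b)
≥25% at 0.0001, and (c) all significant cells share one sign. The
thresholds operationalize "robust and ordered" significance patterns and
are configurable and logged; under the null the whole grid-plus-criterion
procedure declares an edge in well under 5% of runs (measured in the
acceptance suite). Causation is always tested reciprocally (X→Y and Y→X),
pairs are classified as unidirectional, bidirectional or unconnected,
chains are verified link by link, and per-condition graphs are compared
edge-wise into a plasticity report (conserved / lost / gained /
sign-inverted).

## The synthetic-data generators

Because public datasets of tracked cell/CMAC object tables are scarce,
every stage is exercised on synthetic data with known causal ground truth, at two levels of
realism.

`simulate_var_panel()` draws one independent stationary VAR realization
per cell (rejecting specs whose companion spectral radius is ≥ 1,
discarding a 100-frame burn-in) and records exactly the injected nonzero
cross-couplings as the ground-truth edge set. This generator defines the
study conditions for the statistical calibration results: type-I error is
measured on 500 null panels of 100 independent AR(1) cells × 30 frames
(autoregression 0.5, unit innovations); directed recovery on 100 cells ×
50 frames with a standardized lag-1 coupling of −0.5.

`simulate_microscopy_panel()` renders tracked objects: cells move as
persistent random walks inside star-convex polygon outlines (radial
ellipse with low-order Fourier roughness, 0.21 µm pixels, 5-min frames);
CMACs are born by a Poisson process tracking a target standing count
(default 15), die with geometric lifetimes (default mean 8 frames), and
carry lognormal areas (median ≈ 0.45 µm², floored at 0.12 µm² so fitted
minor axes stay above one pixel, with enough mass in the 0.15–0.2 µm²
standardization window), ellipse axes, and ≥8 paired per-pixel channel
intensities with a controllable correlation plus local-background values.
Causal structure is injected through per-cell latent drivers following a
stationary VAR (self-persistence 0.45) whose components modulate renderer
dials through smooth links — log-linear for positive dials (speed, CMAC
count, area, lifetime, intensity), logistic/tanh squashes for bounded
ones (shape elongation, colocalization). Smooth links are deliberate:
hard clipping would put point masses into the rendered feature
distributions, which no monotone power transform can normalize and which
no real morphodynamic feature exhibits. Track truncation at random entry
and exit frames (never interior gaps, never below 2 frames) emulates
cells entering and leaving the field; lags are only ever formed inside
contiguous tracks, which keeps the 5-minute lag semantics unambiguous.

What the generator does *not* emulate: segmentation error correlated with
signal, optical blur and photobleaching, cell-cell contacts and
collisions, merge/split events in tracking, and drift or batch trends
within a repeat. Passing tests therefore demonstrate that the statistical
machinery recovers known structure from object-level data of realistic
shape — not that it is robust to upstream imaging artifacts.

Lifetime distributions and intensity levels are conventions, not
reproductions of any measured dataset: no quantitative reference
distributions exist for them here, so defaults
were chosen once to give realistic object counts (≈15 CMACs/cell,
lifetimes of ~40 min, speeds of ~0.3 µm/min) and kept fixed.

## Numerical choices and degenerate inputs

* OLS fits refuse rank-deficient designs and designs with fewer than
  `columns + 5` rows; affected grid cells are missing-flagged, not
  imputed.
* Constant pixel vectors make colocalization undefined (missing,
  flagged); constant features are discarded by Box-Cox with a diagnostic
  and missing-flagged in the Spearman map.
* A frame with zero CMACs keeps its cell-scale features; all CMAC
  aggregates are missing.
* Re-normalizing an already-normalized feature is *approximately* the
  identity: the profile-ML $\hat\lambda$ on a finite sample is near, not
  exactly, 1, so values reproduce closely in distribution but not to
  machine precision. The tests assert rank preservation exactly and value
  stability approximately.
* Determinism: every stochastic step takes a seed; pipeline stage seeds
  derive from the master seed by a stable string hash (FNV-1a), all below
  $2^{31}$.
* The Gaussian-mixture degeneracy guard (above) is the one place the
  package overrides a likelihood comparison, and it is always flagged in
  the fit object.

## Problem sizes

The shipped tests and the acceptance script run, end to end, on: 500 null
panels (100 cells × 30 frames) for calibration; 20 seeds of 100 cells ×
50 frames for directed recovery; two conditions of 80 cells × 40 frames
for the plasticity comparison; one 100-cell × 50-frame rendered dataset
for chain recovery; 20 replicates of n = 2000, d = 4 for mixture-order
selection; and n = 2000 for Box-Cox recovery. These sizes give stable
rates (binomial standard errors of 1–3 percentage points on the recovery
and error rates) while keeping a full run in minutes on one core.

## Known limitations

Pairwise only: conditional (multivariate) Granger causality, nonlinear
and frequency-domain variants, and per-phase (protrusion/retraction)
wiring are out of scope. The edge criterion is a transparent
operationalization of a visual judgement; other reasonable thresholds
exist and are exposed in the configuration. Spline-smoothed speed mixes
a small amount of future information into ICS at each frame, which can
inflate reverse-direction evidence for very strong couplings; the default
light smoothing (GCV on low-noise centroids) keeps this below the edge
criterion in all shipped checks. The ADF p-value between tabulated levels
is interpolated and approximate (rejection flags at 1/5/10% are exact to
the response-surface critical values).
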