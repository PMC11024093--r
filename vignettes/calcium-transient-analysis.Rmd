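---
title: "Kinetics and shape space of confined-cell calcium transients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics and shape space of confined-cell calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calshape)
```

## The problem

Cells confined to adhesive micropatterns of defined geometry — a round
"O" disc or an elongated triangular "L" island — remodel their calcium
signalling. Time-lapse fluorescence imaging of a genetically encoded
calcium indicator records, for every segmented single cell, one scalar
trace per 30-second frame over 30 minutes, with a mechanosensitive-channel
agonist added at the tenth acquired frame. The analytical questions this
package addresses are: *how fast does each cell's calcium transient decay*,
*do the trajectory shapes of the two geometry groups differ*, and, on the
tumor side, *where does a bulk expression profile sit on the
epithelial–mesenchymal axis*.

## The kinetic model

A transient is modelled as an exponential rise toward, and a slower
exponential relaxation away from, a steady state:

$$f(t) = -(b + c)\,e^{-(\tau_{\mathrm{decay}} + \tau_\Delta)\,t}
         + b\,e^{-\tau_{\mathrm{decay}}\,t} + c$$

with rates in $s^{-1}$ and amplitudes in fluorescence units. Two
constraints are built into the parameterisation rather than imposed as
penalties. First, the rise rate is written
$\tau_{\mathrm{rise}} = \tau_{\mathrm{decay}} + \tau_\Delta$ with
$\tau_\Delta \ge 0$, so a fit can never describe a decay followed by a
rise. Second, the rise amplitude is fixed at $a = b + c$, which forces
$f(0) = 0$: the transient starts exactly at baseline. `model_eval()`
groups the exponentials as
$b\,(e^{-\tau_{\mathrm{decay}}t} - e^{-\tau_{\mathrm{rise}}t}) +
c\,(1 - e^{-\tau_{\mathrm{rise}}t})$, which is algebraically identical
but evaluates to exactly zero at $t = 0$ in floating point for every
parameter vector. The interior maximum is available in closed form
(`peak_time()`), which the tests exploit as an independent oracle.

The quantity of biological interest is the decay *time*
$1/\tau_{\mathrm{decay}}$ in seconds: slowly decaying cells hold
elevated cytosolic calcium longer.

## Preprocessing conventions

* The first acquired frame is discarded (`drop_first_frame()`); a
  61-frame acquisition leaves 60 analysed frames with the agonist frame
  at 1-based index 9.
* Frames 1–8 are the baseline. `normalize_dff()` produces
  $\Delta F/F_0$ with $F_0$ the baseline mean; `baseline_split()`
  instead subtracts the baseline mean and hands frames 9..N to the
  fitter with $t = 0$ at frame 9. No further detrending is applied:
  the acquisition is short relative to bleaching, and baseline
  referencing is the weakest sufficient normalisation. Both normalised
  forms are available; the shape-space analysis consumes
  $\Delta F/F_0$ by default.
* Windowed summaries (`summary_stats()`) use the trapezoidal rule, the
  standard choice for uniformly sampled series, with the window split at
  750 s. The boundary sample belongs to the early window for pointwise
  statistics and is shared by both trapezoids, so
  `auc_early + auc_late` always equals the full-window area.

## Fitting procedure

Only *eligible* cells are fitted (`check_fit_criteria()`):

1. the median of the baseline-subtracted transient is non-negative
   (otherwise the steady-state initialisation would sit outside its
   bounds);
2. the post-onset frames exceed the baseline frames by a one-sided
   Wilcoxon rank-sum test at $\alpha = 0.005$ — the responsiveness
   gate. With 8 baseline and ~52 transient frames the normal
   approximation with tie correction is accurate, so no exact
   enumeration is used;
3. the transient's maximum falls in the first half of the transient
   segment (1-based argmax $\le \lceil N'/2 \rceil$ of the segment),
   without which too little of the decay is observed for
   $\tau_{\mathrm{decay}}$ to be identifiable. The argmax is taken on
   the baseline-subtracted segment; subtracting a constant cannot move
   it.

Fitting (`fit_transient()`) is bounded nonlinear least squares
(Levenberg–Marquardt with box constraints) restarted from a fixed
300-point grid: ten log-spaced decay times from 15 to 1500 s, six
log-spaced $\tau_\Delta$ from $10^{-6}$ to $10^{-1}$, five log-spaced
$b$ from 0.1 to 1000, with $c$ always initialised at the median of the
transient. Bounds are $\tau_{\mathrm{decay}}, \tau_\Delta, b \ge 0$ and
$0 \le c \le \max y'$ (inclusive). The winner is the converged start
with the smallest residual sum of squares; because candidates are
emitted in a fixed lexicographic order and only a strictly smaller cost
replaces the incumbent, ties resolve deterministically. Convergence
tolerance is $10^{-8}$ on the cost with at most 1000 residual
evaluations per start — tight enough that the 300 restarts agree to
well below the reporting precision, cheap enough that a cell fits in a
fraction of a second.

## Shape space

For group comparison each cell's trajectory is treated as a single
vector observation. `fit_pca()` centers the pooled trajectories (all
groups, all agonist concentrations) and takes a full SVD; the top three
components are retained — on trajectories drawn from the kinetic model
family they carry upwards of 95% of the variance, so little shape
information is lost. Trajectories are centered but never
variance-scaled, because per-frame scaling would distort trajectory
shape, and each component's sign is fixed so its largest-magnitude
loading is positive (the SVD sign is arbitrary; determinism needs a
rule).

`compare_groups()` runs, per concentration, a MANOVA on the 3-D scores
(Wilks' lambda with the standard F approximation; two groups in three
response dimensions give 3 numerator degrees of freedom) with Bonferroni
correction across the concentration levels, plus an LDA on the same
scores with priors proportional to group size. The LDA weight vector is
the direction along which the clusters separate; back-projecting
cluster-mean scores with `reconstruct_mean()` turns that abstract
direction into an average trajectory per group. Whether to feed the PCA
all cells or only fit-eligible ones is left to the caller (filter the
trace matrix first); the default examples use all cells, since shape
space does not require the kinetic model to hold.

## Single-cell QC

High-content segmentation produces four per-well object tables (calcium
objects with area/perimeter/centroid; nucleus–cell association with
nucleus area and nuclei-per-region; nucleus spacing in pixels;
post-stain object centroids). `merge_object_tables()` joins them on the
region identifier, keeping regions absent from some file with explicit
`NA` markers. `apply_filters()` then applies five independent rules: a
shape-factor window ($4\pi A/P^2 \ge 0.9$ for "O"; $0.5$–$0.85$
inclusive for "L"), exactly one nucleus per region, nucleus at least 20
pixels from any other (inclusive), nucleus area strictly below
300 µm², and a largest pairwise centroid difference of at most 30 µm
across the three masks (strictly greater is excluded — roughly one cell
width, so anything beyond it is a registration failure). Because the
rules are evaluated independently and conjoined, the inclusion set is
order-independent. Mixed units are deliberate — areas and centroids in
µm, nucleus spacing in pixels — and a `um_per_pixel` calibration is a
required input, never a default, because it depends on objective and
binning.

## Tumor EPI–MES scoring

Bulk log2 expression profiles are scored on an epithelial–mesenchymal
axis. Genes are z-scored across tumors (n−1 denominator; zero-variance
or incomplete genes are dropped with a warning, never silently zeroed).
Each signature list is refined by keeping genes whose Pearson
correlation with the unweighted mean z-score of the *full* list (the
gene itself included) exceeds 0.5 strictly. A tumor's score is its mean
z over the refined epithelial genes minus its mean z over the refined
mesenchymal genes — means, not sums, so the score is invariant to list
size. Rank quintiles (equal-count fifths, sizes balanced within one
tumor, ties broken by stable input order) label tumors H-MES, L-MES,
Ambig, L-EPI, H-EPI from lowest to highest score. Marker panels are
correlated with a target gene per stratum with raw two-sided p-values
(the display convention is raw p against 0.05, so no multiplicity
adjustment), and correlation matrices are organised by average-linkage
hierarchical clustering of Manhattan distances. The packaged gene
resource preserves its source order — including one duplicated
epithelial symbol, deduplicated on load so every gene participates
exactly once.

## What the synthetic data emulates — and what it does not

The generators exist so the whole pipeline can run end-to-end with known
ground truth:

* `simulate_transient()` / `simulate_cohort()` draw per-cell kinetics
  log-uniformly within per-group ranges and superimpose the model on a
  constant baseline (default 100 a.u. — raw indicator baselines are
  instrument-specific, and a positive constant is all that
  $\Delta F/F_0$ requires) with i.i.d. Gaussian frame noise, the
  weakest assumption compatible with least squares. Defaults mirror the
  targeted experiment: 61 frames at 30 s, agonist at frame ten, "L"
  cells drawn with decay times of 240–900 s against 60–240 s for "O",
  amplitudes giving peak $\Delta F/F_0$ of roughly 1–3, 10%
  non-responders that emit baseline-plus-noise only.
* `simulate_object_tables()` plants records that each violate exactly
  one QC rule, plus optional records exactly on the four rule
  boundaries, with ground-truth labels fixed by the planting intent —
  independent of the filter implementation, so the two can be compared.
* `simulate_expression()` places tumors on a one-dimensional latent
  axis loading positively on epithelial and negatively on mesenchymal
  genes (log-uniform magnitudes 0.8–1.5, noise sd 0.5 log2 units by
  default).

Real data are messier in ways these generators deliberately omit:
photobleaching and focus drift (no trend component), correlated noise,
oscillatory or multi-peak transients outside the model family,
segmentation errors beyond the five tabulated rules, and expression
structure richer than one latent axis. Passing tests therefore
demonstrate correctness of the *computations* under the stated
generative assumptions, not robustness to every artefact of real
acquisitions.

## Numerical and problem-size choices

Tests and the acceptance script run the shape-space analysis on 500
simulated trajectories of 52 post-onset frames, parameter recovery on
100 cells per noise condition, QC cross-checks on 1000 records, the
MANOVA null calibration on 500 replicates of a 200-cell cohort, and
tumor scoring on ~500 tumors — sizes comparable to the targeted
experiments and comfortably reproducible on a laptop. Parameter
recovery is quoted as the median relative error of $1/\tau_{\mathrm{decay}}$:
zero to machine precision on noise-free cells and below 15% at
5%-of-peak noise under the cohort generator's default conditions. The
decay time is only weakly identified when the steady state dominates
the decay amplitude ($c \gtrsim b$, a transient that barely decays);
such shapes sit outside the generator's defaults, and in real data the
late-peak eligibility criterion plays the analogous guard role.

## Known limitations

Single-transient model only (no oscillations, no multi-peak responses);
no hierarchical sharing of kinetic parameters across cells; LDA assumes
shared within-group covariance in score space; quintile labels are
cohort-relative, so scores are not comparable across cohorts scored
separately; the "L" triangle's exact vendor geometry is not modelled —
only the area-scaling of linear dimensions is reproduced for
non-circular patterns.
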