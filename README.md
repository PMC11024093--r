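# calshape

Analysis of single-cell calcium transients in geometrically confined
cells, and epithelial–mesenchymal scoring of tumor expression profiles.

Time-lapse imaging of a fluorescent calcium indicator yields one trace
per cell (one frame every 30 s for 30 min, agonist added at the tenth
frame). Cells confined to round ("O") versus elongated triangular ("L")
adhesive micropatterns respond differently — most visibly in how slowly
the transient decays. `calshape` provides the full downstream pipeline
for such experiments, for imaging scientists and computational
biologists:

* **Kinetic model.** Each transient is fitted with the constrained
  rise–decay model
  `f(t) = -(b + c) e^-(τ_decay + τ_Δ) t + b e^-τ_decay t + c`,
  parameterised so that `f(0) = 0` exactly and the rise is never slower
  than the decay (`τ_rise = τ_decay + τ_Δ`, `a = b + c`). Fitting is
  bounded least squares restarted from a fixed 300-point grid (decay
  times 15–1500 s), applied only to cells passing three eligibility
  criteria (non-negative transient median, rank-sum responsiveness at
  α = 0.005, peak in the first half of the segment). The headline
  readout is the decay time `1/τ_decay` in seconds.
* **Shape space.** Whole trajectories are treated as vector
  observations; PCA retains the top three components, MANOVA (Wilks'
  lambda, Bonferroni across agonist concentrations) tests group
  separation and LDA gives the separating direction, back-projectable
  into an average trajectory per group.
* **Single-cell QC.** Merges the four high-content object tables and
  applies the five inclusion rules (shape-factor window per pattern,
  single nucleus, ≥20 px nucleus spacing, nucleus < 300 µm², centroid
  agreement ≤ 30 µm).
* **EPI–MES tumor scoring.** Per-gene z-scores, correlation-refined
  epithelial/mesenchymal signatures (r > 0.5 with the list-average
  z-score), EPI − MES score, rank quintiles H-MES…H-EPI, per-quintile
  marker correlation panels, correlation-matrix clustering, and
  comparative-Ct (2^−ΔΔCt) utilities.
* **Synthetic data.** Seeded generators for model-based trace cohorts
  with ground-truth kinetics, object tables with planted QC violations,
  and latent-axis expression matrices — the whole pipeline runs
  end-to-end with no external data.

## Worked example

```r
library(calshape)

ch  <- simulate_cohort(cohort_spec(n_cells = 30, seed = 42))
tm  <- drop_first_frame(ch$traces)   # 61 acquired -> 60 analysed frames
dff <- normalize_dff(tm)             # dF/F0 against frames 1-8

fits <- fit_cohort(tm)
ok <- fits$eligible & fits$converged
sum(ok)                                            # 54 of 60 cells fitted
tapply(fits$inv_tau_decay[ok], fits$shape_group[ok], median)
#>   L   O
#> 395 143        # median decay time (s): "L" cells decay ~2.8x more slowly

m <- fit_pca(dff)
#> shape_space_model: 60 cells, 60 frames, top 3 components
#>   explained variance: 87.4%, 8.3%, 2.5% (cumulative 98.1%)

compare_groups(m$scores, dff$metadata$shape_group,
               dff$metadata$concentration_uM)[, c(1, 3, 4, 8)]
#>   concentration wilks_lambda    f_stat p_bonferroni
#> 1           0.3        0.308 11.966    0.000696
#> 2           1.0        0.543  4.485    0.0545
#> 3           3.0        0.609  3.429    0.128
```

The median fitted decay times recover the generating group contrast
(the "L" group is simulated with 240–900 s decay times against
60–240 s for "O"), three components carry ~98% of trajectory variance,
and the MANOVA separates the groups where the per-concentration sample
(10 + 10 cells here) suffices.

Tumor scoring on a simulated 500-tumor cohort:

```r
sim <- simulate_expression(expression_sim_spec(n_tumors = 500, seed = 7))
z   <- zscore_genes(sim$expr)
gl  <- epimes_gene_lists()
sc  <- score_and_stratify(z,
         refine_signature(z, gl$epithelial),
         refine_signature(z, gl$mesenchymal))
table(sc$quintile)
#> H-MES L-MES Ambig L-EPI H-EPI
#>   100   100   100   100   100
cor(sc$score, sim$latent, method = "spearman")   # 0.997
```

See `vignettes/calcium-transient-analysis.Rmd` for the model, the
eligibility criteria, every threshold and the design rationale.

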