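# cnmpk — Cluster Newton Method for ensemble PBPK parameter estimation

Physiologically-based pharmacokinetic (PBPK) models are chronically
underdetermined: the irinotecan model shipped with this package has 55–56
unknown clearances, rate constants and volumes, while the clinical data
consist of 9–14 cumulative excretion measurements.  Point estimation is the
wrong tool for such problems — the meaningful object is the **feasible
solution space**, the set of all parameter vectors consistent with the
observations.  `cnmpk` is for pharmacometricians and systems biologists who
want that set.

## The method

The **Cluster Newton Method (CNM)** co-evolves an ensemble ("cluster") of
virtual samples.  With `x = ln(parameter)` and `y = ln(objective)`:

1. draw `n` samples log-uniformly over broad parameter ranges;
2. evaluate the forward model on every sample;
3. fit one affine surrogate `y ≈ A x + b` to the whole cloud by least
   squares;
4. move every sample by the minimum-norm Newton step
   `x_j ← x_j + A⁺ (y*_j − y_j)` toward its (slightly jittered) copy of the
   observed targets, where `A⁺` is the Moore–Penrose pseudoinverse;
5. **dS replication**: form the internally dividing point
   `X_i = (1 − dS)·X_b + dS·X_a` between each sample's pre- and post-update
   positions, re-solve from there with the same `A⁺` against freshly
   evaluated residuals, and keep either candidate with probability ½.

Minimum-norm steps leave the cloud's spread in data-blind directions
untouched, and the dS rule damps the overshoot that full Newton steps
suffer on stiff nonlinear systems — together they let the final cluster
stand in for the feasible set.  `dS = 0` reproduces the unmodified
algorithm exactly.

The package also ships:

* a compiled five-compound PBPK model of irinotecan (CPT-11) and its
  metabolites SN-38, SN-38G, NPC and APC, with enterohepatic circulation
  and biliary T-tube drainage, producing urinary/fecal/biliary accumulation
  objectives for the two patient groups (`OC`: no drainage tube, 9
  objectives; `BDC`: T-tube in place, 14 objectives);
* post-fit statistics: `SS_log = Σ [ln(A_sim/A_obs)]²` scoring,
  best-sample selection, geometric summaries, `r² > 0.64` correlation
  screening, and dS sweeps;
* synthetic inverse problems (exact affine maps, PBPK with known truth)
  so every algorithmic property is testable with no external data.

## Worked example

Fit the OC scenario at reduced scale (300 samples; the study-scale run uses
3000):

```r
library(cnmpk)
scenario <- pbpk_scenario("OC")        # packaged oc.yaml: ranges + objectives
model <- pbpk_model("OC", scenario$settings)
fit <- run_cnm(model, scenario$space, scenario$spec,
               cnm_config(n_samples = 300, n_iterations = 9, dS = 0.5,
                          seed = 1), verbose = TRUE)
#> iter  0  median|logres| 1.296   [q25 0.65  q75 2.42]  failed 0
#> iter  1  median|logres| 0.2279  [q25 0.105 q75 0.433] failed 0
#> ...
#> iter  9  median|logres| 0.158  failed 0 (final)
```

The median absolute log-residual across the 9 objectives contracts from
1.30 (initial cloud, i.e. simulated accumulations off by a factor ~3.7
typically) to 0.16 (~17%).  The published headline quantity — the renal
clearance of irinotecan, parameter #6 — is read off the final cluster:

```r
gs <- geometric_summary(fit$final_cluster)
subset(gs, name == "CL_r_CPT11")
#>         name geo_mean geo_sd ln_mean ln_sd
#> 6 CL_r_CPT11      5.4   1.41    1.69 0.341
```

a geometric mean of 5.4 ml/min/kg with geometric SD 1.41 — i.e. the
ensemble concentrates CL_R in a ÷/×1.4 band around 5.4, even though its
prior range spanned 1–100.  Correlation screening explains *why* some
parameters converge:

```r
corr <- parameter_correlations(fit$final_cluster)
head(corr$pairs[corr$pairs$screened, c("p1", "p2", "r", "r2")], 1)
#>             p1       p2    r   r2
#> 142 CL_r_CPT11 CL_3A4_1 0.82 0.67
```

renal and metabolic clearances move together because only their ratios are
fixed by the excretion split.

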