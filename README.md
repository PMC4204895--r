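# ssio — small-sample iterative optimization for dynamic GRN models

`ssio` fits quantitative, nonlinear ordinary-differential-equation models
of gene regulatory networks (GRNs) to *short* time-series expression data
— the regime of developmental time courses such as adipocyte
differentiation, where nine (human) or even four (mouse) timepoints must
constrain dozens of regulatory weights and kinetic constants.  It is
aimed at systems biologists who have a literature-curated topology, a
floored expression matrix, and too few samples for direct nonlinear least
squares.

## The model and the estimator

Each gene follows sigmoid transcription kinetics with first-order decay:

    dY_i/dt = F_i(A_i) − d_i · Y_i,      A_i = Σ_j q_ij · X_ij
    F(A)    = k1 / (1 + k2 · exp(−k3 · A))

where `A_i` is the signed, weighted sum of the target's regulators
(transcription-factor levels and external stimuli such as cAMP, GR and
IR), `q_ij` are regulatory weights (positive for activation, negative for
repression) and `(k1, k2, k3, d)` are per-gene kinetic constants.  The
SSIO estimator alternates:

1. **PLS weight estimation** — covariance-based partial least squares
   with mean/sd feature scaling, sign constraints and log-penalized
   component selection, giving low-dimensional weight updates;
2. **trust-region kinetics fitting** — bounded Levenberg–Marquardt on a
   one-step-ahead shooting objective (the ODEs restarted from the
   training data at every timepoint);

and scores every iteration with a BIC whose *effective* parameter count,
`P = Σ |atan(q_t) − atan(q_{t−1})| · ln(iteration)`, charges only for
weights that still move.  The minimum-BIC iterate is returned.

Around the estimator the package provides stiff (BDF) simulation and
equilibrium finding, bistability/hysteresis scans with trigger-level
detection, Metropolis–Hastings regional sensitivity analysis scored by a
binned Kolmogorov–Smirnov statistic, Jacobian-based regulator importance
ranking, cross-species weighted-expression comparison, the curated
15-gene adipogenesis topologies (`model1`, and `model2` with five
candidate feedbacks), and a seeded synthetic-data generator.

## Worked example

Fit the bundled noiseless three-gene cascade and inspect the recovered
regulation:

```r
library(ssio)
cs  <- make_recovery_case("cascade3")      # network + true params + series
fit <- run_ssio(cs$series, cs$net, ssio_config())
fit
#> ssio_fit: 1 iteration(s), weight_convergence; best iteration 1 (BIC -182, err^2 2.34)
fit$best$weights[, c("target", "source", "sign", "q")]
#>   target source sign            q
#> 1     g2     g1    1 1.0000000000
#> 2     g3     g1    1 0.9996837085
#> 3     g3     g2    1 0.0003162915
fit$best$residual_sq / fit$total_ss
#> [1] 1.85e-06
```

Every recovered weight carries its generating sign, the dominant
regulator of `g3` is ranked first (the generating weights were 0.02 vs
0.001), and the one-step residual explains all but ~2 × 10⁻⁴ % of the
signal variation.  A bistability scan of the self-activating toy circuit
locates the saddle-node where the low expression branch jumps to the
high branch:

```r
cb <- make_recovery_case("feedback_bistable2")
m  <- grn_model(cb$net, cb$kinetics, cb$weights)
bistability_scan(m, list(gene = "gA", param = "k1"), cb$truth$scan_grid,
                 cb$truth$init_low, cb$truth$init_high)
#> scan_result: gA k1 over [60, 160], 8/11 bistable, trigger 140
```

The trigger (k1 = 140) matches brute-force enumeration of the 1-D
fixed-point equation to within one grid step.

A command-line wrapper covers the same ground from the shell
(`inst/scripts/ssio`): `ssio fit|simulate|scan|mcmc|rank|synth`, each
writing TSV/JSON results plus a `config.json` echo so any run can be
repeated exactly.

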