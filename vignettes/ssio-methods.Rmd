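---
title: "Modelling gene regulatory dynamics from short time series with SSIO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene regulatory dynamics from short time series with SSIO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Time-course expression experiments in developmental systems such as
adipocyte differentiation typically sample a handful of timepoints — nine
days for a human course, as few as four for mouse — while the regulatory
model of interest has dozens of free parameters: a weight for every
transcription-factor (TF) → target edge plus four kinetic constants per
gene.  Direct nonlinear least squares on such data is badly
under-determined.  `ssio` implements a small-sample iterative optimization
(SSIO) strategy for this regime: a covariance-based partial least-squares
(PLS) regression supplies low-dimensional, sign-constrained estimates of
the regulatory weights, a bound-constrained trust-region least-squares
step fits the kinetics, and the two are alternated under a Bayesian
information criterion (BIC) whose effective parameter count grows with how
much the weights actually move.

## The dynamical model

Each gene's mRNA level \(Y_i\) follows

\[ \frac{dY_i}{dt} = F_i(A_i) - d_i Y_i, \qquad
   A_i = \sum_j q_{ij} X_{ij}, \]

first-order degradation plus a saturating transcription rate driven by the
signed, weighted sum \(A_i\) of the regulator levels \(X_{ij}\) (TF genes
and external stimuli).  The rate law is the sigmoid

\[ F(A) = \frac{k_1}{1 + k_2 e^{-k_3 A}}, \]

bounded by the maximal rate \(k_1\) (a.u./day), with \(k_2\) setting the
basal level and \(k_3\) the steepness.  When repressors dominate and the
realised \(A\) is negative, the reflected form
\(F(A) = k_1 k_2 e^{k_3 A} / (1 + k_2 e^{k_3 A})\) is used instead, which
decays to zero as \(A \to -\infty\); both branches are written in terms of
\(e^{-k_3 A}\) so extreme inputs cannot overflow.  The two branches agree
at \(A = 0\) only for \(k_2 = 1\); the dispatch on the sign of \(A\) is a
documented modelling choice and both forms sit behind
`transcription_rate()` so alternative readings remain pluggable.  A gene
with no declared regulator transcribes at the constant basal rate
\(k_1/(1+k_2)\), the \(A = 0\) value of the canonical branch, so the
constitutive limit is continuous in the model family.

Systems are integrated with the backward-differentiation (Gear-type)
stiff solver from **deSolve** (`method = "bdf"`, rtol 1e-6, atol 1e-8 by
default).  Negative solver excursions are clamped to zero in reported
trajectories only — never fed back into the solver state.

External stimuli (cAMP, glucocorticoid receptor signalling, insulin
receptor signalling) enter \(A\) through dedicated weighted edges.  Their
schedules support three profiles: a linearly decreasing pulse between an
onset and an offset day (human cAMP/GR, active on `[onset, offset)`), a
constant level over a closed interval (the mouse stimuli, whose
intermediate data do not constrain a shape), and a persistent step (IR,
switching on at the immature-adipocyte stage).  "Linearly decreasing" is
itself a choice: only the direction of change is biologically constrained,
so the simplest monotone profile is used.

## Data handling

Expression matrices are floored at 20 a.u. (the truncation applied to the
RMA-normalised arrays upstream) and sparse grids are densified by
per-gene linear interpolation, *strictly inside* the observed range — no
extrapolation, since only intermediate points can be reconstructed
defensibly.  Interpolated columns are flagged so residuals can exclude
them.  Before every PLS fit each regulator row is scaled by mean/sd
(the sample, \(n-1\), standard deviation): dividing by the standard
deviation standardises variance while multiplying by the mean preserves
the premium on highly expressed genes that floor truncation would
otherwise distort.  Constant rows (genes stuck at the floor, e.g. human
GATA2) pass through unchanged rather than erroring, flagged degenerate.

## The PLS core

For a single output the first direction vector is the unit vector
proportional to the covariances \(\mathrm{cov}(x_i, y)\); inputs and
output are regressed on the scores \(t = p^\top X\) (no intercept) and
replaced by their residuals, and the procedure repeats until the residual
is negligible, the next direction is degenerate, or the component count
reaches the sample-size cap \(n_\mathrm{samples} - 1\).  Coefficients
over the original inputs are recovered through the running deflation map
(\(r_1 = p_1\), \(r_k = p_k - \sum_{j<k} (a_j^\top p_k)\, r_j\), so
\(\hat y = X^\top \sum_k a_{y,k} r_k\)); with all components kept on
full-rank tall data this reproduces no-intercept ordinary least squares,
which the tests assert against the normal equations.

Two modifications matter for network fitting:

* **Sign constraints.**  A coefficient whose sign contradicts the
  declared activation/repression sign of its edge is replaced by
  `sign * epsilon` with `epsilon = 1e-3` on the normalised scale — small
  but nonzero, so a mis-signed regulator is demoted rather than deleted.
  The constraint (and the penalty below) can be disabled via
  `ssio_config(sign_constraints = FALSE, penalty = FALSE)` to reproduce
  the over-fitting failure mode in which the fit improves but the
  stimulus-response logic breaks.
* **Log-penalized component choice.**  The retained component count
  minimises \(\mathrm{RSS}(m) + \lambda \ln(1+m)\), with \(\lambda\)
  defaulting to the sample variance of the output; ties go to the smaller
  \(m\).  The penalty body is a design choice (the criterion is only
  specified as log-penalized); \(\lambda\) is exposed for sensitivity
  checks.

Because cAMP and GR dominate the induction of CEBPB between the
preadipocyte and immature-adipocyte stages, callers can mask that window
per target (`ssio_config(masks = list(CEBPB = ...))`); masked timepoints
are dropped from the PLS samples and their one-step pairs are excluded
from the scalar objective, making the fit exactly invariant to the masked
values.

## The SSIO loop

1. **Initialise** weights per target by sign-constrained PLS of the
   regulator levels against the target level, normalised to unit L1 norm
   per target.  Kinetics start at \(k_1 = \max Y_i\), \(k_2 = 1\),
   \(k_3 = 1/\mathrm{sd}(A_i)\) (so the sigmoid operates in its
   responsive range regardless of the weight scale) and
   \(d = \ln 2 / 2\) per day, a two-day mRNA half-life.
2. **Kinetics step (maximisation).**  For each gene, \((k_1,k_2,k_3,d)\)
   minimise the squared one-step-ahead deviation: the gene's ODE is
   started from the training data at each timepoint and integrated to the
   next, with the regulator sum interpolated linearly along the training
   data within the step.  The per-gene problems are solved by damped
   (Levenberg–Marquardt, trust-region style) bounded least squares from
   **minpack.lm**; all timepoint pairs are integrated simultaneously on a
   rescaled unit interval, which keeps the objective one solver call.
   Default bounds keep rates on the data's scale:
   \(k_1 \le 10 \max Y\), \(k_2 \le 100\), \(k_3 \le 10\),
   \(d \in [10^{-4}, 5]\)/day.
3. **Weight step (expectation).**  The full system is re-simulated from
   the first timepoint; per target, a PLS of the *simulated* regulator
   trajectories against the observed target yields an update direction
   (unit L2 norm), and the weights move along it by a scalar chosen by a
   1-D bounded search on the same one-step objective (interval
   \([-c_{\max}, c_{\max}]\), default 1, per target — the update scalars
   are per-target quantities).  Sign constraints are re-enforced after
   the move, and a step is rejected if it does not improve on the zero
   scalar.
4. **Scoring.**  After each iteration the full-system one-step residual
   \(\mathrm{err}^2\) is recomputed (every gene, every consecutive pair,
   the system initialised with training data), summed over genes and
   steps, with an optional per-gene breakdown.  The BIC is
   \(N \ln(\mathrm{err}^2/N) + P \ln N\) — the Gaussian-regression
   Schwarz form with \(N\) the number of one-step observations — where
   the effective parameter count is
   \(P = \big[\sum_{ij} |\arctan q_{ij}^{(t)} - \arctan q_{ij}^{(t-1)}|\big]
   \cdot \ln t\): weights that stop moving stop costing, and iteration 1
   is penalty-free (\(\ln 1 = 0\)).
5. **Stopping and selection.**  The loop ends when the relative L1 change
   of the weight vector falls below 1e-8 or after 100 iterations
   (defaults); the iterate with minimal BIC is returned, with the full
   history attached.

The one-step objective deliberately decouples the genes: within a single
inter-sample step the regulators follow the training data, so each gene's
kinetics problem is one-dimensional in state and the error of this
approximation is second order in the step length.  The *evaluation*
residual, by contrast, integrates the full coupled system.

A post-fit diagnostic, `check_signal_response()`, simulates the fitted
model with and without the stimulus schedule; the fit is behavioural when
every key marker ends above the midpoint of its observed pre/post levels
with stimuli and below it without.  The midpoint is a documented default
for a criterion that is inherently qualitative; a marker exactly at its
threshold fails (strict inequality), making the tie-break deterministic.

## Sensitivity, bistability and comparison tools

**Regional (behavioural) sensitivity.**  Parameters are sampled by
Metropolis–Hastings with an *independence* proposal drawn from uniform
priors, so the transition densities cancel exactly; the residual error is
treated as reciprocal to the posterior probability, giving the acceptance
ratio \(\alpha = \min(1, \mathrm{err}_n/\mathrm{err}^*)\) (the exponent
on the ratio is configurable, default 1, since the published form of the
ratio is ambiguous between errors and squared errors).  Prior ranges
follow fixed rules: degradation constants within ±0.1 of their fitted
values (floored above zero — too-small degradation lets levels grow
without bound), TF weights on \([0,1]\), and all other parameters on
\([0, 2v]\) when the fitted value \(v > 0.25\), else \([0, 0.5]\).  The
chain state is recorded at every step (repeating on rejection), each
state classified behavioural or not by the stimulus-response rule; after
discarding a burn-in (default 10 000 samples) each parameter is scored by
the maximal absolute difference between the behavioural and
non-behavioural cumulative distributions on a fixed grid of 10 intervals
spanning its prior.  A random-walk proposal and convergence monitoring
beyond the bin-frequency check are intentionally out of scope.

**Bistability scans.**  With stimuli set to zero, the equilibrium is
computed from a low and a high initial state at each value of a control
parameter (typically a key gene's \(k_1\)).  Equilibria are found by
integrating over an adequately long window (t = 100 days by default) and
polishing the endpoint by damped least-squares root finding on the
right-hand side to \(\|\dot Y\|_\infty < 10^{-8}\); because trajectories
can linger in the ghost of a saddle-node, the integration window is
extended (up to five times) before conceding failure.  The trigger level
is the smallest control value at which the previously separated low
branch jumps up to rejoin the high branch; branch separation uses a
configurable gap threshold (default 1 a.u.).  `local_sensitivity()`
repeats the scan under relative perturbations of a chosen parameter and
reports whether bistability survives and how the trigger shifts.

**Importance ranking.**  The importance of regulator \(i\) for target
\(j\) at a differentiation stage is \(|\partial(\dot Y_j)/\partial X_i|
\cdot X_i = |F_j'(A_j)\, q_{ij}|\, X_i\) at the stage's state — the
analytic Jacobian of the regulation term scaled by the regulator's
level — with regulators ranked per target per stage.  The analytic
derivative is verified against central finite differences in the tests.
The default stage → day mapping (proliferating = day −2, preadipocyte =
day 0, immature = day 3 human / 2 mouse, mature = last day) is a config
input, since the published mapping table is not reproduced here.

**Cross-species comparison.**  For a target's regulators the
weighted-expression levels \(q_i X_i\) are evaluated at the four stages,
their changes across the three stage transitions are z-score normalised
per species (pooling that species' changes, so cross-transition contrasts
survive), and the two species are compared per transition by the
two-sample Kolmogorov–Smirnov test (asymptotic p-values by default; the
exact small-sample option is available).  Pooling per-regulator changes
within a transition — rather than testing each regulator's stage profile —
is the reading that yields one test per transition; fewer than two
regulators on either side is reported as undefined.

## The synthetic generator and what it does (not) emulate

`synthetic_spec()`/`generate_network()`/`generate_timeseries()` produce
random signed networks and noisy time series with the statistical shape
the fitter assumes: short day grids (the human-style 9-point grid by
default, mouse-style 4-point grids supported), expression floored at 20,
and multiplicative log-normal observation noise (chosen over additive
noise to respect positivity; \(\sigma^2 = \ln(1 + \mathrm{cv}^2)\) so the
requested coefficient of variation is exact).  Sparse draws keep at least
one constitutive gene as an exogenous driver; an explicitly complete
graph (`edge_density = 1`) is honoured as requested.  The generator does
*not* emulate microarray probe-level artifacts, cross-hybridisation, or
biological replicate structure — so green tests certify the estimation
machinery on data from the model family, not robustness to real-data
pathologies.

Four curated cases ship with the package.  `cascade3` (noiseless, 20
daily points) probes weight recovery; its regulator contributions are
deliberately separated in scale and time constant because in a pure
cascade the ranking of two strongly collinear regulators is not
identifiable — an honest limitation of any covariance-seeded method on
monotone data.  `feedback_bistable2` pairs a self-activating gene
(bistable at the reference parameters, verifiable by brute-force 1-D
root enumeration) with a reporter.  `adipo_mini5` is a five-gene
miniature of the adipogenesis motif — a stimulus-driven marker cascade
locked high by positive feedback, with a constitutive repressor — that is
behavioural at its reference parameters.  `model1_like15` instantiates
the full 15-gene topology with invented (synthetic, clearly labelled)
parameters for end-to-end smoke tests; its values are not fitted
estimates of any real course.

## Numerical choices and limitations

* Solver tolerances: rtol 1e-6 / atol 1e-8 for trajectory simulation;
  the internal one-step predictions use rtol 1e-8 / atol 1e-10 since
  their residuals are differenced.  Refining tolerances tenfold moves
  endpoints by less than 1e-4 relative (asserted in the tests).
* The per-gene kinetics solver runs at most 60 Levenberg–Marquardt
  iterations; a gene whose optimisation fails keeps its previous
  kinetics and is reported, so one pathological gene cannot abort a fit.
* Residual-zero BICs are floored at machine epsilon before the log.
* All stochastic operations (generators, Metropolis chains) are
  reproducible bit for bit from their seed; the fitting loop itself is
  deterministic, so identical configs give byte-identical serialised
  results.
* Problem sizes in the shipped tests and the acceptance script are chosen
  for tight feedback: 2–15-gene networks, 9–20 timepoints, 10⁴-step
  Monte-Carlo calibrations.  The machinery itself has no hard size limit,
  but the weight step re-simulates the full system once per iteration, so
  wall time grows with network size times the iteration count.
* Known limitations: ranking recovery degrades under strong regulator
  collinearity (see above); the dominant-negative sigmoid branch is
  discontinuous at \(A = 0\) for \(k_2 \ne 1\); delay, stochastic and
  spatial dynamics are out of scope, as is inferring the network
  *structure* — topologies are inputs, fixed from prior knowledge.
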