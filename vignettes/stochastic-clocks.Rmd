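---
title: "Quantifying the stochastic component of epigenetic clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the stochastic component of epigenetic clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

Epigenetic clocks are penalized linear regressions that predict
chronological age from DNAm beta-values at a fixed CpG set. Age-related DNAm
change, however, appears largely stochastic at single-CpG resolution:
initially unmethylated CpGs drift up, methylated ones drift down, in small,
asynchronous increments. `stocclock` makes this tension quantitative by
simulating a *pure* stochastic accrual process at a clock's own CpGs,
training a "stochastic clock" on the simulated data with the same recipe
used for real clocks, and comparing the two clocks' accuracy on the same
cohorts.

### Single-cell level

At one CpG in one cell, methylation is binary. With per-step switch
probabilities $p$ ($0 \to 1$) and $q$ ($1 \to 0$), the chain's transition
matrix gives

$$P_{01}^{(t)} = \frac{p}{p+q}\left(1 - (1 - p - q)^t\right),$$

with steady state $\pi_1 = p/(p+q)$ and the recurrence
$P_{01}^{(t+1)} = p + (1-p-q)\,P_{01}^{(t)}$. For realistic switch rates
($p, q \sim 10^{-5}$) and human timescales, $(p+q)t \ll 1$ and
$P_{01}^{(t)} \approx p\,t$: the population methylation fraction grows
*linearly* with time. This linearity is why a purely stochastic process can
support an accurate linear age predictor, and it licenses the linear
population-level simulator below. Note the validity condition is on
$(p+q)t$, not on $p\,t$ alone: with $q \gg p$ the approximation fails even
at small $p\,t$ (the implementation's tests assert the bound on the correct
regime).

`markov` functions: `transition_matrix()`, `prob_methylated_closed_form()`,
`prob_methylated_recurrence()`, `steady_state()`, `linear_approximation()`.
The oscillatory regime $p + q > 1$ is supported (the closed form stays
exact) but is outside the biological regime.

### Population level

The simulator works on a cell-population beta profile. Per time step, CpG
$c$ is altered with probability $p_c = 1 - e^{-\gamma\,|\mathrm{EffSize}_c|}$,
where $\mathrm{EffSize}_c$ is the observed old-minus-young mean beta
difference and $\gamma$ is a global rate. An alteration adds a half-normal
deviate $|N(0, \sigma)|$, signed by the effect direction, to the CpG's
inverse-normal quantile $x_c = \Phi^{-1}(\beta_c)$; the profile is mapped
back with $\Phi$. Two consequences are load-bearing:

* betas remain strictly inside $(0, 1)$ with no clipping during simulation;
* a fixed quantile-space increment produces the largest beta change near
  $\beta = 0.5$ and vanishing change near the boundaries — the
  heteroscedasticity beta-values actually display.

Because the quantile-space update is purely additive, the state after $T$
steps is $x_c^{(0)} + \mathrm{sign}(\mathrm{EffSize}_c)\sum_{i=1}^{k_c}
|r_i|$ with $k_c \sim \mathrm{Binomial}(T, p_c)$. `simulate_sample()`
exploits this to draw end states exactly in one shot (the per-step path is
available from `simulate_trajectory()`, and the two are tested to agree in
law). Expected quantile drift is
$T\,p_c\,\sigma\sqrt{2/\pi}\cdot\mathrm{sign}(\mathrm{EffSize}_c)$, the
package's main Monte-Carlo invariant.

Directionality is frozen at effect-estimation time; alterations are
independent Bernoulli draws per CpG and step (the minimal reading — no
joint structure is implied by the model).

## Tunable parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `gamma` | dimensionless | fitted | global alteration rate; small `gamma` makes `p_c` proportional to the effect size, large `gamma` saturates `p_c` at 1 |
| `sigma` | quantile units | fitted | scale of one alteration's half-normal increment |
| `steps_per_year` | 1/year | 35 | time anchor (approximate annual stem-cell divisions for blood); arbitrary, but it sets the scale on which `gamma`, `sigma` are interpreted |
| `base_age` | years | 45 | age of the ground-state profile (the young reference pool) |
| `alpha` | — | 0.5 | elastic-net mixing for clock training |
| lambda grid | — | 0, 0.001, …, 1 | 1,001 penalty candidates; selection by held-out RMSE, ties to the smallest lambda |
| `eps` | — | 1e-6 | beta clipping margin before the quantile transform; clip counts are reported |

With the defaults, simulating from the base age to the old-group anchor age
of 82 runs exactly 1,295 steps, and the cohort protocol (five samples per
age, ages 45–83) yields 195 samples over 39 distinct ages.

## Fitting (gamma, sigma)

`fit_parameters()` is a recursive grid search: at each grid pair it runs 50
simulations from the ground state for the anchor step count and compares
simulated to observed old-group end states; the search then shrinks the
window (factor 0.2 per level, 3 levels, 11×11 grids) around the incumbent
best and returns the global best. Seeds derive from the config seed, so a
refit is bit-identical.

Two numerical choices deserve explanation:

* **Both axes are searched in log space.** The expected drift depends on
  $(\gamma, \sigma)$ essentially through $p_c(\gamma)\,\sigma$ in the
  small-effect regime, so the objective has a near-degenerate valley along
  $\gamma\sigma \approx \mathrm{const}$ — a straight line in log-log
  coordinates. A linear $\gamma$ axis makes the recursive zoom lock onto
  valley points far from the generative truth; log-log spacing lets the
  refinement travel along the valley.
* **The objective matches dispersion as well as means.** The mean end-state
  profile alone cannot break the $\gamma\sigma$ degeneracy. The
  across-simulation per-CpG SD scales differently along the valley (fewer,
  larger increments are more variable), so the default objective is
  MAE(mean profiles) + `dispersion_weight` × MAE(SD profiles), which makes
  the fit identifiable. Set `dispersion_weight = 0` to recover mean-only
  fitting — appropriate when the observed old group carries substantial
  measurement or inter-individual noise that the simulator does not model
  (otherwise `sigma` absorbs that spread); the reported `mae` field is
  always the mean-profile MAE, comparable across objectives.

**Known limitation.** With 50 simulations per grid point, the statistical
error of the recovered parameters in a generative-recovery experiment
(truth $\gamma = 5$, $\sigma = 10^{-3}$, 300 CpGs) is roughly 0.1–0.17 in
log-parameters — about 4–5% relative, but several times larger than the
final-level grid *cell* (~0.025). Recovery to within one final-level cell
is therefore not statistically attainable at this simulation budget, and
the corresponding strict acceptance assertion is deliberately left failing
rather than met by coarsening the final grid. Reported precision should be
read as ±5–20%, not as the grid resolution.

## Clock training and application

Per-CpG beta-values are standardized to mean 0, SD 1 on the training cohort
before the elastic-net fit — this removes cell-type baseline differences
and is what lets a clock trained on one cell type correlate with age in
another. At application time two standardization modes exist: `"within"`
(default) re-z-scores each CpG inside the evaluation dataset, making
predictions invariant to per-CpG affine shifts (the cross-cell-type
rationale); `"frozen"` reuses training statistics and reproduces fitted
values on the training set exactly. Both are exposed because the
application-time recipe is a genuine design choice; results in this package
use `"within"` unless stated. glmnet's lambda parameterization is used
as-is, so lambda values are comparable only within this package — model
selection is by held-out RMSE, never by the lambda value.

## RR2 and what it means

`evaluate_clock()` reports MAE (mean absolute error by default; the median
variant is exposed since both conventions circulate), Pearson's $R$ with a
two-tailed test, and $R^2$ defined as the *squared correlation* — not a
regression $R^2$. RR2 is the ratio of $R^2$ of the stochastic clock to that
of the original clock on the same cohort; cohort-specific factors (age
range, normalization, batch) inflate or deflate both numerators equally and
cancel. RR2 < 1 means part of the original clock's accuracy is not
reproducible by stochastic accrual alone. The `rr2_vs_unexplained()`
diagnostic checks the alternative reading (stochastic clocks capture the
*unexplained* variation, which would imply RR2 ≈ $1/R^2 - 1$);
`meta_compare()` aggregates ratios across cohorts with a one-tailed paired
Wilcoxon signed-rank test and a cohort-size-weighted regression with cohort
fixed effects.

## EAA / IAA

EAA is the residual of DNAm-age regressed on chronological age; IAA
additionally adjusts for 11 of the 12 immune-cell fractions (only 11 are
independent on the simplex; the dropped column is the one with the largest
mean, and residuals are provably invariant to which is dropped — constant
fraction columns are absorbed by the intercept with a warning). Association
tests: exact Wilcoxon rank-sum below a combined n of 50 (no ties),
continuity-corrected normal approximation above; ordinal phenotypes
(smoking 0/1/2) use the regression slope t-test. The package's central
reproducible claim is qualitative: a phenotype acting purely through cell
composition shows a significant EAA association that *vanishes* in IAA,
while a composition-independent effect survives both; and a stochastic
clock shows neither when the generative process ignores the phenotype.

## What the synthetic data does and does not emulate

`make_reference_panel()` draws ground states from a bimodal mixture (beta
modes near 0.1 and 0.9 plus 20% intermediate uniform mass — genome-wide
DNAm bimodality), signed half-normal effect sizes capped at 0.05 beta-units
(the scale seen over ~4 decades in purified cells; the hypermethylating
fraction is a parameter), and heteroscedastic per-sample noise added in
quantile space (`noise_sd = 0.1`; the noise level of real sorted-cell data
at fixed age is not published, so this is a fixture parameter, not a claim
about any cohort). `make_aging_cohort()` layers, on top of stochastic
accrual from a randomly drawn young profile: covariate-scaled per-CpG
offsets (specified in beta-units at the ground state, applied additively in
quantile space so betas stay bounded), optional cell-composition shifts
with a per-CpG signature, a per-sample biological-age jitter
(`age_jitter_sd`, years), and measurement noise. Without the last two, a
simulated cohort maps age to methylation almost deterministically and every
clock saturates at $R^2 \approx 0.99$ — real cohorts do not look like
that, which is why the acceptance experiments use 5-year jitter and 0.1
quantile noise, and train "original" clocks on 400-sample cohorts (real
published clocks are trained on far more data than the 195-sample
simulation protocol; at equal training sizes the stochastic clock, fitted
on clean simulated data, systematically wins and RR2 exceeds 1).

Not emulated: array probe chemistry, batch effects, genomic coordinates,
spatial correlation between CpGs. A green test on synthetic data
establishes internal consistency of the pipeline and the qualitative
confound-separation logic — not any quantitative claim about a real cohort.

## Degenerate inputs and edge policies

* `p = q = 0`: the start state is absorbing; the methylation probability is
  0 for all `t` (no error); the steady state is undefined (error).
* Zero-effect CpGs are kept throughout with `p_c = 0`, so clock CpG sets
  stay intact.
* Zero-variance CpGs in training are excluded from the penalized fit and
  given weight 0 (warning); constant CpGs in a `"within"`-standardized
  evaluation contribute 0.
* Constant predictions make the correlation undefined: MAE is still
  reported, `r` is `NA` with a warning; RR2 with a zero-denominator $R^2$
  is an error, and RR2 > 1 is reported with a warning.
* Fractional ages are handled by rounding the step count; ages below
  `base_age` are errors.
* All generators and the fitter take explicit integer seeds; per-sample
  seeds derive deterministically from the master seed, so cohorts are
  reproducible and order-independent.
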