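---
title: "Modelling rationally inattentive orientation discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rationally inattentive orientation discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rattention)
```

# The task and the modelling problem

`rattention` models a two-alternative forced-choice (2AFC) task in which a
head-fixed mouse sees two oriented gratings and must pick the more
*vertical* one. Orientations live on $[0, 180)$ degrees; the decision rule
operates on the folded *verticality* coordinate $v(\theta) = 90 - |90 -
\theta|$. The two gratings carry independently drawn contrasts from
$\{0.3, 0.6, 1\}$, and the orientation of the correct (more vertical) side
follows a horizontal-heavy prior $\pi(\theta)$. Correct choices are
rewarded according to one of three stimulus–reward environments: a
constant 5 µl everywhere, a linear increase from 1 µl (horizontal) to 8 µl
(vertical), or the reverse.

The scientific question the package operationalizes: given limited,
costly sensory precision and noisy downstream decision circuits, *how
should* a reward-maximizing observer distribute its encoding resources
over orientation space, and do trial-by-trial learning rules based on
reward prediction errors reach the same allocation?

# The observer

## Encoding

A presented orientation $\theta_0$ yields an internal measurement $m$
with a von Mises distribution on the angle-doubled circle
($\psi = 2\theta$, period $2\pi$):

$$p(m \mid \theta_0, c) \propto \exp\{k(c)\, g(\theta_0) \,
  [\cos(\psi_m - \psi_0) - 1]\},$$

discretized on a 2° orientation grid (90 points) and normalized to sum to
one. Two multiplicative factors set the concentration: the contrast
response $k(c) = k_{\max} c^q / (c^q + c_{50}^q)$ (Naka–Rushton form;
defaults $q = 2$, $c_{50} = 0.5$) and the *resource gain* $g(\theta)$, a
positive function normalized to integrate to one over the (normalized)
orientation domain, represented internally with mean 1 so that the
uniform allocation is $g \equiv 1$.

The gain family is polynomial: on the half-domain $x \in [0, 1]$ the
cumulative allocation is $G(x) = x[1 + (x - 1)(g_0 + g_1 x + g_2 x^2)]$,
which satisfies $G(0)=0$, $G(1)=1$ for any coefficients; $g = G'$ is
sampled, mirrored onto the second half of orientation space (the prior is
symmetric about vertical), and renormalized. Coefficients for which $G$
is not strictly increasing are invalid and rejected (the optimizer treats
them as a penalty). `resource_gain(c(0, 0, 0))` is the uniform
allocation.

## Decoding and choice

The observer combines the likelihood with the prior and reports the
posterior circular mean (Bayesian least squares) on the doubled circle;
`bls_estimate()` exposes this decode. Because the decision rule lives in
verticality space, the decoded orientation is folded to $v$ *before*
moments are taken: `estimator_moments()` returns the linear mean and
variance of the folded estimate under the measurement distribution. (The
alternative — circular moments of the raw orientation estimate, folded
afterwards — is available via `observer_params(convention =
"circular")`; the two agree in the high-precision limit. The folding
point matters at low precision and the verticality-first convention is
the default because the probit decision stage is linear-Gaussian in
verticality.)

The choice rule is a probit on the moment difference with additive late
(post-decoding) Gaussian noise $\sigma_{\text{late}}$ and bias terms:

$$P(\text{choose left}) = \Phi\!\left(
  \frac{E[\hat v_l] - E[\hat v_r]}
       {\sqrt{\mathrm{Var}[\hat v_l] + \mathrm{Var}[\hat v_r] +
        \sigma_{\text{late}}^2}}
  + \beta_0 + \beta_1 D + \beta_2 (c_l - c_r)\right),$$

with $D \in \{+1, -1, 0\}$ coding the previous choice (left, right, first
trial). The lapse rate of this family is fixed at zero: apparent lapses
are rationalized by the encoding model. `simulate_choice()` runs the same
machinery mechanistically (sample a measurement, decode, add late noise);
its agreement with the probit approximation is asserted in the tests to
within 0.02 at mouse-like parameters.

**Validity of the Gaussian decision stage.** The probit stage assumes the
folded estimate is approximately Gaussian. This holds well for
$k_{\max} \gtrsim 3$ but fails badly at very low precision, where the
probit overstates accuracy (we measured 0.70 predicted vs 0.53 simulated
at $k_{\max} = 0.67$). The resource optimizer therefore constrains its
$k_{\max}$ search to $[3, 150]$; outside that region the objective would
reward an artifact of the approximation, not performance.

# Endogenous resource allocation

`optimize_gain()` finds $(g^*, k_{\max}^*)$ minimizing expected reward
loss plus a precision cost,

$$\mathcal{L}(g, k_{\max}) = E[\,R \cdot P(\text{error})\,] +
  \eta \, \bar k, \qquad
  \bar k = \frac{1}{|C|}\sum_{c} k(c) \int \pi(\theta) g(\theta)\,
  d\theta,$$

with the reward weight $R$ of a stimulus pair carried by its correct
side: the constant 5 µl, the larger of the two mapped rewards in the
increasing environment, the smaller in the decreasing one. A classical
mutual-information cost ($\eta$ per nat of expected uncertainty
reduction) is available via `cost_model(kind = "mutual_information")`;
no cost is charged on late precision. Optimization is multi-start
Nelder–Mead (default 50 starts, the first always the uniform allocation)
over the three gain coefficients and $\log k_{\max}$.

Three stimulus-pair weightings are implemented. The optimizer defaults to
the *dense* weighting — the full double integral of independent
prior-weighted pairs over the grid — because near-threshold pairs are
where the allocation controls discriminability; restricting the objective
to the task's discrete difficulty set (20°–90° in 10° steps, the
`"task"` weighting) leaves all pairs far apart and nearly erases the
allocation's influence on the objective. Evaluation quantities
(`expected_accuracy()`, `expected_reward()`, the swap analysis) use the
`"task"` weighting, i.e. the generative distribution of the task:
correct-side orientation from the prior restricted to orientations that
admit a difficulty, difficulty uniform over the feasible subset, the
less-vertical grating placed at either preimage of the target verticality
with equal probability. This conditional-difficulty scheme keeps the
reward at stake nearly symmetric between the two linear environments
(4.77 vs 4.23 µl), consistent with the near-equal reward expectations the
task design intends.

## Reference operating point

Simulation studies need a standard parameter set. `reference_settings()`
fixes $\eta = 0.16$, $\sigma_{\text{late}} = 12$ (verticality degrees),
$q = 2$, $c_{50} = 0.5$, chosen once so that the endogenously optimized
observer performs at 77–79% correct in both linear environments — the
mouse-like band — with $k^*_{\max}$ well inside the region where the
Gaussian stage is valid. At this operating point the optimal allocations
show the qualitative regime structure the framework predicts:

* cheap precision and little late noise → allocation tracks the prior
  (more gain at horizontal than vertical);
* substantial late noise and costly precision → the allocation becomes
  *myopic* to the prior peak, shifting gain toward intermediate and
  vertical orientations;
* the increasing environment shifts gain toward vertical relative to the
  decreasing environment, which shifts it toward horizontal.

`swap_study()` quantifies the value of environment-specific allocation by
optimizing both linear environments, evaluating each environment's
expected per-trial reward under its own and under the other's full
optimal solution, and reporting the percent loss in each direction and
their mean. At the reference operating point the mean loss is a few
percent: with all task pairs at least 20° apart and the late noise needed
to reach mouse-like accuracy, the allocation shape controls only a
modest share of the decision variance, and the two environments' optimal
$k_{\max}$ differ, so the swapped-in solution partially compensates its
mismatched shape. Both effects bound the achievable swap cost in this
implementation.

# Descriptive models

`dm_choice_probability()` and `fit_dm()` implement six probit models on
the verticality difference: DM1 (single noise SD, side and
previous-choice biases, symmetric lapse), DM2 (one SD per contrast
level), DM3 (adds a contrast-difference bias), DM4 (separate left/right
lapse rates, mixed as $\Phi(z)(1 - \lambda_L - \lambda_R) + \lambda_L$ so
each $\lambda$ is that side's guess rate), DM5 (adds a previous-trial
reward-by-choice term) and DM6 (DM4 + DM5). The models are nested
(DM1 ⊂ DM2 ⊂ DM3 ⊂ …), which the test suite asserts on maximized
likelihoods. Fits are multi-start maximum likelihood on transformed
scales (log noise, logistic lapse), compared by AIC/BIC via
`compare_fits()`.

The observer itself is fitted in three variants with `fit_observer()`:
`g-endog` (fits $\eta$ and derives $g^*, k^*_{\max}$ from the internal
optimizer at every evaluation — same parameter count as DM3), `g-free`
(fits the gain coefficients and $k_{\max}$ directly) and `g-const`
(uniform gain). The endogenous variant is expensive; its inner
optimization uses few starts and results are cached within a fit.

# Trial-by-trial reallocation

The learning model maintains a reward-belief vector $\hat R(\theta)$ on
the 2° grid, initialized uniformly at the 5 µl constant-environment
reward (the initialization is a free modelling choice; the constant
reward is the natural naive expectation). After choosing
$\tilde\theta$ and receiving reward $R_t$:

* confidence $C_t = \max(p, 1-p)$ from the bias-free choice probability
  under the *current* gain;
* learning rate $\alpha_t = C_t / (C_t + \tilde\alpha^\pm)$ with separate
  divisive constants for positive and negative prediction errors;
* prediction-error vector
  $\delta_t(\theta) = (R_t - \hat R_t(\tilde\theta)) \cdot
  \exp\{\tilde k[\cos(\tilde\psi - \psi) - 1]\}$;
* update $\hat R \leftarrow \max(\hat R + \alpha_t \delta_t, 0)$ and
  divisive normalization $g = \hat R / \sum \hat R$, which feeds back
  into encoding on the next trial (closed loop).

Two kernel forms are implemented (`rl_params(form = )`). The default
scales the scalar prediction error by the kernel, so the belief converges
to a kernel-smoothed map of received reward. The alternative `"literal"`
form applies the kernel to the belief term only
($\delta = R - \hat R(\tilde\theta) \cdot \text{kern}$); far from the
chosen orientation this adds the raw reward on every rewarded trial,
which drives the *normalized* belief toward inverse choice occupancy
rather than the reward map — we keep it for comparison but do not
recommend it. Defaults $\tilde\alpha^\pm = 50$ (slow, confidence-gated
updates) and $\tilde k = 1.4$, matching the population tuning-width
default so that credit spreads over the orientations the chosen
stimulus's neural representation covers.

**Convergence to the static optimum.** `rl_convergence_study()` compares
the time-averaged learned gain (last 500 of 1500 trials) against the
static optimum by Spearman correlation. In this implementation the
correspondence is qualitative, not quantitative: the learned gain is a
normalized *reward* map, which is structurally near zero for
orientations that are rarely rewarded when chosen (no orientation below
20° verticality can ever be the correct choice), whereas the static
optima allocate substantial gain exactly there whenever horizontal
discrimination is at stake. Directional signatures do transfer — the
increasing environment ends with relatively more vertical allocation
than the constant environment, and a mid-stream environment switch
redirects the allocation — and these are what the test suite asserts as
robust properties.

# Poisson population code

`population_code()` builds $N = 30$ independent Poisson neurons with von
Mises tuning $f_n(\theta) = g(\theta_n) k(c) \exp\{\hat\kappa
[\cos(\psi_n - \psi) - 1]\} + \Delta$. Preferred orientations are placed
by the inverse CDF of the prior at quantile midpoints, so their local
density is proportional to $\pi(\theta)$ — which lets the discrete BLS
decoder drop the prior weights (the spacing absorbs them):
$\hat\theta = \sum_n \theta_n L_n / \sum_n L_n$ with $\log L_n = \sum_m
r_m \log f_m(\theta_n) - \sum_m f_m(\theta_n)$, evaluated with a
log-sum-exp shift and combined as a circular mean. The tuning width
default $\hat\kappa = 1.4$ (≈30° half-width at half-maximum) is a
stand-in for a value that would be estimated from population imaging;
$\Delta = 0.1$ spikes/trial is the resting rate.

`optimize_network()` maximizes expected reward minus $\eta$ per expected
spike over the same gain family plus the peak rate $r_{\max}$, with
decision noise $\sigma_{\text{late}}$ added to the decision variable
after the two sides' decodes are compared. Decode moments are estimated
by Monte Carlo with a fixed internal seed (60 draws per
stimulus-contrast cell by default) so the objective is deterministic;
the spike expectation (two populations per trial) is exact. A higher
spike cost robustly lowers overall firing and the optimized peak rate. A
caveat specific to this architecture: because preferred orientations are
placed in proportion to the prior, extra gain at high-prior (horizontal)
orientations is doubly expensive in spikes — it multiplies many neurons,
and those stimuli occur often — while the dense placement already
supports horizontal decoding without extra gain. Across the low-late-
noise spike-cost range we probed, the optimized network therefore tilts
its gain and stimulus-evoked activity toward vertical rather than
concentrating it at the prior peak; the expected-reward term alone does
favor horizontal allocation, but not by enough to pay its spike bill.
The test suite asserts the cost ordering and records the activity
ordering as an open discrepancy of this parameterization.

# Synthetic sessions and studies

`session_spec()` / `generate_trials()` / `simulate_session()` generate
the full task: conditional-difficulty stimulus sampling as above, 2%
equal-orientation trials (rewarded on a random side), iid contrasts,
closed-loop choices from any observer or descriptive ground truth,
rewards by environment, and history columns. The training protocol's
repeated-incorrect trials can be emulated (`repeat_incorrect = TRUE`);
repeats are marked `excluded` and ignored by all likelihoods. What the
generator does *not* emulate: reaction times, wheel kinematics, licking,
pupil dynamics, session-level drifts, or any within-session
non-stationarity of the subject — so passing recovery tests demonstrate
estimator correctness under the model, not robustness to real-data
artifacts.

Two packaged studies drive the headline numbers:

* `recovery_study()` simulates datasets from the observer with known
  per-covariate-level sensory-precision and late-precision factors
  (multiplying $k_{\max}$ and the late precision $1/\sigma^2$), refits
  them by multi-start MLE with all other parameters held at the base
  values, and reports the pooled $R^2$ about the identity line. The two
  factors are strongly correlated in the likelihood (≈0.9), and the
  late factor's likelihood flattens toward high precision, which
  dictates the study design: the base operating point ($k_{\max} = 10$,
  $\sigma_{\text{late}} = 28$) minimizes the *worst-case* joint
  (profile) uncertainty over the factor range $[0.5, 2]$, and each
  dataset holds 150,000 trials — the count at which the design's
  expected estimation error is small relative to the spread of the true
  factors, so the summary measures estimator fidelity rather than
  sampling noise. A cell-aggregation likelihood keeps the fit cost
  independent of the trial count. Defaults: 20 datasets, seeds derived
  from one master seed.
* `swap_study()` as described above (16 optimizer starts per
  environment).

`run_pipeline()` chains optimize → simulate → fit → learn → MDS from a
single YAML/list configuration with one master seed fanned out to every
stage, writing CSV/JSON artifacts and a manifest.

# Psychometric geometry

`build_dissimilarity()` produces the pairwise discriminability matrix on
a 10° grid — $P(\text{correct}) - 0.5$ per pair, zero on the diagonal and
for equal-verticality pairs — either from a model's error probabilities
(averaged over the contrast-pair product) or from pooled trials.
`mds_embedding()` applies classical (metric) multidimensional scaling
via the double-centered eigendecomposition, with a deterministic sign
convention per axis and a normalized stress diagnostic;
`band_distance()` summarizes how far apart the embedded nodes of an
orientation band sit. Vertical-heavy allocations expand the embedded
geometry of near-vertical orientations relative to horizontal-heavy
allocations, the geometric signature of reward-adapted perception.

# Numerical choices and limitations

* All circular computation uses the doubled angle in radians; interfaces
  use degrees on $[0, 180)$. Off-grid inputs are snapped to the nearest
  grid point.
* The 2° grid balances accuracy and cost; measurement distributions,
  decode tables and moments are built once per (gain, contrast) and
  reused across trials.
* Probabilities are clipped to $[10^{-9}, 1 - 10^{-9}]$ inside
  likelihoods.
* Multi-start counts default to desk-scale values (50 for the gain
  optimizer, 100 for descriptive fits, fewer for the expensive network
  and endogenous variants); all are configurable upward.
* Test-suite problem sizes: Monte-Carlo oracles use $10^5$–$10^6$ draws;
  recovery and swap studies run at the sizes stated above; learning runs
  use 700–1500 trials.
* The degree of reward loss under swapped allocations and the
  quantitative convergence of the learning rule to the static optimum
  both depend on regime, as discussed in their sections; the package
  reports what its own calibrated conditions produce.
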