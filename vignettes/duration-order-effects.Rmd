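---
title: "Models, designs and estimators for stimulus-order effects in duration discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, designs and estimators for stimulus-order effects in duration discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(typeBsim)
```

This vignette is the package's account of its science: the generative
observer models, the measurement designs, the estimation chain, the
statistical battery, and the simulation studies built from them — together
with the numerical and design decisions that were genuinely open, and what a
green test suite does and does not establish.

## Observer models

All three models share a Thurstonian front end: the perceived duration of a
physical duration $d$ is a normal draw $X \sim N(d, \sigma(d))$ with

$$\sigma(d) = \sigma_0 + w\,d,$$

a constant floor plus Weber-law scaling (`noise_spec(sigma0, weber)`). The
literature this package engages with leaves the distribution of $X$ open; we
adopt the normal as the standard signal-detection assumption, and the Weber
term keeps Weber fractions comparable across the 80 ms and 500 ms regimes.
Sensations are deliberately **not truncated at 0 ms**: negative draws are
legitimate latent magnitudes, and truncating them would silently distort
short-duration simulations. The only hard floor in the package is the
physical one on staircase stimulus values.

Decisions use the comparison rule "first interval longer iff $D > \gamma$",
with ties ($D = \gamma$) judged in favor of the second interval — the exact
asymmetry of the rule's parenthetical form, which matters for zero-noise
edge cases and is pinned by tests.

* **Difference model** — $D = X_1 - X_2$. The two stimulus orders'
  psychometric functions differ in location by $2\gamma$ and share their
  shape, so the model predicts no Type B effect. Its closed-form
  psychometric function, $P_{\langle sc\rangle}(c) =
  \Phi\!\big((c - s + \gamma)/\sqrt{\sigma(s)^2 + \sigma(c)^2}\big)$ (and
  $-\gamma$ for $\langle cs\rangle$), is verified against Monte-Carlo
  simulation in the test suite before anything else relies on it.
* **Internal reference model (IRM)** — $D_n = I_n - X_{2,n}$ with
  $I_n = g I_{n-1} + (1-g) X_{1,n}$, $g \in [0,1)$. Two initialization
  policies are supported because the literature is silent:
  `first_sensation` (default; trial 1 carries no history, $I_1 = X_{1,1}$)
  and `standard_mean` ($I_0$ set to the standard). With $g = 0$ the model is
  response-identical to the difference model on shared random streams — a
  tested invariant.
* **Sensation weighting model (SWM)** — each sensation is weighted against
  its own reference level, $D = [s_1 X_1 + (1-s_1)R_1] - [s_2 X_2 +
  (1-s_2)R_2]$. $R_1, R_2$ are fixed constants per condition and default to
  the standard duration; their dynamics are not specified by the theory as
  used here, and making them static keeps the model's Type B sign purely a
  function of $\mathrm{sign}(s_1 - s_2)$.

The updating weight $g$ may plausibly depend on the inter-stimulus interval
(shorter ISI, less time to integrate), but no ISI→g law is hard-coded:
ISI and stimulus type (filled/empty) are pure labels in the simulator, and a
scenario that wants ISI-dependent updating sets $g$ per cohort explicitly.
A criterion difference between orders or regimes is likewise not assumed;
$\gamma$ defaults to 0 everywhere.

## Designs

`constant_stimuli_design()` expands into the session used throughout: nine
comparison levels symmetric around the standard (20–140 ms in steps of 15,
or 300–700 ms in steps of 50), crossed with both stimulus orders, each of
the 18 trial types twice per block in a freshly shuffled order, 20 blocks —
720 trials per regime, 40 per cell. Stimulus order varies randomly from
trial to trial, which matters for the IRM: the reference is carried across
trials and blocks within a regime and reset between regimes (the regimes are
separate experimental parts). Part order (short-first vs long-first) is
counterbalanced across observers in cohort simulation; for stateless
observers it is inert and it is not analyzed.

One deliberate deviation is recorded here: the source study's own session
splits its 20 blocks across the two regimes (10 + 10, i.e. 360 trials per
regime). The package's preset follows its build contract of 20 blocks *per
regime* (720 trials/regime, 40 per cell); the paper-literal session is
available as `n_blocks = 10`.

The **weighted up-down staircase** (`staircase_config()`, `run_staircase()`)
targets $c_{.25}$ or $c_{.75}$: after a "comparison longer" response $c$
decreases by `step_down`, otherwise it increases by `step_up`, and zero
drift at target probability $p$ forces `step_up/step_down` $= p/(1-p)$ —
the 3:1 ratio at $p = .75$. Step magnitudes, start values and run lengths
are free parameters (defaults: smaller step 5 ms in the short regime, runs
of 60 trials starting 4 small-steps away from the standard), because the
studies that motivated the staircase engine do not print theirs. The
bias-prone dialect options are all explicit switches: hard floor at 0 ms
(the physical limit), blocked upper/lower runs sharing one evolving IRM
reference, prohibition of the comparison crossing the standard (clamped
`cross_margin` = 1 ms short of it), and threshold estimation from the mean
comparison of the last 20 trials (or from reversal values). A degenerate
run — e.g. a lower run pinned at the floor — yields an inflated or even
negative DL estimate; that is the measurement artifact under study, not an
error.

## Estimation

Response proportions per (order, comparison) cell are first monotonized by
**weighted pool-adjacent-violators** with trial counts as weights — the
least-squares isotonic fit, verified in tests against brute-force
enumeration of all monotone block fits. The **Spearman–Kärber** estimator
then anchors the monotone proportions with $p = 0$ and $p = 1$ at
comparisons where responding is assumed certain (0/160 ms for the short
regime, 200/800 ms for the long one) and reads the result as a distribution
function, spreading each probability increment uniformly over its
comparison interval:

$$\widehat{\mathrm{PSE}} = \sum_k \Delta p_k \frac{c_k + c_{k+1}}{2},
\qquad
\widehat{m_2} = \sum_k \Delta p_k \frac{c_k^2 + c_k c_{k+1} + c_{k+1}^2}{3},$$

$\hat\sigma = \sqrt{\widehat{m_2} - \widehat{\mathrm{PSE}}^2}$,
$\widehat{\mathrm{DL}} = z_{.75}\,\hat\sigma$ and
$\mathrm{WF} = \mathrm{DL}/s$. The uniform-segment second-moment rule is the
exact second moment of the implied piecewise-uniform density (validated in
tests against closed-form cases: a step function gives the uniform moments
of its jump interval, linear proportions give the uniform distribution over
the anchor range). $z_{.75}$ is used at full precision internally; 0.6745 is
display rounding. Two numerical properties deserve note:

* The piecewise-uniform construction **inflates the SD** by roughly
  $h^2$-order discretization error. With the short grid (step 15 ms) the
  inflation is material for generating SDs near the grid step (~8% at
  $\sigma = 15$ ms) and small for shallower functions (~3% at
  $\sigma = 25$ ms); the estimator-consistency tests therefore use
  $\sigma = 25$ against the stated 5% tolerance.
* Estimates whose monotonized response range stays below a configurable
  threshold, or whose SD is exactly 0, are flagged `flat`; the quartile-based
  `dl_from_quartiles()` flags quartiles that the function never brackets.
  Flatness is a per-estimate flag here and a cohort-level exclusion rule in
  `simulate_cohort()`.

The Type B effect is always $\mathrm{DL}_{\langle sc\rangle} -
\mathrm{DL}_{\langle cs\rangle}$ (negative = better sensitivity with the
standard first), and analogously for Weber fractions.

## Statistical battery

The ANOVA layer is implemented from scratch as balanced sums-of-squares
decompositions — a two-way fully-within ANOVA (comparison × order on
response proportions, where the Type B effect appears as the interaction), a
one-way repeated-measures ANOVA on DLs (whose two-level $F$ equals the
squared paired $t$, a tested identity), and a three-way split-plot ANOVA on
WF-based Type B effects (duration within; ISI and stimulus type between),
with partial $\eta^2 = SS_\mathrm{effect}/(SS_\mathrm{effect} +
SS_\mathrm{error})$ per effect. Every implementation is checked exactly
(tolerance 1e-10) against `stats::aov()` error-strata oracles on small
datasets, keeping the implementation and its oracle on separate routes.
Proportions enter untransformed (no arcsine), matching the analysis being
emulated.

Sphericity handling follows the "Mauchly-gated" convention: per within
effect with at least three levels, orthonormal-contrast scores give
Greenhouse–Geisser $\hat\varepsilon = \mathrm{tr}(S)^2/(d\,\mathrm{tr}(S^2))
\in (1/d, 1]$ and Mauchly's $W$ with its $\chi^2$ approximation; the GG
correction is applied only when Mauchly's test is significant at $\alpha =
.05$ (an always-correct and never-correct mode are available). Two-level
factors have $\varepsilon = 1$ exactly. When too few subjects make the
contrast covariance singular, the Mauchly p is `NA` and no correction is
applied.

`power_rm()` follows the G*Power "repeated measures, within factors"
convention: $f = \sqrt{\eta_p^2/(1-\eta_p^2)}$, noncentrality $\lambda = f^2
n m/(1-\rho)$ with $m$ measurements and assumed repeated-measures
correlation $\rho$ (default 0.5), power from the noncentral $F$. The program
behind the convention is named but not its settings; $\rho$ is exposed so
the sensitivity of any power claim to it can be examined directly.

## Synthetic cohorts and the two simulation studies

`simulate_cohort()` composes everything: per observer, parameters drawn from
truncated normal distributions (defaults: $\gamma \sim N(0,5)$ ms,
$\sigma_0 = 2$ ms, $w \sim N(0.15, 0.05)$ bounded away from 0 — Weber
fractions around 0.15–0.2, typical for visual duration discrimination;
$g \sim N(0.4, 0.1)$ for IRM cohorts; $s_1 = 0.7 < s_2 = 1.0$ for SWM
cohorts), both regimes simulated with counterbalanced part order, estimates
per order, and the cohort ANOVA battery. Observers flat in *every*
condition (monotonized response range below 0.25 everywhere) are excluded
and replaced by fresh draws, with the replacement count logged — mirroring
exclusion-and-replacement recruitment.

The **model-sign study** (acceptance suite) checks the theory-level
contracts on 200-observer cohorts: IRM Type B effects are null at $g = 0$,
strictly negative and monotonically more negative in $g$; SWM Type B signs
follow $\mathrm{sign}(s_1 - s_2)$; difference-model cohorts are null.

The **bias study** (`bias_study()`) applies two measurement procedures to
the same generative IRM observers ($g = .5$, $s = 50$ ms): the bias-prone
staircase dialect versus a 720-trial constant-stimuli session with
Spearman–Kärber. The stated mechanism of the bias is that with an extremely
short standard the *lower runs approach the physical floor of 0 ms* without
reaching $c_{.25}$, so the floor (and the crossing prohibition) truncates
the order with the shallower function more, pushing the estimated
$\mathrm{DL}_{\langle sc\rangle} - \mathrm{DL}_{\langle cs\rangle}$ upward.
The study's default noise, $\sigma(d) = 5 + 0.6d$ (so $\sigma(50) = 35$ ms),
was chosen — before freezing any acceptance assertion — precisely so that
this stated condition manifests (lower runs do reach the floor); it puts
discrimination near threshold at 50 ms, which is the regime the staircase
critique is about. With substantially milder noise the floor never binds
and the staircase's positive bias shrinks toward a null difference; the
positive *gap* between the staircase estimate and the constant-stimuli
estimate (~7–10 ms) is present either way. At a long standard with no floor
interaction the staircase mean is approximately null rather than negative:
blocked runs let the IRM reference track the within-block stimulus history,
which largely symmetrizes the two orders — so the honest control property
is "the positive bias disappears without floor interaction", not "the
staircase recovers the negative effect".

**Parameter recovery** (`recover_g()`) exploits the fact that the IRM
reference is a linear Gaussian recursion: its per-trial marginal mean and
variance follow the same recursion, so each trial's marginal response
probability is a closed-form normal integral. These are combined as a
composite likelihood (the across-trial dependence induced by the shared
reference path is ignored for estimation — the standard composite-likelihood
trade of efficiency for tractability) and maximized over explicit grids in
$(g, \gamma, \sigma_0, w)$; the grid resolution bounds the precision. Tests
verify recovery of $g$ to within one grid step at ten pseudo-sessions
(7,200 trials) and boundary recovery at $g = 0$.

## What the generator does and does not emulate

The synthetic world reproduces the designs' trial arithmetic, randomization
and counterbalancing, the estimator chain, and the models' order-effect
signatures. It does **not** emulate: lapses, attention or learning dynamics
(trial-wise feedback is treated as motivational, not modeled), reaction
times, hardware timing, brightness/filled-duration confounds, ISI- or
stimulus-type-specific mechanisms (labels only), or the empirical effect
sizes of any particular human dataset. A green suite therefore establishes
that the estimators and tests behave as specified on their stated generative
world — not that the world matches human observers quantitatively.

## Known limitations

* The composite likelihood in `recover_g()` is not the full sequential
  likelihood; its standard errors (not reported) would be optimistic.
* Spearman–Kärber SDs carry the discretization inflation described above;
  comparisons should stay within one grid geometry.
* The staircase bias study is a directional replication: the original
  exploratory simulations' parameters are unpublished, so magnitudes are
  world-specific even though the sign pattern is robust across seeds.
* ANOVA routines require complete balanced designs by construction and
  reject anything else rather than approximating.
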