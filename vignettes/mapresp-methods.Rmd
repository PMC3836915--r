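---
title: "Measuring health with the multi-attribute preference response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health with the multi-attribute preference response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapresp)
```

## The measurement problem

A preference-based health-state instrument describes health as an
ordered multi-attribute profile — five attributes with three severity
levels each in the EQ-5D-like system bundled with this package — and
needs a single interval-level value per state for use in QALY/DALY
arithmetic, Markov models and economic evaluation. Three measurement
principles drive the design of the model implemented here:
*unidimensionality* (states live on one latent continuum from worst to
best), *interval level* (differences in value must be meaningful), and
*invariance* (state values must not depend on which respondents judged
them, and person measures must not depend on which states they saw).

Two traditions meet these requirements halfway. Probabilistic discrete
choice models (Thurstone's law of comparative judgment, the
Bradley–Terry–Luce family, McFadden's conditional logit) value states
from comparative judgments and can decompose values into attribute
effects, but are usually fed by general-population respondents judging
hypothetical pairs. The Rasch model achieves sample-invariant item
measurement through conditional estimation, but has no value function
over attributes. The multi-attribute preference response (MAPR) model
joins them: the response kernel is Rasch,

$$P(y = 1) = \frac{e^{\,v_s - \theta_r}}{1 + e^{\,v_s - \theta_r}},$$

and the state parameters carry the conditional-logit valuation
restriction $v_s = z_s'\gamma$, where $z_s$ is the dummy coding of the
presented state and $\gamma$ the attribute-level coefficients. The
respondent judges presented states against *their own* health state
("Is this health state better than your own health state?"), which
anchors the task in lived experience and largely removes the need to
imagine unfamiliar states.

### Response orientation

Throughout the package, response 1 means *the presented state is judged
better than the respondent's own state*, so $P(1)$ increases with the
presented state's value $v_s$ and decreases with the respondent's
location $\theta_r$. This orientation is a declared convention of the
package (the sorting of respondents "who agree that all health states
are preferred over their own state" to the top of the scalogram follows
from it); flipping it merely negates both parameter sets.

## Coding, identification and parameters

* **Dummy coding.** Each attribute's best level is the reference; every
  worse level contributes one 0/1 design entry. The best state
  (`"11111"`) therefore encodes to the zero vector and has value 0 —
  this is the identification anchor of the value scale. Coefficients
  have no sign constraint, but worse levels are expected to be
  negative. The value function is additive main-effects only;
  interaction terms are deliberately out of scope.
* **Person locations.** Two modes. In *free* mode each respondent gets
  a free $\theta_r$ (classical joint-ML Rasch treatment); respondents
  answering all 0 or all 1 have non-finite locations and are excluded
  with a warning. In *structured* mode $\theta_r = z_{own}'\gamma$,
  tying the location to the first-stage self-classification of the
  two-stage response mechanism; the model then collapses to a logistic
  regression on $z_s - z_{own}$ and every respondent is retained.
  *Free* is the default: it makes no assumption that the respondent's
  location coincides with the value of their classified state.
* **Scale conventions.** Translation invariance means only differences
  are estimable; fits pin the reference state at 0 (`constraint =
  "ref"`) or centre the estimates (`"sumzero"`). Thurstone's Case V is
  evaluated with unit *comparative* dispersion, $P = \Phi(v_s - v_t)$;
  the unit-per-stimulus convention $\Phi((v_s - v_t)/\sqrt2)$ is
  available via `unit_dispersions = TRUE`, since the choice of unit is
  arbitrary under Case V and sources differ on which is meant.
* **Dead anchoring.** `anchor_to_dead()` applies the affine map
  $v' = (v - v_{dead})/(v_{best} - v_{dead})$ so dead = 0 and best
  health = 1, the scale QALY/DALY computation requires. The dead
  parameter itself is estimated inside the model by mixing the state
  *dead* into choice sets as a pseudo-state with one free parameter
  (a `dead` design column); it is only well identified when designs
  place dead against bad states, and the package makes no claim about
  the empirical validity of the resulting anchor — it implements the
  mechanism.

## Estimation

* **Rasch CML** (`fit_rasch_cml`). The conditional likelihood given
  person raw scores eliminates $\theta$ algebraically — the
  separability property behind the invariance principle. Elementary
  symmetric functions are evaluated with the standard summation
  recursion (state values are re-centred before exponentiation, which
  leaves the conditional likelihood unchanged and keeps the recursion
  in a safe numeric range for the 20-state problems used here);
  scoring is exact Newton with the observed conditional information,
  with step halving. Persons with extreme scores are uninformative and
  dropped; a state with all-identical responses is reported
  non-estimable rather than given a divergent estimate. Standard
  errors come from the inverse observed information on the constrained
  parameterization, and the full covariance is stored so that centred
  contrasts (used by `invariance_check`) get delta-method variances.
* **Rasch JML** (`fit_rasch_jml`). Alternating per-item and per-person
  Newton updates with joint re-anchoring ($v$ and $\theta$ shifted
  together so the reference stays at 0 without changing the
  likelihood). JML's finite-sample bias is acknowledged and not
  corrected; the suite checks that JML and CML state estimates
  correlate above 0.99 on well-conditioned data.
* **Pairwise conditional logit** (`fit_clogit_pairs`). Bradley–Terry
  form: $P(s \succ t) = \mathrm{logistic}(v_s - v_t)$, fitted by
  Newton on aggregated pair counts. The comparison graph must be
  connected (checked, with components reported); states that win or
  lose every comparison are at the likelihood boundary and are
  flagged with non-finite estimates rather than nudged with
  continuity corrections — separation is surfaced, not hidden.
* **MAPR** (`fit_mapr`). Structured mode is a logistic Newton fit on
  the design differences, with a rank check that names collinear
  columns. Free mode maximizes the joint likelihood in $(\gamma,
  \theta)$ with a full Newton step computed through the Schur
  complement of the (diagonal) person block, so each iteration costs
  one $p \times p$ solve regardless of the number of respondents;
  step halving guards the ascent. Convergence for all fits is a
  gradient max-norm below $10^{-8}$ (500-iteration cap, reported as
  non-converged otherwise). With a saturated design matrix (one dummy
  per non-reference state) the free-mode fit reproduces the Rasch JML
  state estimates exactly — the degenerate case in which the linear
  restriction restricts nothing.
* **Gradients.** `loglik_and_gradient()` exposes the analytic
  log-likelihood gradient of all three fitted models at arbitrary
  parameter points; the suite verifies agreement with central finite
  differences to $10^{-6}$ relative error.

## Designs

`full_pairwise_design()` enumerates all unordered pairs (the classical
paired-comparison layout). `pivot_design()` builds the
respondent-centred tasks of the two-stage mechanism: alternatives whose
levels deviate from the respondent's own levels by at most `radius` per
attribute. The default is radius-1, single-attribute deviations — the
closest operational reading of "states that deviate slightly from their
own levels"; multi-attribute neighborhoods and larger radii are
config-gated rather than default. `adaptive_next_state()` picks the
candidate maximizing the binary Fisher information $p(1-p)$ at the
current location estimate, equivalently minimizing $|v_s -
\hat\theta|$ (ties to the lowest candidate index); the information
criterion is the package's choice of "most informative item", since
only the maximal-information principle itself is given.
`partial_profile_select()` draws a reproducible subset of candidate
domains, with omitted domains contributing value 0 — the elementary
assumption of partial-profile designs, which empirical work elsewhere
suggests does not always hold.

## The synthetic-data generator

No empirical MAPR dataset exists yet, so the simulator is the package's
data source, and its defaults encode the intended study conditions:

* Respondent locations are drawn from a declared distribution and must
  span the continuum — a sample clustered at one location (e.g. all
  healthy) is explicitly poor for Rasch-type estimation. Normal and
  uniform families are provided without claiming either is the
  realistic patient mix; recovery studies in the tests and the
  acceptance script use a uniform draw over the full value range
  $[\min_s v_s, 0]$, the cleanest expression of "distributed over the
  whole scale".
* Own states are assigned as the enumerated state whose value is
  nearest the drawn $\theta_r$ (ties to the milder state), keeping the
  first-stage classification consistent with the latent location;
  `snap_theta = TRUE` additionally sets $\theta_r$ equal to that
  state's value, the exact structured-mode data-generating process.
* Responses are Bernoulli draws from the MAPR kernel, streamed through
  per-respondent substreams so reordering choice sets never changes a
  respondent's answers. RUM simulation draws $U = v + \varepsilon$
  with centred Gumbel(0,1) or standard normal errors and records the
  argmax; the suite confirms convergence to the conditional-logit and
  probit kernels respectively within binomial sampling error.
  `simulate_guttman_deterministic()` produces the error-free limit
  ($y = 1$ iff $v_s > \theta_r$), a perfect scalogram by construction.

What the generator does *not* emulate: response shortcuts, irrational
choice, interpretation problems of domain wording, adaptation dynamics,
panel structure, or item-level missingness mechanisms. Passing recovery
tests therefore demonstrate correctness of the estimation machinery
under the model, not robustness of the MAPR approach to real patient
behaviour — the latter is an empirical question the model itself leaves
open.

## Diagnostics

`guttman_sort()` reproduces the scalogram analysis: rows sorted by
agreement count (descending), columns likewise, ties broken by label so
sorting is deterministic and idempotent. Misfits are counted
Goodman-style as cells deviating from the ideal step vector implied by
each row's total after sorting; the graphical cross-marks of scalogram
displays correspond to these cells. Note that a single flipped response
can yield 0, 1 or 2 misfits under this definition (some flips produce
another perfect scalogram); the tests pin the behaviour to an
independent loop-based oracle over all single flips.
`invariance_check()` recentres two fits over their shared states and
reports mean/max absolute differences and per-state z-scores from the
combined delta-method standard errors of the centred estimates.

## Problem sizes and numerical choices

The recovery studies are sized to the package's own simulation design:
Rasch CML at $J = 20$ states on $[-3, 3]$ with $N = 1000$ (recentred
Pearson $r \ge 0.98$, RMSE $\le 0.15$), invariance with two shifted
subsamples of $N = 1500$, MAPR pivot recovery at $N = 2000$ (RMSE
$\le 0.1$, decreasing from $N = 200$), and Monte-Carlo kernel checks at
$10^6$ draws judged at three binomial standard errors. Elementary
symmetric functions are computed in the plain (non-log) domain after
recentring, which is exact and stable for these magnitudes; the
log-sum-exp shift protects the softmax and logistic forms everywhere
else. Degenerate inputs — empty matrices, all-identical responses,
zero pivot radius, coincident anchors, disconnected comparison graphs
— error or warn early with messages naming the offending state,
attribute or component.

## Known limitations

* Marginal ML with an assumed $\theta$ distribution, Bayesian
  estimation, discrimination (2PL) parameters and taste-heterogeneity
  extensions are out of scope, as is any MNL-style use of respondent
  covariates — the invariance requirement is precisely what rules the
  latter out.
* JML standard errors use the profile (per-item) information and JML
  point estimates carry the usual bias; CML is the reference method.
* The dead parameter is only as good as the designs that identify it,
  and the anchoring transform makes no bias claim.
* Partial-profile estimation assumes omitted domains are truly "no
  value"; the package implements the assumption, not a test of it.
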