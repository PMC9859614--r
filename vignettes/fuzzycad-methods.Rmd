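---
title: "Grading coronary-artery lesions with a fuzzy rule base: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading coronary-artery lesions with a fuzzy rule base: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzycad)
```

## The clinical model

`fuzzycad` implements a Mamdani-style fuzzy expert system that grades the
anatomical lesion of the coronary arteries and assigns a patient to one of
four clinical forms of coronary artery disease (CAD):

* **I — NSTEMI**, myocardial infarction without ST-segment elevation,
* **II — UAP**, unstable angina pectoris,
* **III — STEMI**, myocardial infarction with ST-segment elevation,
* **IV — StAP**, stable angina pectoris.

The inputs are four angiographic severity scores (unitless points), each
restricted to the empirical range observed in the underlying cohort:

| factor | meaning | domain |
|--------|---------|--------|
| `X1` | atherosclerotic plaques in the basin of the diagonal branch (DG) or left anterior descending artery (LAD) | [1.83, 2.76] |
| `X2` | hemodynamically significant stenosis (HSS, >50 %) in the DG/LAD basin | [1.74, 3.00] |
| `X3` | HSS in the trunk of the right coronary artery | [1.00, 2.35] |
| `X4` | absence of HSS of the coronary arteries (a protective score) | [2.07, 4.67] |

Each factor is a linguistic variable with five terms — L (low), LA (lower
than average), A (average), HA (higher than average), H (high) — formalised
by piecewise-linear membership functions $\tilde\mu^j(x_i) \in [0,1]$
(twenty functions in total). A knowledge base of fourteen weighted if–then
rules maps complete term combinations to the four classes (3 rules for
class I, 4 for II, 3 for III, 4 for IV). Inference follows the classical
four steps: fix the patient's factor values; fuzzify (evaluate all twenty
term memberships); compose per-class memberships
$$\mu_{d_c}(x_1,\dots,x_4) \;=\; \bigvee_{r \in R_c} w_r \cdot
  \bigwedge_{i=1}^{4} \mu^{A_{r,i}}(x_i),$$
with conjunction/disjunction realised as `min`/`max` by default (a
`product` t-norm and probabilistic-sum s-norm are available as an explicit
alternative, never silently mixed); and decide by the maximum membership,
$d_0 = \arg\max_c \mu_{d_c}$. All rule weights are 1 unless tuned.

The package also provides the shared universe $U=[0,4]$ mapping
$u = 4(x-\underline{x})/(\bar{x}-\underline{x})$ (`normalize_to_u()`) and a
centre-of-gravity defuzzifier (`defuzzify_cog()`), the standard utilities of
this family of systems.

## Fidelity choices for the printed membership functions

The twenty membership functions are shipped exactly as printed, which forces
three policy decisions:

* **Breakpoints are half-open.** Pieces are defined on `[a; b)` intervals
  with the final piece closed, so at an interior breakpoint the right-hand
  segment wins. This follows the printed interval notation directly and
  makes evaluation single-valued everywhere, including breakpoints.
* **Degrees are clamped, not rejected.** Because the printed coefficients are
  rounded, a raw linear value can fall slightly outside $[0,1]$ (e.g.
  $0.71 \cdot 1.83 - 1.31 = -0.0107$); values are clamped to $[0,1]$ after
  evaluation.
* **Continuity is a diagnostic, not an invariant.** The rounded coefficients
  also make adjacent pieces of one term disagree at their shared breakpoint:
  the A term of `X2` rises to $0.897$ at $x=2.3$ while the falling piece
  gives $1.103$ (clamped to 1), a post-clamp jump of $0.103$. We deliberately
  do not smooth or re-fit the published functions;
  `check_variable_consistency()` reports every post-clamp jump (flagging
  those above `jump_tol = 0.05` by default), each term's peak, and the
  variable's *coverage* — the minimum over a dense grid of the maximum
  degree across the five terms. For the default knowledge base every term
  peaks above 0.98 and every factor's coverage exceeds 0.74.

Out-of-domain inputs error by default (`out_of_range = "error"`): the
domains are empirical minima/maxima and silent extrapolation would be
unsafe in a screening context. A `clamp_to_domain` policy is available for
exploratory use.

Ties at the decision step are resolved towards the lowest class index and
flagged (`tie = TRUE`); `tie_break = "report_all"` lists every argmax class.
When no rule fires at all (all four memberships zero) the result defaults to
class I with a warning so that batch runs complete; `on_no_rule = "error"`
turns this into a hard error. Memberships are carried at full floating
precision; any rounding happens only at output formatting, after the argmax.

## The closed-form oracle

`closed_form_class_membership()` hand-codes each class's union of
conjunctions literally instead of iterating over the rule table. It exists
purely as an independent oracle: the test suite and the acceptance script
verify that the generic engine and the closed form agree to machine
precision on thousands of random in-domain patients under both combiner
configurations. The first two conjunctions of the printed class III
*equation* are identical (an apparent typo); the rule *table* is adopted as
canonical, under which class III has exactly three distinct antecedents,
all requiring `X3 = HA`.

## Least-squares tuning

Training data $\langle \hat{x}_l, \hat{y}_l \rangle$ are fitted by
minimising
$$J(\theta) = \sum_{l=1}^{M} \sum_{c} \bigl(\mu_{d_c}(\hat{x}_l;\theta) -
  \hat{y}_{l,c}\bigr)^2,$$
where class labels are converted to one-hot membership targets and
$\theta$ is any subset of: the bell parameters $b$ (peak coordinate) and
$c$ (compression/extension, the half-width at degree 0.5) of every term,
and the rule weights $w \in [0,1]$. Because the tunable form is the bell
function $1/(1+((x-b)/c)^2)$ while the default knowledge base is piecewise
linear, the bridge is explicit: `as_bell_kb()` sets $b$ to the grid argmax
of each printed term (midpoint of a plateau) and $c$ to half the
half-height width, and attaches the conversion table as an attribute.

Further design decisions, each of which the implementation documents and
the tests exercise:

* **Flattening.** One $(b, c)$ pair per factor–term and one $w$ per rule.
  Factor–term pairs that no rule references (`X1`/H, `X2`/H, `X3`/H,
  `X4`/L in the default base) cannot influence the model output; their
  parameters are excluded from the flat vector because they are structurally
  unidentifiable.
* **Optimisation.** The published account cites recurrent update relations
  without stating them, so we minimise the stated objective with standard
  bounded numerical optimisers: Nelder–Mead (derivative-free, the default),
  L-BFGS-B, or `random_restart` — L-BFGS-B from the supplied start plus
  jittered restarts, keeping the best parameters ever evaluated. The
  min/max composition makes $J$ piecewise smooth; restarts are the cheap
  insurance against its kinks.
* **Bounds.** $b$ stays inside its factor domain, $c \in
  [10^{-3}, 2\,(\bar{x}-\underline{x})]$, $w \in [0,1]$. Proposals outside
  the box are folded back by reflection rather than clamped, so a start on
  a bound (e.g. all weights at 1) does not collapse the Nelder–Mead initial
  simplex.
* **Monotone reporting.** The reported trajectory contains the objective at
  the start and at every accepted (improving) evaluation, and the returned
  parameters are the best ever evaluated — so the trajectory is
  non-increasing and the final objective never exceeds the initial one, for
  every optimiser and seed. `max_iter = 0` is an exact no-op. All
  randomness derives from `config$seed`.

The canonical recovery experiment (run by the acceptance script and the
test suite) generates 200 in-domain patients uniformly, computes their
class memberships under a bell-form knowledge base with known parameters,
perturbs every identifiable $b$ by ±10 %, and re-tunes `b` with
`random_restart` (5 starts, 500 iterations each). Across all seeds tried
this recovers every identifiable peak to well within 5 % (typically
$<0.01\,\%$) with a final objective below $10^{-6}$, and the tuned model
matches the generator within $10^{-3}$ on held-out patients.

## The synthetic cohort generator

No patient-level data are deposited, so the generator emulates the study's
group statistics: 165 patients in four groups (90 NSTEMI, 25 UAP, 25 STEMI,
25 StAP), each group characterised per factor by a mean ± standard error
and truncated to the factor domains. Choices a user should know:

* **The "±" is read as the standard error of the mean** (the convention of
  group tables compared by ANOVA/t-tests), so the per-record standard
  deviation is $se\sqrt{n}$. The UAP group's `X3` entry "1.00 ± 0" is taken
  literally: a constant.
* **Family.** Truncated normal by inverse-CDF sampling (a `uniform`
  alternative with matched mean and spread is provided). The family is a
  modelling choice; only means, standard errors and ranges are published.
* **Moment matching.** With the truncation bounds this close to the means
  (often about one standard deviation wide), placing the normal's location
  at the published mean would bias the realised group means towards the
  domain centre by up to ~0.5 points. The generator therefore solves, per
  group and factor, for the location whose *truncated* mean equals the
  published mean, so empirical group means are unbiased for the published
  ones and converge to them as $n$ grows. `mean_match = FALSE` gives the
  literal un-matched model.
* **Labels are the generating group.** Agreement between the engine's
  decisions and these labels is reported (about 35–45 % on default draws)
  but never asserted: per-record noise with sd $se\sqrt{n}$ is large
  relative to the factor ranges, and nothing in the published material
  implies the rule base should recover group membership from such draws.
  The generator reproduces first- and second-moment structure; it does not
  emulate within-patient correlation between factors, comorbidity
  structure, or the expert panel behind the study's 95 % agreement figure
  (whose protocol is unavailable), so passing tests here say nothing about
  performance on real angiographic data.

`fixture_patients()` returns the four group-mean vectors as labelled
patients; they are the worked examples used throughout the documentation.

## Problem sizes and tolerances

The test suite and the acceptance script use: dense grids of $10^3$–$10^4$
points per factor for membership sanity; 1000 random patients (250 in the
unit tests) for engine/oracle equivalence at $10^{-12}$; 200 training
examples for the recovery experiment; 20 seeds for cohort mean stability,
with the tolerance of four standard errors per group mean. These sizes make
the whole suite run in about a minute on a single CPU while leaving every
check statistically comfortable.

## Known limitations

* The rule structure is fixed; only parameters are tuned. Learning rules
  from data is out of scope.
* Class memberships are possibility degrees, not calibrated probabilities;
  the margin field orders confidence but has no frequentist interpretation.
* The published 95 % agreement with clinical experts cannot be reproduced
  or audited without the original 165-patient dataset and panel protocol;
  this package substitutes property-based verification (oracle equivalence,
  transcription checks, recovery experiments, cohort statistics).
* The units of the four severity scores are not defined in the source
  material; they are treated as unitless reals on the printed ranges.
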