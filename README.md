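# fuzzycad

A fuzzy expert system for grading the anatomical lesion of the coronary
arteries. Given four angiographic severity scores, the system assigns a
patient to one of four clinical forms of coronary artery disease —
NSTEMI (I), unstable angina pectoris (II), STEMI (III) or stable angina
pectoris (IV) — by Mamdani-style fuzzy inference, and reports how strongly
the patient belongs to every class. It is aimed at clinical-decision-support
researchers and at anyone who needs a compact, fully testable reference
implementation of a published fuzzy medical knowledge base.

## The model

Four factors, each a linguistic variable on its empirical range:

* `X1` — atherosclerotic plaques in the basin of the DG or LAD (domain [1.83, 2.76]),
* `X2` — hemodynamically significant stenosis (HSS) in that basin ([1.74, 3.00]),
* `X3` — HSS of the right coronary artery trunk ([1.00, 2.35]),
* `X4` — absence of HSS of the coronary arteries ([2.07, 4.67]).

Each variable carries five terms — L, LA, A, HA, H (low … high) — formalised
by twenty piecewise-linear membership functions μ̃ʲ(xᵢ) ∈ [0, 1], shipped
exactly as published (rounded coefficients, half-open pieces, post-clamp
evaluation). A base of fourteen weighted rules maps term combinations to the
four classes; inference is

μ_c(x) = max over rules r of class c of [ w_r · min_i μ^{A_{r,i}}(x_i) ],
    decision d₀ = argmax_c μ_c(x),

with `min`/`max` the default operators (`product`/probabilistic sum
available). The package adds a hand-coded closed-form oracle for the class
equations, strict JSON/YAML knowledge-base serialization, least-squares
tuning of bell-form membership parameters (b, c) and rule weights w, a
seeded synthetic cohort generator reproducing the study's group statistics
(165 patients: 90/25/25/25), and CSV batch classification with a thin
command-line wrapper.

## Worked example

The per-group mean patient of the unstable-angina (UAP) group is
(x1, x2, x3, x4) = (2.15, 2.50, 1.00, 2.50):

```r
library(fuzzycad)
kb <- default_knowledge_base()
infer(c(x1 = 2.15, x2 = 2.50, x3 = 1.00, x4 = 2.50), kb)
#> Decision: class II (UAP), margin 0.2950
#> Memberships:
#>      I     II    III     IV
#> 0.3325 0.7000 0.0000 0.4050
```

The patient belongs to class II (UAP) with degree 0.70 — driven by the rule
(LA, HA, L, LA) whose weakest antecedent is μ_HA(X2) = 1.56·2.50 − 3.20 —
with class IV the runner-up at 0.405 and class III impossible (μ_HA(X3) = 0
at x3 = 1). Batch use:

```r
cohort <- generate_synthetic_cohort(cohort_spec(seed = 42))  # 165 labelled records
out <- infer_cohort(cohort, kb)
out$agreement   # fraction of decisions equal to the generating group
```

A command-line wrapper with `classify`, `validate-kb`, `simulate` and
`tune` subcommands is installed at
`system.file("scripts", "fuzzycad.R", package = "fuzzycad")`.

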