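---
title: "Assessing the greenness of MIP synthesis procedures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the greenness of MIP synthesis procedures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipgreen)
```

## The metric

Molecularly imprinted polymers (MIPs) are tailor-made sorbents: a template
molecule, functional monomer(s), a cross-linker, and a porogen are
polymerized together, and the template is then eluted to leave selective
binding cavities. Most classical recipes are far from green — toxic
monomers and solvents, energy-hungry thermal initiation, Soxhlet elution,
single-use sorbents. The AGREEMIP metric implemented here quantifies that:
twelve criteria, each mapped to a standardized score in $[0, 1]$ (1 =
greenest, 0 = worst), combined into a weighted average

$$\mathrm{overall} = \frac{\sum_{i=1}^{12} w_i s_i}{\sum_{i=1}^{12} w_i},
\qquad w_i \in \{1, 2, 3, 4\}.$$

The twelve criteria, their input type, and their default weights:

| # | Criterion | Input | Weight |
|---|-----------|-------|--------|
| 1 | Removal of polymerization inhibitors | categorical | 1 |
| 2 | Functional monomer | mass x hazards | 2 |
| 3 | Template | mass x hazards | 1 |
| 4 | Cross-linking agent | mass x hazards | 3 |
| 5 | Porogen/solvent | mass x hazards | 4 |
| 6 | Other reagents, adjuvants, carriers | mass x hazards | 3 |
| 7 | Core/particle preparation, surface modification | mass x hazards | 2 |
| 8 | Polymerization initiation | categorical | 3 |
| 9 | Size of polymer particles | categorical | 1 |
| 10 | Template elution solvent | hazards only | 4 |
| 11 | Template elution technique | categorical | 3 |
| 12 | Final product reusability | cycle count | 3 |

The heaviest default weights sit on the two solvent-dominated stages
(porogen and elution solvent); the lightest on the once-per-batch inhibitor
removal, the small-amount template, and particle size. Users may override
the weights (integers on the four-point scale only) and are expected to
justify the change; the justification is echoed into the report.

## Categorical criteria (1, 8, 9, 11, 12)

These use fixed published score sets, available programmatically from
`categorical_scores()`:

```{r}
categorical_scores("initiation")
categorical_scores("particle_size")
```

Reusability (criterion 12) is banded: 1 cycle scores 0, 2–9 cycles 0.5, 10
or more cycles 1. The published band descriptions overlap at exactly 10
cycles ("between 2 and 10" vs. "10 and more"); this implementation assigns
10 cycles to the greener band, following the explicit "10 and more
application cycles" wording. When a procedure's category is not listed
(e.g. a UV + sonication combination), choose the closest equivalent and
note it in the metadata.

## Mass–hazard criteria (2–7)

Each reagent contributes its mass in grams times the sum of the penalty
points of its GHS hazard statements. Mixtures aggregate additively:

$$x = \sum_j m_j \cdot p_j \quad [\mathrm{g \cdot pts}],$$

which is order-independent and reduces to the single-substance product —
the published description ("mass and hazards of each component considered
simultaneously") does not fix a formula, so the additive form is isolated
behind `burden()` and can be swapped. Amounts are accepted in g, mg, or mL;
volumes convert through an explicit density or the packaged table of
typical 20–25 °C solvent densities (`solvent_density()`).

The burden is transformed to a score by an exponential half-decay curve,

$$s(x) = 2^{-x/h},$$

rounded to two decimals. The published account fixes the curves' anchors
and shape (score 1 at $x = 0$, monotone nonincreasing, a sharp fall with
increasing mass or hazard, 0 in the limit, and two deliberately
*different* curves for the reagent-scale and solvent-scale criteria) but
not their printed algebraic forms, so the decay constants are this
package's own calibration:

* criteria 2–4 (`score_burden_c24()`): $h = 10$ g·pts. Template, monomer,
  and cross-linker amounts are typically well under ten grams, so a curve
  that halves every 10 g·pts spreads realistic inputs (tenths of a gram of
  a several-point monomer up to a few grams of a hazardous cross-linker)
  across the full 0–1 range.
* criteria 5–7 (`score_burden_c57()`): $h = 100$ g·pts. Porogens, washing
  solvents, and support-preparation baths run to tens of grams; the
  ten-fold gentler curve keeps discrimination in that regime (10 mL of
  acetonitrile lands mid-scale instead of collapsing to 0.00).

Both curves therefore satisfy every stated constraint while remaining
honest about their provenance; if the published constants become available
they can be dropped in without touching any other module. An absent stage
(e.g. no core or surface modification) has $x = 0$ and scores 1.00 — there
is nothing to penalize.

## Elution solvent (criterion 10)

Elution solvent *volumes* are rarely reported, so only hazards count. The
pooled H-codes of all elution solvents (set union — worst-case operator
exposure) are summed to $p$ points and transformed by the linear ramp

$$s(p) = \max\!\left(0,\; 1 - \frac{p}{40}\right),$$

clamped so that any $p > 39$ scores exactly 0 — reproducing the published
boundary (40 points → score 0). A hazard-free solvent such as water scores
1.00.

## Hazard penalty points

Penalty points per H-statement live in an editable registry
(`load_penalty_table()`). **The packaged default is a synthetic
stand-in**, graded by GHS severity class (fatal-toxicity and CMR
statements at 10 points down to mild irritants at 2); the originally
published point list was not available for transcription, and guessing it
silently would be worse than labelling the substitute. Every assessment
report carries the table's `source_label` so scores are never detached
from the convention that produced them. Supply your own table (CSV
`code,points` or a YAML mapping) via `load_penalty_table(path)`, the
`penalty_table:` field of a procedure file, or `--penalty-table` on the
command line. Comparisons between procedures are meaningful under any
single fixed table; absolute scores change with the convention.

Unknown codes are an error by default; `strict = FALSE` retries suffixed
codes by their 4-character stem (`H360FD` → `H360`) and otherwise counts 0
with a warning. Strictness is the default because silent zeros inflate
greenness.

## Rounding and numerical conventions

Every continuous criterion score is rounded to two decimals, half away
from zero, *before* aggregation (the categorical scores are already
exact); the same rounding convention is applied uniformly to criteria 2–7
and 10. The overall score is kept at full floating precision internally
and rounded only for display, avoiding double-rounding drift when ranking
procedures. Scores are validated to lie in $[0, 1]$ and to equal their own
two-decimal rounding.

One consequence worth knowing: because the particle-size scale (criterion
9) bottoms out at 0.2 rather than 0, the worst achievable overall score
under default weights is $0.2 \cdot 1 / 30 \approx 0.0067$, which displays
as 0.01 — a procedure can display 1.00 but never quite 0.00.

## Pictogram

`render_pictogram()` draws the result as a central circle (overall score,
two decimals) ringed by twelve criterion satellites — an outline
deliberately reminiscent of functional monomers surrounding a template.
Color encodes score through a piecewise-linear red–yellow–green gradient
(stops at 0, 0.5, 1; the exact RGB values are theme parameters, see
`pictogram_theme()`). Weight is encoded twice: satellite radius grows
affinely with weight and center distance shrinks, so important criteria
are big and close. Criterion 1 sits at twelve o'clock with ids increasing
clockwise — a documented convention, as is the whole geometry; only the
ordering ("bigger weight ⇒ bigger and closer") is contractual. SVG output
is deterministic, byte-stable text with exactly 13 circle elements; PNG
rasterizes the same geometry.

## Synthetic procedures and what the tests show

`generate_procedures(n, seed)` emits seeded, schema-valid random
procedures: reagent masses log-uniform over 0.01–100 g (trace additives up
to bulk solvent charges), hazard sets drawn from the penalty registry,
categorical fields uniform over their categories, 1–15 reuse cycles. The
generator reproduces the *statistical shape* of the metric's input space,
not chemically coherent recipes — no correlation between a reagent's role
and its hazards, no mass balance, no relation between porogen and elution
solvent. Property tests over these procedures (bounds, monotonicity,
determinism, aggregation identities — 10^4 random score/weight tuples plus
hundreds of end-to-end assessments; the suite runs in well under a minute)
therefore demonstrate the *metric's* internal consistency on realistic
input magnitudes, not the chemical plausibility of any generated recipe.

The bundled `example_*.yaml` fixtures are labelled approximate: they
follow the printed narratives of two published syntheses (an
electropolymerized film MIP and a toluene-heavy dual-template silica
surface MIP) but stand in plausible amounts and hazard sets where the
original inventories live in the source papers, and their penalty sums
depend on the synthetic default table — they illustrate the workflow and
the expected ranking (the electropolymerized film scores far greener), not
reproduced published scores.

## Limitations

* Absolute scores depend on the penalty-point convention; only the
  categorical criteria and the 40-point elution clamp are
  convention-free anchors.
* The burden decay constants are this package's calibration (above).
* H-codes, masses, and categories are taken as declared — nothing is
  inferred from free-text protocols or fetched from chemical databases
  (the CAS field is metadata only).
* No weight sensitivity analysis; weight 0 (disabling a criterion) is
  rejected, since weights live on the four-point scale.
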