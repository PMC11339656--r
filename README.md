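# mipgreen

Quantitative greenness assessment of molecularly imprinted polymer (MIP)
synthesis procedures, for chemists developing or reviewing imprinting
protocols who want a reproducible, auditable alternative to eyeballing
"green-ness".

MIP synthesis — template + functional monomer + cross-linker in a porogen,
polymerized, then exhaustively washed to elute the template — routinely
involves toxic reagents, large solvent volumes, energy-intensive initiation
and elution, and single-use sorbents. `mipgreen` implements the
twelve-criterion AGREEMIP metric: every criterion is standardized to a
score `s_i` in [0, 1] (1 = greenest), and the overall score is the weighted
average

```
overall = sum(w_i * s_i) / sum(w_i),   w_i in {1, 2, 3, 4}
```

Criteria 1, 8, 9, 11, 12 (inhibitor removal, initiation mode, particle
size, elution technique, reusability) are categorical lookups with
published score sets. Criteria 2–7 (monomer, template, cross-linker,
porogen, other reagents, core/surface modification) score the mass–hazard
burden `x = sum(mass_g * GHS penalty points)` through a decaying curve.
Criterion 10 scores the elution solvent's pooled hazard points `p` through
`max(0, 1 - p/40)` — more than 39 points scores exactly 0. The result is
reported per criterion, aggregated, and drawn as a traffic-light pictogram
(red–yellow–green central circle, twelve weight-sized satellites).

The packaged hazard-penalty table is a clearly labelled **synthetic**
severity-graded stand-in and is fully user-overridable; see the vignette
(`vignettes/greenness-assessment.Rmd`) for why, and for the calibration of
the burden curves.

## Worked example

A procedure is a declarative YAML/JSON file (run
`mipgreen init my_procedure.yaml`, or `procedure_template()`, for a fully
commented skeleton). Assessing the bundled electropolymerized-film example:

```r
library(mipgreen)
out <- assess(system.file("extdata", "example_electropolymerization.yaml",
                          package = "mipgreen"))
print(out$result)
#> Greenness assessment (12 criteria)
#>   c1   score 1.00  weight 1  not_needed_or_no_waste
#>   c2   score 0.64  weight 2  functional_monomer: x = 6.48 g*pts
#>   c3   score 0.47  weight 1  template: x = 10.85 g*pts
#>   c4   score 0.74  weight 3  cross_linker: x = 4.4 g*pts
#>   c5   score 0.65  weight 4  porogen: x = 62.88 g*pts
#>   c6   score 1.00  weight 3  other_reagent: x = 0 g*pts
#>   c7   score 1.00  weight 2  core_surface: x = 0 g*pts
#>   c8   score 0.90  weight 3  electropolymerization
#>   c9   score 1.00  weight 1  macro_extraction_device
#>   c10  score 0.03  weight 4  methanol; 39 penalty point(s)
#>   c11  score 0.50  weight 3  mixing_or_shaking
#>   c12  score 1.00  weight 3  10 cycle(s)
#>   overall (weighted average, default weights): 0.70
```

Reading the result: each line is one criterion's standardized score, its
weight, and the provenance of the score. This initiator-free
electropolymerized film does well on initiation (0.90), avoids waste in
most reagent stages (the absent stages score 1.00), but is dragged down by
methanol elution — 39 penalty points put criterion 10 at 0.03 under the
packaged penalty table, and that criterion carries weight 4. The overall
weighted average displays as 0.70. Swapping the elution solvent for water
is the single most effective improvement this report points to.

Then render the pictogram and a JSON audit report:

```r
render_pictogram(out$result, "procedure.svg")   # or .png
write_report(out$report, "procedure.json")
```

and compare candidate routes (`compare_procedures(...)` in R):

```sh
Rscript inst/cli/mipgreen.R assess my_procedure.yaml --pictogram out.svg -v
Rscript inst/cli/mipgreen.R compare routeA.yaml routeB.yaml --outdir comparison/
```

`generate_procedures(n, seed)` yields seeded random schema-valid
procedures for property testing.

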