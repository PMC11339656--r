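# The 12 criterion transformations.

test_that("categorical maps reproduce their printed scores and are total", {
  printed <- list(
    inhibitor_removal = c(not_needed_or_no_waste = 1, solid_waste = 0.5,
                          liquid_waste = 0.2, solid_and_liquid_waste = 0),
    initiation = c(heating_mixing_only = 0, mixing_with_initiator = 0.2,
                   heating_mixing_with_initiator = 0.4,
                   sonication_or_microwave = 0.6, uv_mediated = 0.8,
                   electropolymerization = 0.9, self_polymerization = 1),
    particle_size = c(macro_extraction_device = 1, above_1000nm = 0.9,
                      nm_100_to_1000 = 0.8, micrometer_crushed_sieved = 0.6,
                      nm_10_to_100 = 0.5, carbon_dots = 0.4, quantum_dots = 0.2),
    elution_technique = c(soxhlet = 0, mixing_or_shaking = 0.5,
                          supercritical_fluid = 0.8, ultrasound_or_microwave = 1))
  scorer <- list(inhibitor_removal = score_inhibitor_removal,
                 initiation = score_initiation,
                 particle_size = score_particle_size,
                 elution_technique = score_elution_technique)
  for (criterion in names(printed)) {
    map <- categorical_scores(criterion)
    expect_setequal(names(map), names(printed[[criterion]]))
    for (cat in names(printed[[criterion]])) {
      expect_equal(scorer[[criterion]](cat)$score,
                   unname(printed[[criterion]][[cat]]),
                   info = paste(criterion, cat))
    }
    # surjective onto the printed score set
    expect_setequal(unname(map), unname(printed[[criterion]]))
    expect_error(scorer[[criterion]]("no_such_category"),
                 class = "mipgreen_validation_error")
  }
})

test_that("reusability bands follow the printed breakpoints", {
  expect_equal(score_reusability(1)$score, 0)
  expect_equal(score_reusability(2)$score, 0.5)
  expect_equal(score_reusability(5)$score, 0.5)
  expect_equal(score_reusability(9)$score, 0.5)
  expect_equal(score_reusability(10)$score, 1)  # boundary joins "10 and more"
  expect_equal(score_reusability(100)$score, 1)
  expect_error(score_reusability(0), class = "mipgreen_validation_error")
  expect_error(score_reusability(2.5), class = "mipgreen_validation_error")
})

test_that("substance amounts convert to grams across units", {
  expect_equal(substance("a", 2, "g", role = "template")$mass_g, 2)
  expect_equal(substance("a", 500, "mg", role = "template")$mass_g, 0.5)
  expect_equal(substance("x", 10, "mL", role = "porogen", density = 0.9)$mass_g, 9)
  # packaged density table resolves known solvent names
  expect_equal(substance("acetonitrile", 4, "mL", role = "porogen")$mass_g,
               4 * solvent_density("acetonitrile"))
  expect_error(substance("mystery brew", 1, "mL", role = "porogen"),
               class = "mipgreen_validation_error")
  expect_error(substance("a", -1, "g", role = "template"),
               class = "mipgreen_validation_error")
})

test_that("burden is the mass-weighted penalty sum and is additive", {
  tbl <- tiny_table()  # H225=6, H301=8, H315=2
  expect_equal(burden(list(), tbl), 0)
  one <- substance("m", 2, "g", codes = "H225", role = "functional_monomer")
  expect_equal(burden(list(one), tbl), 2 * 6)
  two <- substance("n", 0.5, "g", codes = c("H301", "H315"),
                   role = "functional_monomer")
  # per-component oracle: sum of single-substance burdens
  expect_equal(burden(list(one, two), tbl),
               burden(list(one), tbl) + burden(list(two), tbl))
  set.seed(7)
  for (i in 1:20) {
    subs <- lapply(1:4, function(j) {
      substance(paste0("s", j), stats::runif(1, 0, 10),
                codes = sample(tbl$code, sample(0:3, 1)), role = "porogen")
    })
    split <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    expect_equal(burden(subs, tbl),
                 burden(subs[split], tbl) + burden(subs[!split], tbl))
  }
})

test_that("burden curves anchor at 1.00, decay to 0.00, and stay monotone", {
  expect_equal(score_burden_c24(0)$score, 1)
  expect_equal(score_burden_c57(0)$score, 1)
  expect_equal(score_burden_c24(1e6)$score, 0)
  expect_equal(score_burden_c57(1e6)$score, 0)
  set.seed(11)
  for (i in 1:100) {
    xs <- sort(10^stats::runif(2, -2, 4))
    expect_gte(score_burden_c24(xs[1])$score, score_burden_c24(xs[2])$score)
    expect_gte(score_burden_c57(xs[1])$score, score_burden_c57(xs[2])$score)
  }
  expect_error(score_burden_c24(-1), class = "mipgreen_validation_error")
})

test_that("the two burden curves are differentiated at interior points", {
  expect_false(score_burden_c24(50)$score == score_burden_c57(50)$score)
  # gentler curve scores solvent-scale burdens higher
  expect_gt(score_burden_c57(50)$score, score_burden_c24(50)$score)
})

test_that("criterion scores are two-decimal values in [0, 1]", {
  set.seed(13)
  for (x in 10^stats::runif(50, -2, 4)) {
    for (s in c(score_burden_c24(x)$score, score_burden_c57(x)$score)) {
      expect_gte(s, 0)
      expect_lte(s, 1)
      expect_equal(s * 100, round(s * 100))
    }
  }
  expect_error(criterion_score(3, 0.123), class = "mipgreen_validation_error")
  expect_error(criterion_score(13, 0.5), class = "mipgreen_validation_error")
})

test_that("elution-solvent score ramps down and clamps above 39 points", {
  mk <- function(p) {
    tbl <- penalty_table("H225", p)
    score_elution_solvent("H225", tbl)$score
  }
  expect_equal(mk(0), 1)      # hazard-free solvent, e.g. water
  expect_equal(mk(20), 0.5)
  expect_equal(mk(39), 0.03)
  expect_equal(mk(40), 0)
  expect_equal(mk(41), 0)
  expect_equal(mk(400), 0)
  prev <- 1
  for (p in 0:45) {
    s <- mk(p)
    expect_lte(s, prev)
    prev <- s
  }
  expect_error(score_elution_solvent("H999", tiny_table()),
               class = "mipgreen_lookup_error")
})

test_that("hazard-free or massless stages take the greenest scores", {
  tbl <- tiny_table()
  benign <- substance("green monomer", 5, "g", codes = character(),
                      role = "functional_monomer")
  massless <- substance("trace", 0, "g", codes = c("H301"), role = "template")
  expect_equal(score_burden_c24(burden(list(benign), tbl))$score, 1)
  expect_equal(score_burden_c24(burden(list(massless), tbl), 3L)$score, 1)
})
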