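# The 12 criterion transformations: raw procedure facts -> standardized 0-1 scores.
#
# Criteria 1, 8, 9, 11, 12 are categorical lookups with printed score sets.
# Criteria 2-7 transform a mass-hazard burden x = sum(mass_i * penalty_i)
# through a continuous decay curve; criterion 10 transforms the elution
# solvent's penalty-point sum through a linear ramp that hits 0 above 39
# points. All continuous scores are rounded to two decimals (half away from
# zero) before aggregation.

# --- categorical score maps (printed values) ---------------------------------

.categorical_scores <- list(
  inhibitor_removal = c(
    not_needed_or_no_waste = 1.0,
    solid_waste            = 0.5,
    liquid_waste           = 0.2,
    solid_and_liquid_waste = 0.0),
  initiation = c(
    heating_mixing_only          = 0.0,
    mixing_with_initiator        = 0.2,
    heating_mixing_with_initiator = 0.4,
    sonication_or_microwave      = 0.6,
    uv_mediated                  = 0.8,
    electropolymerization        = 0.9,
    self_polymerization          = 1.0),
  particle_size = c(
    macro_extraction_device   = 1.0,
    above_1000nm              = 0.9,
    nm_100_to_1000            = 0.8,
    micrometer_crushed_sieved = 0.6,
    nm_10_to_100              = 0.5,
    carbon_dots               = 0.4,
    quantum_dots              = 0.2),
  elution_technique = c(
    soxhlet                 = 0.0,
    mixing_or_shaking       = 0.5,
    supercritical_fluid     = 0.8,
    ultrasound_or_microwave = 1.0)
)

#' Categorical criterion score maps
#'
#' Returns the full named score vector for one of the categorical criteria:
#' inhibitor removal (criterion 1), polymerization initiation (criterion 8),
#' particle size (criterion 9), or template elution technique (criterion 11).
#' Useful for enumerating valid input categories.
#'
#' @param criterion One of `"inhibitor_removal"`, `"initiation"`,
#'   `"particle_size"`, `"elution_technique"`.
#' @return Named numeric vector mapping category to score.
#' @examples
#' categorical_scores("elution_technique")
#' @export
categorical_scores <- function(criterion = names(.categorical_scores)) {
  criterion <- match.arg(criterion)
  .categorical_scores[[criterion]]
}

#' @keywords internal
round_score <- function(x) {
  # two-decimal rounding, half away from zero; eps guards binary representation
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

#' Construct a single criterion score
#'
#' @param criterion_id Integer 1-12.
#' @param score Score in \[0, 1\], already rounded to two decimals.
#' @param detail Free-text provenance of the score.
#' @return A `criterion_score` list.
#' @export
criterion_score <- function(criterion_id, score, detail = "") {
  criterion_id <- as.integer(criterion_id)
  if (is.na(criterion_id) || criterion_id < 1L || criterion_id > 12L) {
    mip_error("criterion_id must be an integer in 1..12", "mipgreen_validation_error")
  }
  if (!is.numeric(score) || length(score) != 1 || is.na(score) ||
      score < 0 || score > 1) {
    mip_error("score must be a single value in [0, 1]", "mipgreen_validation_error")
  }
  if (abs(score - round_score(score)) > 1e-12) {
    mip_error("score must equal its own two-decimal rounding", "mipgreen_validation_error")
  }
  structure(list(criterion_id = criterion_id, score = score, detail = detail),
            class = "criterion_score")
}

#' @export
print.criterion_score <- function(x, ...) {
  cat(sprintf("criterion %2d: %.2f  (%s)\n", x$criterion_id, x$score, x$detail))
  invisible(x)
}

.lookup_categorical <- function(criterion, choice, criterion_id) {
  map <- .categorical_scores[[criterion]]
  if (!is.character(choice) || length(choice) != 1 || !choice %in% names(map)) {
    mip_error(sprintf("unknown %s category '%s'; valid: %s",
                      criterion, paste(choice, collapse = ","),
                      paste(names(map), collapse = ", ")),
              "mipgreen_validation_error")
  }
  criterion_score(criterion_id, unname(map[[choice]]), detail = choice)
}

#' Criterion 1: removal of polymerization inhibitors
#'
#' Commercial monomers ship with polymerization inhibitors that usually must
#' be removed before synthesis. Generating no waste (or using
#' inhibitor-free reagents) is greenest; solid waste is easier to handle than
#' liquid; generating both is the worst case.
#'
#' @param choice One of `not_needed_or_no_waste` (1.0), `solid_waste` (0.5),
#'   `liquid_waste` (0.2), `solid_and_liquid_waste` (0.0).
#' @return A [criterion_score()] for criterion 1.
#' @export
score_inhibitor_removal <- function(choice) {
  .lookup_categorical("inhibitor_removal", choice, 1L)
}

#' Criterion 8: polymerization initiation
#'
#' Ranks initiation modes by energy demand and need for a chemical
#' initiator, from plain heating/mixing (0.0) through chemically initiated
#' and irradiation-assisted routes up to initiator-free electropolymerization
#' (0.9) and self-polymerization (1.0).
#'
#' @param choice One of the categories in `categorical_scores("initiation")`.
#' @return A [criterion_score()] for criterion 8.
#' @export
score_initiation <- function(choice) {
  .lookup_categorical("initiation", choice, 8L)
}

#' Criterion 9: size of the polymer particles
#'
#' Smaller particles mean higher operator exposure and environmental release
#' risk. In-situ macro devices (e.g. imprinted monolith SPME fibers) score 1;
#' quantum-dot composites score 0.2.
#'
#' @param choice One of the categories in `categorical_scores("particle_size")`.
#' @return A [criterion_score()] for criterion 9.
#' @export
score_particle_size <- function(choice) {
  .lookup_categorical("particle_size", choice, 9L)
}

#' Criterion 11: template elution technique
#'
#' Soxhlet extraction (prolonged heating, large solvent volumes) scores 0;
#' mixing/shaking 0.5; supercritical-fluid extraction 0.8; ultrasound- or
#' microwave-assisted elution 1.
#'
#' @param choice One of the categories in
#'   `categorical_scores("elution_technique")`.
#' @return A [criterion_score()] for criterion 11.
#' @export
score_elution_technique <- function(choice) {
  .lookup_categorical("elution_technique", choice, 11L)
}

#' Criterion 12: final product reusability
#'
#' Single-use sorbents score 0; 2-9 usable sorption-desorption cycles score
#' 0.5; 10 or more cycles score 1. (Exactly 10 cycles takes the higher score;
#' the boundary belongs to the "10 and more" band.)
#'
#' @param cycles Positive integer number of usable cycles.
#' @return A [criterion_score()] for criterion 12.
#' @export
score_reusability <- function(cycles) {
  if (!is.numeric(cycles) || length(cycles) != 1 || is.na(cycles) ||
      cycles < 1 || cycles != floor(cycles)) {
    mip_error("reuse_cycles must be a positive integer", "mipgreen_validation_error")
  }
  s <- if (cycles >= 10) 1.0 else if (cycles >= 2) 0.5 else 0.0
  criterion_score(12L, s, detail = sprintf("%d cycle(s)", as.integer(cycles)))
}

# --- substances and mass-hazard burden (criteria 2-7) ------------------------

.substance_roles <- c("functional_monomer", "template", "cross_linker",
                      "porogen", "other_reagent", "core_surface")

#' Look up a packaged solvent density
#'
#' Densities (g/mL at 20-25 degrees C, typical handbook values) for common
#' MIP-synthesis solvents, used to convert volumes to masses.
#'
#' @param name Solvent name (case-insensitive).
#' @return Density in g/mL.
#' @export
solvent_density <- function(name) {
  path <- system.file("extdata", "solvent_densities.csv",
                      package = "mipgreen", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  i <- match(tolower(trimws(name)), tbl$name)
  if (is.na(i)) {
    mip_error(sprintf(
      "no packaged density for solvent '%s'; supply density explicitly", name),
      "mipgreen_validation_error")
  }
  tbl$density_g_per_ml[i]
}

#' Describe one reagent used in a synthesis stage
#'
#' The unit of input for criteria 2-7: a reagent's identity, amount, GHS
#' hazard statements, and the synthesis role that assigns it to a criterion
#' (functional_monomer = 2, template = 3, cross_linker = 4, porogen = 5,
#' other_reagent = 6, core_surface = 7). Amounts are converted to grams:
#' `"g"` and `"mg"` directly, `"mL"` via an explicit `density` or the
#' packaged density table ([solvent_density()]).
#'
#' @param name Reagent name.
#' @param amount Nonnegative amount in `unit`.
#' @param unit One of `"g"`, `"mg"`, `"mL"`.
#' @param codes GHS H-codes of the reagent (may be empty for benign reagents).
#' @param role One of `functional_monomer`, `template`, `cross_linker`,
#'   `porogen`, `other_reagent`, `core_surface`.
#' @param cas Optional CAS registry number (metadata only; never used to look
#'   up hazards automatically).
#' @param density Optional density in g/mL, required for `"mL"` amounts of
#'   solvents absent from the packaged density table.
#' @return A `mip_substance` list with the computed `mass_g`.
#' @examples
#' substance("methacrylic acid", 0.86, "g", codes = c("H314", "H335"),
#'           role = "functional_monomer")
#' @export
substance <- function(name, amount, unit = c("g", "mg", "mL"),
                      codes = character(), role, cas = NULL, density = NULL) {
  unit <- match.arg(unit)
  role <- match.arg(role, .substance_roles)
  if (!is.numeric(amount) || length(amount) != 1 || is.na(amount) || amount < 0) {
    mip_error(sprintf("amount of '%s' must be a nonnegative number", name),
              "mipgreen_validation_error")
  }
  if (unit == "mL" && is.null(density)) density <- solvent_density(name)
  mass_g <- switch(unit,
    g  = amount,
    mg = amount / 1000,
    mL = amount * density)
  structure(list(name = name, cas = cas, mass_g = mass_g,
                 amount = amount, unit = unit,
                 density = if (unit == "mL") density else NULL,
                 codes = unique(hazard_codes(codes)), role = role),
            class = "mip_substance")
}

#' Mass-hazard burden of a criterion's substances
#'
#' For criteria 2-7 the quantity and the risk of every component are
#' considered simultaneously: each substance contributes its mass in grams
#' multiplied by the sum of its hazard penalty points, and contributions are
#' added over the (possibly multi-component) mixture. An absent stage
#' contributes 0 — the greenest possible burden.
#'
#' @param substances List of [substance()] objects (may be empty).
#' @param table A [penalty_table()].
#' @param strict Passed to [penalty_sum()].
#' @return Nonnegative burden x in gram-points.
#' @export
burden <- function(substances, table = load_penalty_table(), strict = TRUE) {
  if (length(substances) == 0) return(0)
  stopifnot(all(vapply(substances, inherits, logical(1), "mip_substance")))
  sum(vapply(substances, function(s) {
    if (s$mass_g < 0) {
      mip_error(sprintf("negative mass for '%s'", s$name), "mipgreen_validation_error")
    }
    s$mass_g * penalty_sum(s$codes, table, strict = strict)
  }, numeric(1)))
}

# --- continuous transformations ----------------------------------------------

# Half-decay scales (gram-points) mapping the expected burden ranges onto 0-1.
# Criteria 2-4 handle the prepolymerization core (template, monomer,
# cross-linker) where gram-scale amounts are typical, so the curve decays
# fast; criteria 5-7 handle solvents/auxiliaries/supports where tens of
# grams are routine, so the curve is ten-fold gentler. The two curves are
# deliberately differentiated to preserve discrimination in both regimes.
.burden_half_decay <- c(c24 = 10, c57 = 100)

.score_decay <- function(x, half) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    mip_error("burden x must be a single nonnegative number", "mipgreen_validation_error")
  }
  round_score(2^(-x / half))
}

#' Continuous score for criteria 2-4 (functional monomer, template, cross-linker)
#'
#' Transforms the mass-hazard burden x (gram-points, see [burden()]) through
#' an exponential decay with a 10 gram-point half-decay:
#' score = 2^(-x / 10), rounded to two decimals. Hazard-free or massless
#' stages score 1.00; the score falls sharply with increasing mass and/or
#' hazard severity and reaches 0.00 for very large burdens.
#'
#' @param x Nonnegative burden in gram-points.
#' @param criterion_id Which of criteria 2, 3, 4 this burden belongs to
#'   (affects only the returned label).
#' @return A [criterion_score()].
#' @examples
#' score_burden_c24(0)    # 1.00
#' score_burden_c24(10)   # 0.50
#' @export
score_burden_c24 <- function(x, criterion_id = 2L) {
  stopifnot(criterion_id %in% 2:4)
  criterion_score(criterion_id, .score_decay(x, .burden_half_decay[["c24"]]),
                  detail = sprintf("x = %.4g g*pts", x))
}

#' Continuous score for criteria 5-7 (porogen, other reagents, core/surface)
#'
#' Same exponential-decay family as [score_burden_c24()] but with a 100
#' gram-point half-decay (score = 2^(-x / 100)): solvents, auxiliaries, and
#' support preparation involve much larger amounts, and a gentler curve keeps
#' discrimination over that range. The two curves give different scores at
#' any interior burden.
#'
#' @inheritParams score_burden_c24
#' @param criterion_id Which of criteria 5, 6, 7 this burden belongs to.
#' @return A [criterion_score()].
#' @examples
#' score_burden_c57(100)  # 0.50
#' @export
score_burden_c57 <- function(x, criterion_id = 5L) {
  stopifnot(criterion_id %in% 5:7)
  criterion_score(criterion_id, .score_decay(x, .burden_half_decay[["c57"]]),
                  detail = sprintf("x = %.4g g*pts", x))
}

#' Criterion 10: template elution solvent
#'
#' Solvent volumes for template removal are rarely reported, so only the
#' hazards of the elution solvent(s) count: the summed penalty points p of
#' the pooled H-codes are transformed through the linear ramp
#' score = 1 - p/40, clamped so that more than 39 points scores exactly 0.
#' A hazard-free solvent (e.g. water, p = 0) scores 1.00. When several
#' elution solvents are used their H-codes are pooled (set union) before
#' summation — the worst-case operator exposure.
#'
#' @param codes H-codes of the elution solvent(s), pooled.
#' @param table A [penalty_table()].
#' @param strict Passed to [penalty_sum()].
#' @return A [criterion_score()] for criterion 10.
#' @examples
#' tbl <- penalty_table(c("H225", "H336"), c(20, 20))
#' score_elution_solvent(c("H225", "H336"), tbl)  # 40 points -> 0.00
#' @export
score_elution_solvent <- function(codes, table = load_penalty_table(),
                                  strict = TRUE) {
  p <- penalty_sum(codes, table, strict = strict)
  s <- if (p > 39) 0 else round_score(1 - p / 40)
  criterion_score(10L, s, detail = sprintf("%d penalty point(s)", p))
}
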