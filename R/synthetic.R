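# Seeded synthetic-procedure generator, the workhorse of the property suite.
#
# Generated procedures emulate the input space the metric was designed for:
# reagent masses log-uniform over 0.01-100 g (microliter-scale additives up
# to bulk solvent amounts), hazard sets drawn from the penalty registry, and
# categorical choices uniform over their category sets. They are
# schema-valid by construction; they do not emulate chemically coherent
# recipes (e.g. a porogen that is also the elution solvent), only the
# statistical shape of the inputs.

#' Generate random, schema-valid synthesis procedures
#'
#' Reproducible: the same seed yields the same list. The caller's RNG state
#' is left untouched.
#'
#' @param n Number of procedures (>= 1).
#' @param seed Integer seed.
#' @param table Penalty table whose codes are sampled for hazard sets.
#' @return List of `n` validated `mip_procedure` objects.
#' @examples
#' procs <- generate_procedures(3, seed = 42)
#' assess(procs[[1]])$result$display_overall
#' @export
generate_procedures <- function(n, seed, table = load_penalty_table()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    mip_error("n must be a positive integer", "mipgreen_validation_error")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  pool <- table$code
  rand_codes <- function(max_k = 4) {
    k <- sample(0:max_k, 1)
    if (k == 0) character() else sample(pool, k)
  }
  rand_substances <- function(role, max_n = 3) {
    k <- sample(0:max_n, 1)
    lapply(seq_len(k), function(i) {
      list(name = sprintf("reagent_%s_%d", role, i),
           amount = round(10^stats::runif(1, -2, 2), 4),
           unit = "g",
           codes = as.list(rand_codes()))
    })
  }
  pick <- function(criterion) sample(names(categorical_scores(criterion)), 1)

  lapply(seq_len(n), function(i) {
    subs <- stats::setNames(lapply(.substance_roles, rand_substances),
                            .substance_roles)
    procedure(
      metadata = list(title = sprintf("synthetic procedure %d", i)),
      inhibitor_removal = pick("inhibitor_removal"),
      substances = Filter(length, subs),
      initiation = pick("initiation"),
      particle_size = pick("particle_size"),
      elution_solvents = lapply(seq_len(sample(1:2, 1)), function(j) {
        list(name = sprintf("solvent_%d", j), codes = as.list(rand_codes(3)))
      }),
      elution_technique = pick("elution_technique"),
      reuse_cycles = sample(1:15, 1))
  })
}
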