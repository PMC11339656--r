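# Procedure-file schema, validation, assessment pipeline, reports, comparison.
#
# A procedure description is a declarative YAML/JSON document listing, per
# criterion, the facts needed to score it: categorical choices (criteria 1,
# 8, 9, 11, 12), reagents with amounts and H-codes (criteria 2-7), and the
# elution solvent(s) (criterion 10). Schema version 1.

.schema_version <- 1L

.top_level_keys <- c("schema_version", "metadata", "inhibitor_removal",
                     "substances", "initiation", "particle_size",
                     "elution_solvents", "elution_technique", "reuse_cycles",
                     "weights", "weights_justification", "penalty_table")
.required_keys <- c("schema_version", "inhibitor_removal", "initiation",
                    "particle_size", "elution_solvents", "elution_technique",
                    "reuse_cycles")
.metadata_keys <- c("title", "reference", "notes")
.substance_keys <- c("name", "cas", "amount", "unit", "density", "codes")

#' Build a procedure description programmatically
#'
#' The constructor behind [read_procedure()] and the synthetic generator.
#' All categorical fields are validated against their criterion's category
#' set; substances are validated and amounts converted to grams.
#'
#' @param inhibitor_removal,initiation,particle_size,elution_technique
#'   Categorical choices (see [categorical_scores()]).
#' @param elution_solvents List of `list(name =, codes =)` records; the
#'   H-codes of all elution solvents are pooled for criterion 10.
#' @param reuse_cycles Positive integer.
#' @param substances Named list of substance-record lists, keyed by role
#'   (`functional_monomer`, `template`, `cross_linker`, `porogen`,
#'   `other_reagent`, `core_surface`); each record as accepted by
#'   [substance()]. Absent roles score as burden 0 (the stage does not
#'   exist, hence nothing to penalize).
#' @param metadata Optional list with `title`, `reference`, `notes`.
#' @param weights Optional 12-tuple weight override.
#' @param weights_justification Optional justification for the override.
#' @param penalty_table Optional path to a penalty-table override file.
#' @return A validated `mip_procedure` list.
#' @export
procedure <- function(inhibitor_removal, initiation, particle_size,
                      elution_solvents, elution_technique, reuse_cycles,
                      substances = list(), metadata = list(),
                      weights = NULL, weights_justification = NULL,
                      penalty_table = NULL) {
  raw <- list(schema_version = .schema_version,
              metadata = metadata,
              inhibitor_removal = inhibitor_removal,
              substances = substances,
              initiation = initiation,
              particle_size = particle_size,
              elution_solvents = elution_solvents,
              elution_technique = elution_technique,
              reuse_cycles = reuse_cycles,
              weights = weights,
              weights_justification = weights_justification,
              penalty_table = penalty_table)
  validate_procedure(raw)
}

.schema_fail <- function(path, msg) {
  mip_error(sprintf("procedure schema violation at %s: %s", path, msg),
            "mipgreen_schema_error")
}

.check_choice <- function(value, criterion, path) {
  valid <- names(categorical_scores(criterion))
  if (!is.character(value) || length(value) != 1 || !value %in% valid) {
    .schema_fail(path, sprintf("got '%s'; expected one of: %s",
                               paste(value, collapse = ","),
                               paste(valid, collapse = ", ")))
  }
  value
}

#' Validate a raw procedure description
#'
#' Checks the full schema — required fields present, no unknown keys,
#' categorical fields in their category sets, masses nonnegative, H-codes
#' well formed — and returns a canonicalized `mip_procedure`. Error messages
#' name the path to the offending field.
#'
#' @param raw A named list as parsed from YAML/JSON.
#' @return A `mip_procedure` list.
#' @export
validate_procedure <- function(raw) {
  if (!is.list(raw) || is.null(names(raw))) {
    .schema_fail("$", "top level must be a mapping")
  }
  unknown <- setdiff(names(raw), .top_level_keys)
  if (length(unknown) > 0) {
    .schema_fail(paste0("$.", unknown[1]), "unknown key")
  }
  missing_keys <- setdiff(.required_keys, names(raw)[!vapply(raw, is.null, logical(1))])
  if (length(missing_keys) > 0) {
    .schema_fail(paste0("$.", missing_keys[1]), "required field is missing")
  }
  if (!identical(as.integer(raw$schema_version), .schema_version)) {
    .schema_fail("$.schema_version",
                 sprintf("unsupported version '%s' (supported: %d)",
                         raw$schema_version, .schema_version))
  }

  metadata <- raw$metadata %||% list()
  unknown <- setdiff(names(metadata), .metadata_keys)
  if (length(unknown) > 0) .schema_fail(paste0("$.metadata.", unknown[1]), "unknown key")

  out <- list(schema_version = .schema_version, metadata = metadata)
  out$inhibitor_removal <- .check_choice(raw$inhibitor_removal,
                                         "inhibitor_removal", "$.inhibitor_removal")
  out$initiation <- .check_choice(raw$initiation, "initiation", "$.initiation")
  out$particle_size <- .check_choice(raw$particle_size, "particle_size",
                                     "$.particle_size")
  out$elution_technique <- .check_choice(raw$elution_technique,
                                         "elution_technique", "$.elution_technique")

  cyc <- raw$reuse_cycles
  if (!is.numeric(cyc) || length(cyc) != 1 || is.na(cyc) || cyc < 1 ||
      cyc != floor(cyc)) {
    .schema_fail("$.reuse_cycles", "must be a positive integer")
  }
  out$reuse_cycles <- as.integer(cyc)

  subs <- raw$substances %||% list()
  if (!is.list(subs)) .schema_fail("$.substances", "must be a mapping of role to list")
  unknown <- setdiff(names(subs), .substance_roles)
  if (length(unknown) > 0) {
    .schema_fail(paste0("$.substances.", unknown[1]),
                 sprintf("unknown role (valid: %s)",
                         paste(.substance_roles, collapse = ", ")))
  }
  out$substances <- stats::setNames(lapply(.substance_roles, function(role) {
    entries <- subs[[role]] %||% list()
    lapply(seq_along(entries), function(i) {
      rec <- entries[[i]]
      at <- sprintf("$.substances.%s[%d]", role, i)
      if (!is.list(rec)) .schema_fail(at, "must be a mapping")
      unknown <- setdiff(names(rec), .substance_keys)
      if (length(unknown) > 0) .schema_fail(paste0(at, ".", unknown[1]), "unknown key")
      if (is.null(rec$name)) .schema_fail(paste0(at, ".name"), "required field is missing")
      if (is.null(rec$amount)) .schema_fail(paste0(at, ".amount"), "required field is missing")
      tryCatch(
        substance(rec$name, rec$amount, rec$unit %||% "g",
                  codes = unlist(rec$codes) %||% character(),
                  role = role, cas = rec$cas, density = rec$density),
        mipgreen_error = function(e) .schema_fail(at, conditionMessage(e)))
    })
  }), .substance_roles)

  sol <- raw$elution_solvents
  if (!is.list(sol) || length(sol) < 1) {
    .schema_fail("$.elution_solvents", "must be a list with at least one solvent")
  }
  out$elution_solvents <- lapply(seq_along(sol), function(i) {
    rec <- sol[[i]]
    at <- sprintf("$.elution_solvents[%d]", i)
    if (!is.list(rec) || is.null(rec$name)) .schema_fail(at, "needs a 'name'")
    unknown <- setdiff(names(rec), c("name", "codes"))
    if (length(unknown) > 0) .schema_fail(paste0(at, ".", unknown[1]), "unknown key")
    codes <- tryCatch(hazard_codes(unlist(rec$codes) %||% character()),
                      mipgreen_error = function(e) .schema_fail(at, conditionMessage(e)))
    list(name = rec$name, codes = codes)
  })

  if (!is.null(raw$weights)) {
    scheme <- tryCatch(validate_weights(raw$weights, raw$weights_justification),
                       mipgreen_error = function(e) .schema_fail("$.weights", conditionMessage(e)))
    out$weights <- as.integer(scheme$weights)
    out$weights_justification <- raw$weights_justification
  }
  out$penalty_table <- raw$penalty_table
  structure(out, class = "mip_procedure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a procedure description from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` procedure file.
#' @return A validated `mip_procedure`.
#' @examples
#' f <- system.file("extdata", "example_electropolymerization.yaml",
#'                  package = "mipgreen")
#' read_procedure(f)$initiation
#' @export
read_procedure <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    mip_error(sprintf("cannot read procedure file: %s", path), "mipgreen_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_procedure(raw)
}

#' Write a procedure description to YAML or JSON (canonical form)
#'
#' `read_procedure(write_procedure(p, f))` reproduces `p` exactly.
#'
#' @param proc A `mip_procedure`.
#' @param path Output path ending in `.yaml`, `.yml`, or `.json`.
#' @return `path`, invisibly.
#' @export
write_procedure <- function(proc, path) {
  stopifnot(inherits(proc, "mip_procedure"))
  raw <- list(
    schema_version = proc$schema_version,
    metadata = if (length(proc$metadata)) proc$metadata else NULL,
    inhibitor_removal = proc$inhibitor_removal,
    substances = {
      s <- Filter(length, proc$substances)
      if (length(s) == 0) NULL else lapply(s, function(entries) {
        lapply(entries, function(x) {
          rec <- list(name = x$name, cas = x$cas, amount = x$amount,
                      unit = x$unit, density = x$density)
          if (length(x$codes)) rec$codes <- as.list(x$codes)
          Filter(Negate(is.null), rec)
        })
      })
    },
    initiation = proc$initiation,
    particle_size = proc$particle_size,
    elution_solvents = lapply(proc$elution_solvents, function(x) {
      rec <- list(name = x$name)
      if (length(x$codes)) rec$codes <- as.list(x$codes)
      rec
    }),
    elution_technique = proc$elution_technique,
    reuse_cycles = proc$reuse_cycles,
    weights = proc$weights,
    weights_justification = proc$weights_justification,
    penalty_table = proc$penalty_table)
  raw <- Filter(Negate(is.null), raw)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Assess a synthesis procedure against all 12 criteria
#'
#' Runs every criterion transformation, aggregates the scores into the
#' weighted overall score, and assembles an audit report. Deterministic:
#' the same procedure, penalty table, and weights always give the same
#' result.
#'
#' @param x A `mip_procedure` or a path to a procedure file.
#' @param penalty_table A [penalty_table()], a path to one, or `NULL` to use
#'   the procedure's own override (if any) or the packaged default.
#' @param weights Weight override (`NULL`: the procedure's own override or
#'   the default scheme).
#' @param strict Passed to [penalty_sum()]; lenient mode scores unknown
#'   H-codes as 0 with a warning.
#' @param verbose If `TRUE`, print a per-criterion trace (raw input, burden,
#'   score) so each score can be audited.
#' @return List with `result` (an `assessment_result`) and `report` (an
#'   `assessment_report` list).
#' @examples
#' f <- system.file("extdata", "fixture_greenest.yaml", package = "mipgreen")
#' assess(f)$result$display_overall
#' @export
assess <- function(x, penalty_table = NULL, weights = NULL, strict = TRUE,
                   verbose = FALSE) {
  proc <- if (inherits(x, "mip_procedure")) x else read_procedure(x)
  tbl <- if (inherits(penalty_table, "penalty_table")) {
    penalty_table
  } else {
    load_penalty_table(penalty_table %||% proc$penalty_table)
  }

  with_context <- function(criterion_id, expr) {
    tryCatch(expr, mipgreen_error = function(e) {
      mip_error(sprintf("criterion %d: %s", criterion_id, conditionMessage(e)),
                class(e)[1])
    })
  }

  burden_roles <- list(`2` = "functional_monomer", `3` = "template",
                       `4` = "cross_linker", `5` = "porogen",
                       `6` = "other_reagent", `7` = "core_surface")
  scores <- vector("list", 12)
  scores[[1]] <- score_inhibitor_removal(proc$inhibitor_removal)
  for (id in 2:7) {
    role <- burden_roles[[as.character(id)]]
    scores[[id]] <- with_context(id, {
      x_burden <- burden(proc$substances[[role]], tbl, strict = strict)
      s <- if (id <= 4) score_burden_c24(x_burden, id) else score_burden_c57(x_burden, id)
      s$detail <- sprintf("%s: %s", role, s$detail)
      s
    })
  }
  scores[[8]] <- score_initiation(proc$initiation)
  scores[[9]] <- score_particle_size(proc$particle_size)
  scores[[10]] <- with_context(10L, {
    pooled <- unique(unlist(lapply(proc$elution_solvents, `[[`, "codes")))
    s <- score_elution_solvent(pooled %||% character(), tbl, strict = strict)
    s$detail <- sprintf("%s; %s",
                        paste(vapply(proc$elution_solvents, `[[`, character(1), "name"),
                              collapse = " + "),
                        s$detail)
    s
  })
  scores[[11]] <- score_elution_technique(proc$elution_technique)
  scores[[12]] <- score_reusability(proc$reuse_cycles)

  scheme <- validate_weights(weights %||% proc$weights,
                             proc$weights_justification)
  result <- overall_score(scores, scheme)

  if (verbose) {
    for (s in scores) {
      message(sprintf("criterion %2d | %-55s | score %.2f | weight %d",
                      s$criterion_id, s$detail, s$score,
                      scheme$weights[[s$criterion_id]]))
    }
    message(sprintf("overall: %.2f (%s weights)", result$display_overall,
                    scheme$provenance))
  }

  report <- structure(list(
    tool = "mipgreen",
    version = as.character(utils::packageVersion("mipgreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = list(title = proc$metadata$title %||% NA_character_,
                 reference = proc$metadata$reference %||% NA_character_,
                 notes = proc$metadata$notes %||% NA_character_),
    penalty_table_source = attr(tbl, "source_label"),
    weights_provenance = scheme$provenance,
    weights_justification = scheme$justification %||% NA_character_,
    criteria = lapply(scores, function(s) {
      list(criterion = s$criterion_id, score = s$score,
           weight = scheme$weights[[s$criterion_id]], detail = s$detail)
    }),
    overall = result$overall,
    display_overall = result$display_overall),
    class = "assessment_report")

  list(result = result, report = report)
}

#' Write an assessment report to JSON
#'
#' Reports are byte-identical for identical inputs apart from the
#' `timestamp` field.
#'
#' @param report An `assessment_report` from [assess()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "assessment_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Compare several procedures
#'
#' Assesses each file and returns one row per procedure with the 12
#' criterion scores and the overall score, ranked greenest first. Invalid
#' files are reported in the `error` column; valid files are still
#' processed.
#'
#' @param paths Character vector of two or more procedure files.
#' @param penalty_table,weights,strict Passed to [assess()].
#' @return Data frame with columns `file`, `title`, `c1`..`c12`, `overall`,
#'   `rank`, `error`, ordered by decreasing overall score.
#' @export
compare_procedures <- function(paths, penalty_table = NULL, weights = NULL,
                               strict = TRUE) {
  if (length(paths) < 2) {
    mip_error("compare needs at least two procedure files", "mipgreen_validation_error")
  }
  rows <- lapply(paths, function(p) {
    out <- tryCatch(assess(p, penalty_table = penalty_table, weights = weights,
                           strict = strict),
                    error = function(e) e)
    if (inherits(out, "error")) {
      row <- as.data.frame(as.list(stats::setNames(rep(NA_real_, 13),
                                                   c(paste0("c", 1:12), "overall"))))
      cbind(data.frame(file = p, title = NA_character_, stringsAsFactors = FALSE),
            row, data.frame(error = conditionMessage(out), stringsAsFactors = FALSE))
    } else {
      row <- as.data.frame(as.list(out$result$scores))
      row$overall <- out$result$display_overall
      cbind(data.frame(file = p,
                       title = out$report$input$title %||% NA_character_,
                       stringsAsFactors = FALSE),
            row, data.frame(error = NA_character_, stringsAsFactors = FALSE))
    }
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$overall, tab$file, na.last = TRUE), , drop = FALSE]
  tab$rank <- NA_integer_
  ok <- !is.na(tab$overall)
  tab$rank[ok] <- rank(-tab$overall[ok], ties.method = "min")
  rownames(tab) <- NULL
  tab
}

#' Commented procedure-file template
#'
#' Returns (and optionally writes) a fully commented YAML template listing
#' every field and category, ready to edit.
#'
#' @param path Optional output path; `NULL` returns the text only.
#' @return The template text, invisibly if written to `path`.
#' @export
procedure_template <- function(path = NULL) {
  tpl <- system.file("extdata", "procedure_template.yaml",
                     package = "mipgreen", mustWork = TRUE)
  txt <- paste(readLines(tpl), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
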