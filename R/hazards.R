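# GHS hazard-statement registry and penalty-point arithmetic.

#' @keywords internal
mip_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "mipgreen_error"), call = call))
}

#' Validate and normalize GHS hazard-statement codes
#'
#' GHS hazard statements ("H-codes") identify a chemical's physical, health,
#' or environmental hazards, e.g. `"H225"` (highly flammable liquid) or
#' `"H360FD"` (may damage fertility; may damage the unborn child). Codes are
#' the letter `H` followed by three digits and optional suffix letters.
#' Comparison is case-insensitive; codes are stored uppercase.
#'
#' @param codes Character vector of candidate codes.
#' @return Uppercased character vector of validated codes.
#' @examples
#' hazard_codes(c("h225", "H360FD"))
#' @export
hazard_codes <- function(codes) {
  if (length(codes) == 0) return(character())
  codes <- toupper(trimws(as.character(codes)))
  bad <- codes[!grepl("^H[0-9]{3}[A-Z]{0,3}$", codes)]
  if (length(bad) > 0) {
    mip_error(
      sprintf("invalid GHS H-code(s): %s (expected 'H' + 3 digits + optional suffix letters)",
              paste(unique(bad), collapse = ", ")),
      "mipgreen_format_error")
  }
  codes
}

#' Construct a hazard penalty table
#'
#' A penalty table maps GHS H-codes to nonnegative integer penalty points;
#' the more serious and unavoidable the hazard, the higher the penalty.
#' The packaged default (see [load_penalty_table()]) is a synthetic table
#' graded by GHS severity class and is fully user-overridable, so alternative
#' penalty conventions can be assessed.
#'
#' @param codes Character vector of H-codes (see [hazard_codes()]).
#' @param points Nonnegative integer penalty points, one per code.
#' @param source_label Free text identifying where the values come from.
#' @return A `penalty_table`: a data frame with columns `code` and `points`
#'   and a `source_label` attribute.
#' @export
penalty_table <- function(codes, points, source_label = "user") {
  codes <- hazard_codes(codes)
  if (length(codes) != length(points)) {
    mip_error("codes and points must have the same length", "mipgreen_validation_error")
  }
  points <- suppressWarnings(as.numeric(points))
  if (anyNA(points) || any(points < 0) || any(points != floor(points))) {
    mip_error("penalty points must be nonnegative integers", "mipgreen_validation_error")
  }
  dup <- unique(codes[duplicated(codes)])
  if (length(dup) > 0) {
    mip_error(sprintf("duplicate H-code(s) in penalty table: %s",
                      paste(dup, collapse = ", ")),
              "mipgreen_validation_error")
  }
  tbl <- data.frame(code = codes, points = as.integer(points),
                    stringsAsFactors = FALSE)
  attr(tbl, "source_label") <- source_label
  class(tbl) <- c("penalty_table", "data.frame")
  tbl
}

#' Load a hazard penalty table from file
#'
#' Reads a two-column table (`code`, `points`) from CSV (header `code,points`)
#' or from a YAML mapping of code to points. With no `path`, the packaged
#' default table is loaded. The packaged default is labelled synthetic: it is
#' a severity-graded stand-in constructed from GHS hazard classes, intended
#' to be replaced by whichever penalty convention the user works under.
#'
#' @param path Optional path to a CSV or YAML penalty table; `NULL` loads the
#'   packaged default.
#' @return A [penalty_table()].
#' @examples
#' tbl <- load_penalty_table()
#' head(tbl)
#' attr(tbl, "source_label")
#' @export
load_penalty_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "penalty_points_synthetic.csv",
                        package = "mipgreen", mustWork = TRUE)
    label <- "synthetic default (severity-graded stand-in; user-overridable)"
  } else {
    if (!file.exists(path)) {
      mip_error(sprintf("penalty table file not found: %s", path), "mipgreen_io_error")
    }
    label <- path
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(path)
    if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
      mip_error(sprintf("YAML penalty table must be a mapping of code to points: %s", path),
                "mipgreen_format_error")
    }
    codes <- names(raw)
    points <- unlist(raw, use.names = FALSE)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
    if (!all(c("code", "points") %in% names(raw))) {
      mip_error(sprintf("penalty table CSV must have header 'code,points': %s", path),
                "mipgreen_format_error")
    }
    codes <- raw$code
    points <- raw$points
  }
  tryCatch(
    penalty_table(codes, points, source_label = label),
    mipgreen_format_error = function(e) {
      mip_error(sprintf("%s (in %s)", conditionMessage(e), path), "mipgreen_format_error")
    })
}

#' Write a penalty table to CSV
#'
#' Inverse of [load_penalty_table()]: `load(write(tbl))` round-trips exactly.
#'
#' @param table A [penalty_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_penalty_table <- function(table, path) {
  stopifnot(inherits(table, "penalty_table"))
  utils::write.csv(as.data.frame(table)[, c("code", "points")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sum penalty points over a set of hazard codes
#'
#' Codes are deduplicated before summation, so listing the same statement
#' twice never double-counts. In strict mode (the default) a code absent from
#' the table is an error: silently scoring an unknown hazard as zero would
#' inflate apparent greenness. In lenient mode an unknown code is first
#' retried by its 4-character stem (so `"H360FD"` falls back to `"H360"`),
#' and only if that also fails does it contribute 0, with a warning.
#'
#' @param codes Character vector of H-codes; may be empty.
#' @param table A [penalty_table()]; default the packaged table.
#' @param strict If `TRUE` (default), unknown codes raise an error.
#' @return Nonnegative integer sum of penalty points.
#' @examples
#' tbl <- penalty_table(c("H225", "H301"), c(6, 8))
#' penalty_sum(c("H225", "H301"), tbl)
#' @export
penalty_sum <- function(codes, table = load_penalty_table(), strict = TRUE) {
  stopifnot(inherits(table, "penalty_table"))
  codes <- unique(hazard_codes(codes))
  if (length(codes) == 0) return(0L)
  idx <- match(codes, table$code)
  if (anyNA(idx)) {
    missing_codes <- codes[is.na(idx)]
    if (strict) {
      mip_error(sprintf("H-code(s) not in penalty table '%s': %s",
                        attr(table, "source_label"),
                        paste(missing_codes, collapse = ", ")),
                "mipgreen_lookup_error")
    }
    # lenient: retry by 4-character stem, then warn and contribute 0
    stem_idx <- match(substr(missing_codes, 1, 4), table$code)
    still_missing <- missing_codes[is.na(stem_idx)]
    if (length(still_missing) > 0) {
      warning(sprintf("unknown H-code(s) contribute 0 penalty points: %s",
                      paste(still_missing, collapse = ", ")),
              call. = FALSE)
    }
    idx[is.na(idx)] <- stem_idx
  }
  as.integer(sum(table$points[idx[!is.na(idx)]]))
}
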