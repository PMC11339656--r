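# Weighted aggregation of the 12 criterion scores into the overall score.

.default_weights <- c(1L, 2L, 1L, 3L, 4L, 3L, 2L, 3L, 1L, 4L, 3L, 3L)

#' Default criterion weights
#'
#' The suggested expert weights, one integer per criterion on a four-point
#' scale. The highest weights (4) go to the porogen (criterion 5) and the
#' template elution solvent (criterion 10) — the two stages that consume
#' large solvent amounts; the lowest (1) to inhibitor removal, template
#' amount, and particle size.
#'
#' @return Named integer vector of length 12.
#' @examples
#' default_weights()
#' @export
default_weights <- function() {
  stats::setNames(.default_weights, paste0("c", 1:12))
}

#' Validate a weight vector
#'
#' Weights express the relative importance of the 12 criteria on a
#' four-point scale (integers 1-4). User-modified schemes carry provenance
#' `"user"` and may carry a justification string, which is echoed into
#' assessment reports: users changing the defaults are advised to justify
#' the change.
#'
#' @param weights Candidate 12-tuple of integers in 1-4; `NULL` selects the
#'   default scheme.
#' @param justification Optional free-text justification for a user scheme.
#' @return A `weight_scheme` list with `weights`, `provenance`, and
#'   `justification`.
#' @examples
#' validate_weights()                  # default scheme
#' validate_weights(rep(2, 12), "all criteria equally important")
#' @export
validate_weights <- function(weights = NULL, justification = NULL) {
  if (is.null(weights)) {
    return(structure(list(weights = default_weights(), provenance = "default",
                          justification = NULL),
                     class = "weight_scheme"))
  }
  if (inherits(weights, "weight_scheme")) return(weights)
  w <- suppressWarnings(as.numeric(unlist(weights, use.names = FALSE)))
  problems <- character()
  if (length(w) != 12) {
    problems <- c(problems, sprintf("expected 12 weights, got %d", length(w)))
  }
  bad <- which(is.na(w) | w != floor(w) | w < 1 | w > 4)
  if (length(w) == 12 && length(bad) > 0) {
    problems <- c(problems,
                  sprintf("weight(s) at position %s outside the integer 1-4 scale: %s",
                          paste(bad, collapse = ", "),
                          paste(w[bad], collapse = ", ")))
  }
  if (length(problems) > 0) {
    mip_error(paste(problems, collapse = "; "), "mipgreen_validation_error")
  }
  w <- as.integer(w)
  provenance <- if (identical(w, .default_weights)) "default" else "user"
  structure(list(weights = stats::setNames(w, paste0("c", 1:12)),
                 provenance = provenance, justification = justification),
            class = "weight_scheme")
}

#' Overall greenness score: the weighted average of the 12 criterion scores
#'
#' overall = sum(w_i * s_i) / sum(w_i). The overall score is kept at full
#' floating precision internally; `display_overall` is its two-decimal
#' rounding, used everywhere the score is printed. Because the weighted
#' average is normalized, the overall score always lies between the smallest
#' and largest criterion score.
#'
#' @param scores Numeric vector of 12 scores in \[0, 1\], or a list of 12
#'   [criterion_score()] objects (in criterion order).
#' @param weights A `weight_scheme`, a 12-tuple of integers in 1-4, or `NULL`
#'   for the defaults.
#' @return An `assessment_result` list with `scores`, `criterion_scores`
#'   (if given), `weights`, `overall`, and `display_overall`.
#' @examples
#' overall_score(rep(1, 12))$display_overall  # 1
#' overall_score(c(1, rep(0, 11)))$overall    # w1 / sum(w)
#' @export
overall_score <- function(scores, weights = NULL) {
  criterion_scores <- NULL
  if (is.list(scores) && all(vapply(scores, inherits, logical(1), "criterion_score"))) {
    criterion_scores <- scores
    ids <- vapply(scores, `[[`, integer(1), "criterion_id")
    if (!identical(sort(ids), 1:12)) {
      mip_error("need one criterion_score for each criterion 1..12",
                "mipgreen_validation_error")
    }
    scores <- vapply(scores[order(ids)], `[[`, numeric(1), "score")
    criterion_scores <- criterion_scores[order(ids)]
  }
  if (!is.numeric(scores) || length(scores) != 12 || anyNA(scores) ||
      any(scores < 0) || any(scores > 1)) {
    mip_error("scores must be 12 values in [0, 1]", "mipgreen_validation_error")
  }
  scheme <- validate_weights(weights)
  w <- as.numeric(scheme$weights)
  overall <- sum(w * scores) / sum(w)
  structure(list(scores = stats::setNames(scores, paste0("c", 1:12)),
                 criterion_scores = criterion_scores,
                 weights = scheme,
                 overall = overall,
                 display_overall = round_score(overall)),
            class = "assessment_result")
}

#' @export
print.assessment_result <- function(x, ...) {
  cat("Greenness assessment (12 criteria)\n")
  for (i in 1:12) {
    detail <- if (!is.null(x$criterion_scores)) x$criterion_scores[[i]]$detail else ""
    cat(sprintf("  c%-2d  score %.2f  weight %d  %s\n",
                i, x$scores[[i]], x$weights$weights[[i]], detail))
  }
  cat(sprintf("  overall (weighted average, %s weights): %.2f\n",
              x$weights$provenance, x$display_overall))
  invisible(x)
}
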