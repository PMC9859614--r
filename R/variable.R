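#' Linguistic variable
#'
#' A clinical factor together with its five linguistic terms (L, LA, A, HA, H
#' — low, lower than average, average, higher than average, high), each
#' formalised by a membership function sharing the variable's domain.
#'
#' @param factor_id identifier, e.g. `"X1"`.
#' @param description free-text meaning of the factor.
#' @param domain numeric pair `c(xmin, xmax)`.
#' @param terms named list of membership functions; names must be exactly
#'   `L, LA, A, HA, H` and each function's domain must equal `domain`.
#' @return An object of class `linguistic_variable`.
#' @export
linguistic_variable <- function(factor_id, description, domain, terms) {
  domain <- as.numeric(domain)
  if (!identical(sort(names(terms)), sort(TERM_LABELS)) ||
      length(terms) != 5L) {
    fc_stop(sprintf("variable %s must have exactly the five terms %s",
                    factor_id, paste(TERM_LABELS, collapse = ", ")),
            "fuzzycad_contract_error")
  }
  terms <- terms[TERM_LABELS]
  for (lab in TERM_LABELS) {
    if (!inherits(terms[[lab]], "fuzzycad_mf")) {
      fc_stop(sprintf("term %s of %s is not a membership function", lab, factor_id),
              "fuzzycad_contract_error")
    }
    if (any(abs(mf_domain(terms[[lab]]) - domain) > 1e-9)) {
      fc_stop(sprintf("term %s of %s has a domain different from the variable",
                      lab, factor_id),
              "fuzzycad_contract_error")
    }
  }
  structure(list(factor_id = factor_id, description = description,
                 domain = domain, terms = terms),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  kinds <- vapply(x$terms, function(mf) class(mf)[1], character(1))
  cat(sprintf("Linguistic variable %s on [%g, %g]: %s\n", x$factor_id,
              x$domain[1], x$domain[2], x$description))
  cat("  terms:", paste(sprintf("%s (%s)", names(kinds), kinds), collapse = ", "),
      "\n")
  invisible(x)
}

#' Consistency diagnostics for a linguistic variable
#'
#' Published piecewise-linear coefficients are rounded, so adjacent segments
#' of a term need not agree at their shared breakpoint and term peaks need not
#' reach exactly 1. This diagnostic quantifies both effects: for every
#' interior breakpoint of every piecewise term it reports the post-clamp jump
#' between the left-segment limit and the value actually returned (the right
#' segment wins under the half-open convention), flagging jumps above
#' `jump_tol`; it reports each term's peak location and value on a grid; and
#' it reports coverage, the minimum over the grid of the maximum degree across
#' the five terms.
#'
#' @param var a [linguistic_variable()].
#' @param grid_step grid spacing for peak and coverage evaluation.
#' @param jump_tol post-clamp discontinuities larger than this are flagged.
#' @return A list of class `variable_consistency` with elements `factor_id`,
#'   `breakpoints` (data frame: term, x, left, right, jump, flagged),
#'   `peaks` (data frame: term, x, value) and `coverage` (scalar).
#' @export
check_variable_consistency <- function(var, grid_step = 1e-3, jump_tol = 0.05) {
  stopifnot(inherits(var, "linguistic_variable"))
  dom <- var$domain
  grid <- seq(dom[1], dom[2], by = grid_step)
  if (grid[length(grid)] < dom[2]) grid <- c(grid, dom[2])

  bp <- do.call(rbind, lapply(TERM_LABELS, function(lab) {
    mf <- var$terms[[lab]]
    if (!inherits(mf, "piecewise_mf") || nrow(mf$segments) < 2L) return(NULL)
    seg <- mf$segments
    n <- nrow(seg)
    xs <- seg$upper[-n]                 # interior breakpoints
    left <- pmin(1, pmax(0, seg$slope[-n] * xs + seg$intercept[-n]))
    right <- pmin(1, pmax(0, seg$slope[-1L] * xs + seg$intercept[-1L]))
    data.frame(term = lab, x = xs, left = left, right = right,
               jump = abs(right - left))
  }))
  if (is.null(bp)) {
    bp <- data.frame(term = character(), x = numeric(), left = numeric(),
                     right = numeric(), jump = numeric())
  }
  bp$flagged <- bp$jump > jump_tol

  degrees <- vapply(TERM_LABELS,
                    function(lab) evaluate_mf(var$terms[[lab]], grid),
                    numeric(length(grid)))
  peak_idx <- apply(degrees, 2, which.max)
  peaks <- data.frame(term = TERM_LABELS,
                      x = grid[peak_idx],
                      value = degrees[cbind(peak_idx, seq_len(5L))])
  structure(list(factor_id = var$factor_id, breakpoints = bp, peaks = peaks,
                 coverage = min(apply(degrees, 1, max))),
            class = "variable_consistency")
}

#' @export
print.variable_consistency <- function(x, ...) {
  cat(sprintf("Consistency report for %s\n", x$factor_id))
  cat(sprintf("  coverage (min over grid of max over terms): %.4f\n", x$coverage))
  cat("  peaks:\n")
  print(x$peaks, row.names = FALSE)
  n_flag <- sum(x$breakpoints$flagged)
  if (n_flag > 0) {
    cat(sprintf("  %d breakpoint discontinuit%s flagged:\n", n_flag,
                if (n_flag == 1) "y" else "ies"))
    print(x$breakpoints[x$breakpoints$flagged, ], row.names = FALSE)
  } else {
    cat("  no breakpoint discontinuities flagged\n")
  }
  invisible(x)
}
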