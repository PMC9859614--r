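#' Piecewise-linear membership function
#'
#' Constructs a membership function made of contiguous linear segments over a
#' closed factor domain. Segments follow the half-open convention `[lower,
#' upper)`: at an interior breakpoint the right-hand segment applies; only the
#' final segment is closed at its upper end. Raw linear values are clamped to
#' `[0, 1]` at evaluation time, so slightly over- or under-shooting
#' coefficients (as arise from rounding) are tolerated.
#'
#' @param segments data frame with columns `lower`, `upper`, `slope`,
#'   `intercept`, one row per segment, sorted by `lower`, contiguous.
#' @param domain numeric length-2 vector `c(xmin, xmax)`; must coincide with
#'   the segments' joint support.
#' @return An object of class `c("piecewise_mf", "fuzzycad_mf")`.
#' @seealso [bell_mf()], [evaluate_mf()]
#' @export
#' @examples
#' mf <- piecewise_mf(
#'   data.frame(lower = c(0, 1), upper = c(1, 2),
#'              slope = c(1, -1), intercept = c(0, 2)),
#'   domain = c(0, 2))
#' evaluate_mf(mf, c(0.5, 1, 1.5))
piecewise_mf <- function(segments, domain) {
  segments <- as.data.frame(segments)
  needed <- c("lower", "upper", "slope", "intercept")
  if (!all(needed %in% names(segments))) {
    fc_stop("segments must have columns lower, upper, slope, intercept",
            "fuzzycad_contract_error")
  }
  segments <- segments[order(segments$lower), needed, drop = FALSE]
  rownames(segments) <- NULL
  n <- nrow(segments)
  if (n < 1L) fc_stop("at least one segment required", "fuzzycad_contract_error")
  if (any(segments$lower >= segments$upper)) {
    fc_stop("every segment needs lower < upper", "fuzzycad_contract_error")
  }
  if (n > 1L) {
    gaps <- segments$lower[-1L] - segments$upper[-n]
    if (any(abs(gaps) > 1e-9)) {
      fc_stop("segments must be contiguous (no gaps or overlaps)",
              "fuzzycad_contract_error")
    }
    # snap to exact contiguity so segment selection is unambiguous
    segments$lower[-1L] <- segments$upper[-n]
  }
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2]) {
    fc_stop("domain must be a finite pair (xmin, xmax) with xmin < xmax",
            "fuzzycad_contract_error")
  }
  if (abs(segments$lower[1L] - domain[1]) > 1e-9 ||
      abs(segments$upper[n] - domain[2]) > 1e-9) {
    fc_stop("segments must jointly cover the domain exactly",
            "fuzzycad_contract_error")
  }
  segments$lower[1L] <- domain[1]
  segments$upper[n] <- domain[2]
  structure(list(segments = segments, domain = domain),
            class = c("piecewise_mf", "fuzzycad_mf"))
}

#' Generalised bell membership function
#'
#' The bell form `1 / (1 + ((x - b) / c)^2)` used by the tuning procedure:
#' `b` is the coordinate of the peak (membership exactly 1 at `x = b`) and
#' `c > 0` controls compression/extension (the half-width at membership 0.5).
#'
#' @param b peak coordinate.
#' @param c spread parameter, strictly positive.
#' @param domain numeric length-2 vector `c(xmin, xmax)`.
#' @return An object of class `c("bell_mf", "fuzzycad_mf")`.
#' @export
#' @examples
#' evaluate_mf(bell_mf(2, 0.5, c(0, 4)), c(1.5, 2, 2.5))
bell_mf <- function(b, c, domain) {
  domain <- as.numeric(domain)
  if (length(domain) != 2L || domain[1] >= domain[2]) {
    fc_stop("domain must be a pair (xmin, xmax) with xmin < xmax",
            "fuzzycad_contract_error")
  }
  if (!is.finite(b) || !is.finite(c) || c <= 0) {
    fc_stop("bell_mf requires finite b and c > 0", "fuzzycad_contract_error")
  }
  structure(list(b = as.numeric(b), c = as.numeric(c), domain = domain),
            class = c("bell_mf", "fuzzycad_mf"))
}

#' Evaluate a membership function
#'
#' Returns the membership degree of `x`, a number in `[0, 1]`. For
#' piecewise-linear functions the unique segment containing `x` is selected
#' under the half-open convention (right segment wins at interior breakpoints,
#' final segment closed) and the linear value is clamped to `[0, 1]`.
#'
#' @param mf a membership function created by [piecewise_mf()] or [bell_mf()].
#' @param x numeric vector of factor values.
#' @param out_of_range `"error"` (default) signals a domain violation for any
#'   `x` outside the domain; `"clamp_to_domain"` evaluates at the nearest
#'   domain boundary instead.
#' @return numeric vector of degrees in `[0, 1]`, same length as `x`.
#' @export
evaluate_mf <- function(mf, x, out_of_range = c("error", "clamp_to_domain")) {
  UseMethod("evaluate_mf")
}

check_domain <- function(x, domain, out_of_range, what = "x") {
  if (any(!is.finite(x))) {
    fc_stop(sprintf("%s must be finite", what), "fuzzycad_contract_error")
  }
  out <- x < domain[1] | x > domain[2]
  if (any(out)) {
    if (out_of_range == "error") {
      fc_stop(sprintf("%s = %s outside domain [%g, %g]", what,
                      paste(format(x[out][1]), collapse = ", "),
                      domain[1], domain[2]),
              "fuzzycad_domain_error")
    }
    x <- pmin(pmax(x, domain[1]), domain[2])
  }
  x
}

#' @export
evaluate_mf.piecewise_mf <- function(mf, x,
                                     out_of_range = c("error", "clamp_to_domain")) {
  out_of_range <- match.arg(out_of_range)
  x <- check_domain(x, mf$domain, out_of_range)
  seg <- mf$segments
  breaks <- c(seg$lower[1L], seg$upper)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  pmin(1, pmax(0, seg$slope[idx] * x + seg$intercept[idx]))
}

#' @export
evaluate_mf.bell_mf <- function(mf, x,
                                out_of_range = c("error", "clamp_to_domain")) {
  out_of_range <- match.arg(out_of_range)
  x <- check_domain(x, mf$domain, out_of_range)
  1 / (1 + ((x - mf$b) / mf$c)^2)
}

#' @export
print.piecewise_mf <- function(x, ...) {
  cat(sprintf("Piecewise-linear membership function on [%g, %g], %d segment(s)\n",
              x$domain[1], x$domain[2], nrow(x$segments)))
  print(x$segments)
  invisible(x)
}

#' @export
print.bell_mf <- function(x, ...) {
  cat(sprintf("Bell membership function on [%g, %g]: b = %g, c = %g\n",
              x$domain[1], x$domain[2], x$b, x$c))
  invisible(x)
}

mf_domain <- function(mf) mf$domain
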