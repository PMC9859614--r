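#' Combiner configuration for the inference engine
#'
#' Bundles the logical operators and policies the engine uses. The defaults —
#' `min` for AND, `max` for OR, hard error on out-of-domain inputs, lowest
#' class index on ties — reproduce the published decision algorithm, in which
#' conjunction and disjunction over membership degrees are carried out by the
#' operations min and max.
#'
#' @param t_norm fuzzy conjunction: `"min"` (default) or `"product"`.
#' @param s_norm fuzzy disjunction: `"max"` (default) or `"prob_sum"`
#'   (probabilistic sum, `1 - prod(1 - v)`).
#' @param out_of_range `"error"` (default) or `"clamp_to_domain"`.
#' @param tie_break `"lowest_index"` (default) or `"report_all"`.
#' @return An object of class `combiner_config`.
#' @export
combiner_config <- function(t_norm = c("min", "product"),
                            s_norm = c("max", "prob_sum"),
                            out_of_range = c("error", "clamp_to_domain"),
                            tie_break = c("lowest_index", "report_all")) {
  structure(list(t_norm = match.arg(t_norm),
                 s_norm = match.arg(s_norm),
                 out_of_range = match.arg(out_of_range),
                 tie_break = match.arg(tie_break)),
            class = "combiner_config")
}

#' @export
print.combiner_config <- function(x, ...) {
  cat(sprintf("Combiners: AND = %s, OR = %s; out-of-range = %s; ties = %s\n",
              x$t_norm, x$s_norm, x$out_of_range, x$tie_break))
  invisible(x)
}

check_degrees <- function(degrees) {
  if (length(degrees) == 0L) {
    fc_stop("degree list must be non-empty", "fuzzycad_contract_error")
  }
  if (any(!is.finite(degrees)) || any(degrees < 0) || any(degrees > 1)) {
    fc_stop("degrees must lie in [0, 1]", "fuzzycad_contract_error")
  }
  degrees
}

#' Fuzzy conjunction and disjunction
#'
#' `combine_and()` aggregates degrees with a t-norm (`min` or `product`);
#' `combine_or()` aggregates with an s-norm (`max` or probabilistic sum).
#' Inputs must be a non-empty vector of degrees in `[0, 1]`.
#'
#' @param degrees numeric vector of membership degrees in `[0, 1]`.
#' @param t_norm,s_norm operator name, see [combiner_config()].
#' @return a single degree in `[0, 1]`.
#' @export
#' @examples
#' combine_and(c(0.818, 0.7, 1.0, 0.8325), "min")
#' combine_or(c(0.3, 0.4), "prob_sum")
combine_and <- function(degrees, t_norm = c("min", "product")) {
  t_norm <- match.arg(t_norm)
  degrees <- check_degrees(degrees)
  if (t_norm == "min") min(degrees) else prod(degrees)
}

#' @rdname combine_and
#' @export
combine_or <- function(degrees, s_norm = c("max", "prob_sum")) {
  s_norm <- match.arg(s_norm)
  degrees <- check_degrees(degrees)
  if (s_norm == "max") max(degrees) else 1 - prod(1 - degrees)
}

#' Map a factor value onto the common universe U = [0, 4]
#'
#' Linguistic terms are defined on a shared universe `U = [0, 4]`; a factor
#' value is carried onto it by the affine map
#' `u = 4 (x - xmin) / (xmax - xmin)`. `denormalize_from_u()` is the inverse.
#'
#' @param x factor value(s).
#' @param u universe value(s) in `[0, 4]`.
#' @param domain numeric pair `c(xmin, xmax)` with `xmin < xmax`.
#' @return numeric vector.
#' @export
#' @examples
#' normalize_to_u(2.295, c(1.83, 2.76))   # 2
#' denormalize_from_u(4, c(1.83, 2.76))   # 2.76
normalize_to_u <- function(x, domain) {
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2]) {
    fc_stop("degenerate domain: xmin must be < xmax", "fuzzycad_contract_error")
  }
  4 * (x - domain[1]) / (domain[2] - domain[1])
}

#' @rdname normalize_to_u
#' @export
denormalize_from_u <- function(u, domain) {
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2]) {
    fc_stop("degenerate domain: xmin must be < xmax", "fuzzycad_contract_error")
  }
  domain[1] + u / 4 * (domain[2] - domain[1])
}

#' Centre-of-gravity defuzzification
#'
#' Converts a discretised fuzzy set into a crisp value: the membership-weighted
#' mean `sum(u * mu) / sum(mu)`. All-zero memberships leave the centroid
#' undefined and signal an error rather than returning a default.
#'
#' @param universe numeric vector of support points.
#' @param degrees numeric vector of membership degrees, same length.
#' @return crisp value within `[min(universe), max(universe)]`.
#' @export
#' @examples
#' defuzzify_cog(c(0, 1, 2, 3), c(0.2, 0.4, 0.4, 0.2))  # 1.5
defuzzify_cog <- function(universe, degrees) {
  if (length(universe) != length(degrees) || length(universe) < 1L) {
    fc_stop("universe and degrees must have equal length >= 1",
            "fuzzycad_contract_error")
  }
  check_degrees(degrees)
  total <- sum(degrees)
  if (total == 0) {
    fc_stop("all membership degrees are zero: centroid undefined",
            "fuzzycad_undefined_centroid")
  }
  sum(universe * degrees) / total
}
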