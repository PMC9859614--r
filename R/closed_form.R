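#' Closed-form class membership (hand-coded model equations)
#'
#' Evaluates the degree of membership of a patient vector in one clinical
#' class by writing out that class's union of conjunctions literally, term by
#' term, rather than iterating over a rule table. This duplicates the generic
#' engine on purpose: it serves as an independent oracle for
#' [class_memberships()], and the two must agree exactly for every in-domain
#' input and both combiner configurations.
#'
#' The conjunctions follow the canonical rule table (class III rows
#' HA/LA/HA/HA, HA/LA/HA/H and L/A/HA/H).
#'
#' @param x numeric vector of the four factor values `(x1, x2, x3, x4)`.
#' @param class one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param config a [combiner_config()].
#' @param kb knowledge base supplying the membership functions; defaults to
#'   [default_knowledge_base()].
#' @return a single membership degree in `[0, 1]`.
#' @export
#' @examples
#' closed_form_class_membership(c(2.15, 2.50, 1.00, 2.50), "II")
closed_form_class_membership <- function(x, class = CLASS_LABELS,
                                         config = combiner_config(),
                                         kb = default_knowledge_base()) {
  class <- match.arg(class)
  x <- as.numeric(x)
  if (length(x) != 4L) {
    fc_stop("x must be a 4-vector (x1, x2, x3, x4)", "fuzzycad_contract_error")
  }
  d <- function(term, i) {
    evaluate_mf(kb$variables[[i]]$terms[[term]], x[i],
                out_of_range = config$out_of_range)
  }
  AND <- function(...) combine_and(c(...), config$t_norm)
  OR <- function(...) combine_or(c(...), config$s_norm)
  switch(class,
    I = OR(AND(d("HA", 1), d("A", 2), d("L", 3), d("A", 4)),
           AND(d("HA", 1), d("HA", 2), d("L", 3), d("A", 4)),
           AND(d("HA", 1), d("HA", 2), d("L", 3), d("HA", 4))),
    II = OR(AND(d("LA", 1), d("A", 2), d("L", 3), d("H", 4)),
            AND(d("A", 1), d("HA", 2), d("L", 3), d("LA", 4)),
            AND(d("LA", 1), d("HA", 2), d("L", 3), d("LA", 4)),
            AND(d("A", 1), d("L", 2), d("L", 3), d("LA", 4))),
    III = OR(AND(d("HA", 1), d("LA", 2), d("HA", 3), d("HA", 4)),
             AND(d("HA", 1), d("LA", 2), d("HA", 3), d("H", 4)),
             AND(d("L", 1), d("A", 2), d("HA", 3), d("H", 4))),
    IV = OR(AND(d("L", 1), d("L", 2), d("A", 3), d("A", 4)),
            AND(d("LA", 1), d("L", 2), d("A", 3), d("A", 4)),
            AND(d("L", 1), d("LA", 2), d("LA", 3), d("LA", 4)),
            AND(d("LA", 1), d("LA", 2), d("LA", 3), d("LA", 4))))
}
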