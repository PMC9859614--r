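#' Knowledge base container
#'
#' A knowledge base couples the linguistic variables (one per clinical factor)
#' with a weighted rule list. Each rule maps a complete antecedent — one term
#' per factor — to one of the four clinical forms of coronary artery disease
#' (I = NSTEMI, II = UAP, III = STEMI, IV = StAP) with a weight in `[0, 1]`
#' (weight 1 unless tuned).
#'
#' @param variables named list of [linguistic_variable()] objects, names are
#'   the factor ids.
#' @param rules data frame with one column per factor id holding term labels,
#'   plus columns `class` (one of I, II, III, IV) and `weight`.
#' @param metadata free-text provenance string.
#' @return An object of class `knowledge_base`.
#' @seealso [default_knowledge_base()], [validate_knowledge_base()]
#' @export
knowledge_base <- function(variables, rules, metadata = "") {
  if (length(variables) == 0L || is.null(names(variables))) {
    fc_stop("variables must be a named list", "fuzzycad_contract_error")
  }
  for (id in names(variables)) {
    if (!inherits(variables[[id]], "linguistic_variable")) {
      fc_stop(sprintf("variable %s is not a linguistic_variable", id),
              "fuzzycad_contract_error")
    }
  }
  rules <- as.data.frame(rules)
  ids <- names(variables)
  missing_cols <- setdiff(c(ids, "class", "weight"), names(rules))
  if (length(missing_cols)) {
    fc_stop(sprintf("rules lack column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "fuzzycad_validation_error")
  }
  extra <- setdiff(names(rules), c(ids, "class", "weight"))
  if (length(extra)) {
    fc_stop(sprintf("rules reference undefined factor(s): %s",
                    paste(extra, collapse = ", ")),
            "fuzzycad_validation_error")
  }
  rules <- rules[, c(ids, "class", "weight")]
  for (id in ids) {
    bad <- !rules[[id]] %in% TERM_LABELS
    if (any(bad)) {
      fc_stop(sprintf("rule %d has unknown term '%s' for %s",
                      which(bad)[1], rules[[id]][bad][1], id),
              "fuzzycad_validation_error")
    }
  }
  if (!all(rules$class %in% CLASS_LABELS)) {
    fc_stop("rule consequents must be one of I, II, III, IV",
            "fuzzycad_validation_error")
  }
  if (any(!is.finite(rules$weight)) || any(rules$weight < 0) ||
      any(rules$weight > 1)) {
    fc_stop("rule weights must lie in [0, 1]", "fuzzycad_validation_error")
  }
  rownames(rules) <- NULL
  structure(list(variables = variables, rules = rules, metadata = metadata),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("Fuzzy knowledge base\n")
  if (nzchar(x$metadata)) cat(" ", x$metadata, "\n")
  cat(sprintf("  %d variables: %s\n", length(x$variables),
              paste(names(x$variables), collapse = ", ")))
  tab <- table(factor(x$rules$class, levels = CLASS_LABELS))
  cat(sprintf("  %d rules (%s)\n", nrow(x$rules),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

pw <- function(domain, ...) {
  segs <- list(...)
  piecewise_mf(data.frame(lower = vapply(segs, `[`, 0, 1),
                          upper = vapply(segs, `[`, 0, 2),
                          slope = vapply(segs, `[`, 0, 3),
                          intercept = vapply(segs, `[`, 0, 4)),
               domain)
}

#' The published coronary-lesion knowledge base
#'
#' Builds the complete clinical model: four angiographic lesion factors
#' (X1 — atherosclerotic plaques in the basin of the diagonal branch or left
#' anterior descending artery; X2 — hemodynamically significant stenosis in
#' that basin; X3 — hemodynamically significant stenosis of the right coronary
#' artery trunk; X4 — absence of hemodynamically significant stenosis of the
#' coronary arteries), each with five piecewise-linear terms transcribed from
#' the published formulas, and the fourteen-rule base (3 rules for class I,
#' 4 for II, 3 for III, 4 for IV), all weights 1.
#'
#' @return A [knowledge_base()] object.
#' @export
#' @examples
#' kb <- default_knowledge_base()
#' kb
#' class_memberships(c(x1 = 2.15, x2 = 2.50, x3 = 1.00, x4 = 2.50), kb)
default_knowledge_base <- function() {
  d1 <- c(1.83, 2.76); d2 <- c(1.74, 3.0); d3 <- c(1.0, 2.35); d4 <- c(2.07, 4.67)
  variables <- list(
    X1 = linguistic_variable(
      "X1", "Presence of a/p on the territory of DG or LAD LCA", d1,
      list(
        L  = pw(d1, c(1.83, 2.06, -2.17, 4.97), c(2.06, 2.76, -0.71, 1.97)),
        LA = pw(d1, c(1.83, 2.06, 2.17, -3.48), c(2.06, 2.30, -2.08, 5.29),
                    c(2.30, 2.76, -1.09, 3.00)),
        A  = pw(d1, c(1.83, 2.30, 2.13, -3.89), c(2.30, 2.76, -2.17, 6.00)),
        HA = pw(d1, c(1.83, 2.30, 1.06, -1.94), c(2.30, 2.53, 2.17, -4.50),
                    c(2.53, 2.76, -2.17, 6.50)),
        H  = pw(d1, c(1.83, 2.53, 0.71, -1.31), c(2.53, 2.76, 2.17, -5.00)))),
    X2 = linguistic_variable(
      "X2", "Presence of HSS on the territory of DG or LAD LCA", d2,
      list(
        L  = pw(d2, c(1.74, 2.06, -1.56, 3.72), c(2.06, 3.00, -0.53, 1.60)),
        LA = pw(d2, c(1.74, 2.06, 1.56, -2.22), c(2.06, 2.37, -1.61, 4.30),
                    c(2.37, 3.00, -0.79, 2.38)),
        A  = pw(d2, c(1.74, 2.30, 1.59, -2.76), c(2.30, 3.00, -1.59, 4.76)),
        HA = pw(d2, c(1.74, 2.37, 0.79, -1.38), c(2.37, 2.69, 1.56, -3.20),
                    c(2.69, 3.00, -1.61, 5.34)),
        H  = pw(d2, c(1.74, 2.53, 0.53, -0.92), c(2.53, 3.00, 1.61, -3.84)))),
    X3 = linguistic_variable(
      "X3", "Presence of HSS in the trunk of the RCA", d3,
      list(
        L  = pw(d3, c(1.00, 1.34, -1.47, 2.47), c(1.34, 2.35, -0.495, 1.16)),
        LA = pw(d3, c(1.00, 1.34, 1.47, -0.97), c(1.34, 1.68, -1.47, 2.97),
                    c(1.68, 2.35, -0.74, 1.75)),
        A  = pw(d3, c(1.00, 1.68, 1.47, -1.47), c(1.68, 2.35, -1.49, 3.50)),
        HA = pw(d3, c(1.00, 1.68, 0.73, -0.73), c(1.68, 2.02, 1.47, -1.97),
                    c(2.02, 2.35, -1.52, 4.06)),
        H  = pw(d3, c(1.00, 2.02, 0.49, -0.49), c(2.02, 2.35, 1.52, -2.56)))),
    X4 = linguistic_variable(
      "X4", "Absence of HSS CA", d4,
      list(
        L  = pw(d4, c(2.07, 2.72, -0.769, 2.59), c(2.72, 4.67, -0.26, 1.197)),
        LA = pw(d4, c(2.07, 2.72, 0.769, -1.09), c(2.72, 3.37, -0.769, 3.09),
                    c(3.37, 4.67, -0.38, 1.796)),
        A  = pw(d4, c(2.07, 3.37, 0.769, -1.59), c(3.37, 4.67, -0.769, 3.59)),
        HA = pw(d4, c(2.07, 3.37, 0.38, -0.796), c(3.37, 4.02, 0.769, -2.09),
                    c(4.02, 4.67, -0.769, 4.09)),
        H  = pw(d4, c(2.07, 4.02, 0.25, -0.53), c(4.02, 4.67, 0.769, -2.59)))))

  rule <- function(x1, x2, x3, x4, class) {
    data.frame(X1 = x1, X2 = x2, X3 = x3, X4 = x4, class = class, weight = 1)
  }
  rules <- rbind(
    rule("HA", "A",  "L",  "A",  "I"),
    rule("HA", "HA", "L",  "A",  "I"),
    rule("HA", "HA", "L",  "HA", "I"),
    rule("LA", "A",  "L",  "H",  "II"),
    rule("A",  "HA", "L",  "LA", "II"),
    rule("LA", "HA", "L",  "LA", "II"),
    rule("A",  "L",  "L",  "LA", "II"),
    rule("HA", "LA", "HA", "HA", "III"),
    rule("HA", "LA", "HA", "H",  "III"),
    rule("L",  "A",  "HA", "H",  "III"),
    rule("L",  "L",  "A",  "A",  "IV"),
    rule("LA", "L",  "A",  "A",  "IV"),
    rule("L",  "LA", "LA", "LA", "IV"),
    rule("LA", "LA", "LA", "LA", "IV"))

  knowledge_base(variables, rules,
                 metadata = "Coronary artery lesion grading model, four factors, fourteen rules")
}

#' Validate a knowledge base
#'
#' Structural diagnostics beyond what the constructor enforces: duplicate rule
#' rows, classes not covered by any rule, factors unused by any rule, and a
#' per-factor consistency report (see [check_variable_consistency()]).
#'
#' @param kb a [knowledge_base()].
#' @param grid_step,jump_tol forwarded to [check_variable_consistency()].
#' @return A list of class `kb_validation` with elements `duplicate_rules`
#'   (integer row indices), `uncovered_classes`, `unused_factors`,
#'   `consistency` (named list of reports) and logical `ok` (no duplicates and
#'   full class coverage).
#' @export
validate_knowledge_base <- function(kb, grid_step = 1e-3, jump_tol = 0.05) {
  stopifnot(inherits(kb, "knowledge_base"))
  ids <- names(kb$variables)
  key <- do.call(paste, c(kb$rules[c(ids, "class")], sep = "|"))
  duplicate_rules <- which(duplicated(key))
  uncovered_classes <- setdiff(CLASS_LABELS, unique(kb$rules$class))
  used <- ids[vapply(ids, function(id) any(!is.na(kb$rules[[id]])), logical(1))]
  unused_factors <- setdiff(ids, used)
  consistency <- lapply(kb$variables, check_variable_consistency,
                        grid_step = grid_step, jump_tol = jump_tol)
  structure(list(duplicate_rules = duplicate_rules,
                 uncovered_classes = uncovered_classes,
                 unused_factors = unused_factors,
                 consistency = consistency,
                 ok = length(duplicate_rules) == 0L &&
                      length(uncovered_classes) == 0L),
            class = "kb_validation")
}

#' @export
print.kb_validation <- function(x, ...) {
  cat("Knowledge-base validation:", if (x$ok) "OK" else "issues found", "\n")
  if (length(x$duplicate_rules)) {
    cat("  duplicate rule rows:", paste(x$duplicate_rules, collapse = ", "), "\n")
  }
  if (length(x$uncovered_classes)) {
    cat("  classes with no rules:", paste(x$uncovered_classes, collapse = ", "), "\n")
  }
  if (length(x$unused_factors)) {
    cat("  factors unused by any rule:", paste(x$unused_factors, collapse = ", "), "\n")
  }
  for (rep in x$consistency) {
    n_flag <- sum(rep$breakpoints$flagged)
    cat(sprintf("  %s: coverage %.3f, %d flagged breakpoint(s)\n",
                rep$factor_id, rep$coverage, n_flag))
  }
  invisible(x)
}
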