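as_patient_x <- function(patient, ids) {
  if (is.data.frame(patient)) patient <- unlist(patient[1, , drop = TRUE])
  x <- if (!is.null(names(patient))) {
    nm <- names(patient)
    lower_ids <- tolower(ids)
    got <- match(lower_ids, tolower(nm))
    if (any(is.na(got))) {
      fc_stop(sprintf("patient lacks factor value(s): %s",
                      paste(ids[is.na(got)], collapse = ", ")),
              "fuzzycad_contract_error")
    }
    as.numeric(patient[got])
  } else {
    if (length(patient) != length(ids)) {
      fc_stop(sprintf("patient must supply %d factor values", length(ids)),
              "fuzzycad_contract_error")
    }
    as.numeric(patient)
  }
  if (any(!is.finite(x))) {
    fc_stop("patient factor values must be finite", "fuzzycad_contract_error")
  }
  names(x) <- ids
  x
}

#' Fuzzify a patient record
#'
#' Evaluates every term of every factor at the patient's values, producing the
#' 5 x 4 fuzzification matrix (rows: terms L..H, columns: factors).
#'
#' @param patient numeric vector of factor values, either named (`x1`..`x4` or
#'   the factor ids) or positional in factor order; a one-row data frame also
#'   works.
#' @param kb a [knowledge_base()].
#' @param config a [combiner_config()]; its `out_of_range` policy governs
#'   values outside a factor's domain.
#' @return numeric matrix of degrees in `[0, 1]`, dimnames terms x factors.
#' @export
#' @examples
#' fuzzify(c(x1 = 2.15, x2 = 2.50, x3 = 1.00, x4 = 2.50),
#'         default_knowledge_base())
fuzzify <- function(patient, kb, config = combiner_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  ids <- names(kb$variables)
  x <- as_patient_x(patient, ids)
  degrees <- matrix(NA_real_, nrow = 5L, ncol = length(ids),
                    dimnames = list(TERM_LABELS, ids))
  for (id in ids) {
    var <- kb$variables[[id]]
    xi <- tryCatch(check_domain(x[[id]], var$domain, config$out_of_range,
                                what = id),
                   fuzzycad_domain_error = function(e) {
                     fc_stop(conditionMessage(e), "fuzzycad_domain_error")
                   })
    for (lab in TERM_LABELS) {
      degrees[lab, id] <- evaluate_mf(var$terms[[lab]], xi)
    }
  }
  degrees
}

rule_activations <- function(degrees, kb, config) {
  ids <- names(kb$variables)
  vapply(seq_len(nrow(kb$rules)), function(r) {
    ant <- vapply(ids, function(id) degrees[kb$rules[[id]][r], id], numeric(1))
    kb$rules$weight[r] * combine_and(ant, config$t_norm)
  }, numeric(1))
}

#' Per-class membership degrees for a patient
#'
#' The composition step of the decision algorithm: each rule's activation is
#' its weight times the t-norm of its antecedent degrees, and each class's
#' membership is the s-norm over the activations of that class's rules. With
#' the default min/max operators and unit weights this reproduces the
#' published closed-form class equations exactly.
#'
#' @inheritParams fuzzify
#' @return named numeric vector `c(I=, II=, III=, IV=)` of degrees.
#' @export
#' @examples
#' class_memberships(c(2.15, 2.50, 1.00, 2.50), default_knowledge_base())
class_memberships <- function(patient, kb, config = combiner_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  degrees <- fuzzify(patient, kb, config)
  present <- unique(kb$rules$class)
  missing <- setdiff(CLASS_LABELS, present)
  if (length(missing)) {
    fc_stop(sprintf("class(es) without rules: %s",
                    paste(missing, collapse = ", ")),
            "fuzzycad_config_error")
  }
  act <- rule_activations(degrees, kb, config)
  vapply(setNames(CLASS_LABELS, CLASS_LABELS), function(cl) {
    combine_or(act[kb$rules$class == cl], config$s_norm)
  }, numeric(1))
}

#' Decide the clinical class from membership degrees
#'
#' The decision is the class attaining the maximum membership. Exact ties are
#' resolved towards the lowest class index (I before II before III before IV)
#' and flagged; with `tie_break = "report_all"` every argmax class is listed
#' in `argmax_classes`. When no rule fired at all (all four degrees zero) the
#' result defaults to class I with the tie flag set and `no_rule_fired` noted,
#' or errors under `on_no_rule = "error"`.
#'
#' @param memberships named numeric vector with entries I, II, III, IV in
#'   `[0, 1]`.
#' @param tie_break `"lowest_index"` (default) or `"report_all"`.
#' @param on_no_rule `"warn"` (default) or `"error"` when all degrees are 0.
#' @return A list of class `inference_result`: `memberships`, `decision`,
#'   `decision_name`, `margin` (top minus runner-up), `tie`,
#'   `argmax_classes`, `no_rule_fired`, `winning_rule` (`NA` here; filled by
#'   [infer()]).
#' @export
#' @examples
#' decide(c(I = 0.3325, II = 0.7, III = 0, IV = 0.405))
decide <- function(memberships, tie_break = c("lowest_index", "report_all"),
                   on_no_rule = c("warn", "error")) {
  tie_break <- match.arg(tie_break)
  on_no_rule <- match.arg(on_no_rule)
  if (!all(CLASS_LABELS %in% names(memberships))) {
    fc_stop("memberships must be named with classes I, II, III, IV",
            "fuzzycad_contract_error")
  }
  mu <- as.numeric(memberships[CLASS_LABELS])
  if (any(!is.finite(mu)) || any(mu < 0) || any(mu > 1)) {
    fc_stop("membership degrees must be finite and in [0, 1]",
            "fuzzycad_contract_error")
  }
  names(mu) <- CLASS_LABELS
  top <- max(mu)
  argmax <- CLASS_LABELS[mu == top]
  no_rule_fired <- top == 0
  if (no_rule_fired) {
    if (on_no_rule == "error") {
      fc_stop("no rule fired: all class memberships are zero",
              "fuzzycad_no_rule_fired")
    }
    fc_warn("no rule fired: all class memberships are zero; defaulting to class I",
            "fuzzycad_no_rule_fired")
  }
  decision <- argmax[1L]
  runner_up <- if (length(argmax) > 1L) top else max(mu[mu < top], 0)
  structure(list(memberships = mu,
                 decision = decision,
                 decision_name = unname(CLASS_NAMES[decision]),
                 margin = top - runner_up,
                 tie = length(argmax) > 1L,
                 argmax_classes = if (tie_break == "report_all") argmax else decision,
                 no_rule_fired = no_rule_fired,
                 winning_rule = NA_integer_),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("Decision: class %s (%s), margin %.4f%s\n", x$decision,
              x$decision_name, x$margin,
              if (x$tie) " [tie]" else ""))
  cat("Memberships:\n")
  print(round(x$memberships, 4))
  if (x$no_rule_fired) cat("Note: no rule fired\n")
  invisible(x)
}

#' Run the full decision algorithm for one patient
#'
#' Fuzzification, rule activation, class composition and the maximum-degree
#' decision in one call, including the index of the winning rule (the rule of
#' the decided class whose activation attains that class's membership).
#'
#' @inheritParams fuzzify
#' @inheritParams decide
#' @return An `inference_result` (see [decide()]) with `winning_rule` set.
#' @export
infer <- function(patient, kb, config = combiner_config(),
                  on_no_rule = c("warn", "error")) {
  memberships <- class_memberships(patient, kb, config)
  res <- decide(memberships, tie_break = config$tie_break,
                on_no_rule = on_no_rule)
  degrees <- fuzzify(patient, kb, config)
  act <- rule_activations(degrees, kb, config)
  own <- which(kb$rules$class == res$decision)
  res$winning_rule <- own[which.max(act[own])]
  res
}

#' Classify a cohort of patients
#'
#' Applies [infer()] to every row and, when a `label` column is present,
#' reports agreement (fraction of decisions equal to the label) and the
#' confusion table. Labels come from the data-generating process or an
#' expert; agreement is reported, never asserted.
#'
#' @param patients data frame with columns `x1`..`x4` (case-insensitive,
#'   matching the knowledge base's factor ids), optionally `id` and `label`.
#' @param kb a [knowledge_base()].
#' @param config a [combiner_config()].
#' @return A list of class `cohort_inference`: `results` (data frame with
#'   `id`, `mu_I`..`mu_IV`, `decision`, `margin`, `tie`, `warnings`),
#'   `agreement` (or `NA` without labels) and `confusion` (table or `NULL`).
#' @export
infer_cohort <- function(patients, kb, config = combiner_config()) {
  patients <- as.data.frame(patients)
  if (nrow(patients) == 0L) {
    fc_stop("no records: patient table is empty", "fuzzycad_contract_error")
  }
  ids <- names(kb$variables)
  id_col <- if ("id" %in% names(patients)) as.character(patients$id)
            else as.character(seq_len(nrow(patients)))
  rows <- lapply(seq_len(nrow(patients)), function(i) {
    warn <- character(0)
    res <- withCallingHandlers(
      infer(patients[i, , drop = FALSE], kb, config),
      fuzzycad_warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    data.frame(id = id_col[i],
               mu_I = res$memberships[["I"]], mu_II = res$memberships[["II"]],
               mu_III = res$memberships[["III"]], mu_IV = res$memberships[["IV"]],
               decision = res$decision, margin = res$margin, tie = res$tie,
               warnings = paste(warn, collapse = "; "))
  })
  results <- do.call(rbind, rows)
  agreement <- NA_real_
  confusion <- NULL
  if ("label" %in% names(patients)) {
    lab <- factor(as.character(patients$label), levels = CLASS_LABELS)
    dec <- factor(results$decision, levels = CLASS_LABELS)
    agreement <- mean(dec == lab)
    confusion <- table(label = lab, decision = dec)
  }
  structure(list(results = results, agreement = agreement,
                 confusion = confusion),
            class = "cohort_inference")
}

#' @export
print.cohort_inference <- function(x, ...) {
  cat(sprintf("Cohort inference: %d patient(s)\n", nrow(x$results)))
  if (!is.na(x$agreement)) {
    cat(sprintf("Agreement with labels: %.1f%%\n", 100 * x$agreement))
    print(x$confusion)
  }
  invisible(x)
}
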