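# Stable truncated-normal helpers. The "+/-" of the published group table is
# read as the standard error of the mean, so the per-record sd is se * sqrt(n).

trunc_norm_mean <- function(location, sd, lo, hi) {
  a <- (lo - location) / sd
  b <- (hi - location) / sd
  p <- pnorm(b) - pnorm(a)
  location + sd * (dnorm(a) - dnorm(b)) / p
}

# Location parameter whose truncated-normal mean equals `target` on [lo, hi].
match_location <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi) {
    fc_stop(sprintf("target mean %g not strictly inside [%g, %g]",
                    target, lo, hi),
            "fuzzycad_generation_error")
  }
  f <- function(m) trunc_norm_mean(m, sd, lo, hi) - target
  f0 <- f(target)
  if (is.na(f0) || abs(f0) < 1e-12) return(target)
  dir <- if (f0 < 0) 1 else -1   # truncated mean is increasing in location
  k <- 1; cand <- target
  repeat {
    nxt <- target + dir * k * sd
    fn <- f(nxt)
    if (!is.finite(fn)) break
    cand <- nxt
    if (fn * f0 < 0) break
    k <- 2 * k
    if (k > 2^16) break
  }
  uniroot(f, sort(c(target, cand)), tol = 1e-12)$root
}

rtrunc_norm <- function(n, location, sd, lo, hi) {
  pa <- pnorm(lo, location, sd)
  pb <- pnorm(hi, location, sd)
  if (pb - pa <= 0) {
    fc_stop("truncation bounds exclude all probability mass",
            "fuzzycad_generation_error")
  }
  qnorm(pa + runif(n) * (pb - pa), location, sd)
}

#' Group specification for the synthetic cohort generator
#'
#' One clinical group: its class, size, and per-factor mean and standard
#' error, truncated to the factor domains.
#'
#' @param class one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param n group size, positive integer.
#' @param means,ses numeric length-4 vectors (per factor, in factor order);
#'   `ses` entries must be >= 0 and each mean must lie inside its truncation
#'   bounds.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(class, n, means, ses) {
  class <- match.arg(class, CLASS_LABELS)
  if (length(means) != 4L || length(ses) != 4L) {
    fc_stop("means and ses must have length 4", "fuzzycad_contract_error")
  }
  if (n <= 0) fc_stop("group size must be positive", "fuzzycad_contract_error")
  if (any(ses < 0)) fc_stop("standard errors must be >= 0",
                            "fuzzycad_contract_error")
  structure(list(class = class, n = as.integer(n),
                 means = as.numeric(means), ses = as.numeric(ses)),
            class = "group_spec")
}

#' Cohort specification matching the published group statistics
#'
#' The default describes the study cohort of 165 patients: 90 NSTEMI,
#' 25 UAP, 25 STEMI and 25 StAP, with the published per-factor mean and
#' standard error of each group (UAP has X3 fixed at 1.00 with zero spread).
#'
#' @param groups list of [group_spec()] objects with distinct classes.
#' @param seed default seed used by [generate_synthetic_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_group_specs(), seed = 1L) {
  classes <- vapply(groups, function(g) g$class, character(1))
  if (anyDuplicated(classes)) {
    fc_stop("group classes must be distinct", "fuzzycad_contract_error")
  }
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_group_specs <- function() {
  list(
    group_spec("I",   90, c(2.57, 2.42, 2.23, 3.66), c(0.07, 0.18, 0.12, 0.20)),
    group_spec("II",  25, c(2.15, 2.50, 1.00, 2.50), c(0.13, 0.50, 0.00, 0.43)),
    group_spec("III", 25, c(2.64, 2.08, 2.11, 4.32), c(0.12, 0.23, 0.14, 0.35)),
    group_spec("IV",  25, c(2.00, 2.00, 2.00, 3.64), c(0.17, 0.26, 0.26, 0.43)))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  for (g in x$groups) {
    cat(sprintf("  class %s (%s): n = %d, means %s\n", g$class,
                CLASS_NAMES[g$class], g$n,
                paste(format(g$means), collapse = ", ")))
  }
  invisible(x)
}

#' Generate a seeded synthetic cohort
#'
#' Draws factor values per group from a truncated normal with per-record
#' standard deviation `se * sqrt(n)` (the published "+/-" being the standard
#' error of the mean), truncated to the factor domains. By default the
#' location parameter is moment-matched so that the mean of the truncated
#' distribution equals the published group mean (`mean_match = FALSE` places
#' the location at the published mean instead, in which case truncation
#' biases the realised means towards the domain centre). A zero standard
#' error yields the constant mean. Records are labelled with their generating
#' group; the labels are a property of the simulation, not a claim about the
#' classifier.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param kb knowledge base supplying the factor domains (truncation bounds).
#' @param family `"truncnorm"` (default) or `"uniform"` (uniform with the
#'   same mean and sd, intersected with the domain).
#' @param mean_match moment-match the truncated-normal location (default).
#' @return data frame with columns `id`, `x1`..`x4`, `label`, exactly
#'   `sum(n)` rows.
#' @export
#' @examples
#' cohort <- generate_synthetic_cohort(cohort_spec(seed = 42))
#' nrow(cohort)   # 165
generate_synthetic_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                                      kb = default_knowledge_base(),
                                      family = c("truncnorm", "uniform"),
                                      mean_match = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  family <- match.arg(family)
  ids <- names(kb$variables)
  domains <- lapply(kb$variables, `[[`, "domain")
  set.seed(seed)
  out <- lapply(spec$groups, function(g) {
    vals <- lapply(seq_along(ids), function(i) {
      dom <- domains[[i]]
      m <- g$means[i]; se <- g$ses[i]
      if (m < dom[1] || m > dom[2]) {
        fc_stop(sprintf("group %s mean %g outside domain of %s",
                        g$class, m, ids[i]),
                "fuzzycad_generation_error")
      }
      if (se == 0) return(rep(m, g$n))
      sd <- se * sqrt(g$n)
      if (family == "uniform") {
        lo <- max(dom[1], m - sqrt(3) * sd)
        hi <- min(dom[2], m + sqrt(3) * sd)
        runif(g$n, lo, hi)
      } else {
        loc <- if (mean_match) match_location(m, sd, dom[1], dom[2]) else m
        rtrunc_norm(g$n, loc, sd, dom[1], dom[2])
      }
    })
    df <- as.data.frame(setNames(vals, tolower(ids)))
    df$label <- g$class
    df
  })
  cohort <- do.call(rbind, out)
  cohort <- cbind(id = sprintf("P%03d", seq_len(nrow(cohort))), cohort)
  rownames(cohort) <- NULL
  cohort
}

#' The four group-mean fixture patients
#'
#' One patient per clinical group, at the published group means:
#' NSTEMI (2.57, 2.42, 2.23, 3.66), UAP (2.15, 2.50, 1.00, 2.50),
#' STEMI (2.64, 2.08, 2.11, 4.32), StAP (2.00, 2.00, 2.00, 3.64).
#'
#' @return data frame with columns `id`, `x1`..`x4`, `label`.
#' @export
fixture_patients <- function() {
  specs <- default_group_specs()
  df <- do.call(rbind, lapply(specs, function(g) {
    data.frame(id = unname(CLASS_NAMES[g$class]),
               x1 = g$means[1], x2 = g$means[2],
               x3 = g$means[3], x4 = g$means[4],
               label = g$class)
  }))
  rownames(df) <- NULL
  df
}

#' Descriptive cohort statistics
#'
#' `cohort_percentage(k, n)` is `100 k / n` rounded to one decimal;
#' `cohort_ratio(a, b)` is `a / b` rounded to one decimal;
#' `cohort_summary(counts, total)` tabulates subgroup counts with their
#' percentages of `total`.
#'
#' @param k,a numerator count(s), non-negative.
#' @param n,b,total denominator, strictly positive.
#' @param counts named non-negative counts, each `<= total`.
#' @return `cohort_percentage()` / `cohort_ratio()`: numeric;
#'   `cohort_summary()`: data frame with columns `group`, `count`,
#'   `percentage`.
#' @export
#' @examples
#' cohort_ratio(114, 51)        # 2.2
#' cohort_percentage(114, 165)  # 69.1
cohort_percentage <- function(k, n) {
  if (any(n <= 0)) fc_stop("zero or negative denominator",
                           "fuzzycad_contract_error")
  if (any(k < 0)) fc_stop("counts must be non-negative",
                          "fuzzycad_contract_error")
  round(100 * k / n, 1)
}

#' @rdname cohort_percentage
#' @export
cohort_ratio <- function(a, b) {
  if (any(b <= 0)) fc_stop("zero or negative denominator",
                           "fuzzycad_contract_error")
  round(a / b, 1)
}

#' @rdname cohort_percentage
#' @export
cohort_summary <- function(counts, total) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    fc_stop("counts must be named", "fuzzycad_contract_error")
  }
  if (any(counts < 0) || any(counts > total)) {
    fc_stop("counts must be non-negative and no larger than the total",
            "fuzzycad_contract_error")
  }
  data.frame(group = names(counts),
             count = as.numeric(counts),
             percentage = cohort_percentage(as.numeric(counts), total),
             row.names = NULL)
}
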