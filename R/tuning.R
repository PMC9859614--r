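# Vectorised engine used by the tuning objective: evaluates class
# memberships for a whole matrix of patients at once. Must agree with
# class_memberships() row by row (covered by tests).
eval_class_matrix <- function(X, kb, config) {
  ids <- names(kb$variables)
  n <- nrow(X)
  degrees <- lapply(setNames(ids, ids), function(id) {
    var <- kb$variables[[id]]
    xi <- check_domain(X[, id], var$domain, config$out_of_range, what = id)
    matrix(vapply(var$terms, function(mf) evaluate_mf(mf, xi), numeric(n)),
           nrow = n, dimnames = list(NULL, names(var$terms)))
  })
  acts <- vapply(seq_len(nrow(kb$rules)), function(r) {
    cols <- lapply(ids, function(id) degrees[[id]][, kb$rules[[id]][r]])
    a <- if (config$t_norm == "min") do.call(pmin, cols)
         else Reduce(`*`, cols)
    kb$rules$weight[r] * a
  }, numeric(n))
  acts <- matrix(acts, nrow = n)
  out <- vapply(setNames(CLASS_LABELS, CLASS_LABELS), function(cl) {
    sub <- acts[, kb$rules$class == cl, drop = FALSE]
    if (config$s_norm == "max") apply(sub, 1, max)
    else 1 - apply(1 - sub, 1, prod)
  }, numeric(n))
  matrix(out, nrow = n, dimnames = list(NULL, CLASS_LABELS))
}

#' Convert a knowledge base to bell-form membership functions
#'
#' The tuning procedure adjusts the two parameters of the bell form
#' `1 / (1 + ((x - b) / c)^2)`: `b`, the peak coordinate, and `c`, the
#' compression/extension parameter. Piecewise-linear terms are bridged to
#' this form explicitly: `b` is taken as the (midpoint of the) grid argmax of
#' the term and `c` as half the x-distance between the outermost grid points
#' with degree at least 0.5. The conversion table is attached as attribute
#' `"conversion"`.
#'
#' @param kb a [knowledge_base()].
#' @param grid_n number of grid points per factor domain.
#' @return A [knowledge_base()] whose terms are all [bell_mf()] objects, with
#'   a `conversion` attribute (data frame: factor, term, b, c).
#' @export
as_bell_kb <- function(kb, grid_n = 2001L) {
  stopifnot(inherits(kb, "knowledge_base"))
  log_rows <- list()
  variables <- lapply(kb$variables, function(var) {
    dom <- var$domain
    grid <- seq(dom[1], dom[2], length.out = grid_n)
    terms <- lapply(setNames(TERM_LABELS, TERM_LABELS), function(lab) {
      mf <- var$terms[[lab]]
      if (inherits(mf, "bell_mf")) {
        b <- mf$b; cc <- mf$c
      } else {
        mu <- evaluate_mf(mf, grid)
        peak <- which(mu >= max(mu) - 1e-9)
        b <- mean(range(grid[peak]))
        half <- which(mu >= 0.5)
        cc <- (grid[max(half)] - grid[min(half)]) / 2
        if (cc <= 0) cc <- (dom[2] - dom[1]) / grid_n
      }
      log_rows[[length(log_rows) + 1L]] <<-
        data.frame(factor = var$factor_id, term = lab, b = b, c = cc)
      bell_mf(b, cc, dom)
    })
    linguistic_variable(var$factor_id, var$description, dom, terms)
  })
  out <- knowledge_base(variables, kb$rules,
                        metadata = paste(kb$metadata, "(bell form)"))
  attr(out, "conversion") <- do.call(rbind, log_rows)
  out
}

#' Tuning configuration
#'
#' Controls which parameter blocks are adjusted and how. Parameters are
#' flattened as one `(b, c)` pair per factor-term plus one weight per rule;
#' bounds keep `b` inside its factor domain, `c` in `[c_min, c_max]`
#' (`c_max = NULL` means twice the factor's domain width) and weights in
#' `[0, 1]`.
#'
#' @param what subset of `c("b", "c", "w")`, non-empty.
#' @param optimizer `"nelder_mead"` (derivative-free, default), `"lbfgsb"`
#'   (bounded quasi-Newton) or `"random_restart"` (several bounded
#'   quasi-Newton runs, the first from the supplied start and the rest from
#'   jittered starts; the best parameters ever evaluated are kept).
#' @param max_iter iteration budget per optimizer run; 0 returns the initial
#'   parameters unchanged.
#' @param tol relative convergence tolerance.
#' @param seed integer seed; all stochastic choices (restart jitter) derive
#'   from it.
#' @param c_min,c_max bounds for the spread parameter.
#' @param n_restarts number of starts for `"random_restart"`.
#' @param combiners a [combiner_config()] used when evaluating the model.
#' @return An object of class `tuning_config`.
#' @export
tuning_config <- function(what = c("b", "c", "w"),
                          optimizer = c("nelder_mead", "lbfgsb", "random_restart"),
                          max_iter = 500L, tol = 1e-8, seed = 1L,
                          c_min = 1e-3, c_max = NULL, n_restarts = 5L,
                          combiners = combiner_config()) {
  what <- match.arg(what, several.ok = TRUE)
  if (length(what) == 0L) {
    fc_stop("parameter subset 'what' must be non-empty",
            "fuzzycad_contract_error")
  }
  if (c_min <= 0) fc_stop("c_min must be > 0", "fuzzycad_contract_error")
  structure(list(what = what, optimizer = match.arg(optimizer),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), c_min = c_min, c_max = c_max,
                 n_restarts = as.integer(n_restarts), combiners = combiners),
            class = "tuning_config")
}

# Factor-term pairs referenced by at least one rule. Terms outside this set
# cannot influence the model output, so their parameters are excluded from
# tuning (they would be unidentifiable).
live_terms <- function(kb, id) {
  intersect(TERM_LABELS, unique(kb$rules[[id]]))
}

kb_flat_params <- function(kb, what) {
  ids <- names(kb$variables)
  out <- numeric(0)
  for (block in intersect(c("b", "c"), what)) {
    for (id in ids) for (lab in live_terms(kb, id)) {
      mf <- kb$variables[[id]]$terms[[lab]]
      if (!inherits(mf, "bell_mf")) {
        fc_stop("tuning b/c requires bell-form terms; see as_bell_kb()",
                "fuzzycad_contract_error")
      }
      out[sprintf("%s.%s.%s", block, id, lab)] <- mf[[block]]
    }
  }
  if ("w" %in% what) {
    w <- kb$rules$weight
    out[sprintf("w.%d", seq_along(w))] <- w
  }
  out
}

kb_param_bounds <- function(kb, what, c_min, c_max) {
  ids <- names(kb$variables)
  lower <- numeric(0); upper <- numeric(0)
  for (block in intersect(c("b", "c"), what)) {
    for (id in ids) for (lab in live_terms(kb, id)) {
      dom <- kb$variables[[id]]$domain
      nm <- sprintf("%s.%s.%s", block, id, lab)
      if (block == "b") {
        lower[nm] <- dom[1]; upper[nm] <- dom[2]
      } else {
        lower[nm] <- c_min
        upper[nm] <- if (is.null(c_max)) 2 * (dom[2] - dom[1]) else c_max
      }
    }
  }
  if ("w" %in% what) {
    nm <- sprintf("w.%d", seq_len(nrow(kb$rules)))
    lower[nm] <- 0; upper[nm] <- 1
  }
  list(lower = lower, upper = upper)
}

kb_set_params <- function(kb, params, what) {
  ids <- names(kb$variables)
  for (block in intersect(c("b", "c"), what)) {
    for (id in ids) for (lab in live_terms(kb, id)) {
      kb$variables[[id]]$terms[[lab]][[block]] <-
        unname(params[sprintf("%s.%s.%s", block, id, lab)])
    }
  }
  if ("w" %in% what) {
    kb$rules$weight <- unname(params[sprintf("w.%d", seq_len(nrow(kb$rules)))])
  }
  kb
}

training_targets <- function(training) {
  training <- as.data.frame(training)
  mu_cols <- paste0("mu_", CLASS_LABELS)
  if (all(mu_cols %in% names(training))) {
    Y <- as.matrix(training[, mu_cols])
    if (any(Y < 0) || any(Y > 1)) {
      fc_stop("membership targets must lie in [0, 1]",
              "fuzzycad_contract_error")
    }
  } else if ("label" %in% names(training)) {
    lab <- as.character(training$label)
    if (!all(lab %in% CLASS_LABELS)) {
      fc_stop("labels must be one of I, II, III, IV",
              "fuzzycad_contract_error")
    }
    Y <- outer(lab, CLASS_LABELS, `==`) * 1
  } else {
    fc_stop("training data need a 'label' column or mu_I..mu_IV columns",
            "fuzzycad_contract_error")
  }
  colnames(Y) <- CLASS_LABELS
  Y
}

training_x <- function(training, ids) {
  training <- as.data.frame(training)
  cols <- match(tolower(ids), tolower(names(training)))
  if (any(is.na(cols))) {
    fc_stop(sprintf("training data lack factor column(s): %s",
                    paste(ids[is.na(cols)], collapse = ", ")),
            "fuzzycad_contract_error")
  }
  X <- as.matrix(training[, cols])
  colnames(X) <- ids
  X
}

#' Least-squares tuning objective
#'
#' The sum over training examples and classes of the squared difference
#' between the model's class membership and the target membership. Class
#' labels are converted to one-hot membership targets (1 for the labelled
#' class, 0 elsewhere). Zero if and only if the model fits the targets
#' perfectly.
#'
#' @param params named flat parameter vector as produced internally by the
#'   tuner (entries `b.<factor>.<term>`, `c.<factor>.<term>`, `w.<rule>`
#'   according to `config$what`).
#' @param training data frame with factor columns and either a `label` column
#'   or target columns `mu_I`..`mu_IV`.
#' @param kb_template knowledge base supplying everything not being tuned.
#' @param config a [tuning_config()].
#' @return non-negative scalar.
#' @export
tuning_objective <- function(params, training, kb_template,
                             config = tuning_config()) {
  expected <- kb_flat_params(kb_template, config$what)
  if (length(params) != length(expected)) {
    fc_stop(sprintf("parameter vector has length %d, expected %d",
                    length(params), length(expected)),
            "fuzzycad_contract_error")
  }
  names(params) <- names(expected)
  kb <- kb_set_params(kb_template, params, config$what)
  X <- training_x(training, names(kb$variables))
  Y <- training_targets(training)
  M <- eval_class_matrix(X, kb, config$combiners)
  sum((M - Y)^2)
}

#' Tune membership parameters and rule weights by least squares
#'
#' Adjusts the selected parameter blocks (`b`, `c` of every bell-form term
#' and/or the rule weights `w`) to minimise [tuning_objective()] with a
#' bounded numerical optimizer. Piecewise-linear terms are first bridged to
#' bell form via [as_bell_kb()] when `b` or `c` are tuned. Terms not
#' referenced by any rule cannot influence the model output, so their
#' parameters are excluded from the flat parameter vector. The reported
#' trajectory contains the objective at the initial point and at every
#' accepted (improving) evaluation, so it is non-increasing by construction,
#' and the returned parameters are the best ever evaluated, clamped to their
#' bounds. Deterministic given `config$seed`.
#'
#' @param kb a [knowledge_base()].
#' @param training data frame with factor columns and a `label` column or
#'   `mu_I`..`mu_IV` target columns; at least one row.
#' @param config a [tuning_config()].
#' @return A list of class `tuning_result`: `tuned_kb`, `initial_objective`,
#'   `final_objective`, `objective_trajectory`, `recovered_params`,
#'   `initial_params`, `config`.
#' @export
tune_knowledge_base <- function(kb, training, config = tuning_config()) {
  stopifnot(inherits(kb, "knowledge_base"))
  training <- as.data.frame(training)
  if (nrow(training) == 0L) {
    fc_stop("training set is empty", "fuzzycad_contract_error")
  }
  set.seed(config$seed)
  needs_bell <- any(c("b", "c") %in% config$what)
  if (needs_bell &&
      !all(vapply(kb$variables, function(v)
        all(vapply(v$terms, inherits, logical(1), "bell_mf")), logical(1)))) {
    kb <- as_bell_kb(kb)
  }
  p0 <- kb_flat_params(kb, config$what)
  bounds <- kb_param_bounds(kb, config$what, config$c_min, config$c_max)
  if (any(bounds$lower > bounds$upper)) {
    fc_stop("infeasible parameter bounds", "fuzzycad_contract_error")
  }
  clamp <- function(p) pmin(pmax(p, bounds$lower), bounds$upper)
  # reflective fold into the box: out-of-bound proposals are mirrored back
  # instead of clamped, so a start on a bound does not collapse the
  # Nelder-Mead initial simplex onto a single point
  fold <- function(p) {
    span <- bounds$upper - bounds$lower
    q <- (p - bounds$lower) %% (2 * span)
    bounds$lower + pmin(q, 2 * span - q)
  }
  p0 <- clamp(p0)

  X <- training_x(training, names(kb$variables))
  Y <- training_targets(training)
  raw_obj <- function(p) {
    kbp <- kb_set_params(kb, setNames(p, names(p0)), config$what)
    sum((eval_class_matrix(X, kbp, config$combiners) - Y)^2)
  }

  rec <- new.env(parent = emptyenv())
  rec$best <- raw_obj(p0)
  rec$best_par <- p0
  rec$traj <- rec$best
  fn <- function(p) {
    pc <- fold(p)
    val <- raw_obj(pc)
    if (is.finite(val) && val <= rec$best) {
      rec$best <- val
      rec$best_par <- pc
      rec$traj <- c(rec$traj, val)
    }
    val
  }

  if (config$max_iter > 0L) {
    run_nm <- function(start) {
      try(optim(start, fn, method = "Nelder-Mead",
                control = list(maxit = config$max_iter,
                               reltol = config$tol)),
          silent = TRUE)
    }
    run_lbfgsb <- function(start) {
      try(optim(start, fn, method = "L-BFGS-B",
                lower = bounds$lower, upper = bounds$upper,
                control = list(maxit = config$max_iter,
                               factr = max(config$tol /
                                           .Machine$double.eps, 10))),
          silent = TRUE)
    }
    switch(config$optimizer,
      nelder_mead = run_nm(p0),
      lbfgsb = run_lbfgsb(p0),
      random_restart = {
        run_lbfgsb(p0)
        span <- bounds$upper - bounds$lower
        for (k in seq_len(config$n_restarts - 1L)) {
          start <- clamp(p0 + rnorm(length(p0), sd = 0.05 * span))
          run_lbfgsb(start)
        }
      })
  }

  structure(list(tuned_kb = kb_set_params(kb, rec$best_par, config$what),
                 initial_objective = rec$traj[1L],
                 final_objective = rec$best,
                 objective_trajectory = rec$traj,
                 recovered_params = rec$best_par,
                 initial_params = p0,
                 config = config),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Tuning (%s over {%s}): objective %.6g -> %.6g in %d accepted step(s)\n",
              x$config$optimizer, paste(x$config$what, collapse = ","),
              x$initial_objective, x$final_objective,
              length(x$objective_trajectory) - 1L))
  invisible(x)
}
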