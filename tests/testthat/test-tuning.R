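make_training <- function(kb, n, seed, combiners = combiner_config()) {
  set.seed(seed)
  pts <- random_patients(n, kb)
  M <- t(apply(pts, 1, function(x) class_memberships(as.numeric(x), kb,
                                                     combiners)))
  cbind(pts, stats::setNames(as.data.frame(M),
                             paste0("mu_", c("I", "II", "III", "IV"))))
}

test_that("the bell conversion peaks where the printed terms peak", {
  kb <- default_knowledge_base()
  bkb <- as_bell_kb(kb)
  conv <- attr(bkb, "conversion")
  expect_equal(nrow(conv), 20L)
  expect_true(all(conv$c > 0))
  for (i in seq_len(nrow(conv))) {
    var <- kb$variables[[conv$factor[i]]]
    expect_gte(evaluate_mf(var$terms[[conv$term[i]]], conv$b[i]), 0.95)
    expect_true(conv$b[i] >= var$domain[1] && conv$b[i] <= var$domain[2])
  }
})

test_that("the objective is zero at the generating parameters", {
  kb <- as_bell_kb(default_knowledge_base())
  train <- make_training(kb, 40, seed = 21)
  cfg <- tuning_config(what = "b")
  p_true <- fuzzycad:::kb_flat_params(kb, "b")
  expect_equal(tuning_objective(p_true, train, kb, cfg), 0, tolerance = 1e-24)
  expect_error(tuning_objective(p_true[-1], train, kb, cfg),
               class = "fuzzycad_contract_error")
})

test_that("the objective is the summed squared membership divergence", {
  # a model forced to output exactly (1, 0, 0, 0) against target class II
  # diverges by 1^2 + 1^2 = 2
  kb <- as_bell_kb(default_knowledge_base())
  x <- c(2.2, 2.4, 1.5, 3.0)
  kb$rules$weight <- c(1, rep(0, 13))
  r1 <- kb$rules[1, ]
  ids <- c("X1", "X2", "X3", "X4")
  for (i in seq_along(ids)) {
    kb$variables[[ids[i]]]$terms[[r1[[ids[i]]]]]$b <- x[i]
  }
  train <- data.frame(x1 = x[1], x2 = x[2], x3 = x[3], x4 = x[4],
                      label = "II")
  cfg <- tuning_config(what = "w")
  expect_equal(tuning_objective(fuzzycad:::kb_flat_params(kb, "w"),
                                train, kb, cfg), 2.0)
})

test_that("perturbing one peak away from truth increases the objective", {
  kb <- as_bell_kb(default_knowledge_base())
  train <- make_training(kb, 150, seed = 22)
  cfg <- tuning_config(what = "b")
  p <- fuzzycad:::kb_flat_params(kb, "b")
  for (nm in c("b.X2.HA", "b.X3.L", "b.X4.A")) {
    q <- p
    q[nm] <- q[nm] + 0.08
    expect_gt(tuning_objective(q, train, kb, cfg), 1e-4)
  }
})

test_that("a zero iteration budget returns the initial parameters", {
  kb <- as_bell_kb(default_knowledge_base())
  train <- make_training(kb, 20, seed = 23)
  fit <- tune_knowledge_base(kb, train, tuning_config(what = c("b", "w"),
                                                      max_iter = 0))
  expect_equal(fit$recovered_params, fit$initial_params)
  expect_equal(fit$final_objective, fit$initial_objective)
})

test_that("accepted objectives never increase and bounds hold", {
  kb <- default_knowledge_base()
  train <- make_training(kb, 60, seed = 24)
  train$label <- c("I", "II", "III", "IV")[max.col(
    as.matrix(train[paste0("mu_", c("I", "II", "III", "IV"))]))]
  for (optr in c("nelder_mead", "lbfgsb")) {
    for (seed in c(1, 9)) {
      cfg <- tuning_config(what = c("b", "c", "w"), optimizer = optr,
                           max_iter = 60, seed = seed)
      fit <- tune_knowledge_base(kb, train[c("x1", "x2", "x3", "x4", "label")],
                                 cfg)
      expect_true(all(diff(fit$objective_trajectory) <= 0))
      expect_lte(fit$final_objective, fit$initial_objective)
      bkb <- fit$tuned_kb
      bounds <- fuzzycad:::kb_param_bounds(bkb, cfg$what, cfg$c_min, cfg$c_max)
      p <- fuzzycad:::kb_flat_params(bkb, cfg$what)
      expect_true(all(p >= bounds$lower - 1e-12))
      expect_true(all(p <= bounds$upper + 1e-12))
    }
  }
})

test_that("tuning is deterministic given the seed", {
  kb <- as_bell_kb(default_knowledge_base())
  train <- make_training(kb, 40, seed = 25)
  cfg <- tuning_config(what = "b", optimizer = "random_restart",
                       n_restarts = 2, max_iter = 40, seed = 77)
  f1 <- tune_knowledge_base(kb, train, cfg)
  f2 <- tune_knowledge_base(kb, train, cfg)
  expect_identical(f1$recovered_params, f2$recovered_params)
  expect_identical(f1$objective_trajectory, f2$objective_trajectory)
})

test_that("systematically conflicting labels push rule weights down", {
  kb <- default_knowledge_base()
  # patients near the NSTEMI group means activate class III hardest
  # (high X4, mid-high X3); labelling them all II makes the class III rules
  # conflict with the supervision, so their weights should fall
  set.seed(26)
  n <- 60
  base <- c(2.57, 2.42, 2.23, 3.66)
  train <- data.frame(
    x1 = pmin(pmax(base[1] + rnorm(n, 0, 0.03), 1.83), 2.76),
    x2 = pmin(pmax(base[2] + rnorm(n, 0, 0.03), 1.74), 3.0),
    x3 = pmin(pmax(base[3] + rnorm(n, 0, 0.03), 1.0), 2.35),
    x4 = pmin(pmax(base[4] + rnorm(n, 0, 0.03), 2.07), 4.67),
    label = "II")
  cfg <- tuning_config(what = "w", optimizer = "lbfgsb", max_iter = 200,
                       seed = 5)
  mu0 <- class_memberships(as.numeric(train[1, 1:4]), kb)
  conflicting <- names(which.max(mu0))
  expect_identical(conflicting, "III")
  fit <- tune_knowledge_base(kb, train, cfg)
  w <- fit$recovered_params
  w_conf <- w[paste0("w.", which(kb$rules$class == conflicting))]
  expect_lt(mean(w_conf), 1)
  expect_lte(fit$final_objective, fit$initial_objective)
})

test_that("empty training data and empty parameter subsets are rejected", {
  kb <- default_knowledge_base()
  expect_error(tune_knowledge_base(kb, data.frame()),
               class = "fuzzycad_contract_error")
  expect_error(tuning_config(what = character(0)))
  expect_error(tuning_config(c_min = 0), class = "fuzzycad_contract_error")
})
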