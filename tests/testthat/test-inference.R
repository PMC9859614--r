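test_that("fuzzification of the UAP group means matches the printed formulas", {
  kb <- default_knowledge_base()
  m <- fuzzify(uap_fixture, kb)
  expect_equal(dim(m), c(5L, 4L))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m["L", "X3"], 1.0)     # 2.47 - 1.47 * 1.0
  expect_equal(m["H", "X3"], 0.0)     # 0.49 * 1.0 - 0.49
  expect_equal(m["LA", "X1"], 5.29 - 2.08 * 2.15)
  expect_equal(m["A", "X4"], 0.769 * 2.5 - 1.59)
})

test_that("fuzzification accepts domain boundaries and names the bad factor", {
  kb <- default_knowledge_base()
  ok <- fuzzify(c(x1 = 2.0, x2 = 1.74, x3 = 1.5, x4 = 3.0), kb)
  expect_true(all(is.finite(ok)))
  err <- tryCatch(fuzzify(c(x1 = 2.0, x2 = 1.5, x3 = 1.5, x4 = 3.0), kb),
                  fuzzycad_domain_error = identity)
  expect_s3_class(err, "fuzzycad_domain_error")
  expect_match(conditionMessage(err), "X2")
})

test_that("class memberships reproduce the worked example", {
  kb <- default_knowledge_base()
  mu <- class_memberships(uap_fixture, kb)
  expect_equal(mu, uap_expected_memberships(), tolerance = 1e-12)
  expect_equal(round(unname(mu), 4), c(0.3325, 0.7, 0, 0.405))
})

test_that("zero rule weights annihilate every class", {
  kb <- default_knowledge_base()
  kb$rules$weight <- 0
  mu <- class_memberships(uap_fixture, kb)
  expect_equal(unname(mu), rep(0, 4))
})

test_that("a class without rules is a configuration error", {
  kb <- default_knowledge_base()
  kb13 <- knowledge_base(kb$variables, kb$rules[kb$rules$class != "III", ])
  expect_error(class_memberships(uap_fixture, kb13),
               class = "fuzzycad_config_error")
})

test_that("the decision is the argmax with documented tie handling", {
  res <- decide(c(I = 0.3325, II = 0.7, III = 0, IV = 0.405))
  expect_equal(res$decision, "II")
  expect_equal(res$decision_name, "UAP")
  expect_equal(res$margin, 0.295)
  expect_false(res$tie)

  tie <- decide(c(I = 0.5, II = 0.5, III = 0.1, IV = 0.1))
  expect_equal(tie$decision, "I")
  expect_true(tie$tie)
  expect_equal(tie$margin, 0)
  all_of_them <- decide(c(I = 0.5, II = 0.5, III = 0.1, IV = 0.1),
                        tie_break = "report_all")
  expect_equal(all_of_them$argmax_classes, c("I", "II"))

  expect_warning(zero <- decide(c(I = 0, II = 0, III = 0, IV = 0)),
                 class = "fuzzycad_no_rule_fired")
  expect_equal(zero$decision, "I")
  expect_true(zero$tie)
  expect_true(zero$no_rule_fired)
  expect_error(decide(c(I = 0, II = 0, III = 0, IV = 0),
                      on_no_rule = "error"),
               class = "fuzzycad_no_rule_fired")
  expect_error(decide(c(I = NA, II = 0, III = 0, IV = 0)),
               class = "fuzzycad_contract_error")
})

test_that("the decision attains the maximum and ignores rule order", {
  kb <- default_knowledge_base()
  set.seed(33)
  pts <- random_patients(40, kb)
  for (i in seq_len(nrow(pts))) {
    x <- as.numeric(pts[i, ])
    res <- infer(x, kb)
    expect_equal(res$memberships[[res$decision]], max(res$memberships))
    shuffled <- knowledge_base(kb$variables,
                               kb$rules[sample(nrow(kb$rules)), ])
    if (!res$tie) {
      expect_equal(infer(x, shuffled)$decision, res$decision)
    }
  }
})

test_that("raising a rule weight never lowers its class membership", {
  kb <- default_knowledge_base()
  set.seed(44)
  pts <- random_patients(15, kb)
  for (i in seq_len(nrow(pts))) {
    x <- as.numeric(pts[i, ])
    r <- sample(nrow(kb$rules), 1)
    cl <- kb$rules$class[r]
    low <- kb; low$rules$weight[r] <- 0.3
    high <- kb; high$rules$weight[r] <- 0.9
    expect_gte(class_memberships(x, high)[[cl]] + 1e-15,
               class_memberships(x, low)[[cl]])
  }
})

test_that("min/max class memberships are bounded by the largest antecedent degree", {
  kb <- default_knowledge_base()
  set.seed(55)
  pts <- random_patients(50, kb)
  for (i in seq_len(nrow(pts))) {
    x <- as.numeric(pts[i, ])
    degrees <- fuzzify(x, kb)
    mu <- class_memberships(x, kb)
    for (cl in names(mu)) {
      rules <- kb$rules[kb$rules$class == cl, ]
      cap <- max(apply(rules, 1, function(r) {
        max(degrees[r[["X1"]], "X1"], degrees[r[["X2"]], "X2"],
            degrees[r[["X3"]], "X3"], degrees[r[["X4"]], "X4"])
      }))
      expect_gte(mu[[cl]], 0)
      expect_lte(mu[[cl]], cap + 1e-15)
    }
  }
})

test_that("the winning rule attains the decided class's membership", {
  kb <- default_knowledge_base()
  res <- infer(uap_fixture, kb)
  expect_equal(kb$rules$class[res$winning_rule], res$decision)
  degrees <- fuzzify(uap_fixture, kb)
  r <- kb$rules[res$winning_rule, ]
  act <- min(degrees[r$X1, "X1"], degrees[r$X2, "X2"],
             degrees[r$X3, "X3"], degrees[r$X4, "X4"])
  expect_equal(act, res$memberships[[res$decision]])
})

test_that("cohort inference is deterministic and summarises agreement", {
  kb <- default_knowledge_base()
  fx <- fixture_patients()
  out <- infer_cohort(fx, kb)
  expect_equal(nrow(out$results), 4L)
  expect_true(out$agreement >= 0 && out$agreement <= 1)
  expect_equal(dim(out$confusion), c(4L, 4L))
  expect_equal(sum(out$confusion), 4)

  dup <- fx[rep(2, 10), ]
  rep10 <- infer_cohort(dup, kb)$results
  expect_equal(length(unique(rep10$decision)), 1L)
  expect_equal(length(unique(rep10$mu_II)), 1L)

  expect_error(infer_cohort(fx[0, ], kb), class = "fuzzycad_contract_error")
})
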