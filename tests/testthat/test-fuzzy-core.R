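test_that("piecewise evaluation matches the printed formulas and clamps", {
  kb <- default_knowledge_base()
  # mu_L of X3 at 1.0: 2.47 - 1.47 * 1.0 = 1.00
  expect_equal(evaluate_mf(kb$variables$X3$terms$L, 1.0), 1.0)
  # mu_H of X1 at 1.83: 0.71 * 1.83 - 1.31 = -0.0107, clamped to 0
  expect_equal(evaluate_mf(kb$variables$X1$terms$H, 1.83), 0.0)
  # interior of a rising piece, no clamping
  expect_equal(evaluate_mf(kb$variables$X1$terms$LA, 2.15), 5.29 - 2.08 * 2.15)
})

test_that("out-of-range policy errors by default and clamps on request", {
  kb <- default_knowledge_base()
  mf <- kb$variables$X1$terms$L
  expect_error(evaluate_mf(mf, 3.5), class = "fuzzycad_domain_error")
  expect_equal(evaluate_mf(mf, 3.5, out_of_range = "clamp_to_domain"),
               evaluate_mf(mf, 2.76))
  expect_error(evaluate_mf(mf, NaN), class = "fuzzycad_contract_error")
})

test_that("breakpoints follow the half-open convention (right segment wins)", {
  kb <- default_knowledge_base()
  # X2 term A at the 2.3 breakpoint: falling piece 4.76 - 1.59 x applies,
  # giving 1.103 pre-clamp -> 1, not the rising piece's 0.897
  expect_equal(evaluate_mf(kb$variables$X2$terms$A, 2.3), 1.0)
  # the final segment is closed at the domain maximum
  expect_equal(evaluate_mf(kb$variables$X1$terms$L, 2.76),
               min(1, max(0, 1.97 - 0.71 * 2.76)))
})

test_that("malformed segment sets are rejected", {
  expect_error(piecewise_mf(data.frame(lower = 1, upper = 1, slope = 0,
                                       intercept = 0.5), c(1, 1)),
               class = "fuzzycad_contract_error")
  expect_error(piecewise_mf(data.frame(lower = c(0, 2), upper = c(1, 3),
                                       slope = 0, intercept = 0.5), c(0, 3)),
               class = "fuzzycad_contract_error")
  expect_error(bell_mf(2, 0, c(0, 4)), class = "fuzzycad_contract_error")
})

test_that("all default degrees stay in [0, 1] and segment selection is total", {
  kb <- default_knowledge_base()
  for (var in kb$variables) {
    grid <- seq(var$domain[1], var$domain[2], length.out = 10000)
    for (mf in var$terms) {
      mu <- evaluate_mf(mf, grid)
      expect_true(all(is.finite(mu)))
      expect_true(all(mu >= 0 & mu <= 1))
    }
  }
})

test_that("t-norms and s-norms combine degrees correctly", {
  expect_equal(combine_and(c(0.818, 0.7, 1.0, 0.8325), "min"), 0.7)
  expect_equal(combine_and(c(0.5, 0.5), "product"), 0.25)
  expect_equal(combine_and(0.37, "min"), 0.37)
  expect_equal(combine_or(c(0, 0, 0), "max"), 0)
  expect_equal(combine_or(c(0.3, 0.4), "prob_sum"), 1 - 0.7 * 0.6)
  expect_error(combine_and(numeric(0)), class = "fuzzycad_contract_error")
  expect_error(combine_or(c(0.2, 1.4)), class = "fuzzycad_contract_error")
})

test_that("normalization onto U = [0, 4] is exact and invertible", {
  dom <- c(1.83, 2.76)
  expect_equal(normalize_to_u(1.83, dom), 0)
  expect_equal(normalize_to_u(2.76, dom), 4)
  expect_equal(normalize_to_u(2.295, dom), 2)
  set.seed(5)
  x <- runif(200, dom[1], dom[2])
  expect_equal(denormalize_from_u(normalize_to_u(x, dom), dom), x,
               tolerance = 1e-12)
  expect_error(normalize_to_u(1, c(2, 2)), class = "fuzzycad_contract_error")
})

test_that("centre-of-gravity defuzzification is a clamped weighted mean", {
  expect_equal(defuzzify_cog(c(0, 1, 2), c(0, 1, 0)), 1.0)
  expect_equal(defuzzify_cog(c(0, 2), c(0.5, 0.5)), 1.0)
  expect_equal(defuzzify_cog(c(0, 1, 2, 3), c(0.2, 0.4, 0.4, 0.2)), 1.5)
  expect_error(defuzzify_cog(c(0, 1), c(0, 0)),
               class = "fuzzycad_undefined_centroid")
  expect_error(defuzzify_cog(c(0, 1), c(0.2, 0.3, 0.4)),
               class = "fuzzycad_contract_error")
  # translation equivariance
  set.seed(8)
  u <- sort(runif(50)); mu <- runif(50)
  expect_equal(defuzzify_cog(u + 3.2, mu), defuzzify_cog(u, mu) + 3.2)
})

test_that("consistency diagnostics find the rounded-coefficient artifacts", {
  kb <- default_knowledge_base()
  reports <- lapply(kb$variables, check_variable_consistency)
  for (rep in reports) {
    expect_gte(min(rep$peaks$value), 0.95)
    expect_gte(rep$coverage, 0.45)
  }
  # the published X2 term-A pieces disagree at x = 2.3 by > 0.05 post-clamp
  x2 <- reports$X2$breakpoints
  flagged_a <- x2[x2$term == "A" & abs(x2$x - 2.3) < 1e-9, ]
  expect_equal(nrow(flagged_a), 1L)
  expect_true(flagged_a$flagged)
  expect_equal(flagged_a$jump, 1 - (1.59 * 2.3 - 2.76), tolerance = 1e-9)
})

test_that("an exactly continuous triangular variable reports no jumps", {
  tri <- function(lo, peak, hi, dom) {
    seg <- data.frame(
      lower = c(dom[1], peak), upper = c(peak, dom[2]),
      slope = c(1 / (peak - lo), -1 / (hi - peak)),
      intercept = c(-lo / (peak - lo), hi / (hi - peak)))
    piecewise_mf(seg[seg$lower < seg$upper, ], dom)
  }
  dom <- c(0, 4)
  var <- linguistic_variable("T", "triangular test variable", dom, list(
    L = tri(-1, 0, 1, dom), LA = tri(0, 1, 2, dom), A = tri(1, 2, 3, dom),
    HA = tri(2, 3, 4, dom), H = tri(3, 4, 5, dom)))
  rep <- check_variable_consistency(var, grid_step = 0.01)
  expect_true(all(rep$breakpoints$jump < 1e-9))
  expect_false(any(rep$breakpoints$flagged))
})
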