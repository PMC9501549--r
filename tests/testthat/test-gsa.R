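test_that("Latin hypercube samples are exactly stratified", {
  x <- lhs_sample(4, c(a = 0), c(a = 1), seed = 1)
  expect_equal(sort(floor(x[, "a"] * 4)), 0:3)  # one point per quartile
  x2 <- lhs_sample(20, c(a = 2, b = -1), c(a = 4, b = 1), seed = 2)
  for (j in 1:2) {
    u <- (x2[, j] - c(2, -1)[j]) / c(2, 2)[j]
    expect_equal(sort(floor(u * 20)), 0:19)
  }
  expect_false(identical(lhs_sample(10, c(a = 0), c(a = 1), seed = 1),
                         lhs_sample(10, c(a = 0), c(a = 1), seed = 99)))
})

test_that("LHS marginals are uniform over the range", {
  x <- lhs_sample(5000, c(a = 0), c(a = 1), seed = 4)
  kt <- suppressWarnings(stats::ks.test(x[, "a"], "punif"))
  expect_gt(kt$p.value, 0.01)
})

test_that("PRCC isolates the driving parameter", {
  set.seed(10)
  X <- lhs_sample(300, c(x1 = 0, x2 = 0, x3 = 0), c(x1 = 1, x2 = 1, x3 = 1))
  y <- X[, "x1"]^2 + stats::rnorm(300, 0, 1e-3)  # monotone in x1 only
  tab <- prcc(X, y)
  # a noise-free monotone copy is rejected as rank-degenerate
  expect_error(prcc(X, X[, "x1"]^3), "degenerate")
  expect_gt(tab$prcc[tab$parameter == "x1"], 0.99)
  expect_lt(max(abs(tab$prcc[tab$parameter != "x1"])), 0.2)
  expect_true(tab$significant[tab$parameter == "x1"])
  expect_false(any(tab$significant[tab$parameter != "x1"]))
})

test_that("PRCC of an unrelated response is small and insignificant", {
  set.seed(12)
  X <- lhs_sample(200, c(a = 0, b = 0), c(a = 1, b = 1))
  y <- stats::rnorm(200)
  tab <- prcc(X, y)
  expect_lt(max(abs(tab$prcc)), 0.25)
  expect_false(any(tab$significant))
})

test_that("PRCC equals brute-force rank residualisation", {
  set.seed(13)
  n <- 50
  X <- cbind(x1 = stats::runif(n), x2 = stats::runif(n), x3 = stats::runif(n))
  y <- 2 * X[, "x1"] - X[, "x2"] + 0.3 * stats::rnorm(n)
  tab <- prcc(X, y)
  R <- apply(X, 2, rank); ry <- rank(y)
  for (j in 1:3) {
    others <- R[, -j, drop = FALSE]
    rx_res <- stats::residuals(stats::lm(R[, j] ~ others))
    ry_res <- stats::residuals(stats::lm(ry ~ others))
    expect_equal(tab$prcc[j], stats::cor(rx_res, ry_res), tolerance = 1e-10)
  }
})

test_that("PRCC is invariant under monotone transforms of inputs", {
  set.seed(14)
  X <- cbind(a = stats::runif(80, 1, 2), b = stats::runif(80, 1, 2))
  y <- X[, "a"] + 0.5 * X[, "b"]
  t1 <- prcc(X, y)
  X2 <- cbind(a = exp(X[, "a"]), b = X[, "b"]^3)
  t2 <- prcc(X2, y)
  expect_equal(t1$prcc, t2$prcc, tolerance = 1e-12)
  # sign convention: increasing influence gives positive PRCC
  expect_gt(t1$prcc[1], 0)
  y_neg <- -y
  expect_lt(prcc(X, y_neg)$prcc[1], 0)
})

test_that("degenerate inputs are rejected by name", {
  X <- cbind(a = rep(1, 30), b = stats::runif(30))
  expect_error(prcc(X, stats::runif(30)), "a")
  X2 <- cbind(a = stats::runif(30), b = stats::runif(30))
  expect_error(prcc(X2, rep(2, 30)), "constant response")
})

test_that("monotonicity screen keeps, truncates, or excludes correctly", {
  # strictly increasing: full range retained
  sc <- monotonicity_screen(function(v) v^3, 1, 2, n_grid = 11)
  expect_false(sc$excluded)
  expect_equal(c(sc$lower, sc$upper), c(1, 2))
  expect_equal(sc$rho, 1)
  # unimodal with peak at 30%: longer (upper) side retained
  sc2 <- monotonicity_screen(function(v) -(v - 0.3)^2, 0, 1, n_grid = 21)
  expect_false(sc2$excluded)
  expect_gt(sc2$lower, 0.2)
  expect_equal(sc2$upper, 1)
  # symmetric peak: tie broken to the lower side
  sc3 <- monotonicity_screen(function(v) -(v - 0.5)^2, 0, 1, n_grid = 21)
  expect_false(sc3$excluded)
  expect_equal(sc3$lower, 0)
  expect_equal(sc3$upper, 0.5)
  # flat response: excluded
  sc4 <- monotonicity_screen(function(v) 42, 0, 1, n_grid = 11)
  expect_true(sc4$excluded)
  # failing evaluations are dropped with a warning
  expect_warning(
    monotonicity_screen(function(v) if (v > 0.9) stop("boom") else v, 0, 1,
                        n_grid = 11), "dropped")
})

test_that("KS regionalisation flags exactly the planted parameters", {
  set.seed(20)
  n <- 5000
  X <- lhs_sample(n, stats::setNames(rep(0, 5), paste0("x", 1:5)),
                  stats::setNames(rep(1, 5), paste0("x", 1:5)))
  acc <- X[, "x1"] > 0.5 & X[, "x3"] < 0.4   # planted two-parameter rule
  res <- ks_regionalized(X, acc)
  expect_true(all(res$sensitive[res$parameter %in% c("x1", "x3")]))
  expect_false(any(res$sensitive[res$parameter %in% c("x2", "x4", "x5")]))
  expect_gt(res$ks_D[res$parameter == "x1"], 0.5)
  expect_error(ks_regionalized(X, rep(TRUE, n)), "contrast")
})

test_that("the assembled pipeline ranks a known dominant rate on top", {
  cfg <- gsa_config(p0, param_names = c("kon_CR", "kcat16", "Km12", "kc2b"),
                    n_samples = 60, protocol = "LFS", seed = 5,
                    screen = TRUE, screen_points = 7)
  tab <- suppressWarnings(run_gsa(p0, cfg))
  # the relaxed-state C-lobe on-rate gates CaM4 formation; the other three
  # act far downstream of the CaM4 output
  expect_equal(tab$parameter[which.max(abs(tab$prcc))], "kon_CR")
  expect_gt(abs(tab$prcc[tab$parameter == "kon_CR"]), 0.8)
  # deterministic under a fixed seed
  tab2 <- suppressWarnings(run_gsa(p0, cfg))
  expect_identical(tab$prcc, tab2$prcc)
})
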