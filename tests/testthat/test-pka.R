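test_that("the cAMP-free PKA sub-state is stationary and conserved", {
  s <- c(R2C2 = p0[["R2C2_T"]], R2C2cAMP2 = 0, R2C2cAMP4 = 0, PKAc = 0)
  expect_equal(unname(pka_full_rhs(s, 0, p0)), rep(0, 4))
  set.seed(3)
  for (i in 1:15) {
    s <- stats::runif(4, 0, 0.5)
    d <- pka_full_rhs(s, stats::runif(1, 0, 10), p0)
    # R2C2 + cAMP2 + cAMP4 + PKAc/2 is conserved
    expect_equal(sum(d[1:3]) + d[[4]] / 2, 0, tolerance = 1e-12)
  }
  expect_error(pka_full_rhs(c(-0.1, 0, 0, 0), 1, p0))
})

test_that("algebraic steady state agrees with direct integration", {
  for (camp in c(0.2, 1, 5)) {
    alg <- pka_steady_state(camp, p0, method = "algebraic")
    num <- pka_steady_state(camp, p0, method = "integrate")
    expect_equal(alg, num, tolerance = 1e-8)
  }
})

test_that("the dose-response is zero at the origin and strictly increasing", {
  dr <- pka_dose_response(p0, seq(0, 10, length.out = 41))
  expect_equal(dr$PKAc[1], 0)
  expect_true(all(diff(dr$PKAc) > 0))
  expect_error(pka_dose_response(p0, c(-1, 5)))
})

test_that("the Hill fit recovers parameters of exactly Hill-shaped data", {
  grid <- seq(0, 10, length.out = 101)  # IC50 = 0.1 lies on the grid
  truth <- list(max = 0.2, ic50 = 0.1, n = 3)
  resp <- ifelse(grid <= 0, 0,
                 truth$max / (1 + (truth$ic50 / grid)^truth$n))
  fit <- fit_hill(grid, resp)
  expect_equal(fit$PKA_max, max(resp), tolerance = 1e-12)
  expect_equal(fit$IC50, truth$ic50, tolerance = 1e-6)
  expect_equal(fit$n_hill, truth$n, tolerance = 1e-3)
  expect_gt(fit$r_squared, 1 - 1e-8)
})

test_that("the Hill exponent survives small noise on the response", {
  grid <- seq(0, 10, length.out = 101)
  resp <- ifelse(grid <= 0, 0, 0.2 / (1 + (0.4 / grid)^2.5))
  set.seed(5)
  noisy <- sort(resp + stats::rnorm(length(resp), 0, 2e-4))
  fit <- fit_hill(grid, noisy)
  expect_equal(fit$n_hill, 2.5, tolerance = 0.2)
  expect_error(fit_hill(grid, rev(resp)), "monotone")
})

test_that("reduced activation hits its landmarks", {
  fit <- structure(list(PKA_max = 0.2, IC50 = 0.5, n_hill = 2),
                   class = "pka_fit")
  expect_equal(pka_reduced(0.5, fit), 0.1)
  expect_equal(pka_reduced(0, fit), 0)
  # via calibrated parameter-set constants: half activation at IC50
  expect_equal(pka_reduced(p0[["IC50"]], p0), p0[["PKA_max"]] / 2,
               tolerance = 1e-12)
})

test_that("the orientation oracle selects first-order release", {
  sel <- select_k19_orientation(p0)
  expect_identical(as.character(sel), "reversed")
  cand <- attr(sel, "PKAc_10uM")
  # the rejected orientation releases nearly the whole catalytic pool
  expect_gt(cand[["printed"]], 2)
  expect_lt(cand[["reversed"]], 0.5)
})

test_that("reduced and full dose-responses agree to the fitted r-squared", {
  dr <- pka_dose_response(p0, seq(0, 10, length.out = 41))
  fit <- fit_hill(dr$cAMP, dr$PKAc)
  expect_gt(fit$r_squared, 0.99)
  pred <- pka_reduced(dr$cAMP, fit)
  rmse <- sqrt(mean((pred - dr$PKAc)^2))
  expect_lt(rmse, sqrt(1 - 0.99) * stats::sd(dr$PKAc) * 1.5)
})
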