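test_that("compiled and reference right-hand sides integrate identically", {
  proto <- make_protocol("HZ10")
  rC <- integrate_network(p0, proto, t_end = 0.5, mode = "full_pka")
  rR <- integrate_network(p0, proto, t_end = 0.5, mode = "full_pka",
                          engine = "R")
  expect_lt(max(abs(rC$trajectory - rR$trajectory)), 1e-6)
  rC2 <- integrate_network(p0, proto, t_end = 0.5, mode = "reduced_pka")
  rR2 <- integrate_network(p0, proto, t_end = 0.5, mode = "reduced_pka",
                           engine = "R")
  expect_lt(max(abs(rC2$trajectory - rR2$trajectory)), 1e-6)
})

test_that("derivatives conserve every pool at random states", {
  proto <- make_protocol("HZ10")
  set.seed(11)
  for (i in 1:20) {
    y <- stats::runif(25, 0, 0.3)
    names(y) <- names(network_initial_state(p0, proto))
    d <- network_rhs(0.123, y, p0, proto, "full_pka")
    cam_pool <- sum(d[1:9]) + d[["CaMAC1"]] + d[["CaMAC8"]] +
      d[["CaMPDE1"]] + d[["CaMCaNA"]] + d[["CaMCaMKII"]] + d[["CaMCaMKIIP"]]
    expect_equal(cam_pool, 0, tolerance = 1e-9)
    # CaMKII pool: the three explicit forms + implied free; their sum must
    # equal minus the implied-free derivative, i.e. bound-form change is
    # balanced by net binding and dephosphorylation-release terms; here we
    # check the closed combination used by the C side
    pka_pool <- d[["R2C2cAMP2"]] + d[["R2C2cAMP4"]] + 0.5 * d[["PKAc"]]
    # R2C2 is implied, so the explicit sub-states plus released subunits
    # change only through what R2C2 supplies; re-derive R2C2 flux:
    v17 <- p0[["k17f"]] * (p0[["R2C2_T"]] - y[["R2C2cAMP2"]] -
             y[["R2C2cAMP4"]] - 0.5 * y[["PKAc"]]) * y[["cAMP"]]^2 -
           p0[["k17b"]] * y[["R2C2cAMP2"]]
    expect_equal(pka_pool, v17, tolerance = 1e-9)
  }
})

test_that("single-target reduction reaches the analytic binding equilibrium", {
  # only CaMKII present, phosphorylation off: at steady state the bound
  # fraction is CaM4 / (CaM4 + kc5b1/kc5f)
  p <- p0
  for (nm in c("AC1_T", "AC8_T", "PDE1_T", "PP2B_T")) p[[nm]] <- 0
  p <- apply_variant(p, "T286A")
  proto <- make_protocol("HZ100", n_pulses = 1)  # single pulse, then decay
  proto$Ca_basal <- 1; proto$pulse_times <- 0; proto$train_end <- 0.01
  r <- integrate_network(p, proto, t_end = 60, dt_out = 0.5)
  y <- r$trajectory[nrow(r$trajectory), ]
  cam4 <- y[["CaM4"]]
  bound_frac <- y[["CaMCaMKII"]] / p[["CaMKII_T"]]
  expect_equal(bound_frac, cam4 / (cam4 + p[["kc5b1"]] / p[["kc5f"]]),
               tolerance = 1e-4)
})

test_that("a zero-amplitude protocol leaves the calcium module stationary", {
  proto <- make_protocol("LFS", A = 1e-12)
  r <- integrate_fast(p0, proto, t_end = 3)
  expect_equal(max(abs(r$Ca - proto$Ca_basal)), 0, tolerance = 1e-9)
  cam0 <- r$trajectory[1, "CaM0"]
  expect_lt(max(abs(r$trajectory[, "CaM0"] - cam0)) / cam0, 1e-3)
})

test_that("100 Hz converts most of the CaM pool into CaM4", {
  r <- integrate_fast(p0, make_protocol("HZ100"))
  ds <- derived_series(r)
  expect_gt(max(ds$CaM4_total), 0.9 * p0[["CaM_T"]])
})

test_that("low-frequency stimulation dissociates bound targets between pulses", {
  r <- integrate_fast(p0, make_protocol("LFS"))
  ds <- derived_series(r)
  w <- ds$time >= 5 & ds$time <= 6  # one late inter-pulse interval
  for (tg in c("bound_PDE1", "bound_CaMKII", "bound_AC1")) {
    x <- ds[[tg]][w]
    expect_gt(max(x) / max(min(x), 1e-12), 1.5)
  }
})

test_that("observable summaries are ordered and zero-initialised", {
  r <- integrate_fast(p0, make_protocol("HZ10"))
  expect_equal(derived_series(r)$I1PP1[1], 0)
  for (wh in c("CaM4_total", "cAMP", "I1PP1")) {
    pk <- observables(r, wh, "peak")
    eot <- observables(r, wh, "end_of_train")
    expect_gte(pk, eot)
    expect_gte(eot, 0)
    avg <- observables(r, wh, "time_average")
    expect_lte(avg, pk)
  }
})

test_that("derived series recompute bit-identically from the trajectory", {
  r <- integrate_fast(p0, make_protocol("HZ10"))
  expect_identical(derived_series(r), derived_series(r))
  expect_equal(derived_series(r)$CaM4_total,
               rowSums(r$trajectory[, c("CaM4", "CaMAC1", "CaMAC8",
                                        "CaMPDE1", "CaMCaNA", "CaMCaMKII",
                                        "CaMCaMKIIP")]),
               tolerance = 1e-14)
})
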