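test_that("baseline constants match the published kinetic table", {
  # transcription cross-check: the printed kinetic table, typed independently
  # of R/parameters.R
  printed <- c(
    kc1f = 50, kc1b = 1, kc2f = 20, kc2b = 1, kc3f = 100, kc3b = 1,
    kc4f = 46, kc4b1 = 0.0012, Kd1 = 0.5, n1 = 1.8, kc4b2 = 2, Kd2 = 0.1,
    n2 = 3, kc5f = 21, kc5b1 = 1.1, kc5b2 = 0.0011,
    kcat1 = 2.843, kcat2 = 2.843, kcat3 = 3, kcat4 = 18, Km4 = 25,
    k10 = 0.25, kcat5 = 1.7, kcat6 = 3.12, Km5 = 10, kcat7 = 1.56,
    kcat8 = 3.12, kcat9 = 5.4, kcat10 = 10.8, kcat11 = 1.4, Km11 = 5,
    kcat12 = 2, Km12 = 16, kcat13 = 2.8, Km13 = 3, kcat14 = 1.2,
    kcat15 = 1.72, Km15 = 11, kcat16 = 2, Km16 = 16,
    k17f = 8, k17b = 0.02, k18f = 0.7, k18b = 0.2, k19f = 0.25,
    k19b = 0.0016,
    CaM_T = 17.7, CaMKII_T = 20, AC1_T = 2.5, AC8_T = 0.625,
    ACstar_T = 2.5, PDE1_T = 4, PP2B_T = 2.1, PP1_T = 3.5,
    PP2A_T = 0.11111, I1_T = 1.5, PDE4B_T = 1, PDE4D_T = 1, R2C2_T = 1.2)
  expect_identical(unname(unclass(p0)[names(printed)]), unname(printed))
})

test_that("structural premises of the parameter set hold", {
  # 1000-fold CaM trapping on T286 phosphorylation
  expect_equal(p0[["kc5b1"]] / p0[["kc5b2"]], 1000, tolerance = 1e-9)
  # limiting-CaM premise: CaM outnumbered by its binding targets
  targets <- p0[["CaMKII_T"]] + p0[["PDE1_T"]] + p0[["PP2B_T"]] +
    p0[["AC1_T"]] + p0[["AC8_T"]]
  expect_lt(p0[["CaM_T"]], targets)
  expect_true(all(is.finite(unclass(p0))))
  expect_true(all(unclass(p0) >= 0))
})

test_that("knockout variants modify exactly their field and are idempotent", {
  expect_identical(apply_variant(p0, "WT"), p0)
  t286a <- apply_variant(p0, "T286A")
  expect_identical(t286a[["kcat14"]], 0)
  expect_identical(unclass(t286a)[names(t286a) != "kcat14"],
                   unclass(p0)[names(p0) != "kcat14"])
  expect_identical(apply_variant(p0, "PP1_KO")[["PP1_T"]], 0)
  expect_identical(apply_variant(p0, "PDE1_KO")[["PDE1_T"]], 0)
  for (v in c("T286A", "PP1_KO", "PDE1_KO"))
    expect_identical(apply_variant(apply_variant(p0, v), v),
                     apply_variant(p0, v))
  expect_error(apply_variant(p0, "T306A"))
})

test_that("perturbation scales a single field and composes multiplicatively", {
  expect_identical(perturb(p0, "kcat14", 0), p0)
  expect_equal(perturb(p0, "CaMKII_T", -0.9)[["CaMKII_T"]], 2.0)
  expect_equal(perturb(p0, "kc1f", +0.9)[["kc1f"]], 95)
  # composition property over random fields/fractions
  set.seed(42)
  for (i in 1:20) {
    nm <- sample(names(p0), 1)
    f <- stats::runif(1, -0.9, 0.9); g <- stats::runif(1, -0.9, 0.9)
    a <- perturb(perturb(p0, nm, f), nm, g)[[nm]]
    b <- perturb(p0, nm, (1 + f) * (1 + g) - 1)[[nm]]
    expect_equal(a, b, tolerance = 1e-12)
  }
  expect_error(perturb(p0, "kc1f", -1))
  expect_error(perturb(p0, "nonexistent", 0.1))
})

test_that("serialisation round trip is bit-identical", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_parameters(p0, tmp)
  p2 <- read_parameters(tmp)
  expect_identical(unclass(p2), unclass(p0))
})

test_that("validation rejects incomplete or negative sets", {
  bad <- p0; bad[["kc1f"]] <- -1
  expect_error(validate_parameters(bad), "kc1f")
  expect_error(validate_parameters(unclass(p0)[-1]), "kon_NT")
})

test_that("the parameter table exports as CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_parameter_table(p0, tmp)
  tab <- read.csv(tmp)
  expect_setequal(tab$name, names(unclass(p0)))
  expect_equal(tab$value[tab$name == "CaM_T"], 17.7)
})
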