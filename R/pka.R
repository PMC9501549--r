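# Four-state PKA activation model and its Hill-equation reduction.
#
# cAMP activates PKA in two double-binding steps:
#   R2C2 + 2 cAMP <-> R2C2cAMP2       (k17f, k17b)
#   R2C2cAMP2 + 2 cAMP <-> R2C2cAMP4  (k18f, k18b)
#   R2C2cAMP4 <-> R2cAMP4 + 2 PKAc    (k19 pair)
# The released regulatory dimer is tracked implicitly as PKAc/2, so the
# regulatory pool R2C2_T is conserved by construction.
#
# The printed units of the k19 pair conflict with the release direction
# (a second-order rate labelled as release, a first-order rate labelled as
# rebinding). Both orientations are implemented behind a flag:
# "reversed" does first-order release at 0.0016 1/s with third-order
# rebinding at 0.25 1/(uM^2 s); "printed" swaps them. The steady-state
# oracle (select_k19_orientation) picks the orientation whose saturating
# activation matches the calibrated reduced-model maximum; that is the
# "reversed" orientation, which is also the dimensionally consistent one.

#' Derivatives of the four-state PKA activation sub-model
#'
#' @param s named numeric vector \code{c(R2C2, R2C2cAMP2, R2C2cAMP4, PKAc)}
#'   (µM).
#' @param cAMP clamped cAMP concentration (µM).
#' @param p a \code{cam_parameters} object.
#' @param k19_orientation \code{"reversed"} (default) or \code{"printed"}.
#' @return named derivative vector (µM/s). \code{R2C2 + R2C2cAMP2 +
#'   R2C2cAMP4 + PKAc/2} has zero net derivative.
#' @export
pka_full_rhs <- function(s, cAMP, p,
                         k19_orientation = c("reversed", "printed")) {
  k19_orientation <- match.arg(k19_orientation)
  if (any(s < 0)) stop("negative PKA sub-state", call. = FALSE)
  r2c2 <- s[[1]]; x2 <- s[[2]]; x4 <- s[[3]]; pkac <- s[[4]]
  v17 <- p[["k17f"]] * r2c2 * cAMP^2 - p[["k17b"]] * x2
  v18 <- p[["k18f"]] * x2 * cAMP^2 - p[["k18b"]] * x4
  v19 <- if (k19_orientation == "printed")
    p[["k19f"]] * x4 - p[["k19b"]] * (0.5 * pkac) * pkac^2
  else
    p[["k19b"]] * x4 - p[["k19f"]] * (0.5 * pkac) * pkac^2
  c(R2C2 = -v17, R2C2cAMP2 = v17 - v18, R2C2cAMP4 = v18 - v19,
    PKAc = 2 * v19)
}

#' Steady-state active PKA at clamped cAMP
#'
#' The clamped chain is detailed-balanced, so the steady state is the
#' algebraic equilibrium; it is found by root-finding on the released
#' catalytic-subunit concentration. \code{method = "integrate"} instead
#' integrates \code{\link{pka_full_rhs}} until the derivative norm falls
#' below \code{1e-10} µM/s; the two must agree (used as a cross-check in
#' the tests).
#'
#' @param cAMP clamped cAMP (µM).
#' @param p a \code{cam_parameters} object.
#' @param k19_orientation see \code{\link{pka_full_rhs}}.
#' @param method \code{"algebraic"} or \code{"integrate"}.
#' @return steady-state PKAc (µM).
#' @export
pka_steady_state <- function(cAMP, p,
                             k19_orientation = c("reversed", "printed"),
                             method = c("algebraic", "integrate")) {
  k19_orientation <- match.arg(k19_orientation)
  method <- match.arg(method)
  total <- p[["R2C2_T"]]
  if (cAMP <= 0) return(0)
  if (method == "integrate") {
    rhs <- function(t, y, parms)
      list(pka_full_rhs(y, cAMP, p, k19_orientation))
    y <- c(R2C2 = total, R2C2cAMP2 = 0, R2C2cAMP4 = 0, PKAc = 0)
    t_block <- 2000
    for (i in 1:50) {
      out <- deSolve::lsoda(y, c(0, t_block), rhs, NULL,
                            rtol = 1e-10, atol = 1e-14)
      y <- out[nrow(out), -1]
      if (max(abs(pka_full_rhs(y, cAMP, p, k19_orientation))) < 1e-10)
        return(unname(y[["PKAc"]]))
    }
    stop("PKA steady state not reached; residual ",
         max(abs(pka_full_rhs(y, cAMP, p, k19_orientation))), call. = FALSE)
  }
  K17 <- p[["k17f"]] / p[["k17b"]]
  K18 <- p[["k18f"]] / p[["k18b"]]
  denom <- 1 + K17 * cAMP^2 + K17 * K18 * cAMP^4
  krel <- if (k19_orientation == "printed") p[["k19f"]] else p[["k19b"]]
  kreb <- if (k19_orientation == "printed") p[["k19b"]] else p[["k19f"]]
  f <- function(pkac) {
    r0 <- (total - 0.5 * pkac) / denom
    x4 <- K17 * K18 * cAMP^4 * r0
    krel * x4 - kreb * (0.5 * pkac) * pkac^2
  }
  upper <- 2 * total
  if (f(upper) > 0) return(upper)  # fully released
  stats::uniroot(f, c(0, upper), tol = 1e-14)$root
}

#' Steady-state PKA dose-response over a cAMP grid
#'
#' @param p a \code{cam_parameters} object.
#' @param grid cAMP values (µM), spanning at most [0, 10].
#' @param k19_orientation see \code{\link{pka_full_rhs}}.
#' @return data.frame with columns \code{cAMP}, \code{PKAc}; monotone
#'   non-decreasing in \code{cAMP}.
#' @export
pka_dose_response <- function(p, grid = seq(0, 10, length.out = 101),
                              k19_orientation = c("reversed", "printed")) {
  k19_orientation <- match.arg(k19_orientation)
  stopifnot(all(grid >= 0), all(grid <= 10))
  data.frame(cAMP = grid,
             PKAc = vapply(grid, pka_steady_state, numeric(1),
                           p = p, k19_orientation = k19_orientation))
}

#' Fit the Hill dose-response reduction to a PKA activation curve
#'
#' The maximum is read off the curve, the half-activation point is found
#' by interpolation, and only the Hill coefficient is estimated by
#' nonlinear least squares on
#' \deqn{PKAc = PKA_{max} / (1 + (IC_{50}/cAMP)^{n}).}
#'
#' @param dose cAMP values (µM); at least 10 points spanning the
#'   transition.
#' @param response steady-state PKAc (µM); must be non-decreasing.
#' @return A \code{pka_fit} object: list with \code{PKA_max}, \code{IC50},
#'   \code{n_hill}, \code{r_squared}, and the input grid.
#' @export
fit_hill <- function(dose, response) {
  stopifnot(length(dose) == length(response), length(dose) >= 10)
  if (any(diff(response)[diff(dose) > 0] < -1e-12 * max(response)))
    stop("dose-response is not monotone non-decreasing", call. = FALSE)
  pka_max <- max(response)
  half <- pka_max / 2
  i <- which(response >= half)[1]
  if (is.na(i) || i == 1)
    stop("cannot bracket the half-activation point", call. = FALSE)
  ic50 <- dose[i - 1] + (half - response[i - 1]) /
    (response[i] - response[i - 1]) * (dose[i] - dose[i - 1])
  pos <- dose > 0
  df <- data.frame(x = dose[pos], y = response[pos])
  fit <- minpack.lm::nlsLM(y ~ pka_max / (1 + (ic50 / x)^n),
                           data = df, start = list(n = 2),
                           lower = 0.1, upper = 20,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  n_hill <- unname(stats::coef(fit)[["n"]])
  pred <- pka_max / (1 + (ic50 / df$x)^n_hill)
  r2 <- 1 - sum((df$y - pred)^2) / sum((df$y - mean(df$y))^2)
  structure(list(PKA_max = pka_max, IC50 = ic50, n_hill = n_hill,
                 r_squared = r2, dose = dose, response = response),
            class = "pka_fit")
}

#' Reduced (Hill) PKA activation
#'
#' Active PKA as an algebraic function of cAMP. Accepts either a
#' \code{pka_fit} (from \code{\link{fit_hill}}) or a
#' \code{cam_parameters} object carrying the calibrated constants
#' \code{PKA_max}, \code{IC50}, \code{n_pka}.
#'
#' @param cAMP cAMP concentration(s), µM.
#' @param fit a \code{pka_fit} or \code{cam_parameters} object.
#' @return PKAc (µM); 0 at cAMP = 0 (the limit).
#' @export
pka_reduced <- function(cAMP, fit) {
  if (inherits(fit, "pka_fit")) {
    m <- fit$PKA_max; k <- fit$IC50; n <- fit$n_hill
  } else {
    m <- fit[["PKA_max"]]; k <- fit[["IC50"]]; n <- fit[["n_pka"]]
  }
  ifelse(cAMP <= 0, 0, m / (1 + (k / cAMP)^n))
}

#' Select the k19 orientation by the steady-state oracle
#'
#' Computes the saturating steady-state activation (cAMP = 10 µM) under
#' both orientations of the release step and returns the orientation whose
#' value is closer to the calibrated reduced-model maximum carried in the
#' parameter set.
#'
#' @param p a \code{cam_parameters} object.
#' @return \code{"reversed"} or \code{"printed"}, with attribute
#'   \code{"PKAc_10uM"} giving both candidate values.
#' @export
select_k19_orientation <- function(p) {
  cand <- c(reversed = pka_steady_state(10, p, "reversed"),
            printed = pka_steady_state(10, p, "printed"))
  sel <- names(cand)[which.min(abs(cand - p[["PKA_max"]]))]
  structure(sel, PKAc_10uM = cand)
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("<pka_fit> PKA_max = %.4f uM, IC50 = %.4f uM, n = %.3f, R2 = %.4f\n",
              x$PKA_max, x$IC50, x$n_hill, x$r_squared))
  invisible(x)
}
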