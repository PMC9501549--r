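# Full reaction-network right-hand side and integration driver.
#
# The network couples the nine-state Ca2+-CaM module to reversible CaM4
# binding of five targets (AC1, AC8, PDE1, calcineurin A, CaMKII), CaMKII
# T286 autophosphorylation with 1000-fold CaM trapping, cAMP production
# (AC1/AC8/CaM-independent AC) and hydrolysis (PDE1, PDE4B/D), the PKA
# feedback loop on PDE4B/D, and inhibitor-1 regulation of PP1.
#
# Two right-hand sides exist on purpose: the compiled C version
# (src/camnet_rhs.c) used for production integrations, and the pure-R
# reference below, against which the C version is tested.

.state_names <- c(.cam_state_names,
                  "CaMAC1", "CaMAC8", "CaMPDE1", "CaMCaNA", "CaCaNB",
                  "CaMCaMKII", "CaMCaMKIIP", "CaMKIIP", "cAMP",
                  "PDE4BP", "PDE4DP", "I1P", "I1PP1",
                  "R2C2cAMP2", "R2C2cAMP4", "PKAc")

.hill <- function(x, K, n) ifelse(x <= 0, 0, (x / K)^n / (1 + (x / K)^n))

#' Reference implementation of the network right-hand side
#'
#' Pure-R version of the model derivatives, used as the independent
#' cross-check of the compiled right-hand side and as readable
#' documentation of the reaction fluxes. Free pools (inhibited targets,
#' free PP1, free inhibitor-1, ...) are derived algebraically from the
#' total pool constants, so every pool is conserved by construction.
#'
#' @param t time (s).
#' @param state named numeric vector of length 25 (see
#'   \code{\link{network_initial_state}} for the layout).
#' @param p a \code{cam_parameters} object.
#' @param proto a \code{stim_protocol}.
#' @param mode \code{"full_pka"} (four-state PKA activation dynamics) or
#'   \code{"reduced_pka"} (algebraic Hill activation by cAMP).
#' @param k19_orientation \code{"reversed"} (first-order catalytic-subunit
#'   release, third-order rebinding; the orientation selected by the
#'   steady-state oracle) or \code{"printed"}.
#' @return named numeric vector of derivatives (µM/s).
#' @export
network_rhs <- function(t, state, p, proto,
                        mode = c("reduced_pka", "full_pka"),
                        k19_orientation = c("reversed", "printed")) {
  mode <- match.arg(mode)
  k19_orientation <- match.arg(k19_orientation)
  y <- unname(state)
  if (any(!is.finite(y)))
    stop("non-finite state at t = ", t, ": ",
         paste(.state_names[!is.finite(y)], collapse = ", "), call. = FALSE)
  Ca <- calcium_trace(proto, t)
  d <- numeric(25)
  d[1:9] <- cam_fluxes(pmax(y[1:9], 0), Ca, p)

  CaM4 <- y[9]
  ac1f  <- p[["AC1_T"]] - y[10];  ac8f <- p[["AC8_T"]] - y[11]
  pde1f <- p[["PDE1_T"]] - y[12]
  canaf <- p[["PP2B_T"]] - y[13]; canbf <- p[["PP2B_T"]] - y[14]
  kiif  <- p[["CaMKII_T"]] - y[15] - y[16] - y[17]
  camp  <- y[18]
  pde4b <- p[["PDE4B_T"]] - y[19]; pde4d <- p[["PDE4D_T"]] - y[20]
  pp1f  <- p[["PP1_T"]] - y[22]
  i1f   <- p[["I1_T"]] - y[21] - y[22]

  gate  <- if (p[["PP2B_T"]] > 0) y[14] / p[["PP2B_T"]] else 0
  koff4 <- p[["kc4b1"]] * .hill(Ca, p[["Kd1"]], p[["n1"]]) +
           p[["kc4b2"]] * (1 - .hill(Ca, p[["Kd2"]], p[["n2"]]))
  v_ac1  <- p[["kc1f"]] * CaM4 * ac1f  - p[["kc1b"]] * y[10]
  v_ac8  <- p[["kc2f"]] * CaM4 * ac8f  - p[["kc2b"]] * y[11]
  v_pde1 <- p[["kc3f"]] * CaM4 * pde1f - p[["kc3b"]] * y[12]
  v_cana <- p[["kc4f"]] * gate * CaM4 * canaf - koff4 * y[13]
  v_canb <- p[["kB_on"]] * Ca * canbf - p[["kB_on"]] * p[["K1"]] * y[14]
  v_kii  <- p[["kc5f"]] * CaM4 * kiif  - p[["kc5b1"]] * y[15]
  v_kiip <- p[["kc5f"]] * CaM4 * y[17] - p[["kc5b2"]] * y[16]

  pnb <- if (p[["CaMKII_T"]] > 0) (y[15] + y[16]) / p[["CaMKII_T"]] else 0
  v_auto <- p[["kcat14"]] * y[15] * pnb

  S <- y[16] + y[17]
  if (S > 0) {
    v_dep <- p[["kcat15"]] * pp1f * S / (p[["Km15"]] + S) +
             p[["kcat16"]] * p[["PP2A_T"]] * S / (p[["Km16"]] + S)
    v_dep_b <- v_dep * y[16] / S
    v_dep_f <- v_dep * y[17] / S
  } else v_dep_b <- v_dep_f <- 0

  pkac <- if (mode == "full_pka") y[25] else pka_reduced(camp, p)

  v_prod <- p[["kcat1"]] * y[10] + p[["kcat2"]] * y[11] +
            p[["kcat3"]] * p[["ACstar_T"]]
  v_h1  <- (p[["kcat5"]] * pde1f + p[["kcat6"]] * y[12]) * camp / (p[["Km5"]] + camp)
  v_h4b <- (p[["kcat7"]] * pde4b + p[["kcat8"]] * y[19]) * camp / (p[["Km7"]] + camp)
  v_h4d <- (p[["kcat9"]] * pde4d + p[["kcat10"]] * y[20]) * camp / (p[["Km9"]] + camp)

  v_pb <- p[["kcat4"]] * pkac * pde4b / (p[["Km4"]] + pde4b)
  v_pd <- p[["kcat4"]] * pkac * pde4d / (p[["Km4"]] + pde4d)

  v_i1p <- p[["kcat11"]] * pkac * i1f / (p[["Km11"]] + i1f)
  v_i1d <- p[["kcat12"]] * p[["PP2A_T"]] * y[21] / (p[["Km12"]] + y[21]) +
           p[["kcat13"]] * y[13] * y[21] / (p[["Km13"]] + y[21])
  v_bind <- p[["kI1_on"]] * y[21] * pp1f - p[["kI1_off"]] * y[22]

  d[9]  <- d[9] - (v_ac1 + v_ac8 + v_pde1 + v_cana + v_kii + v_kiip)
  d[10] <- v_ac1; d[11] <- v_ac8; d[12] <- v_pde1
  d[13] <- v_cana; d[14] <- v_canb
  d[15] <- v_kii - v_auto + v_dep_b
  d[16] <- v_auto + v_kiip - v_dep_b
  d[17] <- -v_kiip - v_dep_f
  d[18] <- v_prod - v_h1 - v_h4b - v_h4d
  d[19] <- v_pb - p[["k10"]] * y[19]
  d[20] <- v_pd - p[["k10"]] * y[20]
  d[21] <- v_i1p - v_i1d - v_bind
  d[22] <- v_bind

  if (mode == "full_pka") {
    r2c2 <- p[["R2C2_T"]] - y[23] - y[24] - 0.5 * y[25]
    v17 <- p[["k17f"]] * r2c2 * camp^2 - p[["k17b"]] * y[23]
    v18 <- p[["k18f"]] * y[23] * camp^2 - p[["k18b"]] * y[24]
    v19 <- if (k19_orientation == "printed")
      p[["k19f"]] * y[24] - p[["k19b"]] * (0.5 * y[25]) * y[25]^2
    else
      p[["k19b"]] * y[24] - p[["k19f"]] * (0.5 * y[25]) * y[25]^2
    d[23] <- v17 - v18
    d[24] <- v18 - v19
    d[25] <- 2 * v19
    d[18] <- d[18] - 2 * v17 - 2 * v18
  }
  names(d) <- .state_names
  d
}

#' Resting initial state of the network
#'
#' All complexes, cAMP and phospho-forms start at zero; the free CaM pool
#' is distributed across the nine states at its equilibrium for basal
#' calcium.
#'
#' @param p a \code{cam_parameters} object.
#' @param proto a \code{stim_protocol} (supplies the basal calcium level).
#' @return named numeric state vector of length 25.
#' @export
network_initial_state <- function(p, proto) {
  y <- numeric(25)
  y[1:9] <- equilibrate_cam(proto$Ca_basal, p)
  names(y) <- .state_names
  y
}

#' Integrate the signalling network over a stimulation protocol
#'
#' Stiff (lsoda) integration from the resting state. Because calcium
#' pulses are instantaneous amplitude additions, the integration is
#' restarted at every pulse time so that the solver never steps across a
#' discontinuity; between pulses the right-hand side is smooth.
#'
#' @param p a \code{cam_parameters} object.
#' @param proto a \code{stim_protocol}.
#' @param mode \code{"reduced_pka"} (default; algebraic Hill PKA) or
#'   \code{"full_pka"} (four-state activation dynamics, required for cAMP
#'   and I1PP1 outputs).
#' @param t_end end of integration (s); defaults to train + 1 s.
#' @param dt_out output resolution (s).
#' @param rtol,atol solver tolerances.
#' @param k19_orientation see \code{\link{network_rhs}}.
#' @param engine \code{"compiled"} (C right-hand side) or \code{"R"}
#'   (reference implementation; slow, for testing).
#' @return A \code{sim_result} object: list with \code{time}, the state
#'   \code{trajectory} (matrix, one column per species), \code{Ca}, the
#'   protocol, mode and parameters.
#' @export
#' @examples
#' \donttest{
#' p <- default_parameters()
#' r <- integrate_network(p, make_protocol("HZ100"))
#' max(derived_series(r)$CaM4_total)
#' }
integrate_network <- function(p, proto, mode = c("reduced_pka", "full_pka"),
                              t_end = proto$total_duration, dt_out = 0.001,
                              rtol = 1e-8, atol = 1e-12,
                              k19_orientation = c("reversed", "printed"),
                              engine = c("compiled", "R")) {
  mode <- match.arg(mode)
  k19_orientation <- match.arg(k19_orientation)
  engine <- match.arg(engine)
  validate_parameters(p)

  y0 <- network_initial_state(p, proto)
  bounds <- sort(unique(c(0, proto$pulse_times[proto$pulse_times > 0 &
                                               proto$pulse_times < t_end], t_end)))

  if (engine == "compiled") {
    parms <- .pack_parms(p, proto, mode, k19_orientation)
    solver <- function(y, times) {
      deSolve::lsoda(y, times, func = "camnet_derivs", parms = parms,
                     dllname = "camnet", initfunc = "camnet_init",
                     nout = 1, outnames = "Ca", rtol = rtol, atol = atol)
    }
  } else {
    rhs <- function(t, y, parms)
      list(network_rhs(t, y, p, proto, mode, k19_orientation))
    solver <- function(y, times)
      deSolve::lsoda(y, times, func = rhs, parms = NULL,
                     rtol = rtol, atol = atol)
  }

  rows <- vector("list", length(bounds) - 1)
  y <- y0
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    n_int <- floor((b - a) / dt_out - 1e-9)
    seg <- c(a, if (n_int >= 1) a + dt_out * seq_len(n_int), b)
    seg <- seg[c(TRUE, diff(seg) > 1e-12)]
    out <- solver(y, seg)
    if (attr(out, "istate")[1] < 0)
      stop("solver failure in segment [", bounds[i], ", ", bounds[i + 1],
           "]; last good t = ", max(out[, 1]), call. = FALSE)
    y <- out[nrow(out), 1 + seq_len(25)]
    rows[[i]] <- out[if (i == 1) seq_len(nrow(out)) else -1, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  traj <- out[, 1 + seq_len(25), drop = FALSE]
  colnames(traj) <- .state_names
  Ca <- if (engine == "compiled") out[, "Ca"] else calcium_trace(proto, out[, 1])

  structure(list(time = unname(out[, 1]), trajectory = traj, Ca = unname(Ca),
                 proto = proto, mode = mode, params = p,
                 k19_orientation = k19_orientation),
            class = "sim_result")
}

# pack the canonical parameter vector + protocol extras for the C side
.pack_parms <- function(p, proto, mode, k19_orientation) {
  maxpulse <- 1024L
  np <- length(proto$pulse_times)
  if (np > maxpulse) stop("too many pulses (max 1024)", call. = FALSE)
  c(unname(unclass(p)[.param_names]),
    if (mode == "full_pka") 1 else 2,
    if (k19_orientation == "printed") 1 else 0,
    np, proto$amplitude, proto$tau, proto$Ca_basal,
    proto$pulse_times, rep(0, maxpulse - np))
}

#' Derived observable series of a simulation
#'
#' Recomputes, from the raw trajectory, the series the analyses work with:
#' total CaM4 (free plus target-bound), the CaM-bound amount of each
#' target, total phospho-T286 CaMKII (CaM-bound plus free phospho
#' subunits), active PP1, cAMP and the I1PP1 complex.
#'
#' @param r a \code{sim_result}.
#' @return data.frame with one row per output time.
#' @export
derived_series <- function(r) {
  tr <- r$trajectory
  p <- r$params
  data.frame(
    time = r$time,
    Ca = r$Ca,
    CaM4_free = tr[, "CaM4"],
    CaM4_total = tr[, "CaM4"] + tr[, "CaMAC1"] + tr[, "CaMAC8"] +
      tr[, "CaMPDE1"] + tr[, "CaMCaNA"] + tr[, "CaMCaMKII"] +
      tr[, "CaMCaMKIIP"],
    bound_AC1 = tr[, "CaMAC1"], bound_AC8 = tr[, "CaMAC8"],
    bound_PDE1 = tr[, "CaMPDE1"], bound_PP2B = tr[, "CaMCaNA"],
    bound_CaMKII = tr[, "CaMCaMKII"] + tr[, "CaMCaMKIIP"],
    pT286 = tr[, "CaMCaMKIIP"] + tr[, "CaMKIIP"],
    PP1_active = p[["PP1_T"]] - tr[, "I1PP1"],
    cAMP = tr[, "cAMP"], I1PP1 = tr[, "I1PP1"]
  )
}

#' Scalar summary of a named output over the train window
#'
#' @param r a \code{sim_result}.
#' @param which output series: \code{"CaM4_total"}, \code{"cAMP"} or
#'   \code{"I1PP1"}.
#' @param summary \code{"time_average"} (trapezoidal mean over the train,
#'   the default sensitivity-analysis statistic), \code{"end_of_train"}, or
#'   \code{"peak"}.
#' @return scalar (µM).
#' @export
observables <- function(r, which = c("CaM4_total", "cAMP", "I1PP1"),
                        summary = c("time_average", "end_of_train", "peak")) {
  which <- match.arg(which)
  summary <- match.arg(summary)
  ds <- derived_series(r)
  keep <- ds$time <= r$proto$train_end + 1e-12
  tt <- ds$time[keep]
  x <- ds[[which]][keep]
  switch(summary,
    time_average = sum(diff(tt) * (x[-length(x)] + x[-1]) / 2) / (max(tt) - min(tt)),
    end_of_train = x[length(x)],
    peak = max(x)
  )
}

#' Pool-conservation check of a trajectory
#'
#' For each conserved pool, reconstructs total = bound forms + implied free
#' pool at every output time and reports the worst relative violation of
#' 0 <= bound <= total (equivalently, free pool within [0, total]). The
#' free-CaM pool is carried dynamically, so its row measures true solver
#' drift; the other pools are closed algebraically, and their rows catch
#' any negative-excursion failure of the dynamic bound forms.
#'
#' @param r a \code{sim_result}.
#' @return named numeric vector of max relative errors per pool (zero
#'   means the pool is exactly conserved within bounds everywhere).
#' @export
conservation_errors <- function(r) {
  tr <- r$trajectory
  p <- r$params
  # bound-forms-by-pool; implied free = total - bound must lie in [0, total]
  bound <- list(
    CaMKII_T = tr[, "CaMCaMKII"] + tr[, "CaMCaMKIIP"] + tr[, "CaMKIIP"],
    AC1_T = tr[, "CaMAC1"], AC8_T = tr[, "CaMAC8"],
    PDE1_T = tr[, "CaMPDE1"], PP2B_T = tr[, "CaMCaNA"],
    PP1_T = tr[, "I1PP1"], I1_T = tr[, "I1P"] + tr[, "I1PP1"],
    PDE4B_T = tr[, "PDE4BP"], PDE4D_T = tr[, "PDE4DP"],
    R2C2_T = tr[, "R2C2cAMP2"] + tr[, "R2C2cAMP4"] + 0.5 * tr[, "PKAc"]
  )
  out <- vapply(names(bound), function(nm) {
    total <- p[[nm]]
    b <- bound[[nm]]
    viol <- max(0, max(b) - total, -min(b))
    viol / max(total, 1)
  }, numeric(1))
  cam <- rowSums(tr[, .cam_state_names, drop = FALSE]) + tr[, "CaMAC1"] +
    tr[, "CaMAC8"] + tr[, "CaMPDE1"] + tr[, "CaMCaNA"] +
    tr[, "CaMCaMKII"] + tr[, "CaMCaMKIIP"]
  c(CaM_T = max(abs(cam - p[["CaM_T"]])) / p[["CaM_T"]], out)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", x$proto$name, " (", x$mode, "), ",
      length(x$time), " time points to t = ", max(x$time), " s\n", sep = "")
  invisible(x)
}
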