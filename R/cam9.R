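# Nine-state Ca2+-calmodulin binding submodel.
#
# Each lobe (N, C) carries two calcium sites filled sequentially: the first
# ion binds at the tense-state (T) rate, and its binding relaxes the
# neighbouring EF-hand so that the second ion binds at the relaxed-state (R)
# rate. The lobes load independently, so the molecule occupies one of
# 3 x 3 = 9 states; only the fully loaded form (CaM4) binds targets.

# state order: C-lobe occupancy fast index, N-lobe occupancy slow index
.cam_state_names <- c("CaM0", "CaM1C", "CaM2C",
                      "CaM1N", "CaM1C1N", "CaM2C1N",
                      "CaM2N", "CaM1C2N", "CaM4")

.cam_idx <- function(c_occ, n_occ) c_occ + 3L * n_occ + 1L

#' Mass-action fluxes of the nine-state Ca2+-CaM model
#'
#' Computes the time derivative of each of the nine free CaM states at a
#' given free calcium concentration, with no target binding. The lobes are
#' independent 3-state chains; within a lobe the first ion binds with the
#' tense-state rates and the second with the relaxed-state rates. The nine
#' derivatives sum to zero (the free pool is closed here).
#'
#' @param s numeric vector of length 9, the free CaM state concentrations
#'   (µM), in the order \code{CaM0, CaM1C, CaM2C, CaM1N, CaM1C1N, CaM2C1N,
#'   CaM2N, CaM1C2N, CaM4}.
#' @param Ca free calcium (µM).
#' @param p a \code{cam_parameters} object.
#' @return numeric vector of length 9, d(state)/dt in µM/s.
#' @export
cam_fluxes <- function(s, Ca, p) {
  if (length(s) != 9L || any(s < 0))
    stop("state must be 9 non-negative concentrations", call. = FALSE)
  if (Ca < 0) stop("Ca must be >= 0", call. = FALSE)
  d <- numeric(9)
  kon_C <- c(p[["kon_CT"]], p[["kon_CR"]])
  koff_C <- c(p[["koff_CT"]], p[["koff_CR"]])
  kon_N <- c(p[["kon_NT"]], p[["kon_NR"]])
  koff_N <- c(p[["koff_NT"]], p[["koff_NR"]])
  for (n_occ in 0:2) {
    for (c_occ in 0:1) {  # C-lobe step c_occ -> c_occ + 1
      i <- .cam_idx(c_occ, n_occ); j <- .cam_idx(c_occ + 1L, n_occ)
      v <- kon_C[c_occ + 1L] * Ca * s[i] - koff_C[c_occ + 1L] * s[j]
      d[i] <- d[i] - v; d[j] <- d[j] + v
    }
  }
  for (c_occ in 0:2) {
    for (n_occ in 0:1) {  # N-lobe step n_occ -> n_occ + 1
      i <- .cam_idx(c_occ, n_occ); j <- .cam_idx(c_occ, n_occ + 1L)
      v <- kon_N[n_occ + 1L] * Ca * s[i] - koff_N[n_occ + 1L] * s[j]
      d[i] <- d[i] - v; d[j] <- d[j] + v
    }
  }
  names(d) <- .cam_state_names
  d
}

# analytic equilibrium weights of one 3-state lobe at clamped Ca
.lobe_weights <- function(Ca, kon_T, koff_T, kon_R, koff_R) {
  w1 <- if (Ca == 0) 0 else kon_T * Ca / koff_T
  w2 <- w1 * (if (Ca == 0) 0 else kon_R * Ca / koff_R)
  w <- c(1, w1, w2)
  w / sum(w)
}

#' Equilibrium distribution of the lone nine-state model at clamped calcium
#'
#' The two lobes load independently, so the equilibrium occupancy is the
#' tensor product of each lobe's analytic 3-state chain equilibrium, scaled
#' to the total CaM pool. Used to build resting initial conditions at basal
#' calcium.
#'
#' @param Ca clamped free calcium (µM).
#' @param p a \code{cam_parameters} object.
#' @param CaM_total pool to distribute (µM); defaults to \code{p["CaM_T"]}.
#' @return named numeric vector of length 9 (µM), summing to
#'   \code{CaM_total}.
#' @export
equilibrate_cam <- function(Ca, p, CaM_total = p[["CaM_T"]]) {
  if (Ca < 0) stop("Ca must be >= 0", call. = FALSE)
  wc <- .lobe_weights(Ca, p[["kon_CT"]], p[["koff_CT"]],
                      p[["kon_CR"]], p[["koff_CR"]])
  wn <- .lobe_weights(Ca, p[["kon_NT"]], p[["koff_NT"]],
                      p[["kon_NR"]], p[["koff_NR"]])
  s <- as.vector(outer(wc, wn)) * CaM_total  # c fast, n slow
  names(s) <- .cam_state_names
  s
}
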