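#' Stimulation protocols: calcium pulse trains
#'
#' The network is driven by a phenomenological free-calcium time course: a
#' train of instantaneous amplitude additions, each decaying exponentially,
#' on top of a basal level,
#' \deqn{Ca(t) = Ca_{basal} + A \sum_{i: t_i \le t} e^{-(t - t_i)/\tau}.}
#' Pulses arriving before the previous one has decayed therefore summate,
#' which is how higher frequencies reach higher calcium levels.
#'
#' \code{make_protocol} builds one of the four named induction protocols:
#' \describe{
#'   \item{LFS}{1 Hz, 0.4 µM per pulse, 30 pulses (depression-inducing).}
#'   \item{HZ10}{10 Hz, 1 µM per pulse, 10 pulses (1 s train).}
#'   \item{TBS}{theta burst: 10 epochs of 4 pulses at 100 Hz (10 ms apart),
#'     epochs separated by 0.2 s, 1 µM per pulse.}
#'   \item{HZ100}{100 Hz, 1 µM per pulse, 100 pulses (potentiation-inducing).}
#' }
#'
#' @param name protocol name.
#' @param A per-pulse amplitude (µM); defaults depend on the protocol.
#' @param n_pulses number of pulses (LFS/HZ10/HZ100) or epochs (TBS).
#' @param Ca_basal basal calcium (µM).
#' @param tau decay constant between pulses (s).
#' @return A \code{stim_protocol} object: list with fields \code{name},
#'   \code{frequency}, \code{amplitude}, \code{pulse_times}, \code{Ca_basal},
#'   \code{tau}, \code{train_end} (last pulse + one inter-pulse interval)
#'   and \code{total_duration} (train + 1 s follow-up).
#' @export
#' @examples
#' proto <- make_protocol("LFS")
#' length(proto$pulse_times)  # 30
#' calcium_trace(proto, c(0, 0.5, 1.0001))
make_protocol <- function(name = c("LFS", "HZ10", "TBS", "HZ100"),
                          A = NULL, n_pulses = NULL,
                          Ca_basal = 0.1, tau = 0.05) {
  name <- match.arg(name)
  spec <- switch(name,
    LFS   = list(f = 1,   A = 0.4, n = 30),
    HZ10  = list(f = 10,  A = 1,   n = 10),
    HZ100 = list(f = 100, A = 1,   n = 100),
    TBS   = list(f = 100, A = 1,   n = 10)  # n = epochs
  )
  if (!is.null(A)) spec$A <- A
  if (!is.null(n_pulses)) spec$n <- n_pulses
  stopifnot(spec$A > 0, spec$n >= 1, tau > 0, Ca_basal >= 0)

  if (name == "TBS") {
    # epochs of 4 pulses 10 ms apart, epoch onsets 0.2 s apart
    onsets <- (seq_len(spec$n) - 1) * 0.2
    pulse_times <- as.vector(outer(0:3 * 0.01, onsets, `+`))
    pulse_times <- sort(pulse_times)
    ipi <- 0.01
  } else {
    pulse_times <- (seq_len(spec$n) - 1) / spec$f
    ipi <- 1 / spec$f
  }
  train_end <- pulse_times[length(pulse_times)] + ipi
  structure(list(
    name = name, frequency = spec$f, amplitude = spec$A,
    n_pulses = length(pulse_times), pulse_times = pulse_times,
    inter_pulse = ipi, Ca_basal = Ca_basal, tau = tau,
    train_end = train_end, total_duration = train_end + 1
  ), class = "stim_protocol")
}

#' @rdname make_protocol
#' @param proto a \code{stim_protocol} object.
#' @param t time or vector of times (s).
#' @return \code{calcium_trace}: free calcium (µM) at each time.
#' @export
calcium_trace <- function(proto, t) {
  stopifnot(inherits(proto, "stim_protocol"), all(t >= 0))
  vapply(t, function(ti) {
    el <- ti - proto$pulse_times
    proto$Ca_basal + proto$amplitude * sum(exp(-el[el >= 0] / proto$tau))
  }, numeric(1))
}

#' Export a calcium trace as a two-column CSV
#'
#' @param proto a \code{stim_protocol}.
#' @param path output file.
#' @param dt sampling interval (s).
#' @export
write_trace <- function(proto, path, dt = 0.001) {
  t <- seq(0, proto$total_duration, by = dt)
  utils::write.csv(data.frame(t = t, Ca = calcium_trace(proto, t)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol> ", x$name, ": ", x$n_pulses, " pulses, A = ",
      x$amplitude, " uM, tau = ", x$tau, " s, train ", round(x$train_end, 3),
      " s\n", sep = "")
  invisible(x)
}
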