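# Simulation campaigns: protocol x variant grids and redistribution
# metrics on the CaM-bound target series.

#' Run a protocol-by-variant simulation grid
#'
#' Integrates the network for every combination of stimulation protocol
#' and knockout variant. Each run spans the full train plus 1 s
#' follow-up. Integration failures in one cell are caught and stored as
#' condition objects without aborting the rest of the grid.
#'
#' @param p baseline \code{cam_parameters}.
#' @param protocols character vector of protocol names
#'   (\code{"LFS"}, \code{"HZ10"}, \code{"TBS"}, \code{"HZ100"}).
#' @param variants character vector of variants (\code{"WT"},
#'   \code{"T286A"}, \code{"PP1_KO"}, \code{"PDE1_KO"}).
#' @param mode PKA mode passed to \code{\link{integrate_network}};
#'   reduced PKA is the default for CaM-output experiments, full PKA is
#'   required for cAMP/I1PP1 outputs.
#' @param ... further arguments to \code{\link{integrate_network}}.
#' @return named list (\code{"PROTOCOL:VARIANT"}) of \code{sim_result}
#'   objects (or conditions for failed cells).
#' @export
#' @examples
#' \donttest{
#' g <- run_grid(default_parameters(), "HZ100", c("WT", "T286A"))
#' redistribution_metrics(g[["HZ100:WT"]])
#' }
run_grid <- function(p, protocols = c("LFS", "HZ10", "TBS", "HZ100"),
                     variants = c("WT", "T286A", "PP1_KO", "PDE1_KO"),
                     mode = "reduced_pka", ...) {
  stopifnot(length(protocols) >= 1, length(variants) >= 1)
  out <- list()
  for (proto_name in protocols) {
    proto <- make_protocol(proto_name,
                           Ca_basal = p[["Ca_basal"]], tau = p[["tau_decay"]])
    for (v in variants) {
      key <- paste0(proto_name, ":", v)
      out[[key]] <- tryCatch(
        integrate_network(apply_variant(p, v), proto, mode = mode, ...),
        error = function(e) e)
    }
  }
  out
}

#' Peak/decline statistics of the CaM-bound target series
#'
#' For each CaM target, finds the peak bound concentration during the
#' train (earliest time on ties), the bound concentration at the end of
#' the train, and the decline fraction 1 - end/peak. During
#' high-frequency stimulation the low-affinity targets (AC1, AC8, PDE1)
#' peak mid-train and decline as CaM is redistributed to
#' phospho-CaMKII; the decline fraction quantifies that redistribution.
#'
#' @param r a \code{sim_result} spanning a full train.
#' @return data.frame with one row per target: \code{target},
#'   \code{peak}, \code{peak_time}, \code{end_of_train},
#'   \code{decline_fraction}.
#' @export
redistribution_metrics <- function(r) {
  ds <- derived_series(r)
  keep <- ds$time <= r$proto$train_end + 1e-12
  targets <- c("bound_AC1", "bound_AC8", "bound_PDE1",
               "bound_PP2B", "bound_CaMKII")
  rows <- lapply(targets, function(tg) {
    x <- ds[[tg]][keep]
    tt <- ds$time[keep]
    i <- which.max(x)  # which.max returns the earliest maximum
    peak <- x[i]
    endv <- x[length(x)]
    data.frame(target = sub("^bound_", "", tg),
               peak = peak, peak_time = tt[i], end_of_train = endv,
               decline_fraction = if (peak > 0) 1 - endv / peak else 0)
  })
  do.call(rbind, rows)
}
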