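# Configuration loading, result serialisation and run manifests.
# All concentrations are µM, times s, rates µM^-n s^-1 in every file;
# no unit conversion happens at any boundary.

#' Load a run configuration
#'
#' YAML file with up to three blocks: \code{parameters} (name-value
#' overrides of the baseline set), \code{protocol} (\code{name} plus
#' optional \code{A}, \code{n_pulses}, \code{Ca_basal}, \code{tau}), and
#' \code{gsa} (arguments of \code{\link{gsa_config}}). Unknown keys are
#' rejected with the offending key path; an empty file yields all
#' documented defaults.
#'
#' @param path YAML file.
#' @return list with elements \code{params} (\code{cam_parameters}),
#'   \code{proto} (\code{stim_protocol}), and \code{gsa}
#'   (\code{gsa_config} or NULL).
#' @export
load_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path, call. = FALSE)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), c("parameters", "protocol", "gsa"))
  if (length(bad))
    stop("unknown config block: ", paste(bad, collapse = ", "), call. = FALSE)

  p <- default_parameters()
  if (!is.null(cfg$parameters)) {
    bad <- setdiff(names(cfg$parameters), names(p))
    if (length(bad))
      stop("unknown key: parameters.", paste(bad, collapse = ", parameters."),
           call. = FALSE)
    p[names(cfg$parameters)] <- unlist(cfg$parameters)
    validate_parameters(p)
  }

  pr <- cfg$protocol
  if (is.null(pr)) pr <- list(name = "HZ100")
  bad <- setdiff(names(pr), c("name", "A", "n_pulses", "Ca_basal", "tau"))
  if (length(bad))
    stop("unknown key: protocol.", paste(bad, collapse = ", protocol."),
         call. = FALSE)
  proto <- make_protocol(pr$name,
                         A = pr$A, n_pulses = pr$n_pulses,
                         Ca_basal = if (is.null(pr$Ca_basal))
                           p[["Ca_basal"]] else pr$Ca_basal,
                         tau = if (is.null(pr$tau)) p[["tau_decay"]] else pr$tau)

  g <- NULL
  if (!is.null(cfg$gsa)) {
    allowed <- setdiff(names(formals(gsa_config)), "p")
    bad <- setdiff(names(cfg$gsa), allowed)
    if (length(bad))
      stop("unknown key: gsa.", paste(bad, collapse = ", gsa."), call. = FALSE)
    g <- do.call(gsa_config, c(list(p = p), cfg$gsa))
  }
  list(params = p, proto = proto, gsa = g)
}

#' Write a simulation result or PRCC table to disk
#'
#' \code{sim_result} objects export as tidy CSV (time, species, value)
#' or as a JSON summary (protocol, mode, observables);
#' \code{prcc_table} objects export their rows as CSV (parameter rows,
#' the printed-table layout) or full JSON with p-values and ranges.
#'
#' @param x a \code{sim_result} or \code{prcc_table}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"json"}.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(x, "sim_result")) {
    if (format == "csv") {
      tr <- x$trajectory
      long <- data.frame(
        time = rep(x$time, times = ncol(tr)),
        species = rep(colnames(tr), each = nrow(tr)),
        value = as.vector(tr))
      utils::write.csv(long, path, row.names = FALSE)
    } else {
      jsonlite::write_json(list(
        protocol = x$proto$name, mode = x$mode,
        observables = list(
          CaM4_total_peak = observables(x, "CaM4_total", "peak"),
          CaM4_total_end = observables(x, "CaM4_total", "end_of_train"),
          cAMP_end = observables(x, "cAMP", "end_of_train"),
          I1PP1_end = observables(x, "I1PP1", "end_of_train"))),
        path, auto_unbox = TRUE, digits = NA)
    }
  } else if (inherits(x, "prcc_table")) {
    if (format == "csv") {
      utils::write.csv(as.data.frame(x), path, row.names = FALSE)
    } else {
      jsonlite::write_json(list(
        output = attr(x, "output"), protocol = attr(x, "protocol"),
        seed = attr(x, "seed"), n_samples = attr(x, "n_samples"),
        excluded = attr(x, "excluded"), table = as.data.frame(x)),
        path, auto_unbox = TRUE, digits = NA)
    }
  } else stop("unsupported object", call. = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records the package version, a parameter-set hash (md5 of the
#' full-precision JSON serialisation, stable across platforms), the
#' protocol and solver settings, and a seed, sufficient to re-run the job
#' bit-identically.
#'
#' @param p a \code{cam_parameters} object.
#' @param proto a \code{stim_protocol}.
#' @param path output JSON file.
#' @param ... further scalar fields stored verbatim (mode, seed, ...).
#' @export
run_manifest <- function(p, proto, path, ...) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_parameters(p, tmp)
  jsonlite::write_json(list(
    tool = "camnet",
    version = as.character(utils::packageVersion("camnet")),
    parameter_hash = unname(tools::md5sum(tmp)),
    protocol = list(name = proto$name, n_pulses = proto$n_pulses,
                    A = proto$amplitude, tau = proto$tau,
                    Ca_basal = proto$Ca_basal),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    extra = list(...)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
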