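#' @useDynLib camnet, .registration = TRUE
NULL

# Canonical parameter ordering. The C right-hand side indexes the parameter
# vector positionally, so this order is load-bearing: never reorder, only
# append.
.param_names <- c(
  # nine-state CaM lobe kinetics (loaded from the packaged constants file)
  "kon_NT", "kon_NR", "koff_NT", "koff_NR",
  "kon_CT", "kon_CR", "koff_CT", "koff_CR",
  # CaM4-target binding
  "kc1f", "kc1b", "kc2f", "kc2b", "kc3f", "kc3b",
  "kc4f", "kc4b1", "Kd1", "n1", "kc4b2", "Kd2", "n2",
  "kc5f", "kc5b1", "kc5b2",
  # catalytic steps
  "kcat1", "kcat2", "kcat3", "kcat4", "Km4", "k10",
  "kcat5", "kcat6", "Km5", "kcat7", "kcat8", "Km7",
  "kcat9", "kcat10", "Km9", "kcat11", "Km11",
  "kcat12", "Km12", "kcat13", "Km13",
  "kcat14", "kcat15", "Km15", "kcat16", "Km16",
  # full PKA activation
  "k17f", "k17b", "k18f", "k18b", "k19f", "k19b",
  # reduced PKA (Hill) constants
  "PKA_max", "IC50", "n_pka",
  # total pools
  "CaM_T", "CaMKII_T", "AC1_T", "AC8_T", "ACstar_T", "PDE1_T",
  "PP2B_T", "PP1_T", "PP2A_T", "I1_T", "PDE4B_T", "PDE4D_T", "R2C2_T",
  # auxiliary constants (packaged file)
  "K1", "kB_on", "kI1_on", "kI1_off",
  # stimulus configuration
  "Ca_basal", "tau_decay"
)

.load_constants <- function() {
  path <- system.file("extdata", "model_constants.yaml", package = "camnet")
  if (identical(path, "") || !file.exists(path))
    stop("packaged constants file 'model_constants.yaml' not found", call. = FALSE)
  yaml::read_yaml(path)
}

#' Baseline parameter set of the CaM-CaMKII-PP1 network
#'
#' Returns the full set of rate constants, Michaelis and Hill constants,
#' total pool concentrations and stimulus constants of the model. The
#' printed kinetic table of the source network is transcribed here; the
#' nine-state lobe kinetics and a handful of auxiliary constants that were
#' never printed are loaded from the packaged constants file and the call
#' fails, naming the missing symbol, if any of them is absent.
#'
#' Units: concentrations in µM, time in s, on-rates in µM^-1 s^-1 (µM^-2
#' s^-1 for the bimolecular-squared cAMP/PKA steps), first-order rates in
#' s^-1.
#'
#' @return An object of class \code{cam_parameters}: a named numeric vector
#'   with one element per model constant.
#' @export
#' @examples
#' p <- default_parameters()
#' p[["CaM_T"]]          # 17.7 uM, the limiting CaM pool
#' p[["kc5b1"]] / p[["kc5b2"]]  # 1000-fold CaM trapping on T286 phosphorylation
default_parameters <- function() {
  cst <- .load_constants()
  need9 <- c("kon_NT", "koff_NT", "kon_NR", "koff_NR",
             "kon_CT", "koff_CT", "kon_CR", "koff_CR")
  needx <- c("Km7", "Km9", "K1", "kB_on", "kI1_on", "kI1_off")
  for (s in need9)
    if (is.null(cst$nine_state_rates[[s]]))
      stop("constant '", s, "' missing from packaged constants file", call. = FALSE)
  for (s in needx)
    if (is.null(cst$auxiliary[[s]]))
      stop("constant '", s, "' missing from packaged constants file", call. = FALSE)

  p <- c(
    unlist(cst$nine_state_rates[c("kon_NT", "kon_NR", "koff_NT", "koff_NR",
                                  "kon_CT", "kon_CR", "koff_CT", "koff_CR")]),
    # CaM4 binding to targets
    kc1f = 50, kc1b = 1,          # AC1
    kc2f = 20, kc2b = 1,          # AC8
    kc3f = 100, kc3b = 1,         # PDE1
    kc4f = 46, kc4b1 = 0.0012, Kd1 = 0.5, n1 = 1.8,   # CaNA, high-Ca branch
    kc4b2 = 2, Kd2 = 0.1, n2 = 3,                      # CaNA, low-Ca branch
    kc5f = 21, kc5b1 = 1.1, kc5b2 = 0.0011,            # CaMKII / CaMKII-P
    # catalysis
    kcat1 = 2.843, kcat2 = 2.843, kcat3 = 3,
    kcat4 = 18, Km4 = 25, k10 = 0.25,
    kcat5 = 1.7, kcat6 = 3.12, Km5 = 10,
    kcat7 = 1.56, kcat8 = 3.12, Km7 = cst$auxiliary$Km7,
    kcat9 = 5.4, kcat10 = 10.8, Km9 = cst$auxiliary$Km9,
    kcat11 = 1.4, Km11 = 5,
    kcat12 = 2, Km12 = 16, kcat13 = 2.8, Km13 = 3,
    kcat14 = 1.2, kcat15 = 1.72, Km15 = 11, kcat16 = 2, Km16 = 16,
    # full PKA
    k17f = 8, k17b = 0.02, k18f = 0.7, k18b = 0.2, k19f = 0.25, k19b = 0.0016,
    # reduced PKA (calibrated Hill constants)
    PKA_max = 0.2170, IC50 = 0.3760, n_pka = 2.569,
    # totals
    CaM_T = 17.7, CaMKII_T = 20, AC1_T = 2.5, AC8_T = 0.625, ACstar_T = 2.5,
    PDE1_T = 4, PP2B_T = 2.1, PP1_T = 3.5, PP2A_T = 0.11111, I1_T = 1.5,
    PDE4B_T = 1, PDE4D_T = 1, R2C2_T = 1.2,
    # auxiliary
    K1 = cst$auxiliary$K1, kB_on = cst$auxiliary$kB_on,
    kI1_on = cst$auxiliary$kI1_on, kI1_off = cst$auxiliary$kI1_off,
    # stimulus
    Ca_basal = 0.1, tau_decay = 0.05
  )
  p <- p[.param_names]
  names(p) <- .param_names
  validate_parameters(p)
  structure(p, class = "cam_parameters")
}

#' Validate a parameter set
#'
#' Checks that every constant is present, finite and non-negative, and that
#' the structural premises of the model hold: the 1000-fold CaM-trapping
#' ratio of phosphorylated CaMKII, and CaM being outnumbered by the summed
#' pools of its binding targets (the limiting-CaM premise).
#'
#' @param p named numeric vector of parameters.
#' @return \code{p}, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(p) {
  missing <- setdiff(.param_names, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  v <- unclass(p)[.param_names]
  if (!all(is.finite(v)))
    stop("non-finite parameter: ",
         paste(.param_names[!is.finite(v)], collapse = ", "), call. = FALSE)
  if (any(v < 0))
    stop("negative parameter: ",
         paste(.param_names[v < 0], collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Apply a knockout variant to a parameter set
#'
#' \code{"T286A"} removes T286 autophosphorylation (kcat14 = 0), the in
#' silico analogue of the knock-in mutant; \code{"PP1_KO"} and
#' \code{"PDE1_KO"} set the corresponding total pool to zero; \code{"WT"}
#' is the identity.
#'
#' @param p a \code{cam_parameters} object.
#' @param variant one of \code{"WT"}, \code{"T286A"}, \code{"PP1_KO"},
#'   \code{"PDE1_KO"}.
#' @return The modified parameter set.
#' @export
apply_variant <- function(p, variant = c("WT", "T286A", "PP1_KO", "PDE1_KO")) {
  variant <- match.arg(variant)
  switch(variant,
    WT = p,
    T286A = { p[["kcat14"]] <- 0; p },
    PP1_KO = { p[["PP1_T"]] <- 0; p },
    PDE1_KO = { p[["PDE1_T"]] <- 0; p }
  )
}

#' Scale one parameter by a fractional perturbation
#'
#' Used by the sensitivity machinery: \code{fraction = -0.9} and
#' \code{+0.9} span the ±90\% perturbation range.
#'
#' @param p a \code{cam_parameters} object.
#' @param name parameter name.
#' @param fraction fractional change; the field is scaled by
#'   \code{1 + fraction}. Must exceed -1 (rates cannot go negative).
#' @return The perturbed parameter set.
#' @export
perturb <- function(p, name, fraction) {
  if (!name %in% names(p))
    stop("unknown parameter: ", name, call. = FALSE)
  if (!is.finite(fraction) || fraction <= -1)
    stop("fraction must be a finite number > -1", call. = FALSE)
  p[[name]] <- p[[name]] * (1 + fraction)
  p
}

#' Write / read a parameter set (loss-free round trip)
#'
#' Serialisation uses full double precision so that a write/read round trip
#' reproduces every field bit-identically.
#'
#' @param p a \code{cam_parameters} object.
#' @param path file path (JSON).
#' @return \code{read_parameters} returns the \code{cam_parameters} object.
#' @export
write_parameters <- function(p, path) {
  jsonlite::write_json(as.list(unclass(p)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- unlist(x)[.param_names]
  names(p) <- .param_names
  validate_parameters(p)
  structure(p, class = "cam_parameters")
}

#' Export the full parameter table as CSV (provenance record)
#'
#' @param p a \code{cam_parameters} object.
#' @param path file path (CSV with columns name, value).
#' @export
export_parameter_table <- function(p, path) {
  utils::write.csv(
    data.frame(name = names(unclass(p)), value = as.numeric(p)),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cam_parameters <- function(x, ...) {
  cat("<cam_parameters> ", length(x), " constants; CaM_T = ",
      x[["CaM_T"]], " uM, CaMKII_T = ", x[["CaMKII_T"]], " uM\n", sep = "")
  invisible(x)
}
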