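# Global sensitivity analysis: LHS sampling over +/-90% ranges,
# one-at-a-time monotonicity screening with range truncation, partial
# rank correlation coefficients with t-based p-values, and
# Kolmogorov-Smirnov regionalised sensitivity.

# parameters varied by default in the GSA (rates and pools with a path to
# the three outputs; totals of fixed stoichiometric partners excluded)
.gsa_default_params <- c(
  "kon_NT", "kon_NR", "koff_NT", "koff_NR",
  "kon_CT", "kon_CR", "koff_CT", "koff_CR",
  "K1", "kcat3", "kcat5", "kcat11", "kcat14", "kcat15", "kcat16",
  "Km5", "Km9", "Km11", "Km15", "Km16",
  "kc1f", "kc1b", "kc2f", "kc2b", "kc3f", "kc3b", "kc4f",
  "kc5f", "kc5b1", "PKA_max",
  "AC1_T", "AC8_T", "CaMKII_T", "PDE1_T", "PP2B_T",
  "PP1_T", "PP2A_T", "I1_T", "PDE4B_T", "PDE4D_T", "ACstar_T")

#' Configuration of one global sensitivity analysis
#'
#' @param p baseline \code{cam_parameters}.
#' @param param_names parameters to vary (default: the curated model-wide
#'   list).
#' @param fraction perturbation range; ranges are baseline x [1-fraction,
#'   1+fraction] (default ±90\%).
#' @param n_samples LHS sample count (default 5000; a warning is issued
#'   below 10 x the parameter count).
#' @param output observable (\code{"CaM4_total"}, \code{"cAMP"},
#'   \code{"I1PP1"}).
#' @param protocol protocol name.
#' @param summary scalar summary over the train (see
#'   \code{\link{observables}}).
#' @param seed RNG seed for the LHS draw.
#' @param prcc_alpha significance threshold on PRCC p-values.
#' @param ks_alpha significance threshold for the KS screen.
#' @param screen run the monotonicity screen and truncate ranges?
#' @param screen_points one-at-a-time grid size per parameter.
#' @param dt_out,rtol,atol solver settings for the model evaluations.
#' @return A \code{gsa_config} list.
#' @export
gsa_config <- function(p, param_names = .gsa_default_params, fraction = 0.9,
                       n_samples = 5000, output = "CaM4_total",
                       protocol = "HZ100", summary = "time_average",
                       seed = 1L, prcc_alpha = 1e-4, ks_alpha = 0.01,
                       screen = TRUE, screen_points = 21,
                       dt_out = 0.01, rtol = 1e-6, atol = 1e-10) {
  stopifnot(fraction > 0, fraction < 1, n_samples >= 4)
  bad <- setdiff(param_names, names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  if (n_samples < 10 * length(param_names))
    warning("n_samples < 10 x parameter count; PRCC estimates will be noisy")
  base <- unclass(p)[param_names]
  structure(list(
    param_names = param_names,
    lower = base * (1 - fraction), upper = base * (1 + fraction),
    n_samples = as.integer(n_samples), output = output, protocol = protocol,
    summary = summary, seed = as.integer(seed),
    prcc_alpha = prcc_alpha, ks_alpha = ks_alpha,
    screen = screen, screen_points = screen_points,
    dt_out = dt_out, rtol = rtol, atol = atol,
    mode = if (output == "CaM4_total") "reduced_pka" else "full_pka"
  ), class = "gsa_config")
}

#' Latin hypercube sample over parameter ranges
#'
#' Stratified sampling: each parameter's range is split into
#' \code{n} equal strata, one point drawn uniformly in each, and strata
#' are paired across parameters by random permutation (via
#' \code{lhs::randomLHS}), giving evenly spread, minimally correlated
#' samples.
#'
#' @param n sample count.
#' @param lower,upper named vectors of range bounds.
#' @param seed optional RNG seed.
#' @return \code{n} x \code{k} matrix with parameter columns.
#' @export
lhs_sample <- function(n, lower, upper, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, length(lower))
  x <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(x) <- names(lower)
  x
}

#' Partial rank correlation coefficients with p-values
#'
#' All columns are rank-transformed; each parameter's PRCC is the partial
#' correlation between its ranks and the response ranks controlling for
#' all other parameters' ranks, computed from the precision matrix of the
#' joint rank-correlation matrix. p-values use the t statistic
#' \eqn{t = r \sqrt{(N - 2 - k')/(1 - r^2)}} with \eqn{k'} controlled
#' covariates.
#'
#' @param X sample matrix (one parameter per named column).
#' @param y response vector.
#' @param alpha significance threshold (default 1e-4, the table emission
#'   filter).
#' @return A \code{prcc_table}: data.frame with \code{parameter},
#'   \code{prcc}, \code{p_value}, \code{significant}.
#' @export
prcc <- function(X, y, alpha = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n, n > k + 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant parameter column: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  if (stats::sd(y) == 0)
    stop("constant response; PRCC undefined", call. = FALSE)
  R <- cbind(apply(X, 2, rank), .y = rank(y))
  C <- stats::cor(R)
  Om <- tryCatch(solve(C), error = function(e)
    stop("rank-degenerate design (a column is an exact monotone copy of ",
         "another or of the response); partial correlation is undefined",
         call. = FALSE))
  j <- k + 1
  r <- -Om[seq_len(k), j] / sqrt(diag(Om)[seq_len(k)] * Om[j, j])
  df <- n - 2 - (k - 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df)
  structure(data.frame(parameter = colnames(X), prcc = unname(r),
                       p_value = unname(pval),
                       significant = unname(pval < alpha),
                       row.names = NULL),
            class = c("prcc_table", "data.frame"), n_samples = n, alpha = alpha)
}

#' One-at-a-time monotonicity screen of a parameter
#'
#' Sweeps one parameter over a grid with all others at baseline, and
#' returns the largest contiguous subrange on which the response is
#' monotone (longer side of a unimodal response; ties go to the lower
#' side). Parameters with essentially flat response ("no correlation")
#' are excluded, as are subranges whose Spearman correlation falls below
#' the threshold. Failed model evaluations are dropped with a warning.
#'
#' @param model_fn function of one scalar (the parameter value) returning
#'   the scalar observable.
#' @param lower,upper the full perturbation range.
#' @param n_grid grid size (default 21).
#' @param flat_tol relative response variation under which the parameter
#'   counts as uncorrelated and is excluded.
#' @param rho_threshold minimum |Spearman rho| on the retained subrange.
#' @return list with \code{excluded} (logical), \code{lower},
#'   \code{upper}, \code{rho}, \code{grid}, \code{response}.
#' @export
monotonicity_screen <- function(model_fn, lower, upper, n_grid = 21,
                                flat_tol = 1e-6, rho_threshold = 0.5) {
  x <- seq(lower, upper, length.out = n_grid)
  y <- vapply(x, function(v)
    tryCatch(model_fn(v), error = function(e) NA_real_), numeric(1))
  if (anyNA(y)) {
    warning("model failed at ", sum(is.na(y)), " grid point(s); dropped")
    x <- x[!is.na(y)]; y <- y[!is.na(y)]
  }
  if (length(y) < 3) return(list(excluded = TRUE, reason = "too few points"))
  span <- diff(range(y))
  scale <- max(abs(y), span)
  if (span <= flat_tol * scale)
    return(list(excluded = TRUE, reason = "flat response",
                grid = x, response = y))
  d <- diff(y)
  tol <- flat_tol * span / length(d)
  best <- c(1L, 1L)  # start, end (point indices)
  for (dir in c(1, -1)) {
    ok <- dir * d >= -tol
    i <- 1L
    while (i <= length(ok)) {
      if (ok[i]) {
        j <- i
        while (j < length(ok) && ok[j + 1L]) j <- j + 1L
        if ((j - i) > (best[2] - best[1] - 1L) ||
            ((j - i) == (best[2] - best[1] - 1L) && i < best[1]))
          best <- c(i, j + 1L)
        i <- j + 1L
      }
      i <- i + 1L
    }
  }
  idx <- best[1]:best[2]
  sub_span <- diff(range(y[idx]))
  if (length(idx) < 3 || sub_span <= flat_tol * scale)
    return(list(excluded = TRUE, reason = "no correlated monotone subrange",
                grid = x, response = y))
  rho <- suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
  if (!is.finite(rho) || abs(rho) < rho_threshold)
    return(list(excluded = TRUE, reason = "subrange correlation below threshold",
                grid = x, response = y))
  list(excluded = FALSE, lower = x[best[1]], upper = x[best[2]],
       rho = rho, grid = x, response = y)
}

#' Kolmogorov-Smirnov regionalised sensitivity
#'
#' Splits the sample by a binary acceptance label and compares, per
#' parameter, the cumulative distributions of accepted vs rejected
#' values with the two-sample KS test. Parameters whose accepted and
#' rejected distributions differ at \code{alpha} are flagged sensitive.
#'
#' @param X sample matrix (parameter columns).
#' @param accepted logical vector, one label per row.
#' @param alpha significance threshold (default 0.01).
#' @return data.frame with \code{parameter}, \code{ks_D},
#'   \code{p_value}, \code{sensitive}.
#' @export
ks_regionalized <- function(X, accepted, alpha = 0.01) {
  X <- as.matrix(X)
  stopifnot(length(accepted) == nrow(X), is.logical(accepted))
  if (all(accepted) || !any(accepted))
    stop("no contrast: all samples share one acceptance label", call. = FALSE)
  res <- lapply(seq_len(ncol(X)), function(j) {
    kt <- suppressWarnings(
      stats::ks.test(X[accepted, j], X[!accepted, j]))
    data.frame(parameter = colnames(X)[j], ks_D = unname(kt$statistic),
               p_value = kt$p.value, sensitive = kt$p.value < alpha)
  })
  do.call(rbind, res)
}

#' Default acceptance predicate for the KS screen
#'
#' The regionalised screen needs a binary "acceptable behaviour" label per
#' sample; what counts as acceptable is a modelling choice, so
#' \code{\link{ks_regionalized}} takes the labels explicitly. This default
#' labels a sample acceptable when its output lies within ±\code{tol}
#' (default 50\%) of the baseline-run output — an artifact convention, not
#' a published criterion.
#'
#' @param y response vector (one value per sample).
#' @param baseline output of the unperturbed model.
#' @param tol relative half-width of the acceptance band.
#' @return logical vector of labels.
#' @export
ks_acceptance_default <- function(y, baseline, tol = 0.5) {
  stopifnot(is.finite(baseline), baseline != 0)
  abs(y - baseline) <= tol * abs(baseline)
}

# scalar observable for one perturbed parameter vector
.gsa_model_fn <- function(p, cfg) {
  proto <- make_protocol(cfg$protocol,
                         Ca_basal = p[["Ca_basal"]], tau = p[["tau_decay"]])
  function(values) {
    p2 <- p
    p2[names(values)] <- values
    r <- integrate_network(p2, proto, mode = cfg$mode,
                           dt_out = cfg$dt_out, rtol = cfg$rtol,
                           atol = cfg$atol)
    observables(r, cfg$output, cfg$summary)
  }
}

#' Run the full LHS-PRCC sensitivity pipeline
#'
#' Per-parameter monotonicity screening (with range truncation and
#' exclusion of uncorrelated parameters), Latin hypercube sampling over
#' the retained ranges, one model evaluation per sample, and PRCC with
#' p-values. The run aborts if more than 1\% of model evaluations fail.
#'
#' @param p baseline \code{cam_parameters}.
#' @param cfg a \code{gsa_config}.
#' @param progress print a line per pipeline stage?
#' @return A \code{prcc_table} with additional columns
#'   \code{range_low}/\code{range_high} (post-truncation) and attributes
#'   \code{output}, \code{protocol}, \code{seed}, \code{excluded}.
#' @export
run_gsa <- function(p, cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "gsa_config"))
  fn <- .gsa_model_fn(p, cfg)
  lower <- cfg$lower; upper <- cfg$upper
  excluded <- character(0)
  if (isTRUE(cfg$screen)) {
    for (nm in cfg$param_names) {
      sc <- monotonicity_screen(
        function(v) fn(stats::setNames(v, nm)),
        lower[[nm]], upper[[nm]], n_grid = cfg$screen_points)
      if (sc$excluded) {
        excluded <- c(excluded, nm)
        lower <- lower[names(lower) != nm]
        upper <- upper[names(upper) != nm]
      } else {
        lower[[nm]] <- sc$lower
        upper[[nm]] <- sc$upper
      }
      if (progress) message("screen ", nm, ": ",
                            if (nm %in% excluded) "excluded" else
                              sprintf("[%.3g, %.3g]", lower[[nm]], upper[[nm]]))
    }
  }
  if (length(lower) == 0)
    stop("all parameters excluded by the monotonicity screen", call. = FALSE)
  X <- lhs_sample(cfg$n_samples, lower, upper, seed = cfg$seed)
  y <- rep(NA_real_, nrow(X))
  for (i in seq_len(nrow(X))) {
    y[i] <- tryCatch(fn(X[i, ]), error = function(e) NA_real_)
    if (progress && i %% 100 == 0) message("sample ", i, "/", nrow(X))
  }
  fail <- mean(is.na(y))
  if (fail > 0.01)
    stop(sprintf("%.1f%% of model evaluations failed", 100 * fail),
         call. = FALSE)
  ok <- !is.na(y)
  tab <- prcc(X[ok, , drop = FALSE], y[ok], alpha = cfg$prcc_alpha)
  tab$range_low <- unname(lower[tab$parameter])
  tab$range_high <- unname(upper[tab$parameter])
  attr(tab, "output") <- cfg$output
  attr(tab, "protocol") <- cfg$protocol
  attr(tab, "summary") <- cfg$summary
  attr(tab, "seed") <- cfg$seed
  attr(tab, "excluded") <- excluded
  tab
}
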