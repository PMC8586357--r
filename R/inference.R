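# Least-squares calibration of the free rate ratios (gamma1, gamma3, and
# optionally m) against observed per-variant editing fractions.

# Normalise observations to a data.frame with ddEm, pt_obs, pb_obs, weights.
.obs_frame <- function(obs) {
  if (inherits(obs, "synthetic_dataset")) obs <- obs$data
  if (!is.data.frame(obs))
    stop_beselect("'obs' must be a data.frame of variant observations",
                  "beselect_validation_error")
  need <- c("ddEm", "pt_obs", "pb_obs")
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop_beselect(paste0("observations lack column(s): ",
                         paste(missing, collapse = ", ")),
                  "beselect_schema_error")
  keep <- !is.na(obs$pt_obs) & !is.na(obs$pb_obs)
  obs <- obs[keep, , drop = FALSE]
  if (any(obs$pt_obs < 0 | obs$pt_obs > 1 | obs$pb_obs < 0 | obs$pb_obs > 1))
    stop_beselect("observed editing fractions must lie in [0, 1]",
                  "beselect_validation_error")
  if (any(!is.finite(obs$ddEm)))
    stop_beselect("ddEm must be finite for every observation",
                  "beselect_validation_error")
  obs
}

.fit_objective <- function(obs, gamma1, gamma3, m, gamma2, ddE0, weights) {
  p <- tryCatch(
    .pt_pb_core(gamma1, gamma2, gamma3, m, ddE0, obs$ddEm),
    error = function(e) NULL)
  if (is.null(p)) return(1e10)
  sum(weights * ((p$p_t - obs$pt_obs)^2 + (p$p_b - obs$pb_obs)^2))
}

#' Options controlling the gamma fit
#'
#' @param bounds length-2 numeric, bounds on `log10(gamma1)` and
#'   `log10(gamma3)` (default `c(-8, 3)`).
#' @param n_grid coarse multi-start grid resolution per axis (default 5,
#'   i.e. 25 starts).
#' @param fit_m also fit the rebinding attenuation `m` in \[0, 1\]
#'   (default `FALSE`; the observables are nearly flat in `m`, so fitting it
#'   is rarely informative).
#' @param weight_by_sem weight squared residuals by `1/sem^2` when the
#'   observation table carries `pt_sem`/`pb_sem` columns (default `FALSE`:
#'   unweighted least squares over both target and bystander fractions).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(bounds = c(-8, 3), n_grid = 5, fit_m = FALSE,
                        weight_by_sem = FALSE) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2], n_grid >= 2)
  structure(list(bounds = bounds, n_grid = n_grid, fit_m = fit_m,
                 weight_by_sem = weight_by_sem), class = "fit_options")
}

#' Fit gamma1 and gamma3 to observed editing fractions
#'
#' Minimises the unweighted sum of squared residuals
#' `sum over variants of (pt_model - pt_obs)^2 + (pb_model - pb_obs)^2`,
#' where the model is the reduced closed form evaluated at each variant's
#' `ddEm` with `gamma2`, `m` and `ddE0` held fixed. The search runs in
#' `log10(gamma1), log10(gamma3)` space over `options$bounds`, using a
#' coarse multi-start grid followed by L-BFGS-B refinement from every start;
#' the procedure involves no randomness and is fully deterministic.
#'
#' @param obs variant observations: a data.frame with columns `ddEm`,
#'   `pt_obs`, `pb_obs` (e.g. from [read_variant_table()] or
#'   [generate_synthetic()]).
#' @param fixed named list with fixed `gamma2`, `m`, `ddE0`.
#' @param options a [fit_options()] list.
#' @return An object of class `fit_result`: `gamma1_hat`, `gamma3_hat`
#'   (and `m_hat` when fitted), `sse`, `residuals` (length
#'   `2 * nrow(obs)`, target then bystander per variant), `converged`,
#'   `n_restarts_used`, and the `fixed` values used.
#' @examples
#' truth <- a3a_calibration()
#' obs <- pt_pb_reduced(truth, ddEm = c(0, 1, 2.5, 3.5, 4.5))
#' names(obs) <- c("ddEm", "pt_obs", "pb_obs")
#' fit_gammas(obs, fixed = list(gamma2 = 11.4, m = 0, ddE0 = 6))
#' @export
fit_gammas <- function(obs,
                       fixed = list(gamma2 = 11.4, m = 0, ddE0 = 6),
                       options = fit_options()) {
  obs <- .obs_frame(obs)
  if (nrow(obs) < 2 || length(unique(obs$ddEm)) < 2)
    stop_beselect(
      "underdetermined fit: need >= 2 observations spanning >= 2 distinct ddEm values",
      "beselect_underdetermined_error")
  for (nm in c("gamma2", "m", "ddE0"))
    if (is.null(fixed[[nm]]))
      stop_beselect(sprintf("'fixed' must supply '%s'", nm),
                    "beselect_validation_error")
  if (!inherits(options, "fit_options")) options <- do.call(fit_options, options)

  weights <- rep(1, nrow(obs))
  if (options$weight_by_sem && all(c("pt_sem", "pb_sem") %in% names(obs))) {
    sem2 <- (obs$pt_sem^2 + obs$pb_sem^2) / 2
    weights <- ifelse(sem2 > 0, 1 / sem2, max(1 / sem2[sem2 > 0], 1))
  }

  lo <- options$bounds[1]; hi <- options$bounds[2]
  axis <- seq(lo, hi, length.out = options$n_grid)
  starts <- expand.grid(lg1 = axis, lg3 = axis)
  if (options$fit_m) starts$m <- 0.5

  obj <- function(par) {
    m_val <- if (options$fit_m) par[3] else fixed$m
    .fit_objective(obs, 10^par[1], 10^par[2], m_val,
                   fixed$gamma2, fixed$ddE0, weights)
  }
  lower <- c(lo, lo, if (options$fit_m) 0)
  upper <- c(hi, hi, if (options$fit_m) 1)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- as.numeric(starts[i, ])
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e3)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop_beselect("all optimizer starts failed", "beselect_fit_error")

  m_hat <- if (options$fit_m) best$par[3] else fixed$m
  g1 <- 10^best$par[1]; g3 <- 10^best$par[2]
  pred <- .pt_pb_core(g1, fixed$gamma2, g3, m_hat, fixed$ddE0, obs$ddEm)
  residuals <- c(pred$p_t - obs$pt_obs, pred$p_b - obs$pb_obs)
  structure(list(
    gamma1_hat = g1, gamma3_hat = g3,
    m_hat = if (options$fit_m) m_hat else NULL,
    sse = best$value, residuals = residuals,
    converged = best$convergence == 0,
    n_restarts_used = nrow(starts),
    fixed = fixed, n_obs = nrow(obs)),
    class = "fit_result")
}

#' Objective surface over a (gamma1, gamma3) grid
#'
#' Evaluates the fitting SSE at every node of a log10 grid, for diagnostics
#' and visual confirmation that the minimiser found by [fit_gammas()] sits
#' in the global basin.
#'
#' @param obs variant observations (see [fit_gammas()]).
#' @param fixed named list with fixed `gamma2`, `m`, `ddE0`.
#' @param log10_gamma1,log10_gamma3 numeric grid axes.
#' @return data.frame with columns `log10_gamma1`, `log10_gamma3`, `sse`.
#' @export
profile_objective <- function(obs, fixed = list(gamma2 = 11.4, m = 0, ddE0 = 6),
                              log10_gamma1 = seq(-8, 3, length.out = 23),
                              log10_gamma3 = seq(-8, 3, length.out = 23)) {
  obs <- .obs_frame(obs)
  if (!length(log10_gamma1) || !length(log10_gamma3))
    stop_beselect("grid axes must be nonempty", "beselect_validation_error")
  grid <- expand.grid(log10_gamma1 = log10_gamma1,
                      log10_gamma3 = log10_gamma3)
  grid$sse <- vapply(seq_len(nrow(grid)), function(i) {
    .fit_objective(obs, 10^grid$log10_gamma1[i], 10^grid$log10_gamma3[i],
                   fixed$m, fixed$gamma2, fixed$ddE0, rep(1, nrow(obs)))
  }, numeric(1))
  grid
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Gamma fit over %d observations (%d restarts):\n",
              x$n_obs, x$n_restarts_used))
  cat(sprintf("  gamma1_hat = %g   gamma3_hat = %g%s\n", x$gamma1_hat,
              x$gamma3_hat,
              if (!is.null(x$m_hat)) sprintf("   m_hat = %g", x$m_hat) else ""))
  cat(sprintf("  SSE = %g   converged: %s\n", x$sse, x$converged))
  invisible(x)
}
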