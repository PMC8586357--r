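# Explicit transition rates of the editing network and their mapping to and
# from the reduced dimensionless parameterisation.

#' Explicit transition rates of the editing network
#'
#' The full rate set of the two-cytidine editing chain. Rates share one
#' arbitrary time unit; outcome probabilities depend only on ratios.
#'
#' * `u0` Cas9 binding to the substrate; `u4` commitment to the
#'   unproductive/repaired state (these compete from the free state);
#' * `u1`/`u2` engagement of the target/bystander cytidine by the catalytic
#'   site; `w0` Cas9 dissociation;
#' * `u3` deamination chemistry; `w1`/`w2` unbinding of the engaged
#'   target/bystander cytidine;
#' * `m` attenuation of Cas9 rebinding after an edit (rebinding rate `m*u0`).
#'
#' @param u0,u1,u2,u3,u4,w0,w1,w2 non-negative rates; `u0`, `u1`, `u3`
#'   strictly positive.
#' @param m rebinding attenuation in \[0, 1\].
#' @return An object of class `rate_set`.
#' @export
rate_set <- function(u0, u1, u2, u3, u4, w0, w1, w2, m = 0) {
  check_scalar_number(u0, "u0", positive = TRUE)
  check_scalar_number(u1, "u1", positive = TRUE)
  check_scalar_number(u2, "u2", nonneg = TRUE)
  check_scalar_number(u3, "u3", positive = TRUE)
  check_scalar_number(u4, "u4", nonneg = TRUE)
  check_scalar_number(w0, "w0", nonneg = TRUE)
  check_scalar_number(w1, "w1", nonneg = TRUE)
  check_scalar_number(w2, "w2", nonneg = TRUE)
  check_scalar_number(m, "m", nonneg = TRUE)
  if (m > 1)
    stop_beselect(sprintf("'m' must lie in [0, 1] (got %g)", m),
                  "beselect_validation_error")
  structure(list(u0 = u0, u1 = u1, u2 = u2, u3 = u3, u4 = u4,
                 w0 = w0, w1 = w1, w2 = w2, m = m),
            class = "rate_set")
}

#' Build explicit rates from reduced parameters
#'
#' Absolute timescales are unidentifiable from outcome probabilities, so
#' three scales (`u0`, `u1`, `u3`) are free and default to 1. The remaining
#' rates follow from the definitions of the rate ratios and the Boltzmann
#' mapping of binding free energies onto unbinding rates:
#' `u4 = gamma1*u0`, `u2 = u1` (diffusion-controlled engagement is
#' context-blind), `w0 = gamma3*u1`, `w1 = gamma2*u3*exp(ddEm)`,
#' `w2 = w1*exp(ddE0)`.
#'
#' @param p a [reduced_params()] object.
#' @param scales positive numeric vector of length 3 giving the free scales
#'   for `u0`, `u1` and `u3` (default `c(1, 1, 1)`).
#' @return A [rate_set()] that reproduces `p` under [reduced_from_rates()].
#' @examples
#' rates_from_reduced(a3a_calibration())
#' @export
rates_from_reduced <- function(p, scales = c(1, 1, 1)) {
  stopifnot(inherits(p, "reduced_params"))
  if (!is.numeric(scales) || length(scales) != 3L || any(!is.finite(scales)) ||
      any(scales <= 0))
    stop_beselect("'scales' must be three strictly positive numbers",
                  "beselect_validation_error")
  u0 <- scales[[1]]; u1 <- scales[[2]]; u3 <- scales[[3]]
  w1 <- p$gamma2 * u3 * exp(p$ddEm)
  rate_set(u0 = u0, u1 = u1, u2 = u1, u3 = u3, u4 = p$gamma1 * u0,
           w0 = p$gamma3 * u1, w1 = w1, w2 = w1 * exp(p$ddE0), m = p$m)
}

#' Recover reduced parameters from explicit rates
#'
#' Inverts [rates_from_reduced()]. The engagement symmetry `u1 == u2` is a
#' structural assumption of the reduced model and is checked to relative
#' tolerance `tol`. `ddE0 = log(w2/w1)` always; `gamma2` and `ddEm` require a
#' wild-type reference unbinding rate: with the default `w1_wt = NULL` the
#' rate set itself is treated as wild type (`ddEm = 0`,
#' `gamma2 = w1/u3`), otherwise `gamma2 = w1_wt/u3` and
#' `ddEm = log(w1/w1_wt)`.
#'
#' @param r a [rate_set()] with `w1, w2 > 0`.
#' @param w1_wt optional wild-type unbinding rate (1/s) used as the `ddEm`
#'   reference.
#' @param tol relative tolerance for the `u1 == u2` consistency check.
#' @return A [reduced_params()] object.
#' @export
reduced_from_rates <- function(r, w1_wt = NULL, tol = 1e-9) {
  stopifnot(inherits(r, "rate_set"))
  if (abs(r$u1 - r$u2) > tol * max(r$u1, r$u2))
    stop_beselect(sprintf(
      "u1 (%g) and u2 (%g) differ beyond tolerance %g; the reduced model assumes symmetric engagement rates",
      r$u1, r$u2, tol), "beselect_consistency_error")
  if (r$w1 <= 0 || r$w2 <= 0)
    stop_beselect("w1 and w2 must be strictly positive to recover energies",
                  "beselect_validation_error")
  if (is.null(w1_wt)) {
    gamma2 <- r$w1 / r$u3
    ddEm <- 0
  } else {
    check_scalar_number(w1_wt, "w1_wt", positive = TRUE)
    gamma2 <- w1_wt / r$u3
    ddEm <- log(r$w1 / w1_wt)
  }
  reduced_params(gamma1 = r$u4 / r$u0, gamma2 = gamma2,
                 gamma3 = r$w0 / r$u1, m = r$m,
                 ddE0 = log(r$w2 / r$w1), ddEm = ddEm)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Editing-network rates (arbitrary time unit):\n")
  cat(sprintf("  u0 = %g  u1 = %g  u2 = %g  u3 = %g  u4 = %g\n",
              x$u0, x$u1, x$u2, x$u3, x$u4))
  cat(sprintf("  w0 = %g  w1 = %g  w2 = %g  m = %g\n",
              x$w0, x$w1, x$w2, x$m))
  invisible(x)
}
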