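# Analytical first-passage outcome probabilities of the editing network and
# the diagnostic selectivity ratios.

#' Outcome probabilities from explicit rates
#'
#' Closed-form first-passage (splitting) probabilities of the four absorbing
#' products of the editing chain: `CTC` (failed editing), `CTT` (target
#' only), `TTC` (bystander only) and `TTT` (both edited). The derivation is
#' first-step analysis on the 15-state chain: `p5`/`p6` are the probabilities
#' of first reaching the target-edited (state 5) / bystander-edited (state 6)
#' intermediates, and conditional completion probabilities from those states
#' split the remaining mass between single- and double-edit products.
#' Overall editing probabilities are `p_t = p_ctt + p_ttt` and
#' `p_b = p_ttc + p_ttt`.
#'
#' @param r a [rate_set()].
#' @return An object of class `outcome_probs`: a list with `p_ctc`, `p_ctt`,
#'   `p_ttc`, `p_ttt`, `p_t`, `p_b`, `p5`, `p6`.
#' @examples
#' outcomes_from_rates(rates_from_reduced(a3a_calibration()))
#' @export
outcomes_from_rates <- function(r) {
  stopifnot(inherits(r, "rate_set"))
  u0 <- r$u0; u1 <- r$u1; u2 <- r$u2; u3 <- r$u3; u4 <- r$u4
  w0 <- r$w0; w1 <- r$w1; w2 <- r$w2; m <- r$m

  # The first-step denominators are differences of large products as
  # usually written; they simplify to sums of positive terms, which avoids
  # catastrophic cancellation when unbinding rates span many decades.
  D <- (u0 + u4) * (u1 * u3 * (u3 + w2) + u2 * u3 * (u3 + w1)) +
    u4 * w0 * (u3 + w1) * (u3 + w2)
  if (!is.finite(D) || D <= 0)
    stop_beselect("singular model: zero or non-finite first-passage denominator",
                  "beselect_singular_error")
  p5 <- u0 * u1 * u3 * (u3 + w2) / D
  p6 <- u0 * u2 * u3 * (u3 + w1) / D

  # Conditional single-edit completion from states 5 and 6 (release before
  # the second cytidine is converted).
  D5 <- (u4 + m * u0) * u2 * u3 + u4 * w0 * (u3 + w2)
  D6 <- (u4 + m * u0) * u1 * u3 + u4 * w0 * (u3 + w1)
  if (!is.finite(D5) || D5 <= 0 || !is.finite(D6) || D6 <= 0)
    stop_beselect(
      "singular model: post-edit sub-network cannot reach absorption (check u4, m, w0)",
      "beselect_singular_error")
  q5 <- u4 * w0 * (u3 + w2) / D5
  q6 <- u4 * w0 * (u3 + w1) / D6

  p_ctt <- p5 * q5
  p_ttc <- p6 * q6
  p_ttt <- p5 * (1 - q5) + p6 * (1 - q6)
  p_ctc <- 1 - p_ctt - p_ttc - p_ttt
  structure(list(p_ctc = p_ctc, p_ctt = p_ctt, p_ttc = p_ttc, p_ttt = p_ttt,
                 p_t = p_ctt + p_ttt, p_b = p_ttc + p_ttt,
                 p5 = p5, p6 = p6),
            class = "outcome_probs")
}

# Vectorised reduced closed form over ddEm. Numerator and denominator are
# divided by (1+A)(1+B), A = gamma2*exp(ddEm), B = gamma2*exp(ddE0+ddEm), so
# every term stays O(1) while the Boltzmann factors span many decades.
.pt_pb_core <- function(gamma1, gamma2, gamma3, m, ddE0, ddEm) {
  A <- gamma2 * exp(ddEm)
  B <- gamma2 * exp(ddE0 + ddEm)
  G <- gamma1 + m
  H <- gamma1 * gamma3
  inv_a <- 1 / (1 + A)            # 1/(1+A)
  inv_b <- 1 / (1 + B)
  fa <- 1 / (1 + exp(-ddEm) / gamma2)          # A/(1+A), stable both tails
  fb <- 1 / (1 + exp(-(ddE0 + ddEm)) / gamma2) # B/(1+B)
  # N/((1+A)(1+B)) with N the shared numerator of the two closed forms
  n_ab <- (G + H) * inv_a + H * fa + G * inv_b
  # e^{ddE0}/(1+B) = 1/(e^{-ddE0} + gamma2 e^{ddEm})
  e0_term <- 1 / (exp(-ddE0) + gamma2 * exp(ddEm))
  k_ab <- (2 + 2 * gamma1 + H) -
    (1 + gamma1) * fa * (inv_b + 2 * fb + e0_term)
  if (any(!is.finite(k_ab)) || any(k_ab <= 0))
    stop_beselect("singular model: non-positive reduced-form denominator",
                  "beselect_singular_error")
  # p = (N/ab) / (F * K/ab); F11 = G+H+H*A, F12 = G+H+H*B
  f11 <- G + H + H * A
  f12 <- G + H + H * B
  list(p_t = n_ab / (f11 * k_ab), p_b = n_ab / (f12 * k_ab))
}

#' Overall editing probabilities from reduced parameters
#'
#' Evaluates the closed forms for the overall target (`p_t`) and bystander
#' (`p_b`) editing probabilities directly in the six reduced parameters.
#' Equals `outcomes_from_rates(rates_from_reduced(p))` restricted to
#' `(p_t, p_b)`; the reduced evaluation is rescaled by the dominant
#' Boltzmann factors and remains stable for energies up to +/- 300 k_B*T.
#'
#' @param p a [reduced_params()] object.
#' @param ddEm optional numeric vector overriding `p$ddEm` (vectorised
#'   evaluation for scans and fitting).
#' @return If `ddEm` is `NULL`, a named numeric vector `c(p_t=, p_b=)`;
#'   otherwise a data.frame with columns `ddEm`, `p_t`, `p_b`.
#' @examples
#' pt_pb_reduced(a3a_calibration())
#' pt_pb_reduced(a3a_calibration(), ddEm = c(0, 4.5))
#' @export
pt_pb_reduced <- function(p, ddEm = NULL) {
  stopifnot(inherits(p, "reduced_params"))
  if (is.null(ddEm)) {
    v <- .pt_pb_core(p$gamma1, p$gamma2, p$gamma3, p$m, p$ddE0, p$ddEm)
    return(c(p_t = v$p_t, p_b = v$p_b))
  }
  if (!is.numeric(ddEm) || any(!is.finite(ddEm)))
    stop_beselect("'ddEm' must be finite numeric", "beselect_validation_error")
  if (any(abs(ddEm) > .ENERGY_HARD_LIMIT) ||
      any(abs(ddEm + p$ddE0) > .ENERGY_HARD_LIMIT))
    stop_beselect(sprintf("|ddEm| (or |ddE0 + ddEm|) exceeds %g k_B*T",
                          .ENERGY_HARD_LIMIT), "beselect_range_error")
  v <- .pt_pb_core(p$gamma1, p$gamma2, p$gamma3, p$m, p$ddE0, ddEm)
  data.frame(ddEm = ddEm, p_t = v$p_t, p_b = v$p_b)
}

#' First-engagement selectivity ratio R1
#'
#' Ratio of the probability that the target cytidine is engaged and edited
#' first to the probability that the bystander is:
#' `R1 = (1 + gamma2*exp(ddE0+ddEm)) / (1 + gamma2*exp(ddEm))`.
#' In the regime where both Boltzmann terms dominate, `R1 -> exp(ddE0)`;
#' `R1 = 1` when `ddE0 = 0`.
#'
#' @param p a [reduced_params()] object.
#' @return The dimensionless ratio `r1 > 0`.
#' @export
ratio_r1 <- function(p) {
  stopifnot(inherits(p, "reduced_params"))
  (1 + p$gamma2 * exp(p$ddE0 + p$ddEm)) / (1 + p$gamma2 * exp(p$ddEm))
}

#' Post-target-edit outcome ratio R2
#'
#' After the target has been edited, the complex either releases (product
#' CTT) or goes on to edit the bystander (product TTT). The odds are
#' `R2 = P(CTT path) / P(TTT path) = gamma3 * (1 + gamma2*exp(ddE0+ddEm))`.
#' `R2 < 1` means the double edit dominates; driving `R2` above 1 by
#' increasing `ddEm` is the core of bystander suppression.
#'
#' The formula describes the no-rebinding chain (`m = 0`, the default
#' calibration assumption). With rebinding the realised CTT:TTT odds on the
#' network carry an extra factor `u4/(u4 + m*u0)`.
#'
#' @param p a [reduced_params()] object.
#' @return The dimensionless ratio `r2 >= 0`.
#' @export
ratio_r2 <- function(p) {
  stopifnot(inherits(p, "reduced_params"))
  p$gamma3 * (1 + p$gamma2 * exp(p$ddE0 + p$ddEm))
}

#' @export
print.outcome_probs <- function(x, digits = 4, ...) {
  cat("Editing outcome probabilities:\n")
  cat(sprintf("  CTC = %.*f  CTT = %.*f  TTC = %.*f  TTT = %.*f\n",
              digits, x$p_ctc, digits, x$p_ctt, digits, x$p_ttc,
              digits, x$p_ttt))
  cat(sprintf("  P_t = %.*f  P_b = %.*f\n", digits, x$p_t, digits, x$p_b))
  invisible(x)
}

#' Flatten outcome probabilities to a one-row data.frame
#'
#' @param x an `outcome_probs` object.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return One-row data.frame with columns `p_ctc`, `p_ctt`, `p_ttc`,
#'   `p_ttt`, `p_t`, `p_b`, `p5`, `p6`.
#' @export
as.data.frame.outcome_probs <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  as.data.frame(unclass(x), row.names = row.names, optional = optional, ...)
}
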