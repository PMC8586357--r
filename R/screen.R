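# Selectivity landscapes over the mutation perturbation ddEm, peak and
# design-window identification, candidate screening, and sensitivity scans.

#' Selectivity curve over a ddEm grid
#'
#' Evaluates the overall target and bystander editing probabilities and the
#' selectivity `S = p_t - p_b` along a grid of mutation-induced binding
#' perturbations, with all other reduced parameters held at `p`.
#'
#' @param p a [reduced_params()] object; its `ddEm` field is ignored (the
#'   grid is the swept variable).
#' @param ddEm strictly increasing numeric grid in k_B*T
#'   (default `seq(-5, 15, by = 0.05)`).
#' @return A data.frame of class `selectivity_curve` with columns `ddEm`,
#'   `p_t`, `p_b`, `S`; the generating parameters are kept in attribute
#'   `"params"`.
#' @examples
#' curve <- selectivity_scan(a3a_calibration())
#' curve$ddEm[which.max(curve$S)]
#' @export
selectivity_scan <- function(p, ddEm = seq(-5, 15, by = 0.05)) {
  stopifnot(inherits(p, "reduced_params"))
  if (!length(ddEm) || any(!is.finite(ddEm)))
    stop_beselect("'ddEm' grid must be nonempty and finite",
                  "beselect_validation_error")
  if (is.unsorted(ddEm, strictly = TRUE))
    stop_beselect("'ddEm' grid must be strictly increasing",
                  "beselect_validation_error")
  df <- pt_pb_reduced(p, ddEm = ddEm)
  df$S <- df$p_t - df$p_b
  attr(df, "params") <- p
  class(df) <- c("selectivity_curve", "data.frame")
  df
}

#' Locate the selectivity peak and design window
#'
#' Finds the grid argmax of `S` and refines it by golden-section search
#' between the neighbouring grid nodes (to `refine_tol` in k_B*T). The
#' design window is the contiguous `ddEm` interval around the peak where
#' `S >= fraction * s_max`, with endpoints located by root finding on the
#' smooth closed form (clamped to the grid range when the threshold is not
#' crossed). Grid ties break toward the smallest `ddEm`, i.e. the least
#' destabilising mutation.
#'
#' @param curve a [selectivity_scan()] result.
#' @param fraction window threshold as a fraction of peak selectivity
#'   (default 0.9).
#' @param refine_tol golden-section convergence tolerance (default 1e-4).
#' @return A list of class `peak_info`: `ddEm_peak`, `s_max`, `window`
#'   (length-2 numeric), `fraction`, `degenerate` (TRUE when the curve is
#'   flat at zero selectivity, e.g. `ddE0 = 0`).
#' @export
find_peak <- function(curve, fraction = 0.9, refine_tol = 1e-4) {
  stopifnot(inherits(curve, "selectivity_curve"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_beselect("'fraction' must lie in (0, 1]", "beselect_validation_error")
  p <- attr(curve, "params")
  s_fun <- function(x) {
    v <- .pt_pb_core(p$gamma1, p$gamma2, p$gamma3, p$m, p$ddE0, x)
    v$p_t - v$p_b
  }
  i <- which.max(curve$S)     # which.max takes the first (smallest ddEm) tie
  if (max(abs(curve$S)) < 1e-12) {
    return(structure(list(ddEm_peak = NA_real_, s_max = 0,
                          window = c(NA_real_, NA_real_),
                          fraction = fraction, degenerate = TRUE),
                     class = "peak_info"))
  }
  lo_i <- max(i - 1L, 1L); hi_i <- min(i + 1L, nrow(curve))
  ref <- golden_section_max(s_fun, curve$ddEm[lo_i], curve$ddEm[hi_i],
                            tol = refine_tol)
  ddEm_peak <- ref$x; s_max <- ref$value
  thresh <- fraction * s_max

  grid_lo <- curve$ddEm[1]; grid_hi <- curve$ddEm[nrow(curve)]
  below <- function(x) s_fun(x) - thresh
  # left edge: march down the grid from the peak until S drops under the
  # threshold, then bracket the crossing
  left <- grid_lo
  idx <- which(curve$ddEm < ddEm_peak & curve$S < thresh)
  if (length(idx)) {
    a <- curve$ddEm[max(idx)]
    left <- stats::uniroot(below, c(a, ddEm_peak), tol = refine_tol)$root
  }
  right <- grid_hi
  idx <- which(curve$ddEm > ddEm_peak & curve$S < thresh)
  if (length(idx)) {
    b <- curve$ddEm[min(idx)]
    right <- stats::uniroot(below, c(ddEm_peak, b), tol = refine_tol)$root
  }
  structure(list(ddEm_peak = ddEm_peak, s_max = s_max,
                 window = c(left, right), fraction = fraction,
                 degenerate = FALSE),
            class = "peak_info")
}

#' @export
print.peak_info <- function(x, ...) {
  if (x$degenerate) {
    cat("Selectivity peak: degenerate (curve identically ~0)\n")
  } else {
    cat(sprintf(
      "Selectivity peak: ddEm_peak = %.4f k_B*T, S_max = %.4f\n", x$ddEm_peak,
      x$s_max))
    cat(sprintf("  window (S >= %.2f * S_max): [%.4f, %.4f]\n", x$fraction,
                x$window[1], x$window[2]))
  }
  invisible(x)
}

#' Screen candidate mutations by predicted selectivity
#'
#' Predicts `(p_t, p_b, S)` for each candidate's `ddEm`, flags whether it
#' falls inside the design window of the selectivity landscape, and ranks
#' candidates by `S` (descending, name as deterministic tiebreaker).
#'
#' @param p a [reduced_params()] object describing the system (wild-type
#'   `ddEm` reference = 0).
#' @param candidates data.frame with columns `name`, `ddEm` (optionally
#'   `ddEm_sem`, carried through).
#' @param fraction design-window threshold passed to [find_peak()].
#' @param ddEm_grid grid for the underlying landscape scan.
#' @return data.frame of class `screen_result`, ordered by rank, with
#'   columns `name`, `ddEm`, (`ddEm_sem`,) `p_t`, `p_b`, `S`, `in_window`,
#'   `rank`; peak metadata in attribute `"peak"`.
#' @export
screen_candidates <- function(p, candidates, fraction = 0.9,
                              ddEm_grid = seq(-5, 15, by = 0.05)) {
  stopifnot(inherits(p, "reduced_params"))
  if (!is.data.frame(candidates) || !nrow(candidates))
    stop_beselect("'candidates' must be a nonempty data.frame",
                  "beselect_validation_error")
  if (!all(c("name", "ddEm") %in% names(candidates)))
    stop_beselect("'candidates' needs columns 'name' and 'ddEm'",
                  "beselect_schema_error")
  peak <- find_peak(selectivity_scan(p, ddEm_grid), fraction = fraction)
  pred <- pt_pb_reduced(p, ddEm = candidates$ddEm)
  out <- data.frame(name = as.character(candidates$name),
                    ddEm = candidates$ddEm,
                    stringsAsFactors = FALSE)
  if ("ddEm_sem" %in% names(candidates)) out$ddEm_sem <- candidates$ddEm_sem
  out$p_t <- pred$p_t
  out$p_b <- pred$p_b
  out$S <- pred$p_t - pred$p_b
  out$in_window <- if (peak$degenerate) rep(FALSE, nrow(out))
                   else out$ddEm >= peak$window[1] & out$ddEm <= peak$window[2]
  ord <- order(-out$S, out$name)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "peak") <- peak
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Sensitivity of the selectivity landscape to gamma1, gamma3 or m
#'
#' Rescales one reduced parameter by each factor and recomputes the
#' selectivity curve on a shared grid. Reproduces the standard diagnostic
#' scans: dividing `gamma1` raises the attainable peak selectivity while
#' leaving the unmutated (`ddEm = 0`) selectivity nearly unchanged; dividing
#' `gamma3` right-shifts the peak without changing its height; `m` has a
#' negligible effect at realistic calibrations.
#'
#' @param p base [reduced_params()].
#' @param param one of `"gamma1"`, `"gamma3"`, `"m"`.
#' @param factors positive multipliers applied to `param` (for `m`, the
#'   factors are absolute replacement values in \[0, 1\] instead, since the
#'   baseline is often exactly 0).
#' @param ddEm shared grid.
#' @return Named list of `selectivity_curve` objects, one per factor.
#' @export
sensitivity_scan <- function(p, param = c("gamma1", "gamma3", "m"),
                             factors = c(1, 1 / 5),
                             ddEm = seq(-5, 15, by = 0.05)) {
  stopifnot(inherits(p, "reduced_params"))
  param <- match.arg(param)
  if (!length(factors) || any(!is.finite(factors)))
    stop_beselect("'factors' must be finite and nonempty",
                  "beselect_validation_error")
  if (param != "m" && any(factors <= 0))
    stop_beselect("'factors' must be positive", "beselect_validation_error")
  out <- lapply(factors, function(f) {
    q <- unclass(p)
    q[[param]] <- if (param == "m") f else q[[param]] * f
    selectivity_scan(do.call(reduced_params, q[c("gamma1", "gamma2", "gamma3",
                                                 "m", "ddE0", "ddEm")]),
                     ddEm = ddEm)
  })
  names(out) <- paste0(param, "=",
                       vapply(out, function(cv) {
                         format(attr(cv, "params")[[param]])
                       }, character(1)))
  out
}
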