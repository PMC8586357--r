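# Synthetic editing observations: multinomial outcome counts per variant
# drawn from the model at known true parameters. This is the package's
# stated world for parameter-recovery tests: it emulates per-variant
# sequencing summaries (editing fractions across many independent cells),
# not read-level noise, locus context, or ddEm estimation error.

#' Generate synthetic per-variant editing observations
#'
#' For each variant (one `ddEm` value), draws `n_cells` independent editing
#' outcomes from the four-way categorical distribution (CTC/CTT/TTC/TTT)
#' given by the exact outcome probabilities at the true parameters, and
#' summarises them as observed fractions `pt_obs = (CTT+TTT)/n_cells`,
#' `pb_obs = (TTC+TTT)/n_cells`.
#'
#' @param true_params a [reduced_params()] object (its `ddEm` field is
#'   replaced per variant).
#' @param ddEm numeric vector of per-variant binding perturbations (k_B*T).
#' @param n_cells cells (independent outcomes) per variant; 0 yields
#'   missing observed fractions (`NA`), not 0/0.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param variant_id optional character vector of variant names.
#' @return An object of class `synthetic_dataset`: `params`, `seed`,
#'   `n_cells`, and `data` — a data.frame with columns `variant_id`, `ddEm`,
#'   `n_cells`, `n_ctc`, `n_ctt`, `n_ttc`, `n_ttt`, `pt_obs`, `pb_obs`.
#' @examples
#' generate_synthetic(a3a_calibration(), ddEm = c(0, 2.5, 4.5),
#'                    n_cells = 1000, seed = 1)
#' @export
generate_synthetic <- function(true_params, ddEm, n_cells = 1e4, seed,
                               variant_id = NULL) {
  stopifnot(inherits(true_params, "reduced_params"))
  if (!length(ddEm) || any(!is.finite(ddEm)))
    stop_beselect("'ddEm' must be nonempty and finite",
                  "beselect_validation_error")
  check_scalar_number(n_cells, "n_cells", nonneg = TRUE)
  n_cells <- as.integer(n_cells)
  if (is.null(variant_id)) variant_id <- sprintf("v%02d", seq_along(ddEm))
  if (length(variant_id) != length(ddEm))
    stop_beselect("'variant_id' must match 'ddEm' in length",
                  "beselect_validation_error")

  probs <- vapply(ddEm, function(e) {
    q <- unclass(true_params); q$ddEm <- e
    o <- outcomes_from_rates(rates_from_reduced(do.call(reduced_params, q)))
    c(o$p_ctc, o$p_ctt, o$p_ttc, o$p_ttt)
  }, numeric(4))

  counts <- with_seed(seed, {
    if (n_cells == 0) matrix(0L, 4, length(ddEm))
    else vapply(seq_along(ddEm),
                function(j) as.integer(stats::rmultinom(1, n_cells, probs[, j])),
                integer(4))
  })

  pt_obs <- if (n_cells > 0) (counts[2, ] + counts[4, ]) / n_cells
            else rep(NA_real_, length(ddEm))
  pb_obs <- if (n_cells > 0) (counts[3, ] + counts[4, ]) / n_cells
            else rep(NA_real_, length(ddEm))
  data <- data.frame(variant_id = variant_id, ddEm = ddEm,
                     n_cells = n_cells,
                     n_ctc = counts[1, ], n_ctt = counts[2, ],
                     n_ttc = counts[3, ], n_ttt = counts[4, ],
                     pt_obs = pt_obs, pb_obs = pb_obs,
                     stringsAsFactors = FALSE)
  structure(list(params = true_params, seed = seed, n_cells = n_cells,
                 data = data),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic editing dataset: %d variants x %d cells (seed %s)\n",
    nrow(x$data), x$n_cells, format(x$seed)))
  print(utils::head(x$data, 10))
  invisible(x)
}
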