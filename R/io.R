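# Tabular I/O: variant observation tables, candidate tables, and reports.
# CSV vs TSV is sniffed from the file extension; headers are matched
# case-insensitively and extra columns are ignored.

.read_delim_auto <- function(path) {
  if (!file.exists(path))
    stop_beselect(sprintf("file not found: %s", path), "beselect_io_error")
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

.match_columns <- function(df, schema, required, what) {
  lower <- tolower(names(df))
  idx <- match(tolower(schema), lower)
  names(idx) <- names(schema)
  missing <- names(schema)[is.na(idx) & names(schema) %in% required]
  if (length(missing))
    stop_beselect(sprintf("%s is missing required column(s): %s", what,
                          paste(schema[missing], collapse = ", ")),
                  "beselect_schema_error")
  idx
}

.num_col <- function(df, i, col, what) {
  x <- df[[i]]
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(v))
  if (length(bad))
    stop_beselect(sprintf("%s: unparseable numeric in column '%s' at row(s) %s",
                          what, col, paste(bad, collapse = ", ")),
                  "beselect_parse_error")
  v
}

#' Read a per-variant observation table
#'
#' Expected header (case-insensitive; extra columns are ignored):
#' `variant_id, ddEm_kBT, ddEm_sem, pt_obs, pb_obs, locus, n_reps`, of which
#' `variant_id`, `ddEm_kBT`, `pt_obs`, `pb_obs` are required. Delimiter is
#' sniffed from the extension (`.csv` comma; `.tsv`/`.txt`/`.tab` tab).
#' Malformed rows are reported with their row numbers.
#'
#' @param path input file path.
#' @return data.frame of class `variant_table` with columns `variant_id`,
#'   `ddEm`, `ddEm_sem`, `pt_obs`, `pb_obs`, `locus`, `n_reps`.
#' @export
read_variant_table <- function(path) {
  df <- .read_delim_auto(path)
  schema <- c(variant_id = "variant_id", ddEm = "ddEm_kBT",
              ddEm_sem = "ddEm_sem", pt_obs = "pt_obs", pb_obs = "pb_obs",
              locus = "locus", n_reps = "n_reps")
  idx <- .match_columns(df, schema,
                        required = c("variant_id", "ddEm", "pt_obs", "pb_obs"),
                        what = basename(path))
  out <- data.frame(variant_id = as.character(df[[idx[["variant_id"]]]]),
                    stringsAsFactors = FALSE)
  out$ddEm <- .num_col(df, idx[["ddEm"]], "ddEm_kBT", basename(path))
  out$ddEm_sem <- if (!is.na(idx[["ddEm_sem"]]))
    .num_col(df, idx[["ddEm_sem"]], "ddEm_sem", basename(path)) else NA_real_
  out$pt_obs <- .num_col(df, idx[["pt_obs"]], "pt_obs", basename(path))
  out$pb_obs <- .num_col(df, idx[["pb_obs"]], "pb_obs", basename(path))
  out$locus <- if (!is.na(idx[["locus"]]))
    as.character(df[[idx[["locus"]]]]) else NA_character_
  out$n_reps <- if (!is.na(idx[["n_reps"]]))
    .num_col(df, idx[["n_reps"]], "n_reps", basename(path)) else NA_real_

  bad <- which(!is.na(out$pt_obs) & (out$pt_obs < 0 | out$pt_obs > 1) |
                 !is.na(out$pb_obs) & (out$pb_obs < 0 | out$pb_obs > 1))
  if (length(bad))
    stop_beselect(sprintf(
      "%s: editing fractions outside [0, 1] at row(s) %s", basename(path),
      paste(bad, collapse = ", ")), "beselect_validation_error")
  bad <- which(!is.finite(out$ddEm))
  if (length(bad))
    stop_beselect(sprintf("%s: non-finite ddEm_kBT at row(s) %s",
                          basename(path), paste(bad, collapse = ", ")),
                  "beselect_validation_error")
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Write a variant observation table
#'
#' Inverse of [read_variant_table()]; emits the canonical header so that
#' write -> read round-trips preserve all fields.
#'
#' @param x a `variant_table` (or compatible data.frame).
#' @param path output path; delimiter sniffed from extension.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  cols <- c(variant_id = "variant_id", ddEm = "ddEm_kBT",
            ddEm_sem = "ddEm_sem", pt_obs = "pt_obs", pb_obs = "pb_obs",
            locus = "locus", n_reps = "n_reps")
  out <- data.frame(row.names = seq_len(nrow(x)))
  for (nm in names(cols))
    out[[cols[[nm]]]] <- if (nm %in% names(x)) x[[nm]] else NA
  ext <- tolower(tools::file_ext(path))
  sep <- if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a candidate-mutation table
#'
#' Required columns (case-insensitive): `name`, `ddEm_kBT`; optional
#' `ddEm_sem`.
#'
#' @param path input file path (CSV or TSV by extension).
#' @return data.frame with columns `name`, `ddEm`, `ddEm_sem`.
#' @export
read_candidate_table <- function(path) {
  df <- .read_delim_auto(path)
  schema <- c(name = "name", ddEm = "ddEm_kBT", ddEm_sem = "ddEm_sem")
  idx <- .match_columns(df, schema, required = c("name", "ddEm"),
                        what = basename(path))
  out <- data.frame(name = as.character(df[[idx[["name"]]]]),
                    stringsAsFactors = FALSE)
  out$ddEm <- .num_col(df, idx[["ddEm"]], "ddEm_kBT", basename(path))
  out$ddEm_sem <- if (!is.na(idx[["ddEm_sem"]]))
    .num_col(df, idx[["ddEm_sem"]], "ddEm_sem", basename(path)) else NA_real_
  bad <- which(!is.finite(out$ddEm))
  if (length(bad))
    stop_beselect(sprintf("%s: non-finite ddEm_kBT at row(s) %s",
                          basename(path), paste(bad, collapse = ", ")),
                  "beselect_validation_error")
  out
}

#' Write an analysis report
#'
#' Dispatches on the result type: flat JSON records for outcome
#' probabilities and fit results (full precision), TSV for curves and screen
#' tables.
#'
#' @param x an `outcome_probs`, `fit_result`, `selectivity_curve`,
#'   `screen_result` or `simulation_result` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) UseMethod("write_report")

#' @export
write_report.outcome_probs <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_report.fit_result <- function(x, path) {
  out <- list(gamma1_hat = x$gamma1_hat, gamma3_hat = x$gamma3_hat,
              m_hat = x$m_hat, sse = x$sse, converged = x$converged,
              n_restarts_used = x$n_restarts_used, n_obs = x$n_obs,
              fixed = x$fixed, residuals = x$residuals)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
write_report.simulation_result <- function(x, path) {
  out <- list(counts = as.list(x$counts), freq = as.list(x$freq),
              se = as.list(x$se), n_traj = x$n_traj, seed = x$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_report.selectivity_curve <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
write_report.screen_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
write_report.data.frame <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
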