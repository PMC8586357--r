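# Model parameters: enzyme kinetics, reduced dimensionless parameters, and
# the energy -> rate Boltzmann mapping.

#' Enzyme kinetic constants of the deaminase
#'
#' Bundles the Michaelis-Menten description of deaminase activity on ssDNA:
#' the dissociation constant `Kd`, the Michaelis constant `KM` and the
#' catalytic rate `kcat`. These are the independently measured quantities
#' from which the site-level kinetics (substrate on-rate, wild-type cytidine
#' unbinding rate, deamination rate) are inferred.
#'
#' @param Kd dissociation constant (concentration units, e.g. uM); > 0.
#' @param KM Michaelis constant (same units as `Kd`); must exceed `Kd`,
#'   otherwise the inferred on-rate `kcat / (KM - Kd)` is not positive.
#' @param kcat catalytic (deamination) rate, 1/s; > 0.
#' @return An object of class `enzyme_kinetics`.
#' @examples
#' enzyme_kinetics(Kd = 57, KM = 62, kcat = 1.1)
#' @seealso [infer_site_kinetics()]
#' @export
enzyme_kinetics <- function(Kd, KM, kcat) {
  check_scalar_number(Kd, "Kd", positive = TRUE)
  check_scalar_number(KM, "KM", positive = TRUE)
  check_scalar_number(kcat, "kcat", positive = TRUE)
  if (KM <= Kd)
    stop_beselect(sprintf(
      "KM must exceed Kd for a positive inferred on-rate (KM = %g <= Kd = %g)",
      KM, Kd), "beselect_domain_error")
  structure(list(Kd = Kd, KM = KM, kcat = kcat), class = "enzyme_kinetics")
}

#' Infer site-level kinetics from Michaelis-Menten constants
#'
#' Under a simple binding-then-chemistry scheme, `KM = Kd + kcat/kon`, so the
#' substrate-engagement rate constant is `kon = kcat / (KM - Kd)`, the
#' wild-type unbinding rate of cytidine from the catalytic site is
#' `w1_wt = Kd * kon`, and the chemical (deamination) rate is `u3 = kcat`.
#' The dimensionless ratio `gamma2 = w1_wt / u3` measures how many unbinding
#' attempts occur per chemical conversion once the cytidine is engaged.
#'
#' For APOBEC3A the published constants Kd = 57 uM, KM = 62 uM,
#' kcat = 1.1 /s give `w1_wt = 12.54 /s` and `gamma2 = 11.4`.
#'
#' @param ek an [enzyme_kinetics()] object.
#' @return An object of class `site_kinetics` with fields `kon`
#'   (1/(conc * s)), `w1_wt` (1/s), `u3` (1/s) and `gamma2` (dimensionless).
#' @examples
#' sk <- infer_site_kinetics(enzyme_kinetics(57, 62, 1.1))
#' sk$w1_wt   # 12.54
#' sk$gamma2  # 11.4
#' @export
infer_site_kinetics <- function(ek) {
  if (!inherits(ek, "enzyme_kinetics"))
    ek <- do.call(enzyme_kinetics, as.list(ek)[c("Kd", "KM", "kcat")])
  kon <- ek$kcat / (ek$KM - ek$Kd)
  w1_wt <- ek$Kd * kon
  u3 <- ek$kcat
  structure(list(kon = kon, w1_wt = w1_wt, u3 = u3, gamma2 = w1_wt / u3),
            class = "site_kinetics")
}

#' Reduced dimensionless parameters of the editing model
#'
#' The outcome probabilities of the two-cytidine editing network depend on
#' rates only through six dimensionless quantities:
#' * `gamma1 = u4/u0` — unproductive-initiation vs productive-binding rate
#'   ratio (fraction of editor encounters that commit to the inactive state);
#' * `gamma2 = w1_wt/u3` — wild-type cytidine unbinding vs deamination
#'   chemistry at the catalytic site;
#' * `gamma3 = w0/u1` — Cas9 dissociation vs cytidine engagement (inverse
#'   residence-time measure of the Cas9 anchor);
#' * `m` in \[0, 1\] — attenuation of Cas9 rebinding after a completed edit
#'   has changed the protospacer;
#' * `ddE0` — binding free-energy penalty (k_B*T) of engaging the bystander's
#'   sequence context relative to the target's;
#' * `ddEm` — mutation-induced perturbation (k_B*T) of the deaminase-ssDNA
#'   binding free energy relative to wild type, the design variable.
#'
#' Energies act on unbinding rates through Boltzmann factors:
#' `w1 = gamma2 * u3 * exp(ddEm)` and `w2 = w1 * exp(ddE0)`.
#'
#' @param gamma1,gamma2,gamma3 positive rate ratios (`gamma3 = 0` is
#'   admitted as the no-dissociation boundary used by diagnostic ratios).
#' @param m rebinding attenuation in \[0, 1\].
#' @param ddE0,ddEm free energies in k_B*T (any sign; warning above
#'   |50|, hard error above |300| to avoid overflow).
#' @return An object of class `reduced_params`.
#' @examples
#' a3a_calibration()
#' reduced_params(gamma1 = 2.1, gamma2 = 11.4, gamma3 = 2.9e-5,
#'                m = 0, ddE0 = 6, ddEm = 4.5)
#' @export
reduced_params <- function(gamma1, gamma2, gamma3, m = 0, ddE0 = 0, ddEm = 0) {
  check_scalar_number(gamma1, "gamma1", positive = TRUE)
  check_scalar_number(gamma2, "gamma2", positive = TRUE)
  check_scalar_number(gamma3, "gamma3", nonneg = TRUE)
  check_scalar_number(m, "m", nonneg = TRUE)
  if (m > 1)
    stop_beselect(sprintf("'m' must lie in [0, 1] (got %g)", m),
                  "beselect_validation_error")
  check_energy(ddE0, "ddE0")
  check_energy(ddEm, "ddEm")
  structure(list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 m = m, ddE0 = ddE0, ddEm = ddEm),
            class = "reduced_params")
}

#' A3A-BE3 calibration constants
#'
#' Convenience constructor for the reduced parameters calibrated for
#' APOBEC3A-BE3 editing a TC-motif site: `gamma1 = 2.1`,
#' `gamma2 = 11.4` (from Kd/KM/kcat), `gamma3 = 2.9e-5`, `m = 0`,
#' `ddE0 = 6` k_B*T (TC vs GC motif penalty), and `ddEm` as given.
#'
#' @param ddEm mutation-induced binding perturbation in k_B*T (default 0,
#'   wild type).
#' @return A [reduced_params()] object.
#' @export
a3a_calibration <- function(ddEm = 0) {
  reduced_params(gamma1 = 2.1, gamma2 = 11.4, gamma3 = 2.9e-5,
                 m = 0, ddE0 = 6, ddEm = ddEm)
}

#' @export
print.enzyme_kinetics <- function(x, ...) {
  cat(sprintf("Enzyme kinetics: Kd = %g, KM = %g, kcat = %g /s\n",
              x$Kd, x$KM, x$kcat))
  invisible(x)
}

#' @export
print.site_kinetics <- function(x, ...) {
  cat(sprintf(
    "Site kinetics: kon = %g, w1_wt = %g /s, u3 = %g /s, gamma2 = %g\n",
    x$kon, x$w1_wt, x$u3, x$gamma2))
  invisible(x)
}

#' @export
print.reduced_params <- function(x, ...) {
  cat("Reduced editing-model parameters:\n")
  cat(sprintf("  gamma1 = %g  gamma2 = %g  gamma3 = %g  m = %g\n",
              x$gamma1, x$gamma2, x$gamma3, x$m))
  cat(sprintf("  ddE0 = %g k_B*T  ddEm = %g k_B*T\n", x$ddE0, x$ddEm))
  invisible(x)
}

#' Read model configuration from JSON or YAML
#'
#' The configuration carries the reduced parameters under keys `gamma1`,
#' `gamma2`, `gamma3`, `m`, `ddE0_kBT`, `ddEm_kBT`. `gamma2` may be omitted
#' when an `enzyme_kinetics` block (`Kd_uM`, `KM_uM`, `kcat_per_s`) is
#' present, in which case it is derived via [infer_site_kinetics()].
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A [reduced_params()] object; the raw configuration list is
#'   attached as attribute `"config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_beselect(sprintf("config file not found: %s", path),
                  "beselect_io_error")
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  gamma2 <- cfg$gamma2
  if (is.null(gamma2)) {
    ek <- cfg$enzyme_kinetics
    if (is.null(ek))
      stop_beselect(
        "config must provide 'gamma2' or an 'enzyme_kinetics' block",
        "beselect_config_error")
    gamma2 <- infer_site_kinetics(
      enzyme_kinetics(ek$Kd_uM, ek$KM_uM, ek$kcat_per_s))$gamma2
  }
  p <- reduced_params(
    gamma1 = cfg$gamma1, gamma2 = gamma2, gamma3 = cfg$gamma3,
    m = if (is.null(cfg$m)) 0 else cfg$m,
    ddE0 = if (is.null(cfg$ddE0_kBT)) 0 else cfg$ddE0_kBT,
    ddEm = if (is.null(cfg$ddEm_kBT)) 0 else cfg$ddEm_kBT)
  attr(p, "config") <- cfg
  p
}

#' Write model configuration
#'
#' Serialises a [reduced_params()] object to JSON or YAML using the same
#' schema accepted by [read_config()]; the round trip is lossless.
#'
#' @param p a [reduced_params()] object.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "reduced_params"))
  cfg <- list(gamma1 = p$gamma1, gamma2 = p$gamma2, gamma3 = p$gamma3,
              m = p$m, ddE0_kBT = p$ddE0, ddEm_kBT = p$ddEm)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
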