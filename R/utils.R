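# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Energies are dimensionless multiples of k_B*T; beyond this magnitude the
# Boltzmann factors degrade double precision, so we refuse rather than NaN.
.ENERGY_HARD_LIMIT <- 300
.ENERGY_WARN_LIMIT <- 50

stop_beselect <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "beselect_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                                finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_beselect(sprintf("'%s' must be a single non-missing number", name),
                  "beselect_validation_error")
  if (finite && !is.finite(x))
    stop_beselect(sprintf("'%s' must be finite", name),
                  "beselect_validation_error")
  if (positive && x <= 0)
    stop_beselect(sprintf("'%s' must be strictly positive (got %g)", name, x),
                  "beselect_validation_error")
  if (nonneg && x < 0)
    stop_beselect(sprintf("'%s' must be non-negative (got %g)", name, x),
                  "beselect_validation_error")
  invisible(x)
}

check_energy <- function(x, name) {
  check_scalar_number(x, name)
  if (abs(x) > .ENERGY_HARD_LIMIT)
    stop_beselect(sprintf(
      "|%s| = %g exceeds %g k_B*T; Boltzmann factor would overflow",
      name, abs(x), .ENERGY_HARD_LIMIT), "beselect_range_error")
  if (abs(x) > .ENERGY_WARN_LIMIT)
    warning(sprintf("|%s| = %g k_B*T is outside the trusted range (|dE| <= %g)",
                    name, abs(x), .ENERGY_WARN_LIMIT), call. = FALSE)
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream (one seeded generator per call; no global state leaks).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_beselect("'seed' must be a single integer", "beselect_validation_error")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Golden-section maximisation of a smooth unimodal f on [lo, hi].
# Deterministic, derivative-free; used to refine grid argmaxima.
golden_section_max <- function(f, lo, hi, tol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol) {
    if (f1 >= f2) {          # >= keeps ties drifting toward smaller x
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a)
      f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a)
      f2 <- f(x2)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}
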