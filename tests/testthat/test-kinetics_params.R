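test_that("infer_site_kinetics reproduces the published A3A constants", {
  sk <- infer_site_kinetics(enzyme_kinetics(Kd = 57, KM = 62, kcat = 1.1))
  expect_equal(sk$kon, 1.1 / 5, tolerance = 1e-12)
  expect_equal(sk$w1_wt, 12.54, tolerance = 1e-12)
  expect_equal(sk$u3, 1.1, tolerance = 1e-12)
  expect_equal(sk$gamma2, 11.4, tolerance = 1e-12)

  # unit-symmetric case forced by the formulas
  sk1 <- infer_site_kinetics(enzyme_kinetics(1, 2, 1))
  expect_equal(unlist(sk1[c("kon", "w1_wt", "gamma2")]),
               c(kon = 1, w1_wt = 1, gamma2 = 1))
})

test_that("enzyme kinetics preconditions are enforced", {
  expect_error(enzyme_kinetics(57, 57, 1.1), class = "beselect_domain_error")
  expect_error(enzyme_kinetics(57, 50, 1.1), class = "beselect_domain_error")
  expect_error(enzyme_kinetics(-1, 62, 1.1),
               class = "beselect_validation_error")
  expect_error(enzyme_kinetics(57, 62, 0),
               class = "beselect_validation_error")
})

test_that("rates_from_reduced maps the calibration to the expected rates", {
  r <- rates_from_reduced(a3a_calibration())
  expect_equal(r$u0, 1)
  expect_equal(r$u4, 2.1)
  expect_equal(r$u1, 1)
  expect_equal(r$u2, 1)
  expect_equal(r$w0, 2.9e-5)
  expect_equal(r$u3, 1)
  expect_equal(r$w1, 11.4)
  expect_equal(r$w2, 11.4 * exp(6))

  rid <- rates_from_reduced(reduced_params(1, 1, 1, m = 1, ddE0 = 0, ddEm = 0))
  expect_equal(unlist(rid[c("u0", "u1", "u2", "u3", "u4", "w0", "w1", "w2")]),
               c(u0 = 1, u1 = 1, u2 = 1, u3 = 1, u4 = 1, w0 = 1, w1 = 1,
                 w2 = 1))
  expect_error(rates_from_reduced(a3a_calibration(), scales = c(1, -1, 1)),
               class = "beselect_validation_error")
})

test_that("reduced_from_rates round-trips and checks consistency", {
  set.seed(41)
  for (i in 1:25) {
    p <- random_reduced()
    r <- rates_from_reduced(p, scales = 10^runif(3, -2, 2))
    # treat w1 at ddEm = 0 as the wild-type reference to recover ddEm
    w1_wt <- p$gamma2 * r$u3
    q <- reduced_from_rates(r, w1_wt = w1_wt)
    for (f in c("gamma1", "gamma2", "gamma3", "m", "ddE0", "ddEm"))
      expect_equal(q[[f]], p[[f]], tolerance = 1e-12)
  }

  # default reference treats the rate set itself as wild type
  r <- rates_from_reduced(a3a_calibration())
  q <- reduced_from_rates(r)
  expect_equal(q$ddEm, 0)
  expect_equal(q$ddE0, 6, tolerance = 1e-12)

  expect_equal(reduced_from_rates(
    rate_set(1, 1, 1, 1, 1, 1, w1 = 1, w2 = exp(6)))$ddE0, 6)

  r_bad <- rate_set(1, 1, 1 + 1e-3, 1, 1, 1, 1, 1)
  expect_error(reduced_from_rates(r_bad),
               class = "beselect_consistency_error")
})

test_that("probabilities are invariant to the three free rate scales", {
  set.seed(42)
  for (i in 1:10) {
    p <- random_reduced()
    o1 <- outcome_vec(outcomes_from_rates(rates_from_reduced(p)))
    o2 <- outcome_vec(outcomes_from_rates(
      rates_from_reduced(p, scales = c(7, 3, 0.2))))
    expect_equal(o1, o2, tolerance = 1e-10)
    # also against the independent linear-solve oracle
    o3 <- solve_outcomes(rates_from_reduced(p, scales = c(7, 3, 0.2)))
    expect_equal(o1, o3, tolerance = 1e-10)
  }
})

test_that("w1 is strictly increasing in ddEm and w2/w1 == exp(ddE0)", {
  dd <- seq(-10, 10, by = 0.5)
  w1 <- vapply(dd, function(e) rates_from_reduced(
    reduced_params(2.1, 11.4, 2.9e-5, ddE0 = 6, ddEm = e))$w1, numeric(1))
  expect_true(all(diff(w1) > 0))
  set.seed(43)
  for (i in 1:10) {
    p <- random_reduced()
    r <- rates_from_reduced(p)
    expect_identical(r$w2, r$w1 * exp(p$ddE0))
  }
})

test_that("parameter validation catches out-of-range values", {
  expect_error(reduced_params(0, 1, 1), class = "beselect_validation_error")
  expect_error(reduced_params(1, 1, 1, m = 1.5),
               class = "beselect_validation_error")
  expect_error(reduced_params(1, 1, 1, ddEm = NA),
               class = "beselect_validation_error")
  expect_warning(reduced_params(1, 1, 1, ddEm = 60), "trusted range")
  expect_error(reduced_params(1, 1, 1, ddEm = 301),
               class = "beselect_range_error")
  # gamma3 = 0 is an admitted boundary (used by the diagnostic ratios)
  expect_silent(reduced_params(1, 1, 0))
})

test_that("config files round-trip through JSON and YAML", {
  p <- a3a_calibration(ddEm = 4.5)
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_config(p, path)
    q <- read_config(path)
    for (f in c("gamma1", "gamma2", "gamma3", "m", "ddE0", "ddEm"))
      expect_equal(q[[f]], p[[f]], tolerance = 1e-12)
  }
})

test_that("config derives gamma2 from an enzyme_kinetics block when absent", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    gamma1 = 2.1, gamma3 = 2.9e-5, m = 0, ddE0_kBT = 6,
    enzyme_kinetics = list(Kd_uM = 57, KM_uM = 62, kcat_per_s = 1.1)),
    path, auto_unbox = TRUE)
  p <- read_config(path)
  expect_equal(p$gamma2, 11.4, tolerance = 1e-12)

  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(gamma1 = 1, gamma3 = 1), path2, auto_unbox = TRUE)
  expect_error(read_config(path2), class = "beselect_config_error")
})
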