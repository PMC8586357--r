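test_that("outcome probabilities are normalised and internally consistent", {
  set.seed(11)
  for (i in 1:100) {
    r <- random_rates()
    o <- outcomes_from_rates(r)
    probs <- outcome_vec(o)
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_equal(o$p_t, o$p_ctt + o$p_ttt, tolerance = 1e-12)
    expect_equal(o$p_b, o$p_ttc + o$p_ttt, tolerance = 1e-12)
    expect_lt(abs((o$p5 + o$p6) - (1 - o$p_ctc)), 1e-12)
    expect_false(any(is.nan(probs)))
  }
})

test_that("target/bystander symmetry holds when ddE0 = 0 and u1 = u2", {
  set.seed(12)
  for (i in 1:20) {
    p <- random_reduced(); p$ddE0 <- 0
    o <- outcomes_from_rates(rates_from_reduced(p))
    expect_equal(o$p_ctt, o$p_ttc, tolerance = 1e-12)
  }
})

test_that("absorbing-shortcut limit: u4 >> u0 drives everything to CTC", {
  r <- rate_set(u0 = 1, u1 = 1, u2 = 1, u3 = 1, u4 = 1e9,
                w0 = 1, w1 = 1, w2 = 1, m = 0)
  o <- outcomes_from_rates(r)
  expect_equal(o$p_ctc, 1, tolerance = 1e-6)
  expect_lt(o$p_t + o$p_b, 1e-6)
})

test_that("degenerate rate sets raise a singular-model error, never NaN", {
  # u4 = 0 with m = 0: post-edit release states have no exit
  r <- rate_set(u0 = 1, u1 = 1, u2 = 1, u3 = 1, u4 = 0,
                w0 = 1, w1 = 1, w2 = 1, m = 0)
  expect_error(outcomes_from_rates(r), class = "beselect_singular_error")
})

test_that("reduced closed form equals the rate-set composition", {
  p <- a3a_calibration()
  for (e in c(-3, 0, 1.5, 4.5, 8, 12)) {
    q <- p; q$ddEm <- e
    o <- outcomes_from_rates(rates_from_reduced(q))
    v <- pt_pb_reduced(q)
    expect_equal(unname(v["p_t"]), o$p_t, tolerance = 1e-9)
    expect_equal(unname(v["p_b"]), o$p_b, tolerance = 1e-9)
  }
  set.seed(13)
  for (i in 1:50) {
    q <- random_reduced()
    o <- outcomes_from_rates(rates_from_reduced(q))
    v <- pt_pb_reduced(q)
    expect_equal(unname(v["p_t"]), o$p_t, tolerance = 1e-9)
    expect_equal(unname(v["p_b"]), o$p_b, tolerance = 1e-9)
  }
})

test_that("vectorised evaluation matches scalar evaluation", {
  p <- a3a_calibration()
  grid <- seq(-5, 15, by = 0.5)
  df <- pt_pb_reduced(p, ddEm = grid)
  for (i in c(1, 11, 41)) {
    q <- p; q$ddEm <- grid[i]
    v <- pt_pb_reduced(q)
    expect_equal(df$p_t[i], unname(v["p_t"]), tolerance = 1e-12)
    expect_equal(df$p_b[i], unname(v["p_b"]), tolerance = 1e-12)
  }
})

test_that("ddE0 = 0 makes target and bystander probabilities identical", {
  set.seed(14)
  for (i in 1:10) {
    p <- random_reduced(); p$ddE0 <- 0
    v <- pt_pb_reduced(reduced_params(p$gamma1, p$gamma2, p$gamma3,
                                      m = p$m, ddE0 = 0, ddEm = p$ddEm))
    expect_equal(unname(v["p_t"]), unname(v["p_b"]), tolerance = 1e-14)
  }
})

test_that("editing is blocked in the strong-destabilisation limit", {
  v <- suppressWarnings(pt_pb_reduced(a3a_calibration(ddEm = 50)))
  expect_lt(v[["p_t"]], 1e-15)
  expect_lt(v[["p_b"]], 1e-15)
  # monotone decay toward the limit
  df <- pt_pb_reduced(a3a_calibration(), ddEm = seq(10, 40, by = 1))
  expect_true(all(diff(df$p_t) < 0))
  expect_true(all(diff(df$p_b) < 0))
  # explicit range guard
  expect_error(pt_pb_reduced(a3a_calibration(), ddEm = 400),
               class = "beselect_range_error")
})

test_that("numerator identity: p_t/p_b equals the closed-form ratio", {
  set.seed(15)
  for (i in 1:50) {
    p <- random_reduced()
    v <- pt_pb_reduced(p)
    lhs <- v[["p_t"]] / v[["p_b"]]
    G <- p$gamma1 + p$m; H <- p$gamma1 * p$gamma3
    rhs <- (G + H + H * p$gamma2 * exp(p$ddE0 + p$ddEm)) /
      (G + H + H * p$gamma2 * exp(p$ddEm))
    expect_equal(lhs, rhs, tolerance = 1e-9)
    if (p$ddE0 >= 0) expect_gte(v[["p_t"]], v[["p_b"]])
  }
})

test_that("R1 matches its closed form, its rate-set counterpart and limits", {
  p <- a3a_calibration()
  expect_equal(ratio_r1(p), (1 + 11.4 * exp(6)) / (1 + 11.4),
               tolerance = 1e-12)
  expect_equal(ratio_r1(reduced_params(1, 5, 1, ddE0 = 0, ddEm = 2)), 1)
  # first-step ratio computed directly from the rates:
  # R1 = [u3/(u3+w1)] / [u3/(u3+w2)] = (u3+w2)/(u3+w1)
  set.seed(16)
  for (i in 1:10) {
    q <- random_reduced()
    r <- rates_from_reduced(q)
    expect_equal(ratio_r1(q), (r$u3 + r$w2) / (r$u3 + r$w1),
                 tolerance = 1e-12)
  }
  # large-ddEm limit is exp(ddE0)
  p_lim <- a3a_calibration(ddEm = 30)
  expect_equal(ratio_r1(p_lim), exp(6), tolerance = 1e-9)
})

test_that("R2 matches its closed form and the network splitting ratio", {
  expect_equal(ratio_r2(reduced_params(1, 1, 0, ddE0 = 1, ddEm = 1)), 0)
  p <- a3a_calibration()
  expect_equal(ratio_r2(p), 2.9e-5 * (1 + 11.4 * exp(6)), tolerance = 1e-12)
  # rate-set counterpart: R2 = (w0/u2) * (1 + w2/u3)
  set.seed(17)
  for (i in 1:10) {
    q <- random_reduced()
    q$m <- 0  # the ratio describes the no-rebinding chain; see ?ratio_r2
    r <- rates_from_reduced(do.call(reduced_params, unclass(q)))
    expect_equal(ratio_r2(q), (r$w0 / r$u2) * (1 + r$w2 / r$u3),
                 tolerance = 1e-12)
    # and the splitting probabilities started from the target-edited state
    sp <- splitting_probabilities(build_editing_network(r), start = 5L)
    expect_equal(unname(sp["CTT"] / sp["TTT"]), ratio_r2(q),
                 tolerance = 1e-10)
  }
  # with rebinding (m > 0) the realised CTT:TTT odds carry the extra
  # factor u4/(u4 + m*u0)
  q <- random_reduced()
  r <- rates_from_reduced(q)
  sp <- splitting_probabilities(build_editing_network(r), start = 5L)
  expect_equal(unname(sp["CTT"] / sp["TTT"]),
               ratio_r2(q) * r$u4 / (r$u4 + r$m * r$u0), tolerance = 1e-10)
})
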