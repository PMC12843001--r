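test_that("ATP waveform matches its closed form at the quarter points", {
  dp <- driver_params()
  expect_equal(atp_norm(0, dp), 1.0)
  expect_equal(atp_norm(0.5, dp), 0.0, tolerance = 1e-12)
  expect_equal(atp_norm(0.25, dp), 0.5)
  expect_error(atp_norm(NA_real_, dp), "finite")
  expect_error(atp_norm(Inf, dp), "finite")
})

test_that("ATP and NADH waveforms are exactly T0-periodic", {
  dp <- driver_params(tau_nadh = 0.13, tau_atp = -0.07)
  set.seed(42)
  t <- stats::runif(100, -3, 3)
  expect_equal(atp_norm(t + dp$T0, dp), atp_norm(t, dp), tolerance = 1e-12)
  expect_equal(nadh_norm(t + dp$T0, dp), nadh_norm(t, dp), tolerance = 1e-12)
})

test_that("NADH proxy is the shifted ATP waveform", {
  dp <- driver_params()
  expect_identical(nadh_norm(0.2, dp), atp_norm(0.2, dp))
  dp_full <- driver_params(tau_nadh = 1)
  expect_equal(nadh_norm(c(0, 0.3, 0.77), dp_full),
               atp_norm(c(0, 0.3, 0.77), driver_params()),
               tolerance = 1e-12)
  dp_half <- driver_params(tau_nadh = 0.5)
  expect_equal(nadh_norm(0, dp_half), 0, tolerance = 1e-12)
})

test_that("calcium RHS selects the branch by phase time, right-continuously", {
  dp <- driver_params()
  expect_equal(ca_rhs(0, 0.1, dp), 22)
  expect_equal(ca_rhs(1, 0.3, dp), 0)
  expect_equal(ca_rhs(1, 0.7, dp), -10)
  # switch times belong to the branch on their right
  expect_equal(ca_rhs(0.5, 0.25, dp), -15 * 0.5)
  expect_equal(ca_rhs(0.5, 0.5, dp), -10 * 0.5)
  expect_equal(ca_rhs(0.5, 1.0, dp), 22 * 0.5)
  # periodic in t
  expect_equal(ca_rhs(0.3, 2.1, dp), ca_rhs(0.3, 0.1, dp))
  expect_error(ca_rhs(NaN, 0, dp), "finite")
})

test_that("calcium solution matches the first-branch closed form", {
  dp <- driver_params()
  t <- seq(0, 0.249, by = 1e-3)
  ca <- solve_ca(dp, t)
  expect_equal(ca$ca, 1 - exp(-22 * t), tolerance = 1e-6)
  expect_equal(ca$ca[t == 0.249][1], 1 - exp(-22 * 0.249), tolerance = 1e-8)
})

test_that("calcium solution is frozen when all rates vanish", {
  dp <- driver_params(k0_ca = 0, k1_ca = 0, k2_ca = 0, ca_init = 0)
  ca <- solve_ca(dp, seq(0, 2, by = 0.01))
  expect_true(all(ca$ca == 0))
})

test_that("calcium orbit is bounded, near-periodic and correctly phased", {
  dp <- driver_params()
  t <- seq(0, 4, by = 1e-3)
  ca <- solve_ca(dp, t)$ca
  expect_true(all(ca >= 0 & ca <= 1))
  # epsilon-periodicity after the first period
  late <- t >= 1 & t <= 3
  shifted <- ca[match(round(t[late] + 1, 9), round(t, 9))]
  expect_lt(max(abs(shifted - ca[late])), 1e-4)
  # waveform shape: per-period max inside [0, t2), min inside [t2, T0)
  # (open the window just past the wrap point, where the previous decay ends)
  p3 <- t >= 3.01 & t < 4
  phase <- t[p3] - 3
  expect_lt(phase[which.max(ca[p3])], dp$t2)
  expect_gte(phase[which.min(ca[p3])], dp$t2)
  # pulse rises fast: high calcium shortly after onset
  expect_gt(ca[t == 3.25][1], 0.95)
  expect_lt(min(ca[p3]), 0.1)
})

test_that("ATP maximum coincides with calcium pulse onset at zero offsets", {
  dp <- driver_params()
  t <- seq(0, 0.999, by = 1e-3)
  expect_equal(t[which.max(atp_norm(t, dp))], 0)
  expect_equal(t[which.max(nadh_norm(t, dp))], 0)
  # with tau_atp > 0 the ATP peak precedes onset
  dp_lead <- driver_params(tau_atp = 0.1)
  expect_equal(t[which.max(atp_norm(t, dp_lead))], 0.9)
})

test_that("driver parameter invariants are enforced", {
  expect_error(driver_params(t1 = 0.6), "t1 < t2")
  expect_error(driver_params(T0 = 0), "positive")
  expect_error(driver_params(A1 = 0.7), "exceed 1")
  expect_error(driver_params(k1_ca = -2), "non-negative")
  expect_error(driver_params(ca_init = 1.5), "0, 1")
})

test_that("driver trace tabulates all three signals consistently", {
  dp <- driver_params()
  tr <- driver_trace(dp, seq(0, 1, by = 0.01))
  expect_named(tr, c("t", "ca", "atp", "nadh"))
  expect_equal(tr$atp, atp_norm(tr$t, dp))
  expect_equal(tr$nadh, tr$atp)
})
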