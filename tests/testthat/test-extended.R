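test_that("the regulated influx reduces to its scale when unregulated", {
  gp <- glycolysis_params(j0_scale = 0.8, alpha_atp = 0, alpha_cit = 0,
                          beta_fbp = 0)
  expect_equal(flux_j0(0.7, 0.2, 0.4, gp), 0.8)
  # strong ATP inhibition shuts the influx down
  gp2 <- glycolysis_params()
  expect_lt(flux_j0(1e4, 0.2, 0.4, gp2), 1e-6)
  expect_error(flux_j0(-0.1, 0.2, 0.4, gp2), "non-negative")
})

test_that("the regulated influx is monotone in each of its inputs", {
  gp <- glycolysis_params()
  atp <- seq(0.05, 1, length.out = 10)
  p0 <- seq(0.05, 1.5, length.out = 10)
  p1 <- seq(0.05, 1.5, length.out = 10)
  lattice <- expand.grid(atp = atp, p0 = p0, p1 = p1)
  j <- array(flux_j0(lattice$atp, lattice$p0, lattice$p1, gp),
             dim = c(10, 10, 10))
  expect_true(all(apply(j, c(2, 3), diff) < 0))   # decreasing in atp
  expect_true(all(aperm(apply(j, c(1, 3), diff),
                        c(2, 1, 3)) > 0))          # increasing in p0
  expect_true(all(aperm(apply(j, c(1, 2), diff),
                        c(2, 3, 1)) < 0))          # decreasing in p1
})

test_that("disabling the extension reproduces the core model exactly", {
  a <- simulate_dam_extended(gp = NULL, n_periods = 6)
  b <- simulate_dam(n_periods = 6)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(attr(a, "extended"))
})

test_that("carbon in the three mitochondrial pools stays conserved", {
  traj <- simulate_dam_extended(n_periods = 8)
  expect_lt(max(abs(traj$p1 + traj$p2 + traj$p3 - 1.5)), 1e-6)
  expect_true(attr(traj, "extended"))
})

test_that("with influx and efflux both off the glycolytic pool is frozen", {
  gp <- glycolysis_params(j0_scale = 0)
  mp <- model_params(k01 = 0)
  traj <- simulate_dam_extended(mp = mp, gp = gp, p0_init = 0.33,
                                n_periods = 6)
  expect_equal(range(traj$p0), c(0.33, 0.33), tolerance = 1e-10)
})

test_that("without oxidative efflux the pool follows the reduced influx ODE", {
  mp <- model_params(k01 = 0)
  gp <- glycolysis_params()
  traj <- simulate_dam_extended(mp = mp, gp = gp, p0_init = 0.1,
                                n_periods = 5)
  # influx-only dynamics: monotone filling
  expect_true(all(diff(traj$p0) >= -1e-12))
  # oracle: the scalar ODE dp0/dt = J0(atp(t), p0, p1(t)) integrated
  # independently, with p1 interpolated from the pool solution (p1 is
  # unaffected by p0 when k01 = 0)
  p1_fun <- stats::approxfun(traj$t, traj$p1, rule = 2)
  dp <- driver_params()
  red <- deSolve::lsoda(
    y = c(p0 = 0.1), times = traj$t,
    func = function(t, y, parms) {
      list(flux_j0(atp_norm(t, dp), max(y, 0), p1_fun(t), gp))
    }, rtol = 1e-10, atol = 1e-10)
  expect_equal(traj$p0, unname(red[, "p0"]), tolerance = 1e-6)
})

test_that("the glycolytic waveform is a sawtooth: slow rise, fast fall", {
  traj <- simulate_dam_extended(n_periods = 10)
  expect_gt(waveform_asymmetry(traj), 0.55)
  # the fall is steeper than the rise
  w <- traj[traj$t >= max(traj$t) - 1, ]
  rate <- diff(w$p0) / diff(w$t)
  expect_gt(max(-rate), max(rate))
})

test_that("removing the positive-feedback factor raises the influx gain", {
  gp <- glycolysis_params()
  gp0 <- glycolysis_params(beta_fbp = 0)
  # pointwise the Hill activation factor is <= 1, so influx can only grow
  set.seed(3)
  atp <- stats::runif(30); p0 <- stats::runif(30, 0.05, 1)
  p1 <- stats::runif(30, 0.05, 1)
  expect_true(all(flux_j0(atp, p0, p1, gp0) >= flux_j0(atp, p0, p1, gp)))
  # and the operating range of the pool shifts up accordingly
  a <- simulate_dam_extended(gp = gp, n_periods = 10)
  b <- simulate_dam_extended(gp = gp0, n_periods = 10)
  expect_gt(mean(b$p0[b$t >= 9]), mean(a$p0[a$t >= 9]))
})
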