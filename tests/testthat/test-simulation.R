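test_that("total carbon in the three pools is conserved along the orbit", {
  traj <- default_traj()
  expect_lt(max(abs(traj$p1 + traj$p2 + traj$p3 - 1.5)), 1e-6)
  expect_true(all(diff(traj$t) > 0))
})

test_that("pools stay non-negative from assorted starting partitions", {
  for (init in list(c(1.4, 0.05, 0.05), c(0.05, 0.05, 1.4),
                    c(0.0, 1.5, 0.0))) {
    traj <- simulate_dam(init = init, n_periods = 6)
    expect_gte(min(traj$p1, traj$p2, traj$p3), -1e-9)
  }
})

test_that("zero rate constants freeze the pools at their start values", {
  mp <- model_params(k01 = 0, k12 = 0, k13 = 0, k32 = 0)
  traj <- simulate_dam(mp = mp, n_periods = 6)
  expect_equal(range(traj$p1), c(0.4, 0.4), tolerance = 1e-9)
  expect_equal(range(traj$p2), c(0.6, 0.6), tolerance = 1e-9)
  expect_equal(range(traj$p3), c(0.5, 0.5), tolerance = 1e-9)
  # pool amplitudes collapse to zero; the slaved glycolytic pool keeps its
  # driver-imposed span of k0A * (2 A1) = 0.20
  amps <- periodic_amplitudes(traj)
  expect_equal(amp_of(amps, "p1"), 0, tolerance = 1e-9)
  expect_equal(amp_of(amps, "p2"), 0, tolerance = 1e-9)
  expect_equal(amp_of(amps, "p3"), 0, tolerance = 1e-9)
  expect_equal(amp_of(amps, "p0"), 0.20, tolerance = 1e-9)
})

test_that("amplitude extraction guards trajectory length and periodicity", {
  short <- simulate_dam(n_periods = 3)
  expect_error(periodic_amplitudes(short), "at least")
  # after only two burn-in periods the transient has not decayed to 1e-3
  expect_error(periodic_amplitudes(short, n_discard = 2), "not periodic")
  amps <- default_amps()
  expect_true(all(amps$amplitude >= 0))
  expect_true(all(amps$t_max >= 0 & amps$t_max < 1))
  expect_true(all(amps$t_min >= 0 & amps$t_min < 1))
})

test_that("the periodic orbit does not depend on the initial partition", {
  a <- final_period(default_traj(), 1)
  b <- final_period(simulate_dam(init = c(0.5, 0.5, 0.5)), 1)
  for (pool in c("p1", "p2", "p3")) {
    expect_lt(max(abs(a[[pool]] - b[[pool]])), 1e-3)
  }
})

test_that("reported amplitudes are insensitive to grid and tolerance", {
  base <- default_amps()
  fine <- periodic_amplitudes(
    simulate_dam(dt_out = 1 / 2000, tol = 1e-11))
  expect_equal(fine$amplitude, base$amplitude, tolerance = 1e-4)
})

test_that("pool series are consistent with the balance equations", {
  traj <- default_traj()
  # centered differences away from the driver's branch switches
  dt <- traj$t[2] - traj$t[1]
  i <- 3:(nrow(traj) - 2)
  phase <- traj$t[i] %% 1
  interior <- phase > 0.02 & abs(phase - 0.25) > 0.02 &
    abs(phase - 0.5) > 0.02 & phase < 0.98
  fd <- (traj$p1[i + 1] - traj$p1[i - 1]) / (2 * dt)
  rhs <- traj$j21[i] - traj$j12[i] - traj$j13[i]
  expect_lt(max(abs(fd - rhs)[interior]), 1e-3)
})

test_that("recomputed fluxes agree with the trajectory's flux series", {
  traj <- default_traj()
  fl <- flux_trace(traj)
  for (col in c("j01", "j21", "j12", "j13", "j32")) {
    expect_lt(max(abs(fl[[col]] - traj[[col]])), 1e-10)
  }
  expect_identical(fl$j01, fl$j21)
  # redox-gated fluxes vanish where NADH does
  t0 <- seq(0, 5, by = 0.5)   # NADH = 0 at half-periods
  nz <- abs(traj$t %% 1 - 0.5) < 1e-9
  expect_lt(max(traj$j12[nz]), 1e-10)
  expect_lt(max(traj$j13[nz]), 1e-10)
})

test_that("the GABA shunt peaks while the GABA pool is draining", {
  win <- final_period(default_traj(), 1)
  at_max <- which.max(win$j32)
  expect_lt(win$j13[at_max] - win$j32[at_max], 0)  # dP3/dt < 0 there
})

test_that("phase annotation splits the period at the dP1/dt sign changes", {
  ann <- annotate_phases(default_traj())
  expect_setequal(unique(ann$label), c("mito_ox", "mito_cat"))
  expect_equal(attr(ann, "n_sign_changes"), 2L)
  expect_equal(min(ann$start), 0)
  expect_equal(max(ann$end), 1)
  expect_true(all(ann$end > ann$start))
  # oxidative filling starts at/just after the calcium pulse onset
  ox_start <- min(ann$start[ann$label == "mito_ox"])
  expect_gte(ox_start, 0)
  expect_lt(ox_start, 0.1)
})

test_that("without oxidative inflow the right pool only empties", {
  traj <- simulate_dam(mp = model_params(k01 = 0), n_periods = 6)
  ann <- annotate_phases(traj)
  expect_true(all(ann$label == "mito_cat"))
  expect_true(all(diff(traj$p1) <= 1e-12))
})

test_that("constant drivers settle on the fixed point with no phases", {
  # frozen calcium at 0.5 and constant ATP = NADH = 0.5
  dp <- driver_params(k0_ca = 0, k1_ca = 0, k2_ca = 0, ca_init = 0.5,
                      A0 = 0.5, A1 = 0)
  traj <- simulate_dam(dp = dp, n_periods = 60, dt_out = 0.01)
  # fixed point from the flux balance at ca = atp = nadh = 0.5:
  # k01*0.5*p2*0.2 = (k12+k13)*p1*0.25 and k13*p1*0.25 = k32*p3*0.5,
  # with p1+p2+p3 = 1.5
  p1s <- 1.5 / (1 + 0.75 / 0.7 + 1)
  p2s <- p1s * 0.75 / 0.7
  p3s <- p1s
  n <- nrow(traj)
  expect_equal(traj$p1[n], p1s, tolerance = 1e-4)
  expect_equal(traj$p2[n], p2s, tolerance = 1e-4)
  expect_equal(traj$p3[n], p3s, tolerance = 1e-4)
  ann <- annotate_phases(traj)
  expect_equal(nrow(ann), 0L)
})

test_that("trajectory summaries expose size and drift", {
  g <- glance(default_traj())
  expect_equal(g$n, 10001L)
  expect_equal(g$total_carbon, 1.5)
  expect_lt(g$max_drift, 1e-6)
  expect_false(g$extended)
})
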