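test_that("integration honours fixed points and the collapse dichotomy", {
  p24 <- bee_params(m = 0.24)
  # empty colony stays empty
  z <- simulate_colony(p24, c(H = 0, F = 0), 50)
  expect_true(all(z$H == 0) && all(z$F == 0))
  # first sample is the initial condition, times strictly increase
  traj <- simulate_colony(p24, c(H = 9000, F = 0), 2000, output_step = 10)
  expect_equal(unlist(traj[1, c("H", "F")]), c(H = 9000, F = 0))
  expect_true(all(diff(traj$t) > 0))
  expect_true(all(traj$H >= 0) && all(traj$F >= 0))
  # terminal state within 0.1% of the closed form
  eq <- steady_state(p24)
  expect_equal(traj$H[nrow(traj)], eq$H0, tolerance = 1e-3)
  expect_equal(traj$F[nrow(traj)], eq$F0, tolerance = 1e-3)
  # super-critical death rate: extinction below one bee
  doomed <- simulate_colony(bee_params(m = 0.40), c(H = 9000, F = 0), 2500,
                            output_step = 25)
  expect_lt(doomed$N[nrow(doomed)], 1)
})

test_that("integrator agrees with an independent fixed-step RK4 oracle", {
  # smooth vector field: fixed-step RK4 and lsoda agree tightly
  ps <- bee_params(m = 0.3)
  traj <- simulate_colony(ps, c(H = 2000, F = 6000), 60, output_step = 60)
  oracle <- rk4_integrate(ps, 2000, 6000, 60, dt = 0.01)
  expect_equal(traj$H[nrow(traj)], unname(oracle["H"]), tolerance = 1e-7)
  expect_equal(traj$F[nrow(traj)], unname(oracle["F"]), tolerance = 1e-7)
  # with the piecewise death-rate branch the R = 0 crossing costs both
  # schemes an order of accuracy; agreement is still at the 1e-4 level
  p <- bee_params(m = 0.3, precocious_mode = "when_R_negative")
  traj <- simulate_colony(p, c(H = 2000, F = 6000), 60, output_step = 60)
  oracle <- rk4_integrate(p, 2000, 6000, 60, dt = 0.005)
  expect_equal(traj$H[nrow(traj)], unname(oracle["H"]), tolerance = 1e-4)
  expect_equal(traj$F[nrow(traj)], unname(oracle["F"]), tolerance = 1e-4)
})

test_that("adults are conserved along trajectories: dN/dt tracks E - m_eff * F", {
  p <- bee_params(m = 0.3)
  traj <- simulate_colony(p, c(H = 9000, F = 0), 50, output_step = 0.1)
  n <- nrow(traj)
  dN <- (traj$N[3:n] - traj$N[1:(n - 2)]) / (traj$t[3] - traj$t[1])
  rhs <- (traj$E - traj$m_eff * traj$F)[2:(n - 1)]
  # central differences on a 0.1-day grid; O(dt^2) discretisation error
  expect_lt(max(abs(dN - rhs)), 1e-2 * max(abs(rhs)))
})

test_that("halving the tolerances barely moves the terminal state", {
  p <- bee_params(m = 0.24)
  a <- simulate_colony(p, c(H = 9000, F = 0), 300, output_step = 300)
  b <- simulate_colony(p, c(H = 9000, F = 0), 300, output_step = 300,
                       rtol = 5e-9, atol = 5e-7)
  expect_equal(a$N[nrow(a)], b$N[nrow(b)], tolerance = 1e-4)
})

test_that("phase portraits funnel onto the slow manifold F = J H", {
  p24 <- bee_params(m = 0.24)
  inits <- expand.grid(H = c(2000, 9000, 16000), F = c(0, 4000, 12000))
  trajs <- phase_portrait(p24, inits, t_end = 1500, output_step = 10)
  eq <- steady_state(p24)
  for (tr in trajs) {
    expect_equal(tr$H[nrow(tr)], eq$H0, tolerance = 1e-3)
    expect_equal(tr$F[nrow(tr)], eq$F0, tolerance = 1e-3)
    # after the transient the ratio hugs J while N is still adjusting
    late <- tr$t > 100
    expect_true(all(abs(tr$F[late] / tr$H[late] - eq$J) < 0.05 * eq$J))
  }
})

test_that("the caste ratio relaxes much faster than the population settles", {
  p24 <- bee_params(m = 0.24)
  J <- equilibrium_ratio(p24)
  traj <- simulate_colony(p24, c(H = 9000, F = 0), 1000, output_step = 1)
  tt <- ratio_relaxation_time(traj, J, band = 0.05)
  expect_lt(tt$ratio, tt$population / 3)
  # starting on the line means immediate convergence
  on_line <- simulate_colony(p24, c(H = 8000, F = 8000 * J), 200)
  expect_identical(ratio_relaxation_time(on_line, J)$ratio, 0)
  # a doomed colony still locks onto its quasi-ratio before extinction
  p40 <- bee_params(m = 0.40)
  J40 <- equilibrium_ratio(p40)
  doomed <- simulate_colony(p40, c(H = 9000, F = 0), 800, output_step = 1)
  td <- ratio_relaxation_time(doomed, J40, band = 0.05)
  expect_false(is.na(td$ratio))
  expect_lt(td$ratio, 60)
})

test_that("extinction versus persistence depends on m, not on the start", {
  grid <- expand.grid(H = seq(1000, 20000, length.out = 5),
                      F = seq(0, 16000, length.out = 5))
  eq <- steady_state(bee_params(m = 0.24))
  for (tr in phase_portrait(bee_params(m = 0.24), grid, 2000,
                            output_step = 100))
    expect_equal(tr$N[nrow(tr)], eq$N0, tolerance = 1e-3)
  for (tr in phase_portrait(bee_params(m = 0.40), grid, 2500,
                            output_step = 100))
    expect_lt(tr$N[nrow(tr)], 5)
})

test_that("decline comparison runs paired scenarios with and without the feedback", {
  p <- bee_params(m = 0.40)
  cmp <- decline_comparison(p, c(H = 1000, F = 8000), 700,
                            mode = "when_R_negative", output_step = 2)
  expect_named(cmp, c("baseline", "precocious"))
  # collapse time is finite and reported in days for the doomed baseline
  tc <- collapse_time(cmp$baseline, threshold = 50)
  expect_false(is.na(tc))
  expect_gt(tc, 0)
  # degenerate feedback settings reproduce the baseline exactly:
  # from forager-free starts R never goes negative, so the branch never fires
  same <- decline_comparison(p, c(H = 9000, F = 0), 200,
                             mode = "when_R_negative")
  expect_equal(same$baseline$N, same$precocious$N, tolerance = 1e-10)
  # a viable baseline triggers a warning, not an error
  expect_warning(
    decline_comparison(bee_params(m = 0.2), c(H = 9000, F = 0), 10),
    "viable")
})
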