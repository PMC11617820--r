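test_that("first-order source emits the expected cumulative mass", {
  # ~99% of the load leaves in the first hour at the AgCur mean constant
  e <- source_emission(60, 0.086, 1)
  expect_equal(e$cumulative_ng, 1 - exp(-5.16))
  expect_gt(e$cumulative_ng, 0.99)

  # zero-rate and zero-time degenerate cases
  expect_equal(source_emission(c(0, 30, 1e6), 0, 5)$cumulative_ng,
               c(0, 0, 0))
  expect_equal(source_emission(0, 0.1, 5)$cumulative_ng, 0)
  # total depletion in the long-time limit
  expect_equal(source_emission(1e7, 0.05, 42)$cumulative_ng, 42)

  # inverse of the estimator on the AgCurA abrasion numbers: at the
  # estimated constant the 10-s emission equals the measured release
  k <- estimate_rate_constant(release_experiment(1 / 6, 849, 17.6))$k_per_min
  expect_equal(source_emission(1 / 6, k, 849)$cumulative_ng, 17.6,
               tolerance = 1e-10)

  expect_error(source_emission(-1, 0.1, 5), ">= 0")
  expect_error(source_emission(10, -0.1, 5), ">= 0")
})

test_that("emission rate integrates to the cumulative emitted mass", {
  # trapezoid integration of the rate as a brute-force check
  t <- seq(0, 120, by = 0.01)
  e <- source_emission(t, 0.086, 1000)
  integral <- cumsum(c(0, diff(t) * (head(e$rate_ng_min, -1) +
                                     tail(e$rate_ng_min, -1)) / 2))
  expect_equal(integral, e$cumulative_ng, tolerance = 1e-6)
})

test_that("simulation matches the closed-form oracle when k_sc*T is small", {
  sc <- face_mask_scenario("AgCur", "fresh")
  m_sc <- sc_intake(simulate_exposure(sc, dt_min = 0.01))
  oracle <- cumulative_intake_closed_form(8, 555 * 1530, 0.086, 1.8e-6)
  expect_lt(abs(m_sc - oracle) / oracle, 0.001)

  # also at the glycerolized rate (k_sc*T = 2.7e-4, still small)
  scg <- face_mask_scenario("AgCur", "glycerolized")
  m_scg <- sc_intake(simulate_exposure(scg, dt_min = 0.01))
  oracle_g <- cumulative_intake_closed_form(8, 555 * 1530, 0.086, 34e-6)
  expect_lt(abs(m_scg - oracle_g) / oracle_g, 0.001)
})

test_that("closed form agrees with its two-exponential exact branch", {
  # frozen reference values, derived analytically
  expect_equal(cumulative_intake_closed_form(8, 849150, 0.086, 34e-6),
               225.4, tolerance = 1e-3)
  expect_equal(cumulative_intake_closed_form(8, 920190, 0.12, 34e-6),
               245.9, tolerance = 1e-3)
  expect_identical(cumulative_intake_closed_form(8, 849150, 0.086, 0), 0)

  # approximation vs exact branch at the 0.01 threshold boundary
  near <- cumulative_intake_closed_form(8, 1e6, 0.1, 0.00124)
  exact <- local({
    kp <- 6; ksc <- 0.00124; T <- 8
    ksc * kp * 1e6 / (kp - ksc) *
      ((1 - exp(-ksc * T)) / ksc - (1 - exp(-kp * T)) / kp)
  })
  expect_equal(near, exact, tolerance = 5e-3)
})

test_that("simulation cross-checks against an independent stiff solver", {
  library(deSolve)
  kp <- 0.086; ksc <- 34e-6 / 60
  rhs <- function(t, y, parms) {
    list(c(-kp * y[1], kp * y[1] - ksc * y[2], ksc * y[2]))
  }
  out <- ode(c(tex = 849150, skin = 0, sc = 0), seq(0, 480, by = 1),
             rhs, NULL, method = "lsoda", rtol = 1e-10, atol = 1e-8)
  sc <- face_mask_scenario("AgCur", "glycerolized")
  traj <- simulate_exposure(sc, dt_min = 0.1)
  expect_equal(sc_intake(traj), unname(out[nrow(out), "sc"]),
               tolerance = 1e-6)
})

test_that("mass is conserved and compartments are monotone", {
  for (sc in random_scenarios(20)) {
    traj <- simulate_exposure(sc, dt_min = 0.5)
    expect_lt(conservation_residual(traj), 1e-6)
    expect_true(all(diff(traj$m_sc) >= -1e-12))
    expect_true(all(diff(traj$m_oral) >= -1e-12))
    expect_true(all(diff(traj$m_ww) >= -1e-12))
    expect_true(all(diff(traj$m_textile) <= 1e-12))
    expect_true(all(as.matrix(traj[-1]) > -1e-12))
  }
})

test_that("integrator converges at fourth order", {
  # fast kinetics and a coarse step so truncation error is visible above
  # roundoff (at scenario-scale rates RK4 is already exact to rounding)
  sc <- make_scenario(load = 1000, area = 1, kp = 0.5, ksc = 6,
                      ko = 0.02, kww = 0.01, wear_h = 1)
  m <- vapply(c(4, 2, 1), function(dt) {
    sc_intake(simulate_exposure(sc, dt_min = dt))
  }, numeric(1))
  d1 <- abs(m[1] - m[2])
  d2 <- abs(m[2] - m[3])
  expect_lt(d2, d1)            # refinement reduces the error
  expect_gt(d1 / d2, 8)        # at a rate consistent with order 4 (~16x)
  expect_lt(d1 / d2, 40)
})

test_that("intake is linear in the donor mass and contact area", {
  base <- sc_intake(simulate_exposure(make_scenario(load = 500), dt_min = 0.5))
  doubled <- sc_intake(simulate_exposure(make_scenario(load = 1000),
                                         dt_min = 0.5))
  expect_equal(doubled / base, 2, tolerance = 1e-9)

  # identical textiles: full-body / face-mask intake ratio is the area ratio
  fm <- sc_intake(simulate_exposure(face_mask_scenario("AgCur", "fresh")))
  fb <- sc_intake(simulate_exposure(full_body_scenario("AgCur", "fresh")))
  expect_equal(fb / fm, 20000 / 555, tolerance = 1e-9)
})

test_that("degenerate and invalid simulation inputs behave as specified", {
  # all loss rates zero: skin mass equals cumulative emitted, nothing absorbed
  sc <- make_scenario(ksc = 0)
  traj <- simulate_exposure(sc, dt_min = 0.1)
  n <- nrow(traj)
  expect_equal(traj$m_skin[n],
               source_emission(120, 0.1, 1000 * 100)$cumulative_ng,
               tolerance = 1e-9)
  expect_equal(max(traj$m_sc), 0)

  # zero load gives a valid all-zero trajectory
  z <- simulate_exposure(make_scenario(load = 0), dt_min = 0.5)
  expect_equal(max(abs(as.matrix(z[-1]))), 0)

  expect_error(simulate_exposure(sc, dt_min = 0), "> 0")
  expect_error(simulate_exposure(sc, dt_min = 300),
               "shortest wear interval")
  expect_error(exposure_scenario(textile_product(1, 1),
                                 rate_constants(), list(), 60),
               "non-empty")
})

test_that("washing empties the skin surface into the wear-and-wash sink", {
  sc <- make_scenario(kp = 0.1, ksc = 2e-6, wear_h = 1, horizon_h = 2,
                      wash_at_min = 60)
  traj <- simulate_exposure(sc, dt_min = 0.1)
  at_wash <- which(traj$time_min == 60)[1]
  expect_equal(traj$m_skin[at_wash], 0)
  expect_gt(traj$m_ww[at_wash], 0)
  expect_lt(conservation_residual(traj), 1e-6)
  # nothing reaches the stratum corneum after the wash (skin is clean
  # and the source is off)
  expect_equal(sc_intake(traj), traj$m_sc[at_wash], tolerance = 1e-12)
})
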