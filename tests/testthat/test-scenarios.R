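test_that("face-mask scenario reproduces the published fresh-skin intake", {
  sc <- face_mask_scenario("AgCur", "fresh")
  expect_equal(sc$product$area_cm2, 555)
  expect_equal(sc$product$areal_load_ng_cm2, 1530)
  expect_equal(sc$rates$kp_per_min, 0.086)
  expect_equal(sc$rates$ksc_per_h, 1.8e-6)

  traj <- simulate_exposure(sc)
  expect_equal(sc_intake(traj), 12, tolerance = 0.02)

  # cryopreserved/fresh absorption ratio 1.5
  cryo <- simulate_exposure(face_mask_scenario("AgCur", "cryopreserved"))
  expect_equal(round(sc_intake(cryo) / sc_intake(traj), 1), 1.5)

  # zero wear time yields a zero trajectory
  zero <- simulate_exposure(face_mask_scenario("AgCur", "fresh",
                                               wear_hours = 0,
                                               horizon_hours = 8),
                            dt_min = 0.5)
  expect_equal(max(abs(as.matrix(zero[c("m_skin", "m_sc")]))), 0)

  expect_error(face_mask_scenario("AgFoo"), "arg")
  expect_error(face_mask_scenario("AgCur", "waxed"), "arg")
})

test_that("full-body scenario scales the face mask by contact area", {
  fb <- simulate_exposure(full_body_scenario("AgHEC6.4", "glycerolized"))
  expect_equal(sc_intake(fb), 8835, tolerance = 0.02)
  fresh <- simulate_exposure(full_body_scenario("AgCur", "fresh"))
  expect_equal(sc_intake(fresh), 429, tolerance = 0.02)

  fm <- simulate_exposure(face_mask_scenario("AgHEC6.4", "glycerolized"))
  expect_equal(sc_intake(fb) / sc_intake(fm), 20000 / 555,
               tolerance = 1e-9)
})

test_that("glove mouthing transfers the fingertip load to the oral route", {
  # 1-h AgCur glove wear, 11.5 cm^2 fingertips, TF = 0.1 -> ~1.76 ug
  traj <- simulate_exposure(glove_mouthing_scenario())
  expect_equal(oral_intake(traj), 11.5 * 1530 * 0.1, tolerance = 0.01)
  # conservation across the discrete event
  expect_lt(conservation_residual(traj), 1e-6)

  # TF = 0 ingests nothing; TF = 1 ingests the full contact-area load
  t0 <- simulate_exposure(glove_mouthing_scenario(transfer_efficiency = 0))
  expect_equal(oral_intake(t0), 0)
  t1 <- simulate_exposure(glove_mouthing_scenario(transfer_efficiency = 1))
  expect_equal(t1$m_oral[nrow(t1)], 11.5 * 1530, tolerance = 0.01)

  expect_error(glove_mouthing_scenario(fingertip_area_cm2 = 1000),
               "hand contact area")
  expect_error(glove_mouthing_scenario(transfer_efficiency = 2),
               "\\[0, 1\\]")
})

test_that("wear time shapes intake as published", {
  full <- sc_intake(simulate_exposure(face_mask_scenario("AgCur", "fresh")))
  two_h <- sc_intake(simulate_exposure(
    face_mask_scenario("AgCur", "fresh", wear_hours = 2,
                       horizon_hours = 8)))
  half_h <- sc_intake(simulate_exposure(
    face_mask_scenario("AgCur", "fresh", wear_hours = 0.5,
                       horizon_hours = 8)))
  # 2-h and 8-h wear give similar intakes (within 1%)
  expect_lt(abs(full - two_h) / full, 0.01)
  # 30-min wear reduces the intake by about 1 ng
  expect_equal(round(full - half_h), 1)
  # wear to the horizon is the continuous scenario
  cont <- sc_intake(simulate_exposure(
    face_mask_scenario("AgCur", "fresh", wear_hours = 8,
                       horizon_hours = 8)))
  expect_identical(cont, full)
})

test_that("wear schedules and intervals are validated", {
  expect_equal(wear_schedule(8, 2), list(c(0, 120)))
  expect_error(wear_schedule(2, 8), "exceed")
  expect_error(wear_schedule(-1), ">= 0")
  expect_error(make_scenario(wear_h = 2, horizon_h = 1), "exceed")
  expect_error(
    exposure_scenario(textile_product(1, 1), rate_constants(),
                      list(c(0, 30), c(20, 60)), 60),
    "non-overlapping")
})

test_that("indirect surface contact load is the triple product", {
  expect_equal(indirect_contact_load(10, 100, 0.5), 500)
  expect_equal(indirect_contact_load(10, 100, 0), 0)
  expect_equal(indirect_contact_load(7.3, 1, 1), 7.3)
  expect_error(indirect_contact_load(10, 100, 1.5), "\\[0, 1\\]")
  expect_error(indirect_contact_load(-1, 100, 0.5), ">= 0")
})

test_that("scenario builders are pure", {
  a <- face_mask_scenario("AgHEC", "damaged", wear_hours = 3)
  b <- face_mask_scenario("AgHEC", "damaged", wear_hours = 3)
  expect_identical(a, b)
  expect_identical(simulate_exposure(a, dt_min = 0.5),
                   simulate_exposure(b, dt_min = 0.5))
})

test_that("sport scenario needs explicit garment masses", {
  expect_error(sport_scenario(), "supplementary")
  expect_error(sport_scenario(list()), "supplementary")
  expect_error(sport_scenario(list(tshirt = list(kp_per_min = 0.0017))),
               "ag_mass_ng")

  # with garment parameters supplied, dermal exposure is the cumulative
  # emission after 60 min and zero release constants emit nothing
  cfg <- list(tshirt = list(ag_mass_ng = 1e9, kp_per_min = 0.0017),
              trousers = list(ag_mass_ng = 5e8, kp_per_min = 0.0050))
  scs <- sport_scenario(cfg)
  expect_named(scs, c("tshirt", "trousers"))
  traj <- simulate_exposure(scs$tshirt, dt_min = 0.5)
  released <- 1e9 - traj$m_textile[nrow(traj)]
  expect_equal(released, 1e9 * released_fraction(60, 0.0017),
               tolerance = 1e-9)
  zero <- sport_scenario(list(g = list(ag_mass_ng = 1e9, kp_per_min = 0)))
  expect_equal(max(simulate_exposure(zero$g, dt_min = 0.5)$m_skin), 0)
})
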