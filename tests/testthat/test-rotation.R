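# Pivot rotation experiments: TMJ translation, mandible policies, the
# stationary-mandible feasibility test and jaw closure at the TMJ.

bulldog <- generate_skull(skull_preset("bulldogging"))

test_that("free return at the caudal neck needs a dorsal turn equal to the arc", {
  r <- apply_trial(bulldog,
                   rotation_trial("CAUDAL_NECK", 15,
                                  "FREE_RETURN_TO_VERTICAL"))
  expect_equal(r$mandible_return_deg, 15, tolerance = 1e-9)
  expect_equal(r$mandible_angle_after_deg, 0, tolerance = 1e-9)
})

test_that("rotation at the TMJ leaves the TMJ exactly in place", {
  for (policy in c("FIXED_TO_CRANIUM", "FREE_RETURN_TO_VERTICAL",
                   "STATIONARY_MANDIBLE")) {
    r <- apply_trial(bulldog, rotation_trial("TMJ", 37, policy))
    expect_equal(r$tmj_disp_mm, 0, tolerance = 1e-12)
  }
})

test_that("TMJ displacement at other pivots follows the chord law", {
  p <- skull_preset("bulldogging")
  r <- apply_trial(bulldog, rotation_trial("AOJ", 15, "FIXED_TO_CRANIUM"))
  expect_equal(r$tmj_disp_mm, chord_displacement(p$aoj_tmj, 15),
               tolerance = 1e-9)
  lm <- bulldog$landmarks
  for (pv in c("CAUDAL_NECK", "MID_NECK")) {
    r <- apply_trial(bulldog, rotation_trial(pv, 25, "FIXED_TO_CRANIUM"))
    expect_equal(r$tmj_disp_mm,
                 chord_displacement(sqrt(sum((lm["TMJ", ] - lm[pv, ])^2)),
                                    25),
                 tolerance = 1e-9)
  }
})

test_that("free return restores verticality for any pivot, arc and skull", {
  set.seed(202)
  for (i in 1:25) {
    cfg <- generate_skull(random_skull_params())
    pv <- sample(c("CAUDAL_NECK", "MID_NECK", "AOJ", "TMJ"), 1)
    arc <- runif(1, 1, 179)
    r <- apply_trial(cfg, rotation_trial(pv, arc,
                                         "FREE_RETURN_TO_VERTICAL"))
    expect_equal(r$mandible_return_deg, arc, tolerance = 1e-9)
    expect_lt(abs(measure_mandible_angle(r$transformed)), 1e-9)
  }
})

test_that("gape is invariant when the mandible is fixed to the cranium", {
  for (pv in c("CAUDAL_NECK", "MID_NECK", "AOJ", "TMJ")) {
    r <- apply_trial(bulldog, rotation_trial(pv, 15, "FIXED_TO_CRANIUM"))
    expect_equal(gape_after_trial(r), 90, tolerance = 1e-9)
  }
})

test_that("free return closes the gape by the arc but only by moving the mandible", {
  r <- apply_trial(bulldog,
                   rotation_trial("CAUDAL_NECK", 15,
                                  "FREE_RETURN_TO_VERTICAL"))
  expect_equal(gape_after_trial(r), 75, tolerance = 1e-9)
  # the mandible itself was displaced ventrally with the TMJ, so no
  # bite closed on a stationary prey
  expect_gt(r$tmj_disp_mm, 1)
})

test_that("the stationary-mandible test is feasible only at the TMJ", {
  for (arc in c(1, 15, 45, 90)) {
    tab <- feasibility_table(bulldog, arc)
    expect_identical(tab$feasible,
                     c(FALSE, FALSE, FALSE, TRUE))
    expect_identical(tab$pivot,
                     c("CAUDAL_NECK", "MID_NECK", "AOJ", "TMJ"))
  }
  # infeasible rows explain themselves
  r <- apply_trial(bulldog, rotation_trial("AOJ", 15,
                                           "STATIONARY_MANDIBLE"))
  expect_match(r$infeasibility_reason, "TMJ translated")
})

test_that("a full 360 degree turn is the degenerate feasible identity", {
  tab <- feasibility_table(bulldog, 360)
  expect_true(all(tab$feasible))
  expect_true(all(tab$tmj_disp_mm < 1e-9))
})

test_that("anterior rotation of the cranium at the TMJ closes the jaws by the arc", {
  expect_equal(measure_gape(rotate_cranium(bulldog, 15)), 75,
               tolerance = 1e-9)
  expect_equal(measure_gape(rotate_cranium(bulldog, 90)), 0,
               tolerance = 1e-9)
  # the mandible and its TMJ attachment never move
  shut <- rotate_cranium(bulldog, 45)
  expect_identical(shut$landmarks["LOWER_INCISOR_TIP", ],
                   bulldog$landmarks["LOWER_INCISOR_TIP", ])
  expect_identical(shut$landmarks["TMJ", ], bulldog$landmarks["TMJ", ])
})

test_that("trial construction rejects bad pivots, arcs and policies", {
  expect_error(rotation_trial("MASTOID", 15), "pivot")
  expect_error(rotation_trial("AOJ", -3), "positive")
  expect_error(rotation_trial("AOJ", 15, "WELDED"))
})
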