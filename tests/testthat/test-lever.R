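# Lever mechanics: in-/out-lever, mechanical advantage, lever classes,
# the three named bite levers, and the pressure conversion.

bulldog <- generate_skull(skull_preset("bulldogging"))

test_that("in-lever is the perpendicular distance from the effort line", {
  lv <- lever_system(c(0, 0), c(-200, 0), c(0, 1), c(100, 0), c(0, 1))
  expect_equal(in_lever(lv), 200)
  expect_equal(out_lever(lv), 100)
  expect_equal(mechanical_advantage(lv), 2.0)
  thru <- lever_system(c(0, 0), c(-100, -100), c(1, 1), c(100, 0), c(0, 1))
  expect_equal(in_lever(thru), 0, tolerance = 1e-12)
  up <- lever_system(c(0, 0), c(-100, -100), c(0, 1), c(100, 0), c(0, 1))
  expect_equal(in_lever(up), 100, tolerance = 1e-12)
})

test_that("MA equals one for equal levers and errors on a zero out-lever", {
  lv <- lever_system(c(0, 0), c(-50, 0), c(0, 1), c(50, 0), c(0, 1))
  expect_equal(mechanical_advantage(lv), 1.0)
  bad <- lever_system(c(0, 0), c(-50, 0), c(0, 1), c(50, 0), c(1, 0))
  expect_error(mechanical_advantage(bad), "out-lever")
})

test_that("collinear textbook levers classify by the middle element", {
  expect_identical(classify_lever(
    lever_system(c(0, 0), c(-1, 0), c(0, 1), c(1, 0), c(0, 1))), 1L)
  expect_identical(classify_lever(
    lever_system(c(-2, 0), c(2, 0), c(0, 1), c(1, 0), c(0, 1))), 2L)
  expect_identical(classify_lever(
    lever_system(c(-2, 0), c(-1, 0), c(0, 1), c(1, 0), c(0, 1))), 3L)
  expect_error(classify_lever(
    lever_system(c(0, 1e-15), c(-1e-15, 0), c(0, 1), c(1, 0), c(0, 1))),
    "ambiguous")
})

test_that("classifier agrees with the projection-sorting oracle", {
  set.seed(303)
  for (i in 1:1000) {
    lv <- random_lever()
    expect_identical(classify_lever(lv), classify_oracle(lv))
  }
})

test_that("the neck-powered bite is a Class 3 lever, the forelimb-powered one Class 1", {
  expect_identical(classify_lever(build_named_lever(bulldog, "shear_bite")),
                   3L)
  expect_identical(classify_lever(build_named_lever(bulldog, "c1lm")), 1L)
})

test_that("shared fulcrum and out-lever make the MA ratio equal the in-lever ratio", {
  set.seed(404)
  for (i in 1:50) {
    cfg <- generate_skull(random_skull_params())
    a <- build_named_lever(cfg, "c1lm")
    b <- build_named_lever(cfg, "mandibular_bite")
    expect_identical(a$fulcrum, b$fulcrum)
    expect_equal(out_lever(a), out_lever(b), tolerance = 1e-12)
    expect_equal(mechanical_advantage(a) / mechanical_advantage(b),
                 in_lever(a) / in_lever(b), tolerance = 1e-12)
  }
})

test_that("the forelimb-powered lever out-muscles the adductor bite on the default skull", {
  ma_c1 <- mechanical_advantage(build_named_lever(bulldog, "c1lm"))
  ma_mand <- mechanical_advantage(build_named_lever(bulldog,
                                                    "mandibular_bite"))
  expect_gt(ma_c1, ma_mand)
})

test_that("MA is invariant under rigid motion of the whole configuration", {
  tf <- rigid_transform(33, c(40, -10), c(120, -60))
  moved <- bulldog
  moved$landmarks <- apply_transform(tf, bulldog$landmarks)
  for (nm in c("shear_bite", "c1lm")) {
    lv0 <- build_named_lever(bulldog, nm)
    # rebuild with the same anatomy expressed in the moved frame: force
    # directions that are anatomy-relative travel with the configuration
    lv1 <- lever_system(apply_transform(tf, lv0$fulcrum),
                        apply_transform(tf, lv0$force_point),
                        as.numeric(tf$R %*% lv0$force_dir),
                        apply_transform(tf, lv0$resist_point),
                        as.numeric(tf$R %*% lv0$resist_dir),
                        lv0$label)
    expect_equal(mechanical_advantage(lv1), mechanical_advantage(lv0),
                 tolerance = 1e-9)
    expect_identical(classify_lever(lv1), classify_lever(lv0))
  }
})

test_that("MA grows strictly with the in-lever at fixed out-lever", {
  mas <- vapply(c(50, 100, 150, 200), function(d)
    mechanical_advantage(
      lever_system(c(0, 0), c(-d, 0), c(0, 1), c(100, 0), c(0, 1))),
    numeric(1))
  expect_true(all(diff(mas) > 0))
})

test_that("a posterior bite point shortens the out-lever and raises both MAs", {
  rep_canine <- lever_report(bulldog, bite_point = "UPPER_CANINE_TIP")
  rep_post <- lever_report(bulldog, bite_point = "UPPER_INCISOR_TIP")
  expect_equal(rep_canine$label, c("shear_bite", "c1lm", "mandibular_bite"))
  expect_identical(rep_canine$class, c(3L, 1L, 3L))
})

test_that("mm Hg converts to N/mm^2 at the documented factor", {
  expect_equal(signif(mmHg_to_N_per_mm2(120), 2), 0.016)
  expect_equal(mmHg_to_N_per_mm2(0), 0)
  expect_equal(mmHg_to_N_per_mm2(760), 0.101325, tolerance = 1e-3)
  expect_error(mmHg_to_N_per_mm2(-1), "non-negative")
})
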