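geom_ped <- build_geometry("pediatric")
geom_adu <- build_geometry("adult")

test_that("axis scales invert exactly and lay out monotonically", {
  for (geom in list(geom_ped, geom_adu)) {
    for (a in geom$axes) {
      v <- exp(seq(log(a$range[1]), log(a$range[2]), length.out = 100))
      y <- axis_value_to_y(a, v)
      expect_true(all(diff(y) > 0))  # larger value -> higher on the page
      expect_rel_equal(axis_y_to_value(a, y), v, 1e-9)
    }
  }
  expect_error(axis_scale("rbc", 50, 10, 0, c(5, 5)),
               class = "hctnomo_validation_error")
  expect_error(axis_scale("rbc", 50, -1, 0, c(5, 50)),
               class = "hctnomo_validation_error")
})

test_that("geometry construction places the middle axis correctly", {
  # equal outer moduli put the RBC axis exactly midway
  D <- geom_ped$page[1] - 2 * geom_ped$margin
  expect_equal(geom_ped$axes$rbc$x, D / 2, tolerance = 1e-12)

  # asymmetric moduli follow x3 = D m1/(m1+m2)
  g <- build_geometry("pediatric", modulus_ratio = 2)
  m1 <- g$axes$bv_weight$modulus; m2 <- g$axes$hct$modulus
  expect_equal(m1 / m2, 2, tolerance = 1e-12)
  expect_equal(g$axes$rbc$x, D * m1 / (m1 + m2), tolerance = 1e-12)
  expect_equal(g$axes$rbc$modulus, m1 * m2 / (m1 + m2), tolerance = 1e-12)

  # derived RBC range spans the products of the outer extremes
  expect_equal(geom_ped$axes$rbc$range, c(75 * 10, 1500 * 70) / 100)
  expect_equal(geom_ped$axes$bv_weight$range, c(75, 1500))

  expect_error(build_geometry("pediatric", weight_range = c(5, 2)),
               class = "hctnomo_validation_error")
  expect_error(build_geometry("pediatric", hct_range = c(0, 70)),
               class = "hctnomo_validation_error")
  expect_error(build_geometry("pediatric", page = c(40, 40)),
               class = "hctnomo_validation_error")
})

test_that("dual weight/BV labels coincide on the left axis", {
  wt <- weight_ticks(geom_ped)
  expect_equal(wt$weight_kg, 1:20)
  expect_equal(wt$bv_ml, wt$weight_kg * 75)
  y_w <- axis_value_to_y(geom_ped$axes$bv_weight, wt$bv_ml)
  y_bv <- axis_value_to_y(geom_ped$axes$bv_weight, 75 * wt$weight_kg)
  expect_identical(y_w, y_bv)
})

test_that("the alignment property recovers any third value from two", {
  set.seed(71)
  for (geom in list(geom_ped, geom_adu, build_geometry("pediatric",
                                                       modulus_ratio = 1.7))) {
    bvr <- geom$axes$bv_weight$range; hctr <- geom$axes$hct$range
    bv <- exp(runif(150, log(bvr[1]), log(bvr[2])))
    hct <- exp(runif(150, log(hctr[1]), log(hctr[2])))
    rbc <- bv * hct / 100
    for (i in seq_len(150)) {
      r1 <- isopleth_read(geom, anchor("bv_weight", bv[i]),
                          anchor("hct", hct[i]), "rbc")
      r2 <- isopleth_read(geom, anchor("rbc", rbc[i]),
                          anchor("bv_weight", bv[i]), "hct")
      r3 <- isopleth_read(geom, anchor("rbc", rbc[i]),
                          anchor("hct", hct[i]), "bv_weight")
      expect_equal(r1$read_value, rbc[i], tolerance = 1e-6)
      expect_equal(r2$read_value, hct[i], tolerance = 1e-6)
      expect_equal(r3$read_value, bv[i], tolerance = 1e-6)
      expect_lt(r1$residual, 1e-9)
    }
  }
})

test_that("isopleth_read validates anchors and names out-of-range axes", {
  expect_equal(isopleth_read(geom_ped, anchor("bv_weight", 900),
                             anchor("hct", 35), "rbc")$read_value,
               rbc_volume(900, 35), tolerance = 1e-9)
  expect_equal(isopleth_read(geom_ped, anchor("bv_weight", 900),
                             anchor("hct", 70), "rbc")$read_value,
               630, tolerance = 1e-6)  # range-max monotonicity probe
  expect_equal(isopleth_read(geom_ped, anchor("rbc", 245),
                             anchor("bv_weight", 1100), "hct")$read_value,
               245 / 1100 * 100, tolerance = 1e-6)
  expect_error(isopleth_read(geom_ped, anchor("hct", 35),
                             anchor("hct", 50), "rbc"),
               "distinct axes", class = "hctnomo_validation_error")
  expect_error(isopleth_read(geom_ped, anchor("bv_weight", 900),
                             anchor("rbc", 315), "bv_weight"),
               class = "hctnomo_validation_error")
  expect_error(isopleth_read(geom_ped, anchor("bv_weight", 5000),
                             anchor("hct", 35), "rbc"),
               "bv_weight", class = "hctnomo_validation_error")
  # in-range anchors whose line exits the target scale name the target
  expect_error(isopleth_read(geom_ped, anchor("bv_weight", 80),
                             anchor("rbc", 1000), "hct"),
               "hct axis", class = "hctnomo_validation_error")
})

test_that("collinearity residual is null for exact geometry, nonzero when corrupted", {
  for (geom in list(geom_ped, geom_adu)) {
    bvr <- geom$axes$bv_weight$range; hctr <- geom$axes$hct$range
    bv <- exp(seq(log(bvr[1]), log(bvr[2]), length.out = 50))
    hct <- exp(seq(log(hctr[1]), log(hctr[2]), length.out = 50))
    resid <- outer(bv, hct, Vectorize(function(b, h)
      collinearity_residual(geom, b, h)))
    expect_lt(max(resid), 1e-9)
  }
  bad <- geom_ped
  bad$axes$rbc$modulus <- bad$axes$rbc$modulus * 1.01
  resid_bad <- collinearity_residual(bad, 300, 20)
  expect_gt(resid_bad, 1e-6)
})

test_that("the virtual straight-edge replays all four procedures", {
  fx <- figure_fixtures()
  for (geom in list(geom_ped, geom_adu)) {
    # dehydration and small-BV cases only fit the pediatric chart
    if (geom$population == "pediatric") {
      expect_equal(run_graphical_procedure(geom, fx$blood_loss_equilibrated),
                   fx$blood_loss_equilibrated$expected, tolerance = 1e-6)
      expect_equal(run_graphical_procedure(geom, fx$infusion),
                   fx$infusion$expected, tolerance = 1e-6)
      expect_equal(run_graphical_procedure(geom, fx$combined),
                   fx$combined$expected, tolerance = 1e-6)
      expect_equal(run_graphical_procedure(geom, fx$dehydration),
                   fx$dehydration$expected, tolerance = 1e-6)
    }
  }
  # adult chart replays the same procedures at adult scale
  adult_loss <- list(procedure = "blood_loss_equilibrated", weight_kg = 70,
                     initial_hct_pct = 40, loss_ml = 1000)
  expect_equal(run_graphical_procedure(geom_adu, adult_loss),
               hct_after_blood_loss(40, 5250, 1000), tolerance = 1e-6)
  adult_inf <- list(procedure = "infusion", weight_kg = 70,
                    initial_hct_pct = 40, infusion_ml = 2000)
  expect_equal(run_graphical_procedure(geom_adu, adult_inf),
               hct_after_infusion(40, 5250, 2000), tolerance = 1e-6)

  # an off-chart intermediate read reports the failing step
  tiny <- list(procedure = "blood_loss_equilibrated", weight_kg = 1.1,
               initial_hct_pct = 35, loss_ml = 80)
  expect_error(run_graphical_procedure(geom_ped, tiny), "step 2",
               class = "hctnomo_validation_error")
  expect_error(run_graphical_procedure(geom_ped, list(procedure = "nope")),
               class = "hctnomo_validation_error")
})

test_that("geometry JSON export describes all three axes", {
  js <- jsonlite::fromJSON(geometry_json(geom_ped))
  expect_equal(js$population, "pediatric")
  expect_named(js$axes, c("bv_weight", "rbc", "hct"))
  expect_equal(js$axes$bv_weight$range, c(75, 1500))
  expect_true(all(c(100, 200, 500, 1000) %in%
                    js$axes$bv_weight$major_ticks))
})
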