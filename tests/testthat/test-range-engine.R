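water_box <- function(hu = 0, nx = 130) {
  image_volume(array(hu, dim = c(nx, 7, 7)), spacing = c(2, 20, 20),
               modality = "CT")
}
xbeam <- function(modality, step = 0.5) {
  beam_spec(c(0, 60, 60), c(1, 0, 0), modality, step = step)
}

test_that("WET in water equals geometric depth; slabs add linearly", {
  wp <- wet_profile(water_box(0), xbeam("proton"))
  d <- c(10, 50, 123.4)
  expect_equal(wp$fn(d), d, tolerance = 1e-9)
  ## 50 mm of RSP 1 then an RSP 2 slab: WET(100) = 50 + 2*50 = 150
  cal <- default_rsp_calibration()
  hu2 <- 1500 + (2 - 1.85) / (2.4 - 1.85) * 1500   # maps to RSP 2 exactly
  v <- water_box(0)
  v$data[v$data == 0] <- 0
  v$data[26:130, , ] <- hu2                        # slab from x = 50 mm
  wp2 <- wet_profile(v, xbeam("proton"), cal)
  ## half-voxel partial-volume blur at the slab face bounds the error
  expect_equal(wp2$fn(100), 150, tolerance = 1.5)
  expect_equal(wp2$fn(0), 0)
  expect_true(all(diff(wp2$wet) >= 0))
})

test_that("WET converges under step halving on smooth phantoms", {
  case <- test_case()
  beam <- cohort_beams()$beams[[3]]
  w1 <- wet_profile(case$reference, beam_spec(beam$entry, beam$direction,
                                              "proton", step = 0.5))
  w2 <- wet_profile(case$reference, beam_spec(beam$entry, beam$direction,
                                              "proton", step = 0.25))
  dmax <- max(w1$depth)
  probe <- seq(0, dmax, length.out = 40)
  expect_lt(max(abs(w1$fn(probe) - w2$fn(probe))), 0.1)
})

test_that("rays that miss the volume raise a geometry error", {
  expect_error(wet_profile(water_box(), beam_spec(c(0, 500, 60),
                                                  c(1, 0, 0), "proton")),
               "does not intersect")
})

test_that("in water the sampled curve equals the analytic model at the grid", {
  for (mod in c("photon", "electron", "proton")) {
    model <- water_curve_model(mod)
    cv <- central_axis_curve(water_box(), xbeam(mod), model = model)
    expect_equal(cv$dose, eval_pdd(model, cv$depths), tolerance = 1e-9)
    expect_equal(diff(cv$depths)[1], if (mod == "electron") 1 else 2)
  }
  ## proton curve has a unique global maximum (Bragg peak)
  cvp <- central_axis_curve(water_box(), xbeam("proton"))
  expect_identical(sum(cvp$dose == max(cvp$dose)), 1L)
})

test_that("a proximal high-RSP slab shifts the distal fall-off upstream", {
  v <- water_box(0)
  v$data[6:15, , ] <- 1909.0909   # RSP 2 over 20 mm
  m0 <- extract_depth_metrics(refine_curve(
    central_axis_curve(water_box(), xbeam("proton"))), "proton")
  m1 <- extract_depth_metrics(refine_curve(
    central_axis_curve(v, xbeam("proton"))), "proton")
  expect_lt(m1[["R_80"]], m0[["R_80"]])
  expect_equal(m0[["R_80"]] - m1[["R_80"]], 20, tolerance = 1)
})

test_that("cubic refinement reproduces nodes and straight segments", {
  z <- seq(0, 40, by = 2)
  cv <- depth_dose_curve(z, 3 + 0.5 * z)
  rf <- refine_curve(cv, 0.01)
  ## natural cubic spline through a line is the line
  expect_equal(rf$dose, 3 + 0.5 * rf$depths, tolerance = 1e-9)
  set.seed(9)
  bumpy <- depth_dose_curve(z, exp(-((z - 20) / 7)^2) + 0.05)
  rf2 <- refine_curve(bumpy, 0.001)
  at_nodes <- rf2$dose[match(round(z, 3), round(rf2$depths, 3))]
  expect_equal(at_nodes, bumpy$dose, tolerance = 1e-9)
  expect_error(refine_curve(depth_dose_curve(c(0, 1, 2), c(0, 1, 0))),
               "at least 4")
})

test_that("sub-resolution peak shifts are recovered within 0.1 mm", {
  lam <- function(z, z0) (1 + abs(z - z0) / 8) * exp(-abs(z - z0) / 8)
  for (shift in c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85, 1.0)) {
    z <- seq(0, 200, by = 2)
    rf <- refine_curve(depth_dose_curve(z, lam(z, 100 + shift)), 1e-3)
    smax <- extract_depth_metrics(rf, "photon")[["S_max"]]
    expect_lt(abs(smax - 100 - shift), 0.1)
  }
})

test_that("metric extraction: argmax, tie-break and distal crossing", {
  z <- seq(0, 200, by = 1)
  tri <- pmax(0, 1 - abs(z - 100) / 50)
  m <- extract_depth_metrics(depth_dose_curve(z, tri), "photon")
  expect_equal(m[["S_max"]], 100)
  ## flat-topped curve: ties broken to the smallest depth
  flat <- ifelse(z >= 80 & z <= 120, 1, 0.1)
  expect_equal(extract_depth_metrics(depth_dose_curve(z, flat),
                                     "photon")[["S_max"]], 80)
  ## distal 80% crossing of the triangle: 1 - (d-100)/50 = 0.8 -> d = 110
  mp <- extract_depth_metrics(depth_dose_curve(z, tri), "proton")
  expect_equal(mp[["R_80"]], 110, tolerance = 1e-9)
  ## beam exiting before the crossing is an out-of-field error
  rising <- depth_dose_curve(z, 0.1 + z / 250)
  expect_error(extract_depth_metrics(rising, "proton"), "out of field")
})

test_that("uniform water reproduces the analytic water metrics to 0.01 mm", {
  for (mod in c("photon", "electron", "proton")) {
    model <- water_curve_model(mod)
    got <- extract_depth_metrics(refine_curve(
      central_axis_curve(water_box(), xbeam(mod), model = model)), mod)
    ref <- water_curve_metrics(model)
    key <- switch(mod, photon = "S_max", electron = "R_90", proton = "R_80")
    expect_lt(abs(got[[key]] - ref[[key]]), 0.01)
  }
})

test_that("doubling the RSP halves the geometric proton range", {
  m1 <- extract_depth_metrics(refine_curve(
    central_axis_curve(water_box(0), xbeam("proton"))), "proton")
  m2 <- extract_depth_metrics(refine_curve(
    central_axis_curve(water_box(1909.0909), xbeam("proton"))), "proton")
  expect_lt(abs(m2[["R_80"]] * 2 - m1[["R_80"]]), 0.1)
})

test_that("range comparison tables are zero for identical volumes", {
  v <- water_box()
  tab <- range_comparison(list(a = v, b = v),
                          list(xbeam("proton"), xbeam("electron")),
                          reference = "a")
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$d_range == 0))
  expect_true(all(tab$abs_dS_max == 0))
  expect_error(range_comparison(list(a = v), list(xbeam("proton")),
                                reference = "nope"), "not among")
})
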