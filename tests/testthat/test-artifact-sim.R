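test_that("an empty phantom spec voxelizes to uniform air", {
  ph <- build_phantom(phantom_spec(shape = c(16, 16, 2)))
  expect_true(all(ph$truth$data == -1000))
  expect_false(any(ph$body$data))
})

test_that("phantom construction is deterministic and pins are local", {
  spec <- default_phantom_spec(n_pins = 2, seed = 5)
  ph1 <- build_phantom(spec)
  ph2 <- build_phantom(spec)
  expect_identical(ph1$truth$data, ph2$truth$data)
  spec_free <- spec
  spec_free$pins <- list()
  ph0 <- build_phantom(spec_free)
  differs <- ph1$truth$data != ph0$truth$data
  expect_true(any(differs))
  expect_true(all(differs == ph1$metal$data))
})

test_that("invalid specs are rejected and overlapping pins warn", {
  expect_error(default_phantom_spec(n_pins = 2, pin_hu = 2000),
               ">= 3000")
  expect_error(phantom_spec(shape = c(16, 16, 2),
                            primitives = list(list(type = "cylinder",
                                                   center = c(500, 5),
                                                   radius = 2,
                                                   label = "soft_tissue"))),
               "outside the grid")
  spec <- default_phantom_spec(n_pins = 1)
  spec$pins <- c(spec$pins, list(list(center = spec$pins[[1]]$center + 1,
                                      radius = 2.5, hu = 6000,
                                      z_range = spec$pins[[1]]$z_range)))
  expect_warning(build_phantom(spec), "overlapping")
})

test_that("monochromatic noiseless FBP reconstructs the phantom interior", {
  ph <- build_phantom(default_phantom_spec(n_pins = 0))
  rec <- simulate_corrupted_ct(ph$truth, ph$metal, mono_model())
  err <- rec$data - ph$truth$data
  ## interior: in-plane eroded soft tissue, away from tissue edges
  off <- as.matrix(expand.grid(-3:3, -3:3, 0))
  interior <- kermar:::.erode_mask(ph$labels$soft_tissue$data, off)
  expect_lt(sqrt(mean(err[interior]^2)), 10)
})

test_that("the acquisition simulation is reproducible for a fixed seed", {
  ph <- build_phantom(default_phantom_spec(n_pins = 1))
  m <- sinogram_model(seed = 3)
  r1 <- suppressWarnings(simulate_corrupted_ct(ph$truth, ph$metal, m))
  r2 <- suppressWarnings(simulate_corrupted_ct(ph$truth, ph$metal, m))
  expect_identical(r1$data, r2$data)
})

test_that("metal plus polychromatic noise produces bilateral tails near pins", {
  case <- test_case()
  roi <- mask_volume(case$masks$corrupted$data &
                       case$masks$soft_tissue$data,
                     case$truth$spacing, case$truth$origin)
  th <- tail_thresholds("phantom_soft_tissue", -200, 300)
  dn <- delta_n(case$corrupted, roi, th = th,
                reference_volume = case$reference)
  expect_gt(dn$dn_high, 0)
  expect_gt(dn$dn_low, 0)
})

test_that("artifacts concentrate in metal-bearing slices and vanish without them", {
  case <- test_case()
  err <- abs(case$corrupted$data - case$reference$data)
  pin_slices <- apply(case$masks$pins$data, 3, any)
  body <- case$masks$body$data
  in_err <- mean(err[, , pin_slices][body[, , pin_slices]])
  out_err <- mean(err[, , !pin_slices][body[, , !pin_slices]])
  expect_gt(in_err, 3 * out_err)
  ## with noise and hardening off (and no alloy attenuation boost) the
  ## with/without-pin difference collapses to reconstruction error
  ph <- build_phantom(default_phantom_spec(n_pins = 1))
  spec_free <- ph$spec
  spec_free$pins <- list()
  ph0 <- build_phantom(spec_free)
  clean <- mono_model(metal_boost = 1)
  r1 <- suppressWarnings(simulate_corrupted_ct(ph$truth, ph$metal, clean))
  r0 <- simulate_corrupted_ct(ph0$truth, ph0$metal, clean)
  d <- abs(r1$data - r0$data)
  far <- ph$body$data &
    !kermar:::.dilate_mask(ph$metal$data,
                           as.matrix(expand.grid(-4:4, -4:4, -1:1)))
  expect_lt(sqrt(mean(d[far]^2)), 15)
})

test_that("photon starvation clamps counts with a warning", {
  ph <- build_phantom(default_phantom_spec(n_pins = 2))
  expect_warning(simulate_corrupted_ct(ph$truth, ph$metal,
                                       sinogram_model(noise = FALSE,
                                                      fluence = 1e3)),
                 "starvation")
})

test_that("sinogram model validates its spectrum", {
  expect_error(sinogram_model(spectrum = data.frame(energy_kev = 75,
                                                    weight = 0.7)),
               "sum to 1")
  expect_error(sinogram_model(spectrum = data.frame(energy_kev = 75,
                                                    weight = 1),
                              beam_hardening = TRUE),
               "at least 2 energies")
  expect_error(sinogram_model(fluence = 0), "positive")
})

test_that("clean MR is exactly piecewise constant and aligned", {
  ph <- build_phantom(default_phantom_spec(n_pins = 1))
  mr <- simulate_mr(ph, noise_sd = 0, bias_amplitude = 0, void_mm = 0)
  tt <- ph$spec$tissues
  for (l in tt$label) {
    sel <- ph$labels[[l]]$data & !ph$metal$data
    if (any(sel))
      expect_true(all(mr$data[sel] == tt$mr_mean[tt$label == l]))
  }
  expect_true(all(mr$data[ph$metal$data] == 0))
  expect_true(volumes_aligned(mr, ph$truth))
})

test_that("the MR signal void extends beyond the pins", {
  ph <- build_phantom(default_phantom_spec(n_pins = 1))
  mr <- simulate_mr(ph, noise_sd = 0, bias_amplitude = 0, void_mm = 3)
  ring <- kermar:::.dilate_mask(ph$metal$data,
                                as.matrix(expand.grid(-1:1, -1:1, 0))) &
    !ph$metal$data
  expect_true(all(mr$data[ring] == 0))
})

test_that("misregistration shifts the MR content", {
  ph <- build_phantom(default_phantom_spec(n_pins = 0))
  mr0 <- simulate_mr(ph, noise_sd = 0, bias_amplitude = 0)
  mr1 <- simulate_mr(ph, misregistration = c(4, 0, 0), noise_sd = 0,
                     bias_amplitude = 0)
  ## a 4 mm = 2 voxel shift along +x: shifted image content moved by -2 voxels
  d <- dim(mr0$data)
  expect_equal(mr1$data[1:(d[1] - 2), , ], mr0$data[3:d[1], , ],
               tolerance = 1e-12)
})

test_that("the thresholded corruption mask isolates metal-induced change", {
  case <- test_case()
  m <- corrupted_region_mask(case$reference, case$corrupted,
                             case$masks$body, case$masks$metal,
                             threshold = 100)
  expect_gt(sum(m$data), 0)
  expect_false(any(m$data & case$masks$metal$data))
  ## every strongly deviating non-metal body voxel is captured, and the mask
  ## never strays beyond the one-voxel growth of those voxels
  raw <- abs(case$corrupted$data - case$reference$data) > 100 &
    case$masks$body$data & !case$masks$metal$data
  expect_true(all(m$data[raw]))
  grown <- kermar:::.dilate_mask(raw, as.matrix(expand.grid(-1:1, -1:1, 0)))
  expect_true(all(grown[m$data]))
})
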