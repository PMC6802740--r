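## a 2-pair training set whose patches are equidistant from the origin query
two_point_train <- function() {
  structure(list(y = c(0, 1000), M = rbind(c(1, 0), c(-1, 0)),
                 voxels = NULL, spec = patch_spec(c(0, 0, 0))),
            class = "training_set")
}

test_that("posterior expectation has the analytic sigma limits", {
  tr <- two_point_train()
  m <- c(0, 0)
  ## flat likelihood: Nadaraya-Watson prior mean
  p_inf <- kermar_params(h = 1, sigma = 1e9, k = 2)
  expect_equal(posterior_expectation(10, m, tr, p_inf), 500,
               tolerance = 1e-6)
  ## sharp likelihood: collapses onto the intensity-nearest training value
  p_sharp <- kermar_params(h = 1, sigma = 1, k = 2)
  expect_equal(posterior_expectation(10, m, tr, p_sharp), 0,
               tolerance = 1e-6)
  expect_equal(posterior_expectation(990, m, tr, p_sharp), 1000,
               tolerance = 1e-6)
  ## symmetric observation: 500 at any sigma
  for (s in c(1, 50, 1e4))
    expect_equal(posterior_expectation(500, m, tr, kermar_params(h = 1,
                 sigma = s, k = 2)), 500, tolerance = 1e-6)
})

test_that("posterior expectation agrees with a full-sum Nadaraya-Watson oracle", {
  set.seed(3)
  n <- 40
  M <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n, 100, 50)
  tr <- structure(list(y = y, M = M, spec = patch_spec(c(0, 0, 0))),
                  class = "training_set")
  h <- 0.8
  sigma <- 40
  params <- kermar_params(h = h, sigma = sigma, k = n)
  for (i in 1:5) {
    m <- rnorm(4)
    t <- rnorm(1, 100, 80)
    w <- exp(-colSums((t(M) - m)^2) / (2 * h^2)) *
      exp(-(t - y)^2 / (2 * sigma^2))
    expect_equal(posterior_expectation(t, m, tr, params),
                 sum(w * y) / sum(w), tolerance = 1e-9)
  }
})

test_that("posterior expectation validates patch dimensions", {
  tr <- two_point_train()
  expect_error(posterior_expectation(0, c(1, 2, 3), tr,
                                     kermar_params(h = 1, sigma = 1)),
               "patch length mismatch")
})

test_that("training extraction is deterministic and respects geometry", {
  case <- test_case()
  params <- kermar_params(seed = 99)
  t1 <- extract_training(case$corrupted, case$mr, case$masks$corrupted,
                         case$masks$body, patch_spec(), params)
  t2 <- extract_training(case$corrupted, case$mr, case$masks$corrupted,
                         case$masks$body, patch_spec(), params)
  expect_identical(t1$y, t2$y)
  expect_identical(t1$M, t2$M)
  ## patch half-sizes (1,1,0) give length-9 patch vectors
  t3 <- extract_training(case$corrupted, case$mr, case$masks$corrupted,
                         case$masks$body, patch_spec(c(1, 1, 0)), params)
  expect_identical(ncol(t3$M), 9L)
  ## no training voxel may lie inside the corrupted mask
  inmask <- case$masks$corrupted$data[t1$voxels]
  expect_false(any(inmask))
})

test_that("a single eligible voxel yields a training set of size one", {
  d <- c(7, 7, 1)
  corrupted <- array(TRUE, d)
  corrupted[3:5, 3:5, 1] <- FALSE
  ct <- image_volume(array(50, d), c(1, 1, 1), modality = "CT")
  mr <- image_volume(array(0.5, d), c(1, 1, 1), modality = "MR")
  cm <- mask_volume(corrupted, c(1, 1, 1))
  body <- mask_volume(array(TRUE, d), c(1, 1, 1))
  tr <- extract_training(ct, mr, cm, body, patch_spec(c(1, 1, 0)),
                         kermar_params())
  expect_length(tr$y, 1L)
  expect_identical(tr$voxels, matrix(c(4L, 4L, 1L), nrow = 1))
  ## and an all-corrupted volume has no eligible voxels
  allbad <- mask_volume(array(TRUE, d), c(1, 1, 1))
  expect_error(extract_training(ct, mr, allbad, body,
                                patch_spec(c(1, 1, 0)), kermar_params()),
               "no eligible training voxels")
})

test_that("run_kermar is the identity when nothing is corrupted", {
  case <- test_case()
  empty <- mask_volume(array(FALSE, dim(case$corrupted$data)),
                       case$corrupted$spacing, case$corrupted$origin)
  out <- run_kermar(case$corrupted, case$mr, empty, case$masks$body,
                    case$masks$metal)
  expect_identical(out$data, case$corrupted$data)
})

test_that("run_kermar only touches corrupted non-metal voxels and stays in hull", {
  case <- test_case()
  ker <- test_kermar_result()
  outside <- !(case$masks$corrupted$data & !case$masks$metal$data)
  expect_identical(ker$data[outside], case$corrupted$data[outside])
  tr_range <- attr(ker, "train_range")
  restored <- ker$data[case$masks$corrupted$data & !case$masks$metal$data]
  expect_true(all(restored >= tr_range[1] & restored <= tr_range[2]))
})

test_that("run_kermar is bit-reproducible for a fixed seed", {
  case <- test_case()
  k2 <- suppressWarnings(
    run_kermar(case$corrupted, case$mr, case$masks$corrupted,
               case$masks$body, case$masks$metal,
               params = kermar_params(seed = 7)))
  expect_identical(test_kermar_result()$data, k2$data)
})

test_that("explicit hyperparameters pass through the fit unchanged", {
  tr <- two_point_train()
  p <- kermar_params(h = 2.5, sigma = 33)
  expect_identical(fit_hyperparameters(tr, params = p), p)
})

test_that("degenerate constant training values fall back with a warning", {
  tr <- structure(list(y = rep(5, 10), M = matrix(rnorm(40), 10, 4),
                       spec = patch_spec(c(0, 0, 0))),
                  class = "training_set")
  expect_warning(p <- fit_hyperparameters(tr, params = kermar_params()),
                 "constant")
  expect_true(p$h > 0)
  expect_identical(p$sigma, kermar_params()$sigma_floor)
})

test_that("fitted bandwidth is near-optimal for a smooth regression", {
  set.seed(11)
  n <- 200
  M <- matrix(runif(n * 4), n, 4)
  y <- 200 * rowMeans(M) + rnorm(n, 0, 2)
  tr <- structure(list(y = y, M = M, spec = patch_spec(c(0, 0, 0))),
                  class = "training_set")
  p <- fit_hyperparameters(tr, params = kermar_params(sigma = 10))
  ## held-out oracle: grid-search Nadaraya-Watson test error
  Mtest <- matrix(runif(60 * 4), 60, 4)
  ytest <- 200 * rowMeans(Mtest)
  nw_err <- function(h) {
    pred <- vapply(seq_len(nrow(Mtest)), function(i) {
      w <- exp(-colSums((t(M) - Mtest[i, ])^2) / (2 * h^2))
      sum(w * y) / sum(w)
    }, numeric(1))
    mean((pred - ytest)^2)
  }
  grid <- exp(seq(log(0.02), log(2), length.out = 15))
  best <- min(vapply(grid, nw_err, numeric(1)))
  expect_lte(nw_err(p$h), 2 * best)
})

test_that("sigma estimate respects its floor on an artifact-free region", {
  d <- c(16, 16, 2)
  set.seed(4)
  ct <- image_volume(array(60 + rnorm(prod(d), 0, 1), d), c(1, 1, 1),
                     modality = "CT")
  mr <- image_volume(array(0.5 + ct$data / 1000, d), c(1, 1, 1),
                     modality = "MR")
  corrupted <- array(FALSE, d)
  corrupted[6:10, 6:10, 1] <- TRUE
  cm <- mask_volume(corrupted, c(1, 1, 1))
  body <- mask_volume(array(TRUE, d), c(1, 1, 1))
  tr <- extract_training(ct, mr, cm, body, patch_spec(c(1, 1, 0)),
                         kermar_params())
  p <- fit_hyperparameters(tr, ct, cm, kermar_params(),
                           mr = normalize_mr(mr, body))
  expect_identical(p$sigma, kermar_params()$sigma_floor)
})

test_that("bulk override replaces exactly the requested region and value", {
  case <- test_case()
  region <- case$masks$corrupted
  for (v in c(0, 60)) {
    out <- bulk_override(case$corrupted, region, value = v)
    expect_true(all(out$data[region$data] == v))
    expect_identical(out$data[!region$data],
                     case$corrupted$data[!region$data])
  }
  empty <- mask_volume(array(FALSE, dim(case$corrupted$data)),
                       case$corrupted$spacing, case$corrupted$origin)
  expect_identical(bulk_override(case$corrupted, empty)$data,
                   case$corrupted$data)
})

test_that("the streak heuristic flags corrupted voxels but is never auto-applied", {
  case <- test_case()
  sug <- suggest_corrupted_mask(case$corrupted, case$masks$body)
  expect_s3_class(sug, "mask_volume")
  expect_gt(sum(sug$data), 0)
  ## flagged voxels are concentrated in metal-bearing slices
  pin_slices <- apply(case$masks$pins$data, 3, any)
  per_slice <- apply(sug$data & case$masks$body$data, 3, mean)
  expect_gt(mean(per_slice[pin_slices]), mean(per_slice[!pin_slices]))
})
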