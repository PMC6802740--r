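#' Cuboidal MRI patch specification
#'
#' Patches are cuboids of `(2 h_x + 1) x (2 h_y + 1) x (2 h_z + 1)` MR voxel
#' intensities centered on a voxel. The default 5x5x1 in-plane patch respects
#' the strong through-plane anisotropy of clinical 2-D T1w acquisitions.
#'
#' @param half_sizes Integer length-3, per-axis half-sizes in voxels (>= 0).
#' @param normalization `"zscore"` (per-volume z-scoring of the MR over the
#'   body mask, making the prior robust to sequence scaling) or `"none"`.
#' @return A `patch_spec`.
#' @export
patch_spec <- function(half_sizes = c(2L, 2L, 0L),
                       normalization = c("zscore", "none")) {
  normalization <- match.arg(normalization)
  half_sizes <- as.integer(half_sizes)
  if (length(half_sizes) != 3L || any(half_sizes < 0))
    stop("'half_sizes' must be 3 non-negative integers")
  structure(list(half_sizes = half_sizes, normalization = normalization),
            class = "patch_spec")
}

#' @rdname patch_spec
#' @param spec A `patch_spec`.
#' @return `patch_length()`: number of voxels in one patch vector.
#' @export
patch_length <- function(spec) prod(2L * spec$half_sizes + 1L)

#' kerMAR algorithm parameters
#'
#' @param h Gaussian kernel bandwidth on (normalized) patch-intensity
#'   Euclidean distance; `NULL` to fit by leave-one-out regression error
#'   (see [fit_hyperparameters()]).
#' @param sigma Artifact-noise standard deviation in HU; `NULL` to estimate
#'   from the corrupted-region residuals.
#' @param k Number of nearest training patches entering the truncated
#'   regression sums.
#' @param subsample Maximum number of training pairs kept.
#' @param seed Random seed controlling training subsampling.
#' @param sigma_floor Lower bound (HU) for the estimated sigma.
#' @param metal_hu Voxels above this HU are treated as metal and passed
#'   through unchanged.
#' @param fit_subsample Training-set size cap used during hyperparameter
#'   fitting.
#' @return A `kermar_params`.
#' @export
kermar_params <- function(h = NULL, sigma = NULL, k = 64L, subsample = 8000L,
                          seed = 1L, sigma_floor = 20, metal_hu = 3000,
                          fit_subsample = 800L) {
  k <- as.integer(k)
  subsample <- as.integer(subsample)
  if (k < 1L) stop("'k' must be >= 1")
  if (subsample < k) stop("'subsample' must be >= k")
  if (!is.null(h) && h <= 0) stop("'h' must be positive")
  if (!is.null(sigma) && sigma <= 0) stop("'sigma' must be positive")
  structure(list(h = h, sigma = sigma, k = k, subsample = subsample,
                 seed = as.integer(seed), sigma_floor = sigma_floor,
                 metal_hu = metal_hu, fit_subsample = as.integer(fit_subsample)),
            class = "kermar_params")
}

#' Normalize an MR volume over the body mask
#'
#' @param mr MR [image_volume()].
#' @param body Body [mask_volume()] (or `NULL` for the whole grid).
#' @param spec A [patch_spec()]; `normalization = "none"` returns `mr`
#'   unchanged.
#' @return Normalized MR volume.
#' @export
normalize_mr <- function(mr, body = NULL, spec = patch_spec()) {
  if (spec$normalization == "none") return(mr)
  sel <- if (is.null(body)) rep(TRUE, length(mr$data)) else body$data
  mu <- mean(mr$data[sel])
  sd <- stats::sd(mr$data[sel])
  if (!is.finite(sd) || sd == 0) sd <- 1
  image_volume((mr$data - mu) / sd, spacing = mr$spacing, origin = mr$origin,
               modality = "MR")
}

.patch_offsets <- function(spec) {
  h <- spec$half_sizes
  as.matrix(expand.grid(dx = -h[1L]:h[1L], dy = -h[2L]:h[2L],
                        dz = -h[3L]:h[3L]))
}

## Gather patch vectors at 1-based voxel rows (n x 3); indices are clamped at
## the array border (replicate padding), which callers for *training* avoid
## by restricting to the interior.
.extract_patches <- function(arr, vox, offsets) {
  d <- dim(arr)
  n <- nrow(vox)
  M <- matrix(0, nrow = n, ncol = nrow(offsets))
  for (j in seq_len(nrow(offsets))) {
    ix <- pmin(pmax(vox[, 1L] + offsets[j, 1L], 1L), d[1L])
    iy <- pmin(pmax(vox[, 2L] + offsets[j, 2L], 1L), d[2L])
    iz <- pmin(pmax(vox[, 3L] + offsets[j, 3L], 1L), d[3L])
    M[, j] <- arr[cbind(ix, iy, iz)]
  }
  M
}

#' Extract the kernel-regression training set
#'
#' Pairs (uncorrupted CT value, MRI patch vector) sampled from voxels that
#' lie in the body, outside the corrupted mask, and far enough from it (and
#' from the grid border) that no patch voxel overlaps the corrupted region.
#' Deterministic for a fixed `params$seed`.
#'
#' @param ct,mr Aligned CT and MR [image_volume()]s (MR is normalized here
#'   according to `spec`).
#' @param corrupted Corrupted-region [mask_volume()].
#' @param body Body-support [mask_volume()].
#' @param spec A [patch_spec()].
#' @param params A [kermar_params()].
#' @return A `training_set` with fields `y` (HU vector), `M` (patch matrix,
#'   rows matching `y`), `voxels` (1-based source indices) and `spec`.
#' @export
extract_training <- function(ct, mr, corrupted, body, spec = patch_spec(),
                             params = kermar_params()) {
  .assert_aligned(ct, mr, corrupted, body)
  mrn <- normalize_mr(mr, body, spec)
  off <- .patch_offsets(spec)
  d <- dim(ct$data)
  ## voxels whose patch touches the corrupted region are ineligible
  grown <- .dilate_mask(corrupted$data, off)
  eligible <- body$data & !grown
  ## keep patches fully inside the grid
  h <- spec$half_sizes
  interior <- array(FALSE, dim = d)
  xs <- (1L + h[1L]):(d[1L] - h[1L])
  ys <- (1L + h[2L]):(d[2L] - h[2L])
  zs <- (1L + h[3L]):(d[3L] - h[3L])
  if (length(xs) && length(ys) && length(zs))
    interior[xs, ys, zs] <- TRUE
  eligible <- eligible & interior
  idx <- which(eligible)
  if (length(idx) == 0L)
    stop("no eligible training voxels: corrupted mask and patch margin ",
         "exclude the entire body support")
  if (length(idx) > params$subsample) {
    set.seed(params$seed)
    idx <- sort(sample(idx, params$subsample))
  }
  vox <- arrayInd(idx, d)
  M <- .extract_patches(mrn$data, vox, off)
  structure(list(y = as.numeric(ct$data[idx]), M = M, voxels = vox,
                 spec = spec),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d pairs, patch length %d, y range [%.1f, %.1f] HU\n",
              length(x$y), ncol(x$M), min(x$y), max(x$y)))
  invisible(x)
}

## Row-wise posterior expectations for a batch of (t, m) pairs.
## T: length-n HU vector; Mq: n x p patch matrix. Returns length-n HU vector.
.posterior_batch <- function(T, Mq, train, params) {
  h <- params$h
  sigma <- params$sigma
  if (is.null(h) || is.null(sigma))
    stop("'h' and 'sigma' must be set (fit or supply them) before prediction")
  y <- train$y
  M <- train$M
  if (ncol(Mq) != ncol(M))
    stop("patch length mismatch: query has ", ncol(Mq),
         ", training has ", ncol(M))
  n <- nrow(Mq)
  k <- min(params$k, nrow(M))
  ## squared Euclidean patch distances, query x training
  D2 <- outer(rowSums(Mq^2), rowSums(M^2), "+") - 2 * tcrossprod(Mq, M)
  D2[D2 < 0] <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    di <- D2[i, ]
    sel <- if (k < length(di)) {
      thr <- sort.int(di, partial = k)[k]
      utils::head(which(di <= thr), k)
    } else seq_along(di)
    lw_prior <- -di[sel] / (2 * h^2)
    lw <- lw_prior - (T[i] - y[sel])^2 / (2 * sigma^2)
    m1 <- max(lw)
    if (is.finite(m1)) {
      w <- exp(lw - m1)
    } else {
      ## likelihood term annihilated every weight: fall back to the prior
      m2 <- max(lw_prior)
      if (is.finite(m2)) {
        w <- exp(lw_prior - m2)
      } else {
        warning("kernel weights underflowed for a voxel; returning its ",
                "observed value unchanged")
        out[i] <- T[i]
        next
      }
    }
    out[i] <- sum(w * y[sel]) / sum(w)
  }
  out
}

#' Posterior-expectation CT value estimate for one voxel
#'
#' Combines the kernel-regression prior over training pairs with a Gaussian
#' artifact-noise likelihood:
#' `y_hat = sum_j K_h(||m - m_j||) phi(t; y_j, sigma^2) y_j / sum_j (...)`,
#' restricted to the `k` training patches nearest to `m`. If the likelihood
#' annihilates every weight the prior alone is used; if that also vanishes
#' the observed value `t` is returned with a warning.
#'
#' @param t Observed (corrupted) CT value in HU.
#' @param m MRI patch vector at the voxel (same normalization and length as
#'   the training patches).
#' @param train A [extract_training()] result.
#' @param params A [kermar_params()] with concrete `h` and `sigma`.
#' @return Estimated CT value in HU.
#' @export
posterior_expectation <- function(t, m, train, params) {
  .posterior_batch(t, matrix(m, nrow = 1L), train, params)
}

#' Fit kerMAR hyperparameters
#'
#' The bandwidth `h` minimizes the leave-one-out Nadaraya-Watson squared
#' prediction error of training CT values from training patches over a
#' logarithmic grid spanning the observed patch-distance scale. The noise
#' level `sigma` is the Gaussian maximum-likelihood scale of the artifact
#' noise - the RMS of `t - prior mean` over corrupted voxels - floored at
#' `params$sigma_floor`. Explicitly supplied `h`/`sigma` are returned
#' unchanged.
#'
#' @param train A training set from [extract_training()].
#' @param ct Corrupted CT volume (needed for the sigma estimate).
#' @param corrupted Corrupted-region mask.
#' @param params A [kermar_params()].
#' @param mr Normalized MR volume (needed to form patches at corrupted
#'   voxels for the sigma estimate; omit to fall back to the floor).
#' @return A [kermar_params()] with `h` and `sigma` filled in.
#' @export
fit_hyperparameters <- function(train, ct = NULL, corrupted = NULL,
                                params = kermar_params(), mr = NULL) {
  if (!is.null(params$h) && !is.null(params$sigma)) return(params)
  if (length(train$y) == 0L) stop("training set is empty")
  if (stats::sd(train$y) == 0) {
    warning("training CT values are constant; returning default ",
            "hyperparameters")
    if (is.null(params$h)) params$h <- sqrt(ncol(train$M))
    if (is.null(params$sigma)) params$sigma <- params$sigma_floor
    return(params)
  }
  y <- train$y
  M <- train$M
  if (length(y) > params$fit_subsample) {
    set.seed(params$seed + 1L)
    sel <- sample(length(y), params$fit_subsample)
    y <- y[sel]
    M <- M[sel, , drop = FALSE]
  }
  if (is.null(params$h)) {
    D2 <- outer(rowSums(M^2), rowSums(M^2), "+") - 2 * tcrossprod(M)
    D2[D2 < 0] <- 0
    dpos <- sqrt(D2[upper.tri(D2)])
    dpos <- dpos[dpos > 0]
    if (length(dpos) == 0L) {
      warning("all training patches identical; using unit bandwidth")
      params$h <- 1
    } else {
      ## the useful bandwidths run from the nearest-neighbour scale (below
      ## it the LOO regression starves) up to the bulk pairwise distance
      D2nn <- D2
      diag(D2nn) <- Inf
      D2nn[D2nn == 0] <- Inf
      dnn <- sqrt(apply(D2nn, 1L, min))
      dnn <- dnn[is.finite(dnn)]
      lo <- max(stats::quantile(dnn, 0.25) / 2, min(dpos))
      hi <- stats::quantile(dpos, 0.95)
      grid <- exp(seq(log(lo), log(hi), length.out = 15))
      loo <- vapply(grid, function(h) {
        W <- exp(-D2 / (2 * h^2))
        diag(W) <- 0
        s <- rowSums(W)
        ok <- s > 0
        if (!any(ok)) return(Inf)
        pred <- (W %*% y)[ok] / s[ok]
        mean((pred - y[ok])^2)
      }, numeric(1L))
      params$h <- grid[which.min(loo)]
    }
  }
  if (is.null(params$sigma)) {
    est <- NA_real_
    if (!is.null(ct) && !is.null(corrupted) && !is.null(mr) &&
        any(corrupted$data)) {
      idx <- which(corrupted$data)
      if (length(idx) > 2000L) {
        set.seed(params$seed + 2L)
        idx <- sample(idx, 2000L)
      }
      vox <- arrayInd(idx, dim(ct$data))
      Mq <- .extract_patches(mr$data, vox, .patch_offsets(train$spec))
      ## prior (Nadaraya-Watson) mean at corrupted voxels
      prior_params <- params
      prior_params$sigma <- 1e12  # flat likelihood: prior-only prediction
      prior <- .posterior_batch(as.numeric(ct$data[idx]), Mq, train,
                                prior_params)
      ## Gaussian-MLE scale of the artifact noise: RMS of the corrupted-region
      ## residuals. A robust (MAD) scale would treat the severe streaks as
      ## outliers, but they are exactly the noise the likelihood must cover.
      est <- sqrt(mean((ct$data[idx] - prior)^2))
    }
    params$sigma <- max(params$sigma_floor, est, na.rm = TRUE)
  }
  params
}

#' Run the kerMAR restoration
#'
#' Replaces each corrupted, non-metal voxel of the CT by the posterior
#' expectation of its true value given the observed value and the local MRI
#' patch. All voxels outside the corrupted mask, and metal voxels, are passed
#' through bit-identically.
#'
#' @inheritParams extract_training
#' @param metal Metal mask; defaults to `ct > params$metal_hu`.
#' @param body Body mask; defaults to the whole grid.
#' @return Restored CT [image_volume()], with attributes `params` (the
#'   hyperparameters actually used) and `n_restored`.
#' @export
run_kermar <- function(ct, mr, corrupted, body = NULL, metal = NULL,
                       spec = patch_spec(), params = kermar_params()) {
  if (is.null(body))
    body <- mask_volume(array(TRUE, dim = dim(ct$data)), ct$spacing,
                        ct$origin, role = "body")
  if (is.null(metal))
    metal <- mask_volume(ct$data > params$metal_hu, ct$spacing, ct$origin,
                         role = "metal")
  .assert_aligned(ct, mr, corrupted, body, metal)
  out <- ct$data
  target <- corrupted$data & !metal$data
  if (!any(target)) {
    res <- image_volume(out, ct$spacing, ct$origin, modality = "CT")
    attr(res, "params") <- params
    attr(res, "n_restored") <- 0L
    return(res)
  }
  train <- extract_training(ct, mr, corrupted, body, spec, params)
  mrn <- normalize_mr(mr, body, spec)
  params <- fit_hyperparameters(train, ct, corrupted, params, mr = mrn)
  idx <- which(target)
  vox <- arrayInd(idx, dim(ct$data))
  off <- .patch_offsets(spec)
  chunk <- 512L
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    rows <- s:e
    Mq <- .extract_patches(mrn$data, vox[rows, , drop = FALSE], off)
    out[idx[rows]] <- .posterior_batch(as.numeric(ct$data[idx[rows]]), Mq,
                                       train, params)
  }
  res <- image_volume(out, ct$spacing, ct$origin, modality = "CT")
  attr(res, "params") <- params
  attr(res, "n_restored") <- length(idx)
  attr(res, "train_range") <- range(train$y)
  res
}

#' Manual bulk HU override
#'
#' Sets every voxel of `region` to a single replacement value (0 HU for a
#' water override, 60 HU for a muscle-like override); all other voxels are
#' untouched.
#'
#' @param ct CT [image_volume()].
#' @param region [mask_volume()] of voxels to replace.
#' @param value Replacement CT value in HU.
#' @return Overridden CT volume.
#' @export
bulk_override <- function(ct, region, value = 0) {
  .assert_aligned(ct, region)
  out <- ct$data
  out[region$data] <- value
  image_volume(out, ct$spacing, ct$origin, modality = "CT")
}

#' Heuristic corrupted-region suggestion
#'
#' Flags voxels whose CT value deviates strongly from a slice-wise 3x3
#' median-filtered version of the image - a streak detector offered as a
#' starting point for manual delineation. It is never applied automatically
#' by any other function in the package.
#'
#' @param ct CT [image_volume()].
#' @param body Optional body mask restricting the search.
#' @param threshold Absolute HU deviation from the median-filtered image
#'   above which a voxel is flagged.
#' @return A [mask_volume()] with role `"corrupted"`.
#' @export
suggest_corrupted_mask <- function(ct, body = NULL, threshold = 150) {
  d <- dim(ct$data)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0))
  stack <- matrix(0, nrow = prod(d), ncol = nrow(off))
  for (j in seq_len(nrow(off)))
    stack[, j] <- as.numeric(.shift_array(ct$data, off[j, ], fill = NA))
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  dev <- abs(as.numeric(ct$data) - med)
  m <- array(dev > threshold, dim = d)
  if (!is.null(body)) m <- m & body$data
  mask_volume(m, ct$spacing, ct$origin, role = "corrupted")
}
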