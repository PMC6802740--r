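#' Digital phantom specification
#'
#' A body-phantom description: grid geometry, geometric primitives
#' (elliptical cylinders and ellipsoids) painted in order with tissue labels,
#' and metal pin descriptors. The default emulates a shank-like phantom: an
#' elliptical soft-tissue body, two cortical-bone cylinders, one air cavity
#' and 1-6 metal pins.
#'
#' @param shape Integer length-3 grid shape (voxels).
#' @param spacing Voxel spacing in mm.
#' @param primitives List of primitives; each is a list with `type`
#'   (`"cylinder"` or `"ellipsoid"`), `label`, and for cylinders `center`
#'   (x, y, mm), `radius` or `semiaxes` (mm) and optional `z_range` (mm);
#'   for ellipsoids `center` (x, y, z) and `semiaxes` (mm). Later primitives
#'   overwrite earlier ones.
#' @param pins List of metal pins: `center` (x, y mm), `radius` (mm), `hu`
#'   (>= 3000), optional `z_range` (mm).
#' @param tissues Data frame mapping `label` to `hu` (at the effective
#'   energy), `mr_mean` (arbitrary units) and `composition` name.
#' @param seed Seed recorded with the spec (used by downstream simulators).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 8L), spacing = c(2, 2, 2),
                         primitives = list(), pins = list(),
                         tissues = default_tissue_table(), seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(spacing) == 3L, all(spacing > 0))
  extent <- (shape - 1) * spacing
  for (p in primitives) {
    if (!p$label %in% tissues$label)
      stop("primitive label '", p$label, "' not in the tissue table")
    ctr <- p$center
    if (any(ctr < 0) || any(ctr > extent[seq_along(ctr)]))
      stop("primitive '", p$label, "' lies outside the grid")
  }
  for (p in pins) {
    if (is.null(p$hu) || p$hu < 3000)
      stop("metal pins must have hu >= 3000")
    if (any(p$center < 0) || any(p$center > extent[1:2]))
      stop("metal pin lies outside the grid")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 primitives = primitives, pins = pins, tissues = tissues,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_tissue_table <- function() {
  data.frame(
    label = c("soft_tissue", "bone", "air_cavity"),
    hu = c(60, 1450, -1000),          # muscle-like soft tissue (40-100 HU)
    mr_mean = c(0.75, 0.15, 0.03),
    composition = c("soft_tissue", "cortical_bone", NA)
  )
}

#' Default shank-like phantom
#'
#' @param n_pins Number of metal pins (1-6), placed at fixed slots in the
#'   soft-tissue region.
#' @param pin_hu Metal CT number (3000-8000 HU).
#' @param soft_hu Soft-tissue CT number; the muscle-like default is 60 HU so
#'   that a 0 HU water override carries the systematic soft-tissue offset.
#' @param seed Seed stored in the spec.
#' @inheritParams phantom_spec
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(n_pins = 2L, pin_hu = 6000, soft_hu = 60,
                                 shape = c(64L, 64L, 8L), spacing = c(2, 2, 2),
                                 seed = 1L) {
  stopifnot(n_pins >= 0L, n_pins <= 6L)
  tissues <- default_tissue_table()
  tissues$hu[tissues$label == "soft_tissue"] <- soft_hu
  zmax <- (shape[3L] - 1) * spacing[3L]
  prims <- list(
    list(type = "cylinder", center = c(63, 63), semiaxes = c(47, 40),
         label = "soft_tissue"),
    list(type = "cylinder", center = c(40, 63), radius = 8, label = "bone"),
    list(type = "cylinder", center = c(86, 63), radius = 8, label = "bone"),
    list(type = "ellipsoid", center = c(63, 38, zmax / 2),
         semiaxes = c(12, 8, 0.45 * zmax), label = "air_cavity")
  )
  slots <- list(c(53, 82), c(73, 82), c(63, 90), c(45, 75), c(81, 75),
                c(63, 70))
  pin_z <- c(0.25, 0.75) * zmax  # pins span the central slices only
  pins <- lapply(seq_len(n_pins), function(i) {
    list(center = slots[[i]], radius = 2.5, hu = pin_hu, z_range = pin_z)
  })
  phantom_spec(shape = shape, spacing = spacing, primitives = prims,
               pins = pins, tissues = tissues, seed = seed)
}

.primitive_mask <- function(p, X, Y, Z) {
  inside <- switch(p$type,
    cylinder = {
      ax <- if (!is.null(p$radius)) c(p$radius, p$radius) else p$semiaxes
      ((X - p$center[1L]) / ax[1L])^2 + ((Y - p$center[2L]) / ax[2L])^2 <= 1
    },
    ellipsoid = {
      ((X - p$center[1L]) / p$semiaxes[1L])^2 +
        ((Y - p$center[2L]) / p$semiaxes[2L])^2 +
        ((Z - p$center[3L]) / p$semiaxes[3L])^2 <= 1
    },
    stop("unknown primitive type '", p$type, "'")
  )
  if (!is.null(p$z_range))
    inside <- inside & Z >= p$z_range[1L] & Z <= p$z_range[2L]
  inside
}

#' Voxelize a phantom specification
#'
#' Paints the primitives in order onto a -1000 HU (air) background, then the
#' metal pins (with a warning if pins overlap; the later pin wins). The same
#' spec with `pins = list()` yields the uncorrupted reference, voxel-for-voxel
#' identical outside the pin regions.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `truth` (HU [image_volume()]),
#'   `labels` (named list of per-tissue [mask_volume()]s), `metal`, `body`
#'   (union of all painted primitives and pins), and `spec`.
#' @export
build_phantom <- function(spec) {
  d <- spec$shape
  sp <- spec$spacing
  x <- (seq_len(d[1L]) - 1) * sp[1L]
  y <- (seq_len(d[2L]) - 1) * sp[2L]
  z <- (seq_len(d[3L]) - 1) * sp[3L]
  X <- array(rep(x, times = d[2L] * d[3L]), dim = d)
  Y <- array(rep(rep(y, each = d[1L]), times = d[3L]), dim = d)
  Z <- array(rep(z, each = d[1L] * d[2L]), dim = d)
  hu <- array(-1000, dim = d)
  lab <- array("background", dim = d)
  for (p in spec$primitives) {
    m <- .primitive_mask(p, X, Y, Z)
    hu[m] <- spec$tissues$hu[spec$tissues$label == p$label]
    lab[m] <- p$label
  }
  metal <- array(FALSE, dim = d)
  for (p in spec$pins) {
    pm <- .primitive_mask(list(type = "cylinder", center = p$center,
                               radius = p$radius, z_range = p$z_range),
                          X, Y, Z)
    if (any(pm & metal))
      warning("overlapping metal pins; the later pin wins")
    hu[pm] <- p$hu
    lab[pm] <- "metal"
    metal <- metal | pm
  }
  labels <- lapply(unique(spec$tissues$label), function(l) {
    mask_volume(lab == l, sp, role = l)
  })
  names(labels) <- unique(spec$tissues$label)
  body <- mask_volume(lab != "background", sp, role = "body")
  structure(list(
    truth = image_volume(hu, sp, modality = "CT"),
    labels = labels,
    metal = mask_volume(metal, sp, role = "metal"),
    body = body,
    spec = spec
  ), class = "phantom")
}

#' Sinogram simulation model
#'
#' Parameters of the slice-wise parallel-beam acquisition used to corrupt the
#' ground-truth CT: a small discrete spectrum (beam hardening arises from
#' summing detector intensities over it), Poisson photon noise at a given
#' fluence per detector bin, and a photon-starvation floor.
#'
#' @param n_angles Projection angles over 180 degrees.
#' @param spectrum Data frame `energy_kev`, `weight` (weights sum to 1).
#' @param fluence Photons per detector bin (per projection), > 0.
#' @param beam_hardening If `FALSE`, the acquisition is monochromatic at
#'   `effective_energy` (the spectrum is ignored).
#' @param noise Poisson noise on detector counts.
#' @param seed Seed for the noise draw.
#' @param effective_energy Energy (keV) at which the phantom HU are defined.
#' @param hardening_exponent Energy-dependence exponent of above-water
#'   attenuation excess: bone/metal excess scales as
#'   `(E / effective_energy)^-hardening_exponent`.
#' @param soft_limit HU below which a material scales with energy like water.
#' @param metal_hu Displayed HU above which a voxel is implant alloy.
#' @param metal_boost Attenuation multiplier on the metal excess: displayed
#'   metal HU are clipped, the physical attenuation of implant alloys is
#'   many times higher, and that is what drives photon starvation.
#' @param floor_counts Lower clamp on detector counts (photon starvation).
#' @param filter Reconstruction kernel: band-limited Ram-Lak apodized with a
#'   `"shepp-logan"` (default) or `"hann"` window, or the bare `"ramp"`.
#' @return A `sinogram_model`.
#' @export
sinogram_model <- function(n_angles = 360L,
                           spectrum = data.frame(
                             energy_kev = c(50, 75, 100),
                             weight = c(0.3, 0.5, 0.2)),
                           fluence = 1e5, beam_hardening = TRUE,
                           noise = TRUE, seed = 1L,
                           effective_energy = 75.2,
                           hardening_exponent = 1.3, soft_limit = 100,
                           metal_hu = 3000, metal_boost = 16,
                           floor_counts = 0.5,
                           filter = c("shepp-logan", "hann", "ramp")) {
  if (abs(sum(spectrum$weight) - 1) > 1e-8)
    stop("spectrum weights must sum to 1")
  if (fluence <= 0) stop("'fluence' must be positive")
  if (beam_hardening && nrow(spectrum) < 2L)
    stop("beam hardening requires a spectrum with at least 2 energies")
  filter <- match.arg(filter)
  structure(list(n_angles = as.integer(n_angles), spectrum = spectrum,
                 fluence = fluence, beam_hardening = beam_hardening,
                 noise = noise, seed = as.integer(seed),
                 effective_energy = effective_energy,
                 hardening_exponent = hardening_exponent,
                 soft_limit = soft_limit, metal_hu = metal_hu,
                 metal_boost = metal_boost, floor_counts = floor_counts,
                 filter = filter),
            class = "sinogram_model")
}

## HU -> linear attenuation (1/mm) at energy E. The above-water excess
## (bone, metal) scales superlinearly with the gap to the effective energy,
## and the metal excess (above metal_hu) is additionally boosted: displayed
## metal CT numbers are clipped far below the true attenuation of implant
## alloys, and it is that true attenuation that starves the detector.
##   mu(E) = mu_w(E) * max(0, 1 + h_soft/1000
##                            + excess_bone/1000 * s
##                            + excess_metal/1000 * s * boost),
##   s = (E/E_eff)^-g
.hu_to_mu <- function(hu, mu_w_E, energy, model) {
  s <- (energy / model$effective_energy)^(-model$hardening_exponent)
  h_soft <- pmin(hu, model$soft_limit)
  excess_bone <- pmax(pmin(hu, model$metal_hu) - model$soft_limit, 0)
  excess_metal <- pmax(hu - model$metal_hu, 0)
  mu <- mu_w_E * (1 + h_soft / 1000 + excess_bone / 1000 * s +
                    excess_metal / 1000 * s * model$metal_boost)
  mu[mu < 0] <- 0
  mu
}

#' Simulate an artifact-corrupted CT by polychromatic noisy FBP
#'
#' Slice-wise parallel-beam pipeline: HU are mapped to linear attenuation at
#' each spectrum energy, forward-projected (rotation + column sums), detector
#' intensities are summed over the spectrum, Poisson noise is added at the
#' configured fluence, near-zero bins are clamped (photon starvation), the
#' log-transformed sinogram is ramp-filtered and back-projected, and the
#' effective attenuation is rescaled to HU against the spectrum-averaged
#' water attenuation. A monochromatic, noiseless model at the effective
#' energy reconstructs the truth up to FBP discretization error.
#'
#' @param truth Ground-truth CT [image_volume()] (square in-plane pixels).
#' @param metal Optional metal [mask_volume()] (carried through for
#'   bookkeeping; attenuation is taken from the HU volume itself).
#' @param model A [sinogram_model()].
#' @return Corrupted CT [image_volume()] on the same grid.
#' @export
simulate_corrupted_ct <- function(truth, metal = NULL,
                                  model = sinogram_model()) {
  d <- dim(truth$data)
  sp <- truth$spacing
  if (abs(sp[1L] - sp[2L]) > 1e-9)
    stop("simulate_corrupted_ct requires square in-plane pixels")
  delta <- sp[1L]
  n <- d[1L]
  if (d[2L] != n) stop("slices must be square")
  nS <- d[3L]

  if (model$beam_hardening) {
    energies <- model$spectrum$energy_kev
    weights <- model$spectrum$weight
  } else {
    energies <- model$effective_energy
    weights <- 1
  }
  nE <- length(energies)
  tab <- attenuation_table()
  water <- tissue_compositions()[["water"]]
  mu_w <- .mu_water_mm(energies, tab, water)
  mu_w_ref <- sum(weights * mu_w)

  ## pad to the rotation-safe (even) size and batch all (energy, slice) images
  np <- 2L * ceiling(n * sqrt(2) / 2)
  pad <- (np - n) %/% 2L
  nimg <- nE * nS
  P <- matrix(0, nrow = np * np, ncol = nimg)
  for (k in seq_len(nE)) {
    for (s in seq_len(nS)) {
      mu <- .hu_to_mu(truth$data[, , s], mu_w[k], energies[k], model)
      padded <- matrix(0, np, np)
      padded[pad + seq_len(n), pad + seq_len(n)] <- mu
      P[, (k - 1L) * nS + s] <- as.numeric(padded)
    }
  }

  nang <- model$n_angles
  thetas <- (seq_len(nang) - 1L) * pi / nang
  c0 <- (np + 1) / 2
  ## 2x supersampling in both detector (u) and integration (v) directions
  ## keeps ramp-amplified interpolation aliasing below ~10 HU
  np2 <- 2L * np
  cu2 <- (seq_len(np2) - (np2 + 1) / 2) / 2   # original-pixel units
  CU <- rep(cu2, times = np2)
  CV <- rep(cu2, each = np2)
  grp <- rep(rep(seq_len(np), each = 2L), times = np2)
  sino <- array(0, dim = c(np, nang, nimg))
  for (l in seq_len(nang)) {
    ct <- cos(thetas[l]); st <- sin(thetas[l])
    ax <- CU * ct - CV * st + c0
    ay <- CU * st + CV * ct + c0
    valid <- ax >= 1 & ax <= np & ay >= 1 & ay <= np
    fx <- pmin(pmax(floor(ax[valid]), 1), np - 1)
    fy <- pmin(pmax(floor(ay[valid]), 1), np - 1)
    wx <- ax[valid] - fx
    wy <- ay[valid] - fy
    l00 <- fx + (fy - 1) * np
    G <- matrix(0, nrow = np2 * np2, ncol = nimg)
    G[valid, ] <- P[l00, , drop = FALSE] * ((1 - wx) * (1 - wy)) +
      P[l00 + 1, , drop = FALSE] * (wx * (1 - wy)) +
      P[l00 + np, , drop = FALSE] * ((1 - wx) * wy) +
      P[l00 + np + 1, , drop = FALSE] * (wx * wy)
    ## sum over v sub-steps (delta/2) and average the 2 sub-detectors
    sino[, l, ] <- rowsum(G, grp) * (delta / 4)
  }

  ## detector counts summed over the spectrum, Poisson noise, starvation clamp
  if (model$noise) set.seed(model$seed)
  starved <- FALSE
  peff <- array(0, dim = c(np, nang, nS))
  for (s in seq_len(nS)) {
    I <- matrix(0, np, nang)
    for (k in seq_len(nE))
      I <- I + weights[k] * model$fluence * exp(-sino[, , (k - 1L) * nS + s])
    if (model$noise) {
      cnt <- matrix(stats::rpois(length(I), I), np, nang)
    } else {
      cnt <- I
    }
    if (any(cnt < model$floor_counts)) {
      starved <- TRUE
      cnt <- pmax(cnt, model$floor_counts)
    }
    peff[, , s] <- log(model$fluence / cnt)
  }
  if (starved)
    warning("photon starvation: detector bins clamped at the count floor")

  ## first-order (water) beam-hardening precorrection, as applied by
  ## clinical scanners: linearize each ray against the polychromatic water
  ## curve, so water-like media reconstruct cleanly and only the bone/metal
  ## attenuation excess produces hardening artifacts
  if (model$beam_hardening) {
    Lgrid <- seq(0, 600, by = 0.5)
    p_poly <- -log(colSums(weights * exp(-outer(mu_w, Lgrid))))
    peff[] <- mu_w_ref *
      stats::approx(p_poly, Lgrid, xout = as.numeric(peff), rule = 2)$y
  }

  ## band-limited Ram-Lak filter: spatial-domain kernel (correct DC
  ## response), applied in the frequency domain with zero padding
  M2 <- 2^ceiling(log2(2 * np))
  pos <- c(0:(M2 / 2 - 1), -(M2 / 2):-1)
  hker <- numeric(M2)
  hker[pos == 0] <- 1 / (4 * delta^2)
  odd <- pos %% 2 != 0
  hker[odd] <- -1 / (pi^2 * pos[odd]^2 * delta^2)
  fabs <- Re(stats::fft(hker)) * delta
  if (model$filter != "ramp") {
    fgrid <- c(0:(M2 / 2), -((M2 / 2 - 1):1)) / (M2 * delta)
    fn <- 1 / (2 * delta)
    win <- switch(model$filter,
      `shepp-logan` = {
        x <- pi * fgrid / (2 * fn)
        w <- rep(1, M2)
        w[x != 0] <- sin(x[x != 0]) / x[x != 0]
        w
      },
      hann = 0.5 * (1 + cos(pi * fgrid / fn)),
      stop("unknown reconstruction filter '", model$filter, "'"))
    fabs <- fabs * win
  }
  ci <- seq_len(n) + pad - c0   # centered coords of unpadded pixels
  CX <- rep(ci, times = n)
  CY <- rep(ci, each = n)
  out <- array(0, dim = d)
  for (s in seq_len(nS)) {
    p <- peff[, , s]
    ppad <- matrix(0, M2, nang)
    ppad[seq_len(np), ] <- p
    q <- Re(stats::mvfft(stats::mvfft(ppad) * fabs, inverse = TRUE)) / M2
    q <- q[seq_len(np), , drop = FALSE]
    f <- numeric(n * n)
    for (l in seq_len(nang)) {
      t <- CX * cos(thetas[l]) + CY * sin(thetas[l]) + c0
      i0 <- pmin(pmax(floor(t), 1), np - 1)
      w <- t - i0
      f <- f + q[i0, l] * (1 - w) + q[i0 + 1, l] * w
    }
    mu_rec <- matrix(f * pi / nang, n, n)
    out[, , s] <- 1000 * (mu_rec - mu_w_ref) / mu_w_ref
  }
  image_volume(out, sp, truth$origin, modality = "CT")
}

#' Simulate a co-registered T1w-like MR volume
#'
#' Piecewise-constant per-tissue means, a signal void around the metal pins
#' (where MR is uninformative exactly where CT is worst), an optional rigid
#' translation applied before sampling (misregistration probe), a smooth
#' multiplicative bias field, and Rician noise. With zero noise, bias and
#' shift the output is exactly piecewise constant.
#'
#' @param phantom A [build_phantom()] result.
#' @param misregistration Translation in mm applied to the MR before
#'   sampling; `c(0, 0, 0)` leaves it aligned with the CT by construction.
#' @param noise_sd Rician noise sigma (arbitrary units).
#' @param bias_amplitude Relative amplitude of the multiplicative bias field.
#' @param void_mm Signal-void margin (mm) around the metal pins.
#' @param background Background (air) MR intensity.
#' @param seed Seed for bias phase and noise.
#' @return MR [image_volume()] aligned with the phantom CT grid.
#' @export
simulate_mr <- function(phantom, misregistration = c(0, 0, 0),
                        noise_sd = 0.04, bias_amplitude = 0.08, void_mm = 3,
                        background = 0.03, seed = 1L) {
  spec <- phantom$spec
  d <- spec$shape
  sp <- spec$spacing
  clean <- array(background, dim = d)
  for (l in names(phantom$labels)) {
    mm <- spec$tissues$mr_mean[spec$tissues$label == l]
    if (length(mm)) clean[phantom$labels[[l]]$data] <- mm
  }
  clean[phantom$metal$data] <- 0
  if (void_mm > 0 && any(phantom$metal$data)) {
    r <- floor(void_mm / sp)
    off <- as.matrix(expand.grid(dx = -r[1L]:r[1L], dy = -r[2L]:r[2L],
                                 dz = -r[3L]:r[3L]))
    keep <- sqrt(colSums((t(off) * sp)^2)) <= void_mm
    void <- .dilate_mask(phantom$metal$data, off[keep, , drop = FALSE])
    clean[void] <- 0
  }
  if (any(misregistration != 0)) {
    idx <- cbind(rep(seq_len(d[1L]) - 1, times = d[2L] * d[3L]),
                 rep(rep(seq_len(d[2L]) - 1, each = d[1L]), times = d[3L]),
                 rep(seq_len(d[3L]) - 1, each = d[1L] * d[2L]))
    shifted <- sweep(idx, 2L, misregistration / sp, "+")
    clean <- array(.sample_array(clean, shifted, "trilinear",
                                 fill = background), dim = d)
  }
  set.seed(seed)
  img <- clean
  if (bias_amplitude > 0) {
    ph <- stats::runif(2L, 0, 2 * pi)
    x <- (seq_len(d[1L]) - 1) / max(d[1L] - 1, 1)
    y <- (seq_len(d[2L]) - 1) / max(d[2L] - 1, 1)
    bx <- cos(pi * x + ph[1L])
    by <- cos(pi * y + ph[2L])
    bias <- 1 + bias_amplitude * outer(bx, by)
    img <- img * array(rep(as.numeric(bias), times = d[3L]), dim = d)
  }
  if (noise_sd > 0) {
    e1 <- array(stats::rnorm(prod(d), 0, noise_sd), dim = d)
    e2 <- array(stats::rnorm(prod(d), 0, noise_sd), dim = d)
    img <- sqrt((img + e1)^2 + e2^2)
  }
  image_volume(img, sp, modality = "MR")
}

#' Ground-truth corrupted-region mask from a simulated pair
#'
#' Voxels of the body support where the with-pins reconstruction deviates
#' from the implant-free reference reconstruction by more than a threshold,
#' grown in-plane by one voxel; metal voxels are excluded (they are passed
#' through by the restoration, not replaced). Comparing two reconstructions
#' - rather than the with-pins scan against the voxelized phantom - cancels
#' reconstruction effects common to both (edge ringing, residual hardening)
#' and isolates the metal-induced corruption.
#'
#' @param reference Implant-free reference reconstruction (or ground truth).
#' @param corrupted With-pins reconstruction, aligned with `reference`.
#' @param body Body mask.
#' @param metal Metal mask.
#' @param threshold Absolute HU deviation defining corruption.
#' @param grow In-plane dilation radius in voxels.
#' @return A [mask_volume()] with role `"corrupted"`.
#' @export
corrupted_region_mask <- function(reference, corrupted, body, metal,
                                  threshold = 100, grow = 1L) {
  .assert_aligned(reference, corrupted, body, metal)
  m <- abs(corrupted$data - reference$data) > threshold & body$data
  if (grow > 0L) {
    off <- as.matrix(expand.grid(dx = -grow:grow, dy = -grow:grow, dz = 0L))
    m <- .dilate_mask(m, off)
  }
  m <- m & body$data & !metal$data
  mask_volume(m, reference$spacing, reference$origin, role = "corrupted")
}

#' Simulate one complete evaluation case
#'
#' Builds the phantom with and without its metal pins, reconstructs both
#' through the same acquisition model (the implant-free scan with an
#' independent noise realization, as two physical acquisitions would have),
#' simulates the co-registered MR, and derives the corrupted-region mask
#' from the with-pins vs implant-free pair - the phantom evaluation pattern
#' in which the implant-free scan, not the voxelized phantom, is the
#' reference. Deterministic reconstruction structure (edge ringing, residual
#' hardening) is common to both scans and cancels in their difference.
#'
#' The corrupted-region mask emulates the visual delineation used in
#' practice: the artifacts are in-plane, so the delineated region is the
#' whole body cross-section of every metal-bearing slice (minus the metal
#' itself). The tighter thresholded difference mask remains available via
#' [corrupted_region_mask()] for diagnostic use.
#'
#' @param spec A [phantom_spec()].
#' @param model A [sinogram_model()].
#' @param misregistration,mr_noise_sd,mr_bias MR simulation knobs, see
#'   [simulate_mr()].
#' @param mask_mode `"slices"` (delineation-style: body support of every
#'   metal-bearing slice) or `"threshold"` (difference against the
#'   implant-free scan above `mask_threshold`).
#' @param mask_threshold HU threshold for [corrupted_region_mask()] when
#'   `mask_mode = "threshold"`.
#' @return List: `truth` (voxelized phantom), `reference` (implant-free
#'   reconstruction), `corrupted` (with-pins reconstruction), `mr`,
#'   `phantom`, and `masks` (named: `metal`, `body`, `corrupted`, plus one
#'   per tissue label).
#' @export
simulate_case <- function(spec = default_phantom_spec(),
                          model = sinogram_model(seed = spec$seed),
                          misregistration = c(0, 0, 0),
                          mr_noise_sd = 0.04, mr_bias = 0.08,
                          mask_mode = c("slices", "threshold"),
                          mask_threshold = 100) {
  mask_mode <- match.arg(mask_mode)
  ph <- build_phantom(spec)
  spec_free <- spec
  spec_free$pins <- list()
  ph_free <- build_phantom(spec_free)
  corrupted <- simulate_corrupted_ct(ph$truth, ph$metal, model)
  ## the implant-free scan is a separate acquisition: independent noise
  ref_model <- model
  ref_model$seed <- model$seed + 1000L
  reference <- simulate_corrupted_ct(ph_free$truth, ph_free$metal, ref_model)
  mr <- simulate_mr(ph, misregistration = misregistration,
                    noise_sd = mr_noise_sd, bias_amplitude = mr_bias,
                    seed = spec$seed)
  ## implant region for processing: pins grown by one in-plane voxel, since
  ## the adjacent voxels partially contain metal (the voxelization is
  ## center-based) and their blooming values belong to the implant, not to
  ## restorable tissue - the usual clinical metal-mask dilation
  off1 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = 0L))
  metal_proc <- mask_volume(.dilate_mask(ph$metal$data, off1),
                            ph$truth$spacing, ph$truth$origin,
                            role = "metal")
  if (mask_mode == "slices") {
    pin_slices <- apply(ph$metal$data, 3L, any)
    m <- ph$body$data & !metal_proc$data
    m[, , !pin_slices] <- FALSE
    cmask <- mask_volume(m, ph$truth$spacing, ph$truth$origin,
                         role = "corrupted")
  } else {
    cmask <- corrupted_region_mask(reference, corrupted, ph$body,
                                   metal_proc, threshold = mask_threshold)
  }
  masks <- c(list(metal = metal_proc, pins = ph$metal, body = ph$body,
                  corrupted = cmask),
             ph$labels)
  list(truth = ph$truth, reference = reference, corrupted = corrupted,
       mr = mr, phantom = ph, masks = masks)
}
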