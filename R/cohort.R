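#' Beams and water models used for the default phantom cohort
#'
#' One lateral beam per modality angled through the streak-corrupted
#' soft-tissue region of the default phantom, passing near both the pins and
#' the bone cylinders but not through the metal itself (the implant-free
#' reference carries no pins, so a beam through metal would measure the pins
#' rather than the artifacts). The proton Bragg peak is rescaled (peak at
#' 70 mm water depth) so that it stops inside the phantom, which is much
#' smaller than a head; photon and electron models keep their defaults.
#'
#' @param spec The [phantom_spec()] the beams are aimed at.
#' @return List with `beams` (list of [beam_spec()]) and `models` (named by
#'   modality).
#' @export
cohort_beams <- function(spec = default_phantom_spec()) {
  zmid <- (spec$shape[3L] - 1) * spec$spacing[3L] / 2
  entry <- c(18, 76, zmid)   # body surface, 6 mm below the main pin row
  dir <- c(1, 0, 0)
  beams <- list(beam_spec(entry, dir, "photon", energy = 6),
                beam_spec(entry, dir, "electron", energy = 12),
                beam_spec(entry, dir, "proton", energy = 150))
  models <- list(photon = water_curve_model("photon"),
                 electron = water_curve_model("electron"),
                 proton = water_curve_model("proton", peak = 70))
  list(beams = beams, models = models)
}

.try_contrast <- function(data, spec, transform, tails) {
  tryCatch(paired_contrast_test(data, spec, transform = transform,
                                tails = tails),
           error = function(e) {
             structure(list(name = spec$name, differences = NULL,
                            mean = NA_real_, se = NA_real_, t = NA_real_,
                            df = nrow(data$values) - 1L, p = NA_real_,
                            tails = tails, signif = "",
                            note = conditionMessage(e)),
                       class = "contrast_result")
           })
}

#' Run the full synthetic evaluation cohort
#'
#' Simulates `n_subjects` seeded phantoms (1-3 metal pins each), applies the
#' compared algorithms (uncorrected FBP, water override at `override_hu`,
#' kerMAR), computes the deltaN corruption metrics in the corrupted
#' soft-tissue ROI against the implant-free truth, traces photon/electron/
#' proton central-axis beams through every volume, and tests the orthogonal
#' contrasts `mean(FBP, kerMAR) vs override` and `FBP vs kerMAR` with paired
#' t-tests.
#'
#' @param n_subjects Number of independent phantom subjects.
#' @param seed Base seed; each subject derives its own from it.
#' @param override_hu Bulk override value (0 = water override; 60 emulates a
#'   muscle override).
#' @param mr_misregistration Optional translation (mm) applied to every
#'   simulated MR, probing registration robustness.
#' @param keep_cases Keep the per-subject volumes in the result (memory!).
#' @return A `kermar_cohort` list: `metrics` (per-subject deltaN table),
#'   `ranges` (per-subject range table), `rmse` (in-mask RMSE per subject
#'   and algorithm), `image_contrasts`, `range_contrasts` (data frames),
#'   `conditions`, and optionally `cases`.
#' @export
run_cohort <- function(n_subjects = 5L, seed = 1L, override_hu = 0,
                       mr_misregistration = c(0, 0, 0), keep_cases = FALSE) {
  conditions <- c("FBP", "override", "kerMAR")
  th_soft <- tail_thresholds("phantom_soft_tissue", -200, 300)
  geo <- cohort_beams()
  metrics <- list()
  ranges <- list()
  rmse <- list()
  cases <- list()
  for (i in seq_len(n_subjects)) {
    sseed <- seed * 101L + i
    spec <- default_phantom_spec(n_pins = ((i - 1L) %% 3L) + 1L,
                                 seed = sseed)
    case <- simulate_case(spec,
                          misregistration = mr_misregistration)
    vols <- list(reference = case$reference, FBP = case$corrupted)
    vols$override <- bulk_override(case$corrupted, case$masks$corrupted,
                                   value = override_hu)
    vols$kerMAR <- run_kermar(case$corrupted, case$mr,
                              case$masks$corrupted, case$masks$body,
                              case$masks$metal,
                              params = kermar_params(seed = sseed))
    roi_soft <- mask_volume(case$masks$corrupted$data &
                              case$masks$soft_tissue$data,
                            case$truth$spacing, case$truth$origin,
                            role = "soft_tissue_corrupted")
    mt <- metric_table(vols[conditions],
                       rois = list(list(name = "phantom_soft_tissue",
                                        corrupted = roi_soft,
                                        reference = NULL)),
                       thresholds = list(phantom_soft_tissue = th_soft),
                       reference_volume = case$reference)
    mt$subject <- i
    metrics[[i]] <- mt
    rt <- range_comparison(vols, geo$beams, models = geo$models,
                           reference = "reference")
    rt$subject <- i
    ranges[[i]] <- rt
    inmask <- case$masks$corrupted$data
    rmse[[i]] <- data.frame(
      subject = i,
      algorithm = conditions,
      rmse = vapply(conditions, function(a)
        sqrt(mean((vols[[a]]$data[inmask] - case$reference$data[inmask])^2)),
        numeric(1L)))
    if (keep_cases) cases[[i]] <- c(case, list(volumes = vols))
  }
  metrics <- do.call(rbind, metrics)
  ranges <- do.call(rbind, ranges)
  rmse <- do.call(rbind, rmse)

  specs <- list(contrast_spec("I: mean(FBP,kerMAR) vs override",
                              c("FBP", "kerMAR"), "override"),
                contrast_spec("II: FBP vs kerMAR", "FBP", "kerMAR"))
  stopifnot(orthogonality_check(specs, conditions)$orthogonal)

  ## image contrasts on |dN_low| and |dN_high|
  img_res <- list()
  for (metric in c("dN_low", "dN_high")) {
    m <- matrix(metrics[[metric]],
                nrow = n_subjects, ncol = length(conditions),
                byrow = TRUE,
                dimnames = list(NULL, unique(metrics$algorithm)))
    rm_data <- repeated_measures(m[, conditions, drop = FALSE])
    for (s in specs) {
      r <- .try_contrast(rm_data, s, "abs_value", 2L)
      img_res[[length(img_res) + 1L]] <-
        cbind(metric = metric, contrast_table(list(r)))
    }
  }
  ## range contrasts on |delta vs implant-free reference| per modality
  rng_res <- list()
  ranges_alg <- ranges[ranges$algorithm != "reference", ]
  for (mod in unique(ranges_alg$modality)) {
    sub <- ranges_alg[ranges_alg$modality == mod, ]
    metric <- if (mod == "photon") "dS_max" else "d_range"
    m <- matrix(NA_real_, nrow = n_subjects, ncol = length(conditions),
                dimnames = list(NULL, conditions))
    for (a in conditions)
      m[, a] <- sub[[metric]][sub$algorithm == a]
    rm_data <- repeated_measures(m)
    for (s in specs) {
      r <- .try_contrast(rm_data, s, "abs_value", 2L)
      rng_res[[length(rng_res) + 1L]] <-
        cbind(modality = mod, metric = paste0("abs_", metric),
              contrast_table(list(r)))
    }
  }
  structure(list(metrics = metrics, ranges = ranges, rmse = rmse,
                 image_contrasts = do.call(rbind, img_res),
                 range_contrasts = do.call(rbind, rng_res),
                 conditions = conditions, contrasts = specs,
                 cases = if (keep_cases) cases else NULL),
            class = "kermar_cohort")
}

#' @export
print.kermar_cohort <- function(x, ...) {
  cat(sprintf("<kermar_cohort> %d subjects, conditions: %s\n",
              length(unique(x$metrics$subject)),
              paste(x$conditions, collapse = ", ")))
  cat("image contrasts:\n")
  print(x$image_contrasts, row.names = FALSE)
  cat("range contrasts:\n")
  print(x$range_contrasts, row.names = FALSE)
  invisible(x)
}
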