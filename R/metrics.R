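#' Tail thresholds for a region of interest
#'
#' @param roi ROI name.
#' @param low,high HU thresholds of the expected tissue range (`low < high`);
#'   voxels strictly below `low` / strictly above `high` count as tail
#'   voxels, boundary values count as in-range.
#' @return A `tail_thresholds`.
#' @export
tail_thresholds <- function(roi, low, high) {
  if (!(low < high)) stop("'low' must be < 'high'")
  structure(list(roi = as.character(roi), low = low, high = high),
            class = "tail_thresholds")
}

#' Fractions of ROI voxels in the histogram tails
#'
#' `N_low = #\{v < low\} / #region`, `N_high = #\{v > high\} / #region`, with
#' strict inequalities at the thresholds.
#'
#' @param volume An [image_volume()].
#' @param region A non-empty [mask_volume()] aligned with `volume`.
#' @param th A [tail_thresholds()].
#' @return Named numeric `c(n_low, n_high)`.
#' @export
tail_fractions <- function(volume, region, th) {
  .assert_aligned(volume, region)
  v <- volume$data[region$data]
  if (length(v) == 0L)
    stop("region '", region$role, "' is empty")
  c(n_low = mean(v < th$low), n_high = mean(v > th$high))
}

#' Tail-fraction difference between corrupted and reference regions
#'
#' `deltaN = N(corrupted) - N(reference)` per tail. Two reference modes:
#' a distinct uncorrupted region of the same volume (patient-style), or -
#' when `reference_volume` is supplied - the same region evaluated on an
#' implant-free reference volume (phantom-style).
#'
#' @param volume Volume under evaluation.
#' @param corrupted_roi Corrupted part of the ROI.
#' @param reference_roi Uncorrupted reference region; ignored when
#'   `reference_volume` is given (then `corrupted_roi` is used on both
#'   volumes).
#' @param th A [tail_thresholds()].
#' @param reference_volume Optional implant-free reference volume.
#' @return A `delta_n` list: `roi`, `dn_low`, `dn_high`, and the underlying
#'   counts and fractions.
#' @export
delta_n <- function(volume, corrupted_roi, reference_roi = NULL, th,
                    reference_volume = NULL) {
  if (is.null(reference_volume) && is.null(reference_roi))
    stop("supply either 'reference_roi' or 'reference_volume'")
  fc <- tail_fractions(volume, corrupted_roi, th)
  if (!is.null(reference_volume)) {
    fr <- tail_fractions(reference_volume, corrupted_roi, th)
    n_ref <- sum(corrupted_roi$data)
  } else {
    if (!any(reference_roi$data))
      stop("region '", reference_roi$role, "' is empty")
    fr <- tail_fractions(volume, reference_roi, th)
    n_ref <- sum(reference_roi$data)
  }
  structure(list(roi = th$roi,
                 dn_low = unname(fc["n_low"] - fr["n_low"]),
                 dn_high = unname(fc["n_high"] - fr["n_high"]),
                 n_corr = sum(corrupted_roi$data), n_ref = n_ref,
                 fractions = c(N_low_corr = unname(fc["n_low"]),
                               N_high_corr = unname(fc["n_high"]),
                               N_low_ref = unname(fr["n_low"]),
                               N_high_ref = unname(fr["n_high"]))),
            class = "delta_n")
}

#' @export
print.delta_n <- function(x, ...) {
  cat(sprintf("<delta_n '%s'> dN_low = %+.4f, dN_high = %+.4f (n_corr = %d, n_ref = %d)\n",
              x$roi, x$dn_low, x$dn_high, x$n_corr, x$n_ref))
  invisible(x)
}

#' Corruption-metric table over algorithms and ROIs
#'
#' One row per (algorithm, ROI) with the tail fractions of both regions and
#' the deltaN differences; CSV-serializable.
#'
#' @param volumes Named list of aligned volumes, one per algorithm.
#' @param rois List of ROI descriptors: each a list with `name`, `corrupted`
#'   (mask), and either `reference` (mask) or nothing (phantom mode, see
#'   `reference_volume`).
#' @param thresholds Named list of [tail_thresholds()], indexed by ROI name.
#' @param reference_volume Optional implant-free volume used as reference
#'   for ROIs without a `reference` mask.
#' @return Data frame with columns `algorithm`, `roi`, `n_corr`, `n_ref`,
#'   `N_low_corr`, `N_high_corr`, `N_low_ref`, `N_high_ref`, `dN_low`,
#'   `dN_high`, `abs_dN_low`, `abs_dN_high`.
#' @export
metric_table <- function(volumes, rois, thresholds,
                         reference_volume = NULL) {
  rows <- list()
  for (alg in names(volumes)) {
    for (roi in rois) {
      th <- thresholds[[roi$name]]
      if (is.null(th)) stop("no thresholds for ROI '", roi$name, "'")
      dn <- delta_n(volumes[[alg]], roi$corrupted,
                    reference_roi = roi$reference, th = th,
                    reference_volume = if (is.null(roi$reference))
                      reference_volume else NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = alg, roi = roi$name, n_corr = dn$n_corr,
        n_ref = dn$n_ref,
        N_low_corr = dn$fractions[["N_low_corr"]],
        N_high_corr = dn$fractions[["N_high_corr"]],
        N_low_ref = dn$fractions[["N_low_ref"]],
        N_high_ref = dn$fractions[["N_high_ref"]],
        dN_low = dn$dn_low, dN_high = dn$dn_high,
        abs_dN_low = abs(dn$dn_low), abs_dN_high = abs(dn$dn_high))
    }
  }
  do.call(rbind, rows)
}
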