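#' Read a kerMAR configuration file
#'
#' YAML configuration whose keys mirror the parameter constructors:
#' `params` ([kermar_params()] fields), `patch` ([patch_spec()] fields:
#' `half_sizes`, `normalization`), `rsp_calibration` (list of `hu`/`rsp`
#' knots), and `thresholds` (list of `roi`/`low`/`high`). Missing sections
#' fall back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return List with elements `params`, `patch`, `calib`, `thresholds`.
#' @export
read_kermar_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(kermar_params, cfg$params %||% list())
  patch <- do.call(patch_spec, cfg$patch %||% list())
  calib <- if (is.null(cfg$rsp_calibration)) default_rsp_calibration()
  else rsp_calibration(do.call(rbind.data.frame, cfg$rsp_calibration))
  thresholds <- if (is.null(cfg$thresholds)) {
    df <- hu_threshold_defaults()
    stats::setNames(lapply(seq_len(nrow(df)), function(i)
      tail_thresholds(df$roi[i], df$low[i], df$high[i])), df$roi)
  } else {
    stats::setNames(lapply(cfg$thresholds, function(t)
      tail_thresholds(t$roi, t$low, t$high)),
      vapply(cfg$thresholds, `[[`, character(1L), "roi"))
  }
  list(params = params, patch = patch, calib = calib,
       thresholds = thresholds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
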