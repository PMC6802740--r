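#' Repeated-measures data for paired contrasts
#'
#' A subjects-by-conditions matrix of a scalar metric: independent subjects
#' (phantom pins or patients), dependent conditions (the MAR algorithms).
#'
#' @param values Numeric matrix, one row per subject, one column per
#'   condition; no missing cells.
#' @param subjects Subject identifiers (default from rownames or 1..N).
#' @param conditions Condition (algorithm) names (default from colnames).
#' @return A `repeated_measures`.
#' @export
repeated_measures <- function(values, subjects = NULL, conditions = NULL) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("repeated measures must have no missing cells")
  if (is.null(conditions)) conditions <- colnames(values)
  if (is.null(conditions)) stop("condition names are required")
  if (is.null(subjects)) subjects <- rownames(values)
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(values)))
  dimnames(values) <- list(subjects, conditions)
  structure(list(values = values, subjects = subjects,
                 conditions = conditions),
            class = "repeated_measures")
}

#' Orthogonal contrast specification
#'
#' A contrast compares the unweighted mean over `term1` conditions with the
#' unweighted mean over `term2` conditions.
#'
#' @param name Contrast name.
#' @param term1,term2 Disjoint, non-empty character vectors of condition
#'   names.
#' @return A `contrast_spec`.
#' @export
contrast_spec <- function(name, term1, term2) {
  if (length(term1) == 0L || length(term2) == 0L)
    stop("both contrast terms must be non-empty")
  if (length(intersect(term1, term2)))
    stop("contrast terms must be disjoint")
  structure(list(name = as.character(name), term1 = term1, term2 = term2),
            class = "contrast_spec")
}

.check_conditions <- function(data, spec) {
  missing <- setdiff(c(spec$term1, spec$term2), data$conditions)
  if (length(missing))
    stop("condition(s) not in data: ", paste(missing, collapse = ", "))
}

.contrast_result <- function(spec, d, tails) {
  n <- length(d)
  if (n < 2L) stop("at least 2 subjects are required")
  sdd <- stats::sd(d)  # sample SD, N-1 denominator
  if (sdd == 0)
    stop("degenerate data: paired differences for contrast '", spec$name,
         "' have zero variance")
  t <- mean(d) * sqrt(n) / sdd
  df <- n - 1L
  p <- if (tails == 2L) 2 * stats::pt(-abs(t), df)
       else stats::pt(t, df, lower.tail = FALSE)
  structure(list(name = spec$name, differences = d, mean = mean(d),
                 se = sdd / sqrt(n), t = t, df = df, p = p,
                 tails = as.integer(tails),
                 signif = if (p < 0.01) "**" else if (p < 0.05) "*" else ""),
            class = "contrast_result")
}

#' Paired t-test of an orthogonal contrast
#'
#' Per subject, `d = mean over term1 of f(value) - mean over term2 of
#' f(value)` with `f` the transform (absolute value for corruption metrics,
#' identity otherwise); then `t = mean(d) sqrt(N) / SD(d)` with the sample
#' SD and Student's t on `N - 1` df. A positive mean implies smaller metric
#' magnitude under the second term. p-values are deliberately not corrected
#' for multiple comparisons: orthogonal contrasts are tested as a family of
#' independent questions.
#'
#' @param data A [repeated_measures()].
#' @param spec A [contrast_spec()].
#' @param transform `"abs_value"` or `"identity"`, applied per cell before
#'   aggregation.
#' @param tails 1 or 2.
#' @return A `contrast_result`: per-subject differences, mean, SE, t, df, p
#'   and significance marker (`*` p < 0.05, `**` p < 0.01).
#' @export
paired_contrast_test <- function(data, spec,
                                 transform = c("abs_value", "identity"),
                                 tails = 2L) {
  transform <- match.arg(transform)
  tails <- as.integer(tails)
  if (!tails %in% c(1L, 2L)) stop("'tails' must be 1 or 2")
  .check_conditions(data, spec)
  f <- if (transform == "abs_value") abs else identity
  v <- f(data$values)
  d <- rowMeans(v[, spec$term1, drop = FALSE]) -
    rowMeans(v[, spec$term2, drop = FALSE])
  .contrast_result(spec, d, tails)
}

#' One-tailed t-test on absolute contrast differences
#'
#' For settings without ground truth the per-subject quantity is
#' `d = |aggregate(term1) - aggregate(term2)|`, which is strictly positive;
#' the one-tailed test asks whether its mean exceeds 0.
#'
#' @inheritParams paired_contrast_test
#' @return A `contrast_result` with `tails = 1`.
#' @export
one_tailed_absolute_test <- function(data, spec) {
  .check_conditions(data, spec)
  v <- data$values
  d <- abs(rowMeans(v[, spec$term1, drop = FALSE]) -
             rowMeans(v[, spec$term2, drop = FALSE]))
  .contrast_result(spec, d, 1L)
}

#' Check a set of contrasts for orthogonality
#'
#' Builds each contrast's coefficient vector (`1/|term1|` on term1,
#' `-1/|term2|` on term2, 0 elsewhere) and returns all pairwise dot
#' products; the set is orthogonal iff every off-diagonal product is 0.
#'
#' @param specs List of [contrast_spec()]s.
#' @param conditions Character vector of all condition names.
#' @return List: `orthogonal` (logical), `gram` (pairwise dot products),
#'   `coefficients` (contrasts x conditions matrix).
#' @export
orthogonality_check <- function(specs, conditions) {
  C <- t(vapply(specs, function(s) {
    missing <- setdiff(c(s$term1, s$term2), conditions)
    if (length(missing))
      stop("contrast '", s$name, "' references unknown condition(s): ",
           paste(missing, collapse = ", "))
    v <- stats::setNames(numeric(length(conditions)), conditions)
    v[s$term1] <- 1 / length(s$term1)
    v[s$term2] <- -1 / length(s$term2)
    v
  }, numeric(length(conditions))))
  rownames(C) <- vapply(specs, `[[`, character(1L), "name")
  gram <- C %*% t(C)
  off <- gram
  diag(off) <- 0
  list(orthogonal = all(abs(off) < 1e-12), gram = gram, coefficients = C)
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast '%s'> mean = %+.4g, SE = %.4g, t(%d) = %.4f, %d-tailed p = %.4g %s\n",
              x$name, x$mean, x$se, x$df, x$t, x$tails, x$p, x$signif))
  invisible(x)
}

#' Tabulate contrast results
#'
#' @param results List of `contrast_result`s.
#' @return Data frame with one row per contrast.
#' @export
contrast_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(contrast = r$name, n = r$df + 1L, mean = r$mean, se = r$se,
               t = r$t, df = r$df, p = r$p, tails = r$tails,
               signif = r$signif)
  }))
}
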