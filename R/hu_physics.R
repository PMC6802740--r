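#' Bundled photon mass attenuation coefficients
#'
#' Loads the packaged table of elemental mass attenuation coefficients
#' (mu/rho, cm^2/g, coherent scattering included) on a 20-150 keV grid,
#' transcribed from the NIST reference tables, for the eleven elements
#' occurring in the bundled ICRU-46 tissue compositions.
#'
#' @param path Optional path to a CSV with columns
#'   `element,energy_kev,mu_over_rho_cm2_g`; defaults to the packaged table.
#' @return An `attenuation_table`: a named list, one data frame
#'   (`energy_kev`, `mu_over_rho`) per element, energies strictly increasing.
#' @export
attenuation_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nist_mass_attenuation.csv",
                        package = "kermar", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- lapply(split(df, df$element), function(d) {
    d <- d[order(d$energy_kev), c("energy_kev", "mu_over_rho_cm2_g")]
    names(d) <- c("energy_kev", "mu_over_rho")
    if (any(diff(d$energy_kev) <= 0))
      stop("attenuation table energies must be strictly increasing")
    if (any(d$mu_over_rho <= 0))
      stop("attenuation coefficients must be positive")
    d
  })
  structure(tab, class = "attenuation_table")
}

#' Named tissue material
#'
#' @param name Material name.
#' @param mass_fractions Named numeric vector of elemental mass fractions;
#'   must sum to 1 within 1e-3.
#' @param density Mass density in g/cm^3, strictly positive.
#' @return A `tissue_composition`.
#' @export
tissue_composition <- function(name, mass_fractions, density) {
  if (is.null(names(mass_fractions)) || any(names(mass_fractions) == ""))
    stop("'mass_fractions' must be a named vector of element symbols")
  if (abs(sum(mass_fractions) - 1) > 1e-3)
    stop("mass fractions of '", name, "' sum to ", sum(mass_fractions),
         ", not 1 (tolerance 1e-3)")
  if (any(mass_fractions < 0))
    stop("mass fractions must be non-negative")
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("'density' must be a single positive number (g/cm^3)")
  structure(list(name = as.character(name),
                 mass_fractions = mass_fractions,
                 density = as.numeric(density)),
            class = "tissue_composition")
}

#' Bundled ICRU-46 tissue compositions
#'
#' Water, adipose, average soft tissue, mandible, cortical bone and enamel
#' (hydroxyapatite mass fractions), with ICRU-46 mass densities; the enamel
#' density shipped here is the nominal literature value, see
#' [enamel_density_estimate()] for the constituent-average estimate.
#'
#' @param path Optional CSV path; defaults to the packaged table.
#' @return Named list of [tissue_composition()] objects.
#' @export
tissue_compositions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "icru46_compositions.csv",
                        package = "kermar", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$tissue), function(d) {
    tissue_composition(d$tissue[1L],
                       stats::setNames(d$mass_fraction, d$element),
                       d$density_g_cm3[1L])
  })
}

.element_data <- function() {
  path <- system.file("extdata", "elements.csv", package = "kermar",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Mass attenuation coefficient of a mixture
#'
#' Applies the mixture rule `sum_i w_i (mu/rho)_i(E)` with per-element
#' log-log interpolation of the tabulated coefficients in energy.
#'
#' @param material A [tissue_composition()].
#' @param table An [attenuation_table()].
#' @param energy_kev Photon energy in keV; must lie within the tabulated span
#'   of every constituent element.
#' @return Mass attenuation coefficient in cm^2/g.
#' @export
mu_over_rho <- function(material, table = attenuation_table(),
                        energy_kev = 75.2) {
  w <- material$mass_fractions
  w <- w[w > 0]
  total <- 0
  for (el in names(w)) {
    d <- table[[el]]
    if (is.null(d))
      stop("element '", el, "' is not in the attenuation table")
    if (energy_kev < min(d$energy_kev) || energy_kev > max(d$energy_kev))
      stop("energy ", energy_kev, " keV outside tabulated span [",
           min(d$energy_kev), ", ", max(d$energy_kev), "] for element '",
           el, "'")
    mu <- exp(stats::approx(log(d$energy_kev), log(d$mu_over_rho),
                            xout = log(energy_kev))$y)
    total <- total + w[[el]] * mu
  }
  unname(total)
}

#' CT number of a material at a given energy
#'
#' `HU = 1000 (rho mu/rho - rho_w (mu/rho)_w) / (rho_w (mu/rho)_w)` evaluated
#' at a single (effective) energy; water returns exactly 0 at any energy.
#'
#' @inheritParams mu_over_rho
#' @param water Water reference composition; defaults to the bundled one.
#' @return CT number in HU.
#' @export
hu_of_material <- function(material, table = attenuation_table(),
                           energy_kev = 75.2, water = NULL) {
  if (is.null(water)) water <- tissue_compositions()[["water"]]
  mw <- water$density * mu_over_rho(water, table, energy_kev)
  mm <- material$density * mu_over_rho(material, table, energy_kev)
  1000 * (mm - mw) / mw
}

## Parse a chemical formula like "Ca10(PO4)6(OH)2" into element counts.
.parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("cannot parse chemical formula: empty input")
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?|\\d+|\\(|\\)", formula))[[1L]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse chemical formula '", formula, "'")
  i <- 0L
  n <- length(toks)
  peek <- function() if (i < n) toks[i + 1L] else ""
  advance <- function() {
    i <<- i + 1L
    toks[i]
  }
  parse_group <- function() {
    counts <- numeric(0)
    add <- function(cnt) {
      for (el in names(cnt))
        counts[el] <<- (if (el %in% names(counts)) counts[[el]] else 0) + cnt[[el]]
    }
    repeat {
      tk <- peek()
      if (tk == "" || tk == ")") break
      if (tk == "(") {
        advance()
        inner <- parse_group()
        if (peek() != ")")
          stop("cannot parse chemical formula '", formula,
               "': unbalanced parentheses")
        advance()
        mult <- 1
        if (grepl("^\\d+$", peek())) mult <- as.numeric(advance())
        add(inner * mult)
      } else if (grepl("^[A-Z]", tk)) {
        advance()
        mult <- 1
        if (grepl("^\\d+$", peek())) mult <- as.numeric(advance())
        add(stats::setNames(mult, tk))
      } else {
        stop("cannot parse chemical formula '", formula, "' near '", tk, "'")
      }
    }
    counts
  }
  counts <- parse_group()
  if (i != n || length(counts) == 0L)
    stop("cannot parse chemical formula '", formula, "'")
  counts
}

#' Constituent-average density estimate from a chemical formula
#'
#' Estimates the mass density of a compound as the mass-fraction-weighted
#' average of the bundled elemental densities of its constituents. This is
#' the documented interpretation of an averaging rule that is ambiguous
#' (count- vs mass-weighting); it is deterministic for fixed inputs and is
#' reported alongside, never instead of, the operating threshold constants.
#'
#' @param formula Chemical formula, e.g. `"Ca10(PO4)6(OH)2"` for
#'   hydroxyapatite (the main component of tooth enamel).
#' @return Density estimate in g/cm^3.
#' @export
enamel_density_estimate <- function(formula = "Ca10(PO4)6(OH)2") {
  counts <- .parse_formula(formula)
  eld <- .element_data()
  missing <- setdiff(names(counts), eld$element)
  if (length(missing))
    stop("no bundled data for element(s): ", paste(missing, collapse = ", "))
  am <- stats::setNames(eld$atomic_mass_u, eld$element)[names(counts)]
  rho <- stats::setNames(eld$density_g_cm3, eld$element)[names(counts)]
  mass <- counts * am
  w <- mass / sum(mass)
  unname(sum(w * rho))
}

#' Shipped HU threshold operating points
#'
#' The tissue-threshold constants used as defaults by the corruption metrics:
#' oral cavity adipose/average-soft-tissue (-200/300 HU), mandible
#' mandibular/cortical (1000/1500 HU), teeth cortical/enamel (1500/2600 HU),
#' and the empirical phantom bone window (1500/1800 HU). These are shipped as
#' fixed constants, independent of the composition-based derivation path
#' (whose computed values are documented in the methods vignette).
#'
#' @return Data frame with columns `roi`, `low`, `high` (HU).
#' @export
hu_threshold_defaults <- function() {
  data.frame(
    roi = c("oral_cavity", "mandible", "teeth",
            "phantom_soft_tissue", "phantom_bone"),
    low = c(-200, 1000, 1500, -200, 1500),
    high = c(300, 1500, 2600, 300, 1800)
  )
}

#' Piecewise-linear HU to relative stopping power calibration
#'
#' @param knots Data frame with columns `hu` (strictly increasing) and `rsp`
#'   (non-negative); must contain the water knot (0 HU, RSP 1).
#' @return An `rsp_calibration`.
#' @export
rsp_calibration <- function(knots) {
  if (!all(c("hu", "rsp") %in% names(knots)))
    stop("'knots' needs columns 'hu' and 'rsp'")
  knots <- knots[order(knots$hu), , drop = FALSE]
  if (any(diff(knots$hu) <= 0))
    stop("HU knots must be strictly increasing")
  if (any(knots$rsp < 0))
    stop("RSP values must be non-negative")
  if (!any(knots$hu == 0 & knots$rsp == 1))
    stop("calibration must contain the water knot (0 HU, RSP 1)")
  structure(list(hu = knots$hu, rsp = knots$rsp), class = "rsp_calibration")
}

#' Default HU to RSP calibration
#'
#' Four-knot curve (-1000, 0.001), (0, 1), (1500, 1.85), (3000, 2.4): a
#' plausible clinical shape, fully overridable via [rsp_calibration()]; no
#' claim of matching any specific treatment planning system.
#'
#' @return An [rsp_calibration()].
#' @export
default_rsp_calibration <- function() {
  rsp_calibration(data.frame(hu = c(-1000, 0, 1500, 3000),
                             rsp = c(0.001, 1.0, 1.85, 2.4)))
}

#' Convert HU to relative stopping power
#'
#' Piecewise-linear interpolation between calibration knots, clamped to the
#' end knots outside the calibrated span; `hu = 0` maps to exactly 1.
#'
#' @param hu Numeric vector of CT numbers.
#' @param calib An [rsp_calibration()].
#' @return Numeric vector of RSP values.
#' @export
hu_to_rsp <- function(hu, calib = default_rsp_calibration()) {
  stats::approx(calib$hu, calib$rsp, xout = hu, rule = 2)$y
}

## water linear attenuation coefficient in 1/mm at given energies
.mu_water_mm <- function(energy_kev, table = attenuation_table(),
                         water = NULL) {
  if (is.null(water)) water <- tissue_compositions()[["water"]]
  vapply(energy_kev,
         function(e) water$density * mu_over_rho(water, table, e) / 10,
         numeric(1L))
}
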