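## Memoized simulation fixtures: the heavier simulated objects are built once
## per test run and shared across files.
.fixtures <- new.env(parent = emptyenv())

test_case <- function(seed = 7, n_pins = 2) {
  key <- sprintf("case_%d_%d", seed, n_pins)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- suppressWarnings(
      simulate_case(default_phantom_spec(n_pins = n_pins, seed = seed)))
  }
  .fixtures[[key]]
}

test_kermar_result <- function(seed = 7, n_pins = 2) {
  key <- sprintf("ker_%d_%d", seed, n_pins)
  if (is.null(.fixtures[[key]])) {
    case <- test_case(seed, n_pins)
    .fixtures[[key]] <- suppressWarnings(
      run_kermar(case$corrupted, case$mr, case$masks$corrupted,
                 case$masks$body, case$masks$metal,
                 params = kermar_params(seed = seed)))
  }
  .fixtures[[key]]
}

test_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- suppressWarnings(
      run_cohort(n_subjects = 5, seed = 1, keep_cases = TRUE))
  }
  .fixtures$cohort
}

## tiny uniform volume helper
uniform_volume <- function(value, dim = c(4, 4, 4), spacing = c(1, 1, 1),
                           modality = "CT") {
  image_volume(array(value, dim = dim), spacing = spacing,
               modality = modality)
}

## monochromatic noiseless acquisition at the effective energy
mono_model <- function(...) {
  sinogram_model(spectrum = data.frame(energy_kev = 75.2, weight = 1),
                 beam_hardening = FALSE, noise = FALSE, ...)
}

## independent Student-t upper-tail probability by numeric integration of the
## density written from its closed form (oracle for p-values)
t_upper_tail <- function(t, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  stats::integrate(dens, t, Inf, rel.tol = 1e-10)$value
}
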