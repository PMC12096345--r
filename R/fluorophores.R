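# Parametric compound optics: absorption and emission are sums of Gaussian
# bands, which is enough to reproduce the qualitative anchors the simulator
# targets (band positions, Stokes shifts, relative quantum yields) without
# pretending to be measured spectra.

WAVELENGTH_MIN <- 185
WAVELENGTH_MAX <- 655

# Gaussian evaluated from centre/FWHM, unit peak height.
gauss_peak <- function(lambda, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-0.5 * ((lambda - center) / sigma)^2)
}

#' Define a synthetic fluorophore
#'
#' A fluorophore is described by a molar-style absorption curve
#' \eqn{\epsilon(\lambda)} (mL mg^-1 cm^-1), a normalized emission profile
#' \eqn{f(\lambda)} (unit area over 185--655 nm), and a quantum yield
#' \eqn{\phi}. Both curves are sums of Gaussian bands, each given as
#' `c(center_nm, fwhm_nm, height)`; emission heights are relative weights
#' (the profile is renormalized to unit area).
#'
#' @param name Compound identifier.
#' @param absorption List of `c(center, fwhm, eps_max)` bands.
#' @param emission List of `c(center, fwhm, weight)` bands.
#' @param quantum_yield Fluorescence quantum yield in (0, 1].
#' @return Object of class `hsf_fluorophore` with evaluator functions.
#' @export
#' @examples
#' f <- fluorophore_spec("demo", list(c(300, 30, 2)), list(c(360, 45, 1)), 0.2)
#' f$absorption(300)
fluorophore_spec <- function(name, absorption, emission, quantum_yield) {
  if (!(quantum_yield > 0 && quantum_yield <= 1))
    stop("quantum_yield must lie in (0, 1]")
  abs_bands <- do.call(rbind, lapply(absorption, as.numeric))
  em_bands  <- do.call(rbind, lapply(emission, as.numeric))
  if (ncol(abs_bands) != 3L || ncol(em_bands) != 3L)
    stop("each band must be c(center, fwhm, height)")
  if (any(abs_bands[, 3] < 0) || any(em_bands[, 3] < 0))
    stop("band heights must be non-negative")

  eps_fun <- function(lambda) {
    out <- numeric(length(lambda))
    for (i in seq_len(nrow(abs_bands)))
      out <- out + abs_bands[i, 3] *
        gauss_peak(lambda, abs_bands[i, 1], abs_bands[i, 2])
    out
  }
  em_raw <- function(lambda) {
    out <- numeric(length(lambda))
    for (i in seq_len(nrow(em_bands)))
      out <- out + em_bands[i, 3] *
        gauss_peak(lambda, em_bands[i, 1], em_bands[i, 2])
    out
  }
  # unit-area normalization over the detector span (trapezoid, fine grid)
  grid <- seq(WAVELENGTH_MIN, WAVELENGTH_MAX, by = 0.05)
  v <- em_raw(grid)
  area <- sum((v[-1] + v[-length(v)]) / 2 * diff(grid))
  if (area <= 0) stop("emission profile has zero area")
  em_fun <- function(lambda) em_raw(lambda) / area

  # Stokes-shift sanity: emission mass must sit redward of the absorption max
  abs_max <- grid[which.max(eps_fun(grid))]
  em_mean <- sum(grid * v) / sum(v)
  if (em_mean <= abs_max)
    stop("emission must lie redward of the absorption maximum (", name, ")")

  structure(list(name = name,
                 absorption = eps_fun,
                 emission_profile = em_fun,
                 quantum_yield = quantum_yield,
                 abs_bands = abs_bands,
                 em_bands = em_bands,
                 absorption_max_nm = abs_max),
            class = "hsf_fluorophore")
}

#' @export
print.hsf_fluorophore <- function(x, ...) {
  cat(sprintf("<hsf_fluorophore> %s  abs max %.0f nm, QY %.2f\n",
              x$name, x$absorption_max_nm, x$quantum_yield))
  invisible(x)
}

#' Define a sample as concentration-weighted fluorophore components
#'
#' @param components List of `list(fluorophore, concentration)` pairs
#'   (concentration in mg/mL). An empty list is blank solvent.
#' @param solvent_baseline Relative diffuse reflectance of the blank
#'   solvent/well, default 0.9.
#' @param path_length Effective optical path in cm, default 1 (the 10 mm
#'   deep sample well).
#' @return Object of class `hsf_sample`.
#' @export
sample_spec <- function(components = list(), solvent_baseline = 0.9,
                        path_length = 1) {
  for (cm in components) {
    if (!inherits(cm[[1]], "hsf_fluorophore"))
      stop("each component must be list(fluorophore, concentration)")
    if (cm[[2]] < 0) stop("concentrations must be >= 0")
  }
  structure(list(components = components,
                 solvent_baseline = solvent_baseline,
                 path_length = path_length),
            class = "hsf_sample")
}

#' Total Beer-Lambert absorbance of a sample
#'
#' \eqn{A(\lambda) = \ell \sum_i \epsilon_i(\lambda) c_i}: additive over
#' components, zero for blank solvent.
#'
#' @param sample An `hsf_sample`.
#' @param wavelength Wavelengths in nm, each within \[185, 655\].
#' @return Numeric absorbance, same length as `wavelength`.
#' @export
#' @examples
#' total_absorbance(sample_spec(), 300)  # blank -> 0
total_absorbance <- function(sample, wavelength) {
  stopifnot(inherits(sample, "hsf_sample"))
  if (any(wavelength < WAVELENGTH_MIN | wavelength > WAVELENGTH_MAX))
    stop("wavelength outside [", WAVELENGTH_MIN, ", ", WAVELENGTH_MAX, "] nm")
  A <- numeric(length(wavelength))
  for (cm in sample$components)
    A <- A + cm[[1]]$absorption(wavelength) * cm[[2]]
  sample$path_length * A
}
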