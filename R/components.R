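#' Lineshapes and metabolite component spectra
#'
#' Bands are synthesised as area-normalised lineshapes so that the
#' integrated intensity of a component is independent of how the intensity
#' is split between 12C and 13C positions (exact up to truncation of
#' Lorentzian tails at the axis edges).
#'
#' @name lineshapes
NULL

# Area-normalised Lorentzian / Gaussian / pseudo-Voigt profiles.
lorentzian_line <- function(nu, center, fwhm) {
  g <- fwhm / 2
  (g / pi) / ((nu - center)^2 + g^2)
}

gaussian_line <- function(nu, center, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(nu - center)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
}

#' Evaluate an area-normalised lineshape
#'
#' @param nu wavenumbers at which to evaluate
#' @param center band centre (cm^-1)
#' @param fwhm full width at half maximum (cm^-1)
#' @param shape \code{"lorentzian"}, \code{"gaussian"} or
#'   \code{"pseudo_voigt"}
#' @param eta Lorentzian mixing fraction for pseudo-Voigt (default 0.7)
#' @return numeric vector, unit integrated area on an unbounded axis
#' @export
lineshape <- function(nu, center, fwhm, shape = "pseudo_voigt", eta = 0.7) {
  stopifnot(fwhm > 0)
  switch(shape,
    lorentzian = lorentzian_line(nu, center, fwhm),
    gaussian = gaussian_line(nu, center, fwhm),
    pseudo_voigt = eta * lorentzian_line(nu, center, fwhm) +
      (1 - eta) * gaussian_line(nu, center, fwhm),
    stop("unknown lineshape: ", shape)
  )
}

#' Pure-component spectrum of a metabolite at a given 13C fraction
#'
#' In \code{two_bands} mode every band contributes
#' \code{(1 - f13) * line(center12) + f13 * line(center13)}; bands without a
#' 13C partner (e.g. the carbon-free polyphosphate P-O vibrations) are
#' isotope-insensitive and contribute at \code{center12} regardless of
#' \code{f13}. In \code{interpolate_position} mode (carotenoids: a mixed
#' 12C/13C molecular population) each band contributes a single line at the
#' interpolated position \code{center12 - f13 * (center12 - center13)}.
#'
#' @param metabolite metabolite name present in \code{band_table}
#' @param axis numeric wavenumber axis
#' @param f13 13C fraction in [0, 1]
#' @param modality instrument modality (selects the Raman or IR band set)
#' @param band_table band table (default [default_band_table()])
#' @param rel_intensity_scale multiplier on all band intensities (e.g. the
#'   resonance-Raman enhancement of carotenoids under 785 nm excitation)
#' @return spectrum object (intensity >= 0, integral proportional to the sum
#'   of the band relative intensities)
#' @export
#' @examples
#' sp <- component_spectrum("TAG", default_axis("HTSFTIR"), f13 = 0)
#' sp$wavenumber[which.max(sp$intensity)]  # ester C=O at 1745
component_spectrum <- function(metabolite, axis, f13, modality,
                               band_table = default_band_table(),
                               rel_intensity_scale = 1) {
  if (!is.numeric(f13) || length(f13) != 1 || is.na(f13) ||
      f13 < 0 || f13 > 1) {
    stop("f13 must be a single value in [0, 1]")
  }
  bands <- band_lookup(band_table, metabolite, modality)
  y <- numeric(length(axis))
  if (nrow(bands) == 0) {
    return(spectrum(axis, y, modality = modality,
                    meta = list(metabolite = metabolite, f13 = f13)))
  }
  span <- range(axis)
  covered <- FALSE
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    centers <- component_band_centers(b, f13)
    for (j in seq_len(nrow(centers))) {
      cj <- centers$center[j]
      if (cj >= span[1] - 3 * b$fwhm && cj <= span[2] + 3 * b$fwhm) covered <- TRUE
      y <- y + rel_intensity_scale * b$rel_intensity * centers$weight[j] *
        lineshape(axis, cj, b$fwhm, b$shape, b$eta)
    }
  }
  if (!covered) {
    warning("axis does not cover any band of ", metabolite, "; returning zeros")
    y[] <- 0
  }
  spectrum(axis, y, modality = modality,
           meta = list(metabolite = metabolite, f13 = f13))
}

# centres and weights contributed by one band at 13C fraction f13
component_band_centers <- function(band, f13) {
  if (is.na(band$center13)) {
    return(data.frame(center = band$center12, weight = 1))
  }
  if (identical(band$isotope_mode, "interpolate_position")) {
    return(data.frame(
      center = band$center12 - f13 * (band$center12 - band$center13),
      weight = 1))
  }
  data.frame(center = c(band$center12, band$center13),
             weight = c(1 - f13, f13))
}
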