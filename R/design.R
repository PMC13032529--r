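#' Growth media and experimental design
#'
#' The study design crosses seven growth media (varying glucose/glycerol
#' ratios, with glucose either standard 12C or fully 13C-labelled) with six
#' harvest timepoints, one culture per cell, and three technical replicates
#' per bulk spectroscopy modality.
#'
#' @name study-design
NULL

#' Table of growth media (carbon sources in g/L)
#'
#' @return data frame with columns \code{medium}, \code{glucose12},
#'   \code{glucose13}, \code{glycerol} (g/L)
#' @export
media_table <- function() {
  data.frame(
    medium    = c("nGlu", "iGlu", "nGlu1:Gly1", "iGlu1:Gly1",
                  "nGlu1:Gly7", "iGlu1:Gly7", "Gly"),
    glucose12 = c(40, 0, 20, 0, 5, 0, 0),
    glucose13 = c(0, 40, 0, 20, 0, 5, 0),
    glycerol  = c(0, 0, 20, 20, 35, 35, 40),
    stringsAsFactors = FALSE
  )
}

medium_spec <- function(medium) {
  mt <- media_table()
  i <- match(medium, mt$medium)
  if (is.na(i)) stop("unknown medium name: ", medium)
  as.list(mt[i, ])
}

#' Default experimental design
#'
#' @param media character vector of medium names (default all seven)
#' @param timepoints harvest times in hours (default 8, 14, 24, 36, 60, 120)
#' @param replicates technical replicates per bulk modality (default 3)
#' @param modalities bulk modalities to simulate
#' @return list of class \code{design}
#' @export
default_design <- function(media = media_table()$medium,
                           timepoints = c(8, 14, 24, 36, 60, 120),
                           replicates = 3L,
                           modalities = c("HTSFTIR", "FTRaman")) {
  stopifnot(all(media %in% media_table()$medium), replicates >= 1)
  structure(list(media = media, timepoints = timepoints,
                 replicates = as.integer(replicates),
                 modalities = vapply(modalities, match_modality, character(1),
                                     USE.NAMES = FALSE)),
            class = "design")
}

#' Design arithmetic
#'
#' @param design design object
#' @return list with \code{n_samples} (media x timepoints),
#'   \code{n_bulk_spectra} (samples x replicates) and
#'   \code{n_pixels_per_image} for a default 128 x 128 focal-plane-array
#'   image
#' @export
design_counts <- function(design = default_design()) {
  n_samples <- length(design$media) * length(design$timepoints)
  list(n_samples = n_samples,
       n_bulk_spectra = n_samples * design$replicates,
       n_pixels_per_image = 128L * 128L)
}

#' Standard error of the mean from a standard deviation
#'
#' @param sd sample standard deviation
#' @param n sample size
#' @return sd / sqrt(n)
#' @export
sem_from_sd <- function(sd, n) {
  stopifnot(n >= 1)
  sd / sqrt(n)
}

#' Carbon mass fraction of a carbon substrate
#'
#' Computed from atomic masses (12C = 12 exactly, 13C = 13.00335,
#' H = 1.00794, O = 15.9994). Glucose is C6H12O6, glycerol C3H8O3.
#'
#' @param substrate \code{"glucose"} or \code{"glycerol"}
#' @param isotope \code{"12C"} or \code{"13C"}
#' @return carbon mass fraction in percent (w/w)
#' @export
#' @examples
#' carbon_mass_fraction("glucose", "12C")  # ~40%
carbon_mass_fraction <- function(substrate = c("glucose", "glycerol"),
                                 isotope = c("12C", "13C")) {
  substrate <- match.arg(substrate)
  isotope <- match.arg(isotope)
  mC <- if (isotope == "12C") 12.000 else 13.00335
  mH <- 1.00794; mO <- 15.9994
  n <- switch(substrate, glucose = c(6, 12, 6), glycerol = c(3, 8, 3))
  100 * n[1] * mC / (n[1] * mC + n[2] * mH + n[3] * mO)
}
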