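#' Wavenumber axes for the supported spectroscopy modalities
#'
#' A wavenumber axis is a strictly monotone, uniformly spaced grid of
#' wavenumbers (cm^-1). Axes are stored ascending; the instrument "range"
#' is anchored at the upper end of the recorded interval, so the lowest grid
#' point may fall slightly above the nominal lower bound when the span is not
#' an integer multiple of the digital spacing.
#'
#' Default instrument grids:
#' \itemize{
#'   \item \code{FTRaman}: 3785--50 cm^-1, spacing 1.928 cm^-1
#'   \item \code{HTSFTIR}: 4000--400 cm^-1, spacing 1.928 cm^-1
#'   \item \code{FTIRMicro}: 3850--900 cm^-1, spacing 3.851 cm^-1
#'   \item \code{RamanMicro}: 2920--0 cm^-1, spacing 1.928 cm^-1 (the CCD
#'     dispersion grid is approximated by a uniform grid at the FT spacing)
#' }
#'
#' @param modality one of \code{"FTRaman"}, \code{"HTSFTIR"},
#'   \code{"FTIRMicro"}, \code{"RamanMicro"}
#' @return numeric vector of wavenumbers (cm^-1), ascending, uniform spacing
#' @export
#' @examples
#' nu <- default_axis("HTSFTIR")
#' range(nu); diff(nu)[1]
default_axis <- function(modality) {
  modality <- match_modality(modality)
  p <- axis_params(modality)
  make_axis(p$hi, p$lo, p$spacing)
}

axis_params <- function(modality) {
  switch(modality,
    FTRaman    = list(hi = 3785, lo = 50,  spacing = 1.928),
    HTSFTIR    = list(hi = 4000, lo = 400, spacing = 1.928),
    FTIRMicro  = list(hi = 3850, lo = 900, spacing = 3.851),
    RamanMicro = list(hi = 2920, lo = 0,   spacing = 1.928),
    stop("unknown modality: ", modality)
  )
}

#' @rdname default_axis
#' @export
modalities <- function() c("FTRaman", "HTSFTIR", "RamanMicro", "FTIRMicro")

match_modality <- function(modality) {
  match.arg(modality, modalities())
}

make_axis <- function(hi, lo, spacing) {
  stopifnot(hi > lo, spacing > 0)
  n <- floor((hi - lo) / spacing) + 1L
  rev(hi - spacing * (seq_len(n) - 1L))
}

#' Check that a wavenumber axis is uniform
#'
#' @param nu numeric vector of wavenumbers
#' @param rel_tol relative tolerance on spacing constancy
#' @return invisible spacing (cm^-1); errors if the axis is not strictly
#'   monotone ascending with constant spacing
#' @keywords internal
axis_spacing <- function(nu, rel_tol = 1e-9) {
  if (length(nu) < 2L) stop("axis needs at least 2 points")
  d <- diff(nu)
  if (any(d <= 0)) stop("axis must be strictly ascending")
  h <- mean(d)
  if (max(abs(d - h)) > rel_tol * max(abs(h), 1)) {
    stop("axis is not uniformly spaced")
  }
  invisible(h)
}

is_uniform_axis <- function(nu, rel_tol = 1e-6) {
  if (length(nu) < 2L) return(FALSE)
  d <- diff(nu)
  all(d > 0) && (max(d) - min(d)) <= rel_tol * max(abs(mean(d)), 1)
}
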