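#' Spectrum and spectral dataset containers
#'
#' A \code{spectrum} holds one intensity trace on a wavenumber axis together
#' with sample metadata and a derivative-order flag. A
#' \code{spectral_dataset} holds many spectra that share one axis, stored as
#' a samples x wavenumbers matrix plus a metadata data frame (one row per
#' spectrum). These are the currency passed between the generator, the
#' preprocessing recipes, the band metrics and the multivariate models.
#'
#' @name spectra-containers
NULL

#' Construct a single spectrum
#'
#' @param wavenumber ascending numeric axis (cm^-1)
#' @param intensity numeric vector, same length as \code{wavenumber}
#' @param modality instrument modality tag (see [modalities()]) or NA
#' @param derivative_order 0, 1 or 2
#' @param meta named list of sample metadata
#' @return object of class \code{spectrum}
#' @export
spectrum <- function(wavenumber, intensity, modality = NA_character_,
                     derivative_order = 0L, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("intensity length must equal axis length")
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensity must be finite")
  }
  if (is.unsorted(wavenumber, strictly = TRUE)) {
    stop("wavenumber axis must be strictly ascending")
  }
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         modality = modality, derivative_order = as.integer(derivative_order),
         meta = meta),
    class = "spectrum"
  )
}

#' Construct a spectral dataset
#'
#' @param wavenumber ascending numeric axis (cm^-1), shared by all spectra
#' @param intensity numeric matrix, samples in rows, wavenumbers in columns
#' @param meta data frame with one row per sample; a \code{sample_id} column
#'   is added when missing
#' @param modality instrument modality tag
#' @param derivative_order 0, 1 or 2
#' @param truth optional data frame of generator ground truth (one row per
#'   sample), carried through preprocessing untouched
#' @return object of class \code{spectral_dataset}
#' @export
spectral_dataset <- function(wavenumber, intensity, meta = NULL,
                             modality = NA_character_, derivative_order = 0L,
                             truth = NULL) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.matrix(intensity)
  if (ncol(intensity) != length(wavenumber)) {
    stop("intensity must have one column per wavenumber")
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("intensities must be finite")
  }
  if (is.null(meta)) {
    meta <- data.frame(sample_id = default_sample_ids(nrow(intensity)))
  }
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(intensity)) {
    stop("meta must have one row per spectrum")
  }
  if (is.null(meta$sample_id)) meta$sample_id <- default_sample_ids(nrow(meta))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids")
  rownames(intensity) <- meta$sample_id
  structure(
    list(wavenumber = wavenumber, intensity = intensity, meta = meta,
         modality = modality, derivative_order = as.integer(derivative_order),
         truth = truth),
    class = "spectral_dataset"
  )
}

default_sample_ids <- function(n) sprintf("s%03d", seq_len(n))

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm-1, modality %s, deriv %d\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              x$modality, x$derivative_order))
  invisible(x)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d spectra x %d points, %.1f-%.1f cm-1, modality %s, deriv %d\n",
    nrow(x$intensity), length(x$wavenumber), min(x$wavenumber),
    max(x$wavenumber), x$modality, x$derivative_order))
  invisible(x)
}

#' Number of spectra in a dataset
#' @param x spectral_dataset
#' @return integer count
#' @export
n_spectra <- function(x) nrow(x$intensity)

#' Coerce a spectrum to a one-row dataset and back
#' @keywords internal
as_dataset <- function(x) {
  if (inherits(x, "spectral_dataset")) return(x)
  if (!inherits(x, "spectrum")) stop("expected a spectrum or spectral_dataset")
  meta <- data.frame(sample_id = if (!is.null(x$meta$sample_id)) x$meta$sample_id else "s001")
  spectral_dataset(x$wavenumber, matrix(x$intensity, nrow = 1), meta,
                   modality = x$modality,
                   derivative_order = x$derivative_order)
}

first_spectrum <- function(ds) {
  spectrum(ds$wavenumber, ds$intensity[1, ], modality = ds$modality,
           derivative_order = ds$derivative_order,
           meta = as.list(ds$meta[1, , drop = FALSE]))
}

# Apply a dataset-level function to spectrum or dataset, preserving the
# caller's class.
dispatch_spectral <- function(x, fn, ...) {
  if (inherits(x, "spectrum")) {
    out <- fn(as_dataset(x), ...)
    if (inherits(out, "spectral_dataset")) return(first_spectrum(out))
    return(out)
  }
  fn(x, ...)
}

#' Extract one spectrum from a dataset
#' @param ds spectral_dataset
#' @param i row index or sample id
#' @return spectrum
#' @export
get_spectrum <- function(ds, i) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.character(i)) i <- match(i, ds$meta$sample_id)
  spectrum(ds$wavenumber, ds$intensity[i, ], modality = ds$modality,
           derivative_order = ds$derivative_order,
           meta = as.list(ds$meta[i, , drop = FALSE]))
}

#' Average technical replicates after preprocessing
#'
#' Collapses spectra sharing a (medium, timepoint) cell to their mean
#' spectrum, yielding sample-to-sample correspondence between data blocks
#' ahead of multiblock analysis.
#'
#' @param ds spectral_dataset whose meta has \code{medium} and
#'   \code{timepoint_h} columns
#' @return spectral_dataset with one spectrum per (medium, timepoint)
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(ds$meta$medium) || is.null(ds$meta$timepoint_h)) {
    stop("replicate averaging needs medium and timepoint_h metadata")
  }
  key <- paste(ds$meta$medium, ds$meta$timepoint_h, sep = "@")
  ukey <- unique(key)
  X <- matrix(0, length(ukey), length(ds$wavenumber))
  meta <- data.frame(
    sample_id = ukey,
    medium = ds$meta$medium[match(ukey, key)],
    timepoint_h = ds$meta$timepoint_h[match(ukey, key)],
    n_replicates = as.integer(table(key)[ukey])
  )
  for (i in seq_along(ukey)) {
    X[i, ] <- colMeans(ds$intensity[key == ukey[i], , drop = FALSE])
  }
  spectral_dataset(ds$wavenumber, X, meta, modality = ds$modality,
                   derivative_order = ds$derivative_order)
}
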