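#' Isotope-resolved marker-band quantification
#'
#' On second-derivative spectra, band maxima appear as negative minima, so
#' the "intensity" of a marker band is the signed minimum of the second
#' derivative within a small window around the target wavenumber: more
#' negative means a stronger band. On raw spectra the window maximum is
#' used instead.
#'
#' @name band-metrics
NULL

#' Define a marker-band target
#'
#' @param label metabolite + isotope tag, e.g. \code{"TAG12"}
#' @param nu target wavenumber (cm^-1)
#' @param halfwidth half-width of the search window (cm^-1, default 4)
#' @param mode \code{"second_deriv_min"} or \code{"raw_max"}
#' @return list of class \code{band_target}
#' @export
band_target <- function(label, nu, halfwidth = 4, mode = "second_deriv_min") {
  mode <- match.arg(mode, c("second_deriv_min", "raw_max"))
  structure(list(label = label, nu = nu, halfwidth = halfwidth, mode = mode),
            class = "band_target")
}

#' Default marker-band target sets
#'
#' Infrared: TAG ester C=O for 12C (1746) and 13C (1700) plus the
#' polyphosphate P=O band (1263), on amide-I-normalised second derivatives.
#' Raman: the lipid CH2 stretch (2855, 12C) and the carotenoid C=C stretch
#' for 12C (1525) and 13C (1490). Positions follow the figure-caption
#' conventions; the +-4 cm^-1 search window absorbs the few-cm^-1
#' differences from the assignment-table positions.
#'
#' @param modality bulk modality (\code{"HTSFTIR"} or \code{"FTRaman"})
#' @return list of band_target objects
#' @export
default_band_targets <- function(modality) {
  modality <- match_modality(modality)
  if (modality_class(modality) == "ir") {
    list(band_target("TAG12", 1746), band_target("TAG13", 1700),
         band_target("polyP", 1263))
  } else {
    list(band_target("lipidCH2_12", 2855), band_target("caro12", 1525),
         band_target("caro13", 1490))
  }
}

#' Signed band intensity within a search window
#'
#' @param spec spectrum (its \code{derivative_order} must match the target
#'   mode: 2 for \code{second_deriv_min}, 0 for \code{raw_max})
#' @param target band_target
#' @return signed intensity (window minimum of the second derivative, or
#'   window maximum of the raw intensity)
#' @export
band_intensity <- function(spec, target) {
  stopifnot(inherits(spec, "spectrum"), inherits(target, "band_target"))
  need <- if (target$mode == "second_deriv_min") 2L else 0L
  if (spec$derivative_order != need) {
    stop("spectrum derivative order ", spec$derivative_order,
         " does not match target mode ", target$mode)
  }
  lo <- target$nu - target$halfwidth; hi <- target$nu + target$halfwidth
  keep <- spec$wavenumber >= lo & spec$wavenumber <= hi
  if (!any(keep)) stop("search window lies outside the axis")
  v <- spec$intensity[keep]
  if (target$mode == "second_deriv_min") min(v) else max(v)
}

#' Peak position with parabolic refinement
#'
#' Finds the extremum within a range (maximum on raw spectra, minimum on
#' second derivatives) and refines it by a three-point parabolic fit around
#' the grid extremum, giving sub-grid accuracy. If the extremum falls on
#' the range boundary the unrefined grid position is returned with
#' attribute \code{refined = FALSE}.
#'
#' @param spec spectrum
#' @param range c(lo, hi) search range (cm^-1), must contain >= 3 grid
#'   points
#' @return refined peak wavenumber (cm^-1)
#' @export
peak_position <- function(spec, range) {
  stopifnot(inherits(spec, "spectrum"))
  range <- sort(range)
  keep <- which(spec$wavenumber >= range[1] & spec$wavenumber <= range[2])
  if (length(keep) < 3) stop("range must contain at least 3 grid points")
  y <- spec$intensity[keep]
  if (spec$derivative_order == 2) y <- -y
  j <- which.max(y)
  if (j == 1 || j == length(y)) {
    warning("extremum at range boundary; position not refined")
    out <- spec$wavenumber[keep[j]]
    attr(out, "refined") <- FALSE
    return(out)
  }
  h <- spec$wavenumber[keep[j + 1]] - spec$wavenumber[keep[j]]
  d1 <- y[j - 1]; d2 <- y[j]; d3 <- y[j + 1]
  denom <- d1 - 2 * d2 + d3
  off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (d1 - d3) / denom
  out <- spec$wavenumber[keep[j]] + off * h
  attr(out, "refined") <- TRUE
  out
}

#' Isotope fraction from a 12C/13C band-intensity pair
#'
#' @param i12,i13 signed band intensities of the 12C and 13C marker bands
#' @return |i13| / (|i12| + |i13|) in [0, 1]
#' @export
isotope_fraction <- function(i12, i13) {
  s <- abs(i12) + abs(i13)
  if (all(s == 0)) stop("both band intensities are zero")
  abs(i13) / s
}

#' Assemble marker-band trajectories over the design
#'
#' One row per spectrum and band target; use [average_replicates()] on the
#' dataset first (or aggregate the returned table) for per-sample
#' trajectories.
#'
#' @param ds preprocessed spectral_dataset with medium / timepoint metadata
#' @param targets list of band_target objects (default
#'   [default_band_targets()] for the dataset's modality)
#' @param recipe_name recorded provenance (defaults to the dataset's
#'   \code{recipe} attribute)
#' @return data frame (tidy): sample_id, medium, timepoint_h, replicate,
#'   label, intensity; attribute \code{provenance} records recipe and
#'   targets
#' @export
metabolite_trajectories <- function(ds, targets = NULL, recipe_name = NULL) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(targets)) targets <- default_band_targets(ds$modality)
  if (is.null(recipe_name)) recipe_name <- attr(ds, "recipe")
  rows <- list()
  for (i in seq_len(n_spectra(ds))) {
    sp <- get_spectrum(ds, i)
    for (tg in targets) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ds$meta$sample_id[i],
        medium = if (!is.null(ds$meta$medium)) ds$meta$medium[i] else NA,
        timepoint_h = if (!is.null(ds$meta$timepoint_h)) ds$meta$timepoint_h[i] else NA,
        replicate = if (!is.null(ds$meta$replicate)) ds$meta$replicate[i] else NA,
        label = tg$label,
        intensity = band_intensity(sp, tg),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(recipe = recipe_name, targets = targets)
  out
}

#' Average a trajectory table over replicates
#'
#' @param traj trajectory table from [metabolite_trajectories()]
#' @return data frame with one row per (medium, timepoint, label), the mean
#'   intensity across replicates
#' @export
aggregate_trajectories <- function(traj) {
  out <- stats::aggregate(intensity ~ medium + timepoint_h + label,
                          data = traj, FUN = mean)
  out[order(out$medium, out$label, out$timepoint_h), ]
}

#' Export a trajectory table as tidy TSV
#'
#' @param traj trajectory table
#' @param path output file
#' @return invisible path
#' @export
write_trajectories <- function(traj, path) {
  utils::write.table(traj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
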