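#' Forward simulation of bulk vibrational spectra
#'
#' The forward model produces the distortions that the preprocessing
#' recipes are designed to remove: a multiplicative effective-path-length
#' factor, an additive baseline (a low-order polynomial fluorescence
#' surrogate for Raman; an offset plus broad sigmoid scatter surrogate for
#' FTIR), and additive i.i.d. Gaussian noise:
#' \deqn{s(\nu) = \ell \sum_m w_m c_m(\nu; f13_m) + b(\nu) + \epsilon(\nu)}
#'
#' @name forward-model
NULL

#' Baseline parameters
#'
#' @param modality instrument modality; selects the baseline family
#'   (degree-3 polynomial for Raman, offset + broad sigmoid for FTIR)
#' @param scale overall baseline magnitude in intensity units (0 = no
#'   baseline)
#' @return list of class \code{baseline_params}
#' @export
baseline_params <- function(modality, scale = 0) {
  modality <- match_modality(modality)
  kind <- if (modality_class(modality) == "raman") "poly3" else "sigmoid"
  structure(list(kind = kind, scale = scale), class = "baseline_params")
}

# Draw one random baseline on the axis using the current RNG stream.
draw_baseline <- function(axis, bp) {
  if (is.null(bp) || bp$scale == 0) return(numeric(length(axis)))
  x <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  if (bp$kind == "poly3") {
    co <- c(stats::runif(1, 0.5, 1), stats::rnorm(3, 0, 0.3))
    b <- co[1] + co[2] * x + co[3] * x^2 + co[4] * x^3
    b <- b - min(b)  # fluorescence offsets are nonnegative
  } else {
    nu0 <- stats::runif(1, stats::quantile(axis, 0.25), stats::quantile(axis, 0.75))
    w <- stats::runif(1, 300, 600)
    b <- stats::runif(1, 0.2, 0.6) + stats::runif(1, 0.4, 1) /
      (1 + exp(-(axis - nu0) / w))
  }
  bp$scale * b
}

resonance_scale <- function(modality, metabolite) {
  # carotenoid resonance enhancement under 785 nm excitation, emulated as a
  # relative-intensity multiplier (no cross-section modelling)
  if (metabolite == "carotenoid" && modality == "RamanMicro") 5 else 1
}

# noiseless mixture signal for a composition (no pathlength/baseline/noise)
clean_mixture <- function(comp, axis, modality, band_table) {
  y <- numeric(length(axis))
  for (m in names(comp$weight)) {
    w <- comp$weight[[m]]
    if (w <= 0) next
    cs <- suppressWarnings(component_spectrum(
      m, axis, comp$f13[[m]], modality, band_table,
      rel_intensity_scale = resonance_scale(modality, m)))
    y <- y + w * cs$intensity
  }
  y
}

#' Simulate one bulk spectrum
#'
#' @param composition \code{composition} object (see [composition()] and
#'   [composition_trajectory()])
#' @param modality instrument modality
#' @param band_table band table (default [default_band_table()])
#' @param baseline \code{baseline_params} or NULL for none
#' @param pathlength positive multiplicative path-length factor
#' @param noise_sd standard deviation of the additive Gaussian noise
#' @param seed optional integer; when given the draw is reproducible
#' @param axis optional custom axis (default: the modality's grid)
#' @return spectrum object; \code{meta} carries the composition and draw
#'   parameters
#' @export
simulate_bulk_spectrum <- function(composition, modality,
                                   band_table = default_band_table(),
                                   baseline = NULL, pathlength = 1,
                                   noise_sd = 0, seed = NULL, axis = NULL) {
  stopifnot(inherits(composition, "composition"), pathlength > 0,
            noise_sd >= 0)
  if (!any(composition$weight > 0)) stop("empty composition")
  modality <- match_modality(modality)
  if (is.null(axis)) axis <- default_axis(modality)
  if (!is.null(seed)) set.seed(seed)
  y <- pathlength * clean_mixture(composition, axis, modality, band_table)
  y <- y + draw_baseline(axis, baseline)
  if (noise_sd > 0) y <- y + stats::rnorm(length(axis), 0, noise_sd)
  spectrum(axis, y, modality = modality,
           meta = list(composition = composition, pathlength = pathlength,
                       noise_sd = noise_sd, seed = seed))
}

#' Simulate the full design for all bulk modalities
#'
#' One biomass composition is drawn per (medium, timepoint) cell and shared
#' by the technical replicates of both bulk modalities; replicates differ
#' only in their path-length factor, baseline draw and noise. Noise is set
#' from the target signal-to-noise ratio at the strongest band of the clean
#' design; a single run seed deterministically derives all substreams.
#'
#' @param design \code{design} object ([default_design()])
#' @param seed integer run seed
#' @param band_table band table
#' @param params trajectory parameters
#' @param snr signal-to-noise ratio at the strongest band (Inf = noiseless)
#' @param pathlength_sdlog log-normal sigma of the replicate path-length
#'   factor (0 = fixed path length)
#' @param baseline_rel baseline magnitude relative to the strongest band
#'   (0 = no baseline)
#' @return named list (one entry per modality) of \code{spectral_dataset}
#'   objects; each dataset's \code{truth} holds the generating weights, 13C
#'   fractions and path-length factors
#' @export
simulate_design_dataset <- function(design = default_design(), seed = 1,
                                    band_table = default_band_table(),
                                    params = trajectory_params(),
                                    snr = 200, pathlength_sdlog = 0.15,
                                    baseline_rel = 0.3) {
  stopifnot(inherits(design, "design"))
  set.seed(seed)
  cells <- expand.grid(medium = design$media,
                       timepoint_h = design$timepoints,
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$medium, design$media), cells$timepoint_h), ]
  comps <- lapply(seq_len(nrow(cells)), function(i) {
    composition_trajectory(cells$medium[i], cells$timepoint_h[i], params)
  })
  rep_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L,
               nrow(cells) * design$replicates * length(design$modalities)),
    nrow = nrow(cells))

  out <- list()
  col <- 0L
  for (mod in design$modalities) {
    axis <- default_axis(mod)
    clean <- t(vapply(comps, clean_mixture, numeric(length(axis)),
                      axis = axis, modality = mod, band_table = band_table))
    smax <- max(abs(clean))
    noise_sd <- if (is.finite(snr)) smax / snr else 0
    bp <- baseline_params(mod, scale = baseline_rel * smax)
    n <- nrow(cells) * design$replicates
    X <- matrix(0, n, length(axis))
    meta <- data.frame(sample_id = character(n), medium = character(n),
                       timepoint_h = numeric(n), replicate = integer(n),
                       modality = mod, seed = seed,
                       stringsAsFactors = FALSE)
    truth <- NULL
    r <- 0L
    for (i in seq_len(nrow(cells))) {
      for (k in seq_len(design$replicates)) {
        r <- r + 1L
        set.seed(rep_seeds[i, col + k])
        pl <- if (pathlength_sdlog > 0) stats::rlnorm(1, 0, pathlength_sdlog) else 1
        y <- pl * clean[i, ] + draw_baseline(axis, bp)
        if (noise_sd > 0) y <- y + stats::rnorm(length(axis), 0, noise_sd)
        X[r, ] <- y
        meta$sample_id[r] <- sprintf("%s_t%03d_r%d_%s", cells$medium[i],
                                     cells$timepoint_h[i], k, mod)
        meta$medium[r] <- cells$medium[i]
        meta$timepoint_h[r] <- cells$timepoint_h[i]
        meta$replicate[r] <- k
        tr <- data.frame(t(c(comps[[i]]$weight,
                             stats::setNames(comps[[i]]$f13,
                                             paste0("f13_", names(comps[[i]]$f13))))),
                         pathlength = pl)
        truth <- rbind(truth, tr)
      }
    }
    col <- col + design$replicates
    out[[mod]] <- spectral_dataset(axis, X, meta, modality = mod, truth = truth)
  }
  out
}
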