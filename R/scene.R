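#' Synthetic hyperspectral imaging scenes
#'
#' A scene is a set of boolean region masks on a pixel grid -- branching
#' hyphae, lipid bodies and polyphosphate granules nested inside them --
#' with one biomass composition per region. Background pixels carry no
#' biomass. The default grid is 128 x 128 pixels at 2.7 um per pixel,
#' matching a focal-plane-array detector (16,384 spectra per image).
#'
#' @param shape integer vector c(rows, cols), default c(128, 128)
#' @param n_hyphae number of hyphal filaments to draw
#' @param n_lipid_bodies number of lipid-body disks (placed inside hyphae)
#' @param n_granules number of polyphosphate granules (inside hyphae,
#'   outside lipid bodies)
#' @param hypha_radius filament half-width in pixels
#' @param lipid_radius,granule_radius disk radii ranges (pixels)
#' @param medium medium name used to derive region compositions
#' @param t_hours fermentation time used to derive region compositions
#' @param lipid_enrich multiplier on the TAG weight inside lipid bodies
#' @param polyp_enrich multiplier on the polyphosphate weight inside
#'   granules
#' @param pixel_size pixel size in micrometres
#' @param seed integer seed (scene geometry and compositions are
#'   reproducible given the seed)
#' @param params trajectory parameters for the region compositions
#' @return object of class \code{scene}: masks (\code{hyphae_mask},
#'   \code{lipid_body_mask}, \code{polyp_granule_mask}), per-region
#'   compositions, shape and pixel size
#' @export
make_scene <- function(shape = c(128, 128), n_hyphae = 6,
                       n_lipid_bodies = 12, n_granules = 10,
                       hypha_radius = 3, lipid_radius = c(2, 5),
                       granule_radius = c(1, 2),
                       medium = "iGlu1:Gly7", t_hours = 120,
                       lipid_enrich = 6, polyp_enrich = 6,
                       pixel_size = 2.7, seed = 1,
                       params = trajectory_params()) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  hyphae <- matrix(FALSE, nr, nc)
  for (h in seq_len(n_hyphae)) {
    r <- stats::runif(1, 0.1 * nr, 0.9 * nr)
    c0 <- stats::runif(1, 0.1 * nc, 0.9 * nc)
    ang <- stats::runif(1, 0, 2 * pi)
    for (step in seq_len(round(1.2 * max(nr, nc)))) {
      ang <- ang + stats::rnorm(1, 0, 0.15)
      r <- r + sin(ang); c0 <- c0 + cos(ang)
      if (r < 1 || r > nr || c0 < 1 || c0 > nc) break
      hyphae <- fill_disk(hyphae, r, c0, hypha_radius)
    }
  }
  inside <- which(hyphae, arr.ind = TRUE)
  lipid <- matrix(FALSE, nr, nc)
  gran <- matrix(FALSE, nr, nc)
  if (nrow(inside) > 0) {
    for (i in seq_len(n_lipid_bodies)) {
      ctr <- inside[sample.int(nrow(inside), 1), ]
      lipid <- fill_disk(lipid, ctr[1], ctr[2],
                         stats::runif(1, lipid_radius[1], lipid_radius[2]))
    }
    lipid <- lipid & hyphae  # bodies lie within hyphae
    free <- which(hyphae & !lipid, arr.ind = TRUE)
    if (nrow(free) > 0) {
      for (i in seq_len(n_granules)) {
        ctr <- free[sample.int(nrow(free), 1), ]
        gran <- fill_disk(gran, ctr[1], ctr[2],
                          stats::runif(1, granule_radius[1], granule_radius[2]))
      }
      gran <- gran & hyphae & !lipid
    }
  }
  base <- composition_trajectory(medium, t_hours, params)
  lw <- base$weight; lw["TAG"] <- max(lw["TAG"], 0.2) * lipid_enrich
  pw <- base$weight; pw["polyphosphate"] <- max(pw["polyphosphate"], 0.2) * polyp_enrich
  structure(list(
    shape = as.integer(shape), pixel_size = pixel_size,
    hyphae_mask = hyphae, lipid_body_mask = lipid, polyp_granule_mask = gran,
    compositions = list(
      hyphae = base,
      lipid_body = composition(lw, base$f13),
      polyp_granule = composition(pw, base$f13)
    ),
    medium = medium, t_hours = t_hours, seed = seed
  ), class = "scene")
}

fill_disk <- function(mask, r0, c0, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  rs <- max(1, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cs <- max(1, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  for (r in rs) for (cc in cs) {
    if ((r - r0)^2 + (cc - c0)^2 <= radius^2) mask[r, cc] <- TRUE
  }
  mask
}

#' Validate scene mask nesting
#' @param scene scene object
#' @return invisible TRUE or an error
#' @export
validate_scene <- function(scene) {
  with(scene, {
    stopifnot(all(dim(hyphae_mask) == shape),
              all(dim(lipid_body_mask) == shape),
              all(dim(polyp_granule_mask) == shape))
    if (any(lipid_body_mask & !hyphae_mask)) {
      stop("lipid bodies must lie within hyphae")
    }
    if (any(polyp_granule_mask & !hyphae_mask)) {
      stop("granules must lie within hyphae")
    }
  })
  invisible(TRUE)
}

#' Simulate a hyperspectral image from a scene
#'
#' Per-pixel spectra are the region composition's mixture spectrum times a
#' smooth spatial path-length field, plus a per-image baseline and pixel
#' noise. Background pixels contain baseline and noise only. The generating
#' component-weight maps are stored as ground truth.
#'
#' @param scene scene from [make_scene()]
#' @param modality imaging modality (\code{"FTIRMicro"} or
#'   \code{"RamanMicro"})
#' @param band_table band table
#' @param noise_sd additive noise sd; \code{NULL} sets it from \code{snr}
#' @param snr signal-to-noise ratio at the strongest band when
#'   \code{noise_sd} is NULL
#' @param baseline_rel baseline magnitude relative to the strongest band
#' @param pathlength_amp amplitude of the smooth spatial path-length field
#'   (0 = uniform)
#' @param seed integer seed
#' @param axis optional custom axis (e.g. a truncated grid)
#' @return object of class \code{hyper_image}: \code{cube} (rows x cols x
#'   wavenumbers), \code{wavenumber}, \code{valid_mask}, \code{pixel_size},
#'   \code{truth} (region masks and per-metabolite weight maps)
#' @export
simulate_hyperspectral_image <- function(scene, modality = "FTIRMicro",
                                         band_table = default_band_table(),
                                         noise_sd = NULL, snr = 200,
                                         baseline_rel = 0.1,
                                         pathlength_amp = 0.2, seed = 1,
                                         axis = NULL) {
  validate_scene(scene)
  modality <- match_modality(modality)
  if (is.null(axis)) axis <- default_axis(modality)
  set.seed(seed)
  nr <- scene$shape[1]; nc <- scene$shape[2]; nw <- length(axis)

  ## region spectra (3 regions; lipid bodies and granules override hyphae)
  regs <- scene$compositions
  spec <- lapply(regs, function(cmp) clean_mixture(cmp, axis, modality, band_table))
  region_id <- matrix(0L, nr, nc)           # 0 background
  region_id[scene$hyphae_mask] <- 1L
  region_id[scene$lipid_body_mask] <- 2L
  region_id[scene$polyp_granule_mask] <- 3L
  smax <- max(abs(unlist(spec)), 0)
  if (is.null(noise_sd)) noise_sd <- if (is.finite(snr) && smax > 0) smax / snr else 0

  ## smooth multiplicative path-length field
  pl <- matrix(1, nr, nc)
  if (pathlength_amp > 0) {
    ph <- stats::runif(4, 0, 2 * pi)
    rr <- matrix(seq_len(nr) / nr, nr, nc)
    cc <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
    pl <- 1 + pathlength_amp * (sin(2 * pi * rr + ph[1]) * cos(2 * pi * cc + ph[2]) +
                                0.5 * sin(4 * pi * cc + ph[3]) * cos(2 * pi * rr + ph[4])) / 1.5
  }
  bp <- baseline_params(modality, scale = baseline_rel * smax)
  base <- draw_baseline(axis, bp)

  cube_mat <- matrix(rep(base, each = nr * nc), nr * nc, nw)
  for (k in 1:3) {
    px <- which(region_id == k)
    if (length(px)) {
      cube_mat[px, ] <- cube_mat[px, , drop = FALSE] +
        outer(pl[px], spec[[k]])
    }
  }
  if (noise_sd > 0) {
    cube_mat <- cube_mat + matrix(stats::rnorm(length(cube_mat), 0, noise_sd),
                                  nrow(cube_mat))
  }

  ## ground-truth component-weight maps
  wts <- sapply(regs, function(cmp) cmp$weight)  # metabolites x regions
  truth_maps <- lapply(rownames(wts), function(m) {
    mp <- matrix(0, nr, nc)
    for (k in 1:3) mp[region_id == k] <- wts[m, k]
    mp
  })
  names(truth_maps) <- rownames(wts)

  structure(list(
    cube = array(cube_mat, c(nr, nc, nw)), wavenumber = axis,
    valid_mask = matrix(TRUE, nr, nc), pixel_size = scene$pixel_size,
    modality = modality,
    truth = list(region_id = region_id, weight_maps = truth_maps,
                 pathlength = pl, scene = scene, noise_sd = noise_sd)
  ), class = "hyper_image")
}

#' Noiseless spectrum of a scene region
#'
#' The clean mixture spectrum of one region's composition -- the ground
#' truth behind a basis-analysis component.
#'
#' @param scene scene object
#' @param region \code{"hyphae"}, \code{"lipid_body"} or
#'   \code{"polyp_granule"}
#' @param axis wavenumber axis
#' @param modality instrument modality (default \code{"FTIRMicro"})
#' @param band_table band table
#' @return numeric intensity vector on \code{axis}
#' @export
clean_region_spectrum <- function(scene, region, axis, modality = "FTIRMicro",
                                  band_table = default_band_table()) {
  region <- match.arg(region, c("hyphae", "lipid_body", "polyp_granule"))
  clean_mixture(scene$compositions[[region]], axis, modality, band_table)
}

#' @export
print.hyper_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<hyper_image> %d x %d pixels x %d wavenumbers (%s), %.1f um/px\n",
              d[1], d[2], d[3], x$modality, x$pixel_size))
  invisible(x)
}

#' Matrix view of a hyperspectral cube (pixels x wavenumbers)
#' @param image hyper_image
#' @param valid_only keep only pixels flagged valid
#' @return matrix with attribute \code{pixel_index} (linear indices)
#' @export
cube_matrix <- function(image, valid_only = FALSE) {
  d <- dim(image$cube)
  m <- matrix(image$cube, d[1] * d[2], d[3])
  idx <- seq_len(d[1] * d[2])
  if (valid_only) {
    keep <- as.vector(image$valid_mask)
    m <- m[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  attr(m, "pixel_index") <- idx
  m
}
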