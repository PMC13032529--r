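#' Hyperspectral image quality control, binning, unmixing and maps
#'
#' @name imaging
NULL

#' Flag empty / nearly empty pixels
#'
#' A pixel is kept when its integrated absolute signal over a
#' signal-to-noise region exceeds a background-derived threshold. The
#' background level is estimated per wavenumber channel from the
#' lowest-decile pixels (ranked by integrated signal): the threshold is
#' the integral of (channel median + k_sigma * channel MAD) over the
#' region. Pixels whose integrated signal is below the threshold -- or
#' identically zero -- are marked invalid.
#'
#' @param image hyper_image
#' @param snr_region c(lo, hi) wavenumber region used for the signal
#'   integral (default 1700-1500, amide I / ester C=O shoulder)
#' @param k_sigma threshold multiplier (default 3)
#' @param bg_quantile fraction of pixels treated as the background
#'   reference (default 0.1)
#' @return logical valid-pixel matrix (also stored back in the returned
#'   image's \code{valid_mask} when assigned); use
#'   \code{image$valid_mask <- remove_empty_pixels(image)}
#' @export
remove_empty_pixels <- function(image, snr_region = c(1500, 1700),
                                k_sigma = 3, bg_quantile = 0.1) {
  stopifnot(inherits(image, "hyper_image"))
  snr_region <- sort(snr_region)
  keep <- image$wavenumber >= snr_region[1] & image$wavenumber <= snr_region[2]
  if (!any(keep)) stop("snr_region lies outside the image axis")
  M <- cube_matrix(image)[, keep, drop = FALSE]
  s <- rowSums(abs(M))
  bg <- M[s <= stats::quantile(s, bg_quantile), , drop = FALSE]
  if (nrow(bg) < 2) bg <- M
  med <- apply(abs(bg), 2, stats::median)
  madc <- apply(abs(bg), 2, stats::mad)
  thr <- sum(med + k_sigma * madc)
  matrix(s >= thr & s > 0, nrow(image$cube), ncol(image$cube))
}

#' Block grid for pixel binning
#'
#' Full blocks tile from the top-left corner; the remainder strip along
#' each axis forms the edge blocks (for a 128-pixel axis with block 10:
#' twelve 10-wide blocks plus one 8-wide edge block, i.e. 10x10, 10x8,
#' 8x10 and 8x8 blocks over the image).
#'
#' @param shape image shape c(rows, cols)
#' @param block nominal block size in pixels (default 10)
#' @param min_pixels minimum valid pixels for a block to be retained
#'   (default 5)
#' @return data frame with one row per block: row0/row1, col0/col1
#'   (inclusive 1-based ranges)
#' @export
block_grid <- function(shape, block = 10, min_pixels = 5) {
  splits <- function(n) {
    nf <- n %/% block
    starts <- seq_len(nf) * block - block + 1
    ends <- starts + block - 1
    if (nf * block < n) { starts <- c(starts, nf * block + 1); ends <- c(ends, n) }
    data.frame(a = starts, b = ends)
  }
  rs <- splits(shape[1]); cs <- splits(shape[2])
  g <- expand.grid(ri = seq_len(nrow(rs)), ci = seq_len(nrow(cs)))
  out <- data.frame(row0 = rs$a[g$ri], row1 = rs$b[g$ri],
                    col0 = cs$a[g$ci], col1 = cs$b[g$ci])
  attr(out, "block") <- block
  attr(out, "min_pixels") <- min_pixels
  out
}

#' Bin a hyperspectral image into block-mean spectra
#'
#' Each block's spectrum is the mean over its valid pixels; blocks with
#' fewer than \code{min_pixels} valid pixels are dropped. Block provenance
#' (pixel ranges and member counts) is kept in the dataset metadata.
#'
#' @param image hyper_image with its \code{valid_mask} set (see
#'   [remove_empty_pixels()])
#' @param block nominal block size (default 10)
#' @param min_pixels retention threshold (default 5)
#' @return spectral_dataset of block-mean spectra
#' @export
bin_image <- function(image, block = 10, min_pixels = 5) {
  stopifnot(inherits(image, "hyper_image"))
  d <- dim(image$cube)
  grid <- block_grid(d[1:2], block, min_pixels)
  M <- cube_matrix(image)
  vm <- image$valid_mask
  rows <- list(); X <- list()
  for (i in seq_len(nrow(grid))) {
    rr <- grid$row0[i]:grid$row1[i]; cc <- grid$col0[i]:grid$col1[i]
    pix <- as.vector(outer(rr, (cc - 1) * d[1], "+"))
    pix <- pix[vm[pix]]
    if (length(pix) < min_pixels) next
    X[[length(X) + 1]] <- colMeans(M[pix, , drop = FALSE])
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = sprintf("b_r%03d_c%03d", grid$row0[i], grid$col0[i]),
      block_row0 = grid$row0[i], block_row1 = grid$row1[i],
      block_col0 = grid$col0[i], block_col1 = grid$col1[i],
      n_pixels = length(pix))
  }
  if (!length(X)) stop("no blocks survive the minimum-pixel threshold")
  spectral_dataset(image$wavenumber, do.call(rbind, X), do.call(rbind, rows),
                   modality = image$modality, derivative_order = 0L)
}

#' Build a basis set of component spectra
#'
#' @param spectra K x wavenumbers matrix, or list of spectrum objects
#' @param names component names
#' @param wavenumber axis (taken from the spectra when omitted)
#' @return object of class \code{basis_set}
#' @export
basis_set <- function(spectra, names = NULL, wavenumber = NULL) {
  if (is.list(spectra) && inherits(spectra[[1]], "spectrum")) {
    wavenumber <- spectra[[1]]$wavenumber
    spectra <- do.call(rbind, lapply(spectra, function(s) s$intensity))
  }
  spectra <- as.matrix(spectra)
  if (is.null(names)) names <- paste0("component", seq_len(nrow(spectra)))
  if (anyDuplicated(spectra)) stop("basis spectra must be non-identical")
  structure(list(spectra = spectra, names = names, wavenumber = wavenumber),
            class = "basis_set")
}

#' Per-pixel least-squares basis analysis (unmixing)
#'
#' Each pixel spectrum is fitted as a linear combination of the basis
#' spectra by least squares; with \code{nonneg = TRUE} (the default,
#' physically motivated: concentrations cannot be negative) the fitting
#' factors are constrained to be nonnegative (NNLS). The fitting factors
#' of component k across the image form its component map.
#'
#' @param image hyper_image
#' @param basis basis_set on the image axis (K <= number of wavenumbers)
#' @param nonneg constrain factors to be >= 0 (default TRUE)
#' @param offset include a constant-offset column in the fit (off by
#'   default)
#' @param valid_only fit only valid pixels (invalid pixels get NA factors)
#' @return object of class \code{basis_fit_result}: \code{factors} (rows x
#'   cols x K), \code{residual_norm} (rows x cols), \code{basis}
#' @export
basis_fit <- function(image, basis, nonneg = TRUE, offset = FALSE,
                      valid_only = FALSE) {
  stopifnot(inherits(image, "hyper_image"), inherits(basis, "basis_set"))
  B <- t(basis$spectra)                       # wavenumbers x K
  if (ncol(B) > nrow(B)) stop("more basis components than wavenumbers")
  if (nrow(B) != length(image$wavenumber)) {
    stop("basis spectra must lie on the image axis")
  }
  if (offset) B <- cbind(B, 1)
  if (kappa(B) > 1e8) warning("basis is nearly degenerate (condition number > 1e8)")
  S <- cube_matrix(image)
  use <- if (valid_only) as.vector(image$valid_mask) else rep(TRUE, nrow(S))
  Fm <- nnls_batch(B, t(S[use, , drop = FALSE]), nonneg = nonneg)
  K <- ncol(B)
  d <- dim(image$cube)
  factors <- matrix(NA_real_, d[1] * d[2], K)
  factors[use, ] <- t(Fm)
  resid <- rep(NA_real_, d[1] * d[2])
  resid[use] <- sqrt(colSums((t(S[use, , drop = FALSE]) - B %*% Fm)^2))
  structure(list(
    factors = array(factors, c(d[1], d[2], K)),
    residual_norm = matrix(resid, d[1], d[2]),
    basis = basis, nonneg = nonneg, offset = offset
  ), class = "basis_fit_result")
}

# Solve min ||y - B f|| for many right-hand sides; NNLS via a vectorised
# fast path (accept unconstrained solutions that are already feasible)
# with pracma::lsqnonneg for the remainder.
nnls_batch <- function(B, Y, nonneg = TRUE) {
  Fu <- qr.solve(B, Y)
  if (!nonneg) return(Fu)
  Fu <- as.matrix(Fu)
  bad <- which(apply(Fu, 2, function(f) any(f < -1e-10)))
  Fu[Fu < 0] <- 0
  for (j in bad) Fu[, j] <- pracma::lsqnonneg(B, Y[, j])$x
  Fu
}

#' Derive basis spectra from an image
#'
#' \code{method = "kmeans"}: k-means centroids of the area-normalised
#' valid-pixel spectra (deterministic given the seed).
#' \code{method = "manual"}: the spectra at caller-supplied pixel
#' coordinates become the basis.
#'
#' @param image hyper_image
#' @param k number of components (1-4 typical)
#' @param method \code{"kmeans"} or \code{"manual"}
#' @param coords for \code{"manual"}: matrix/data.frame of (row, col) pixel
#'   coordinates, one per component
#' @param seed integer seed for k-means
#' @return basis_set
#' @export
derive_basis <- function(image, k, method = c("kmeans", "manual"),
                         coords = NULL, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(image, "hyper_image"), k >= 1)
  if (method == "manual") {
    coords <- as.matrix(coords)
    sp <- t(apply(coords, 1, function(rc) image$cube[rc[1], rc[2], ]))
    return(basis_set(sp, names = paste0("manual", seq_len(nrow(coords))),
                     wavenumber = image$wavenumber))
  }
  M <- cube_matrix(image, valid_only = TRUE)
  if (nrow(M) < k) stop("fewer valid pixels than components")
  a <- apply(M, 1, function(y) trapz_area(image$wavenumber, abs(y)))
  a[a <= 0] <- 1
  Mn <- M / a
  if (nrow(unique(Mn)) < k) stop("k exceeds the number of distinct spectra")
  set.seed(seed)
  km <- stats::kmeans(Mn, centers = k, nstart = 5, iter.max = 50)
  basis_set(km$centers, names = paste0("kmeans", seq_len(k)),
            wavenumber = image$wavenumber)
}

#' Single-wavenumber absorbance map
#'
#' Per-pixel maximum intensity within a small window around a target
#' wavenumber -- e.g. the TAG ester C=O band at 1745 cm^-1 maps the lipid
#' bodies.
#'
#' @param image hyper_image
#' @param nu target wavenumber (default 1745)
#' @param halfwidth window half-width (cm^-1, default 4)
#' @return rows x cols numeric matrix
#' @export
absorbance_map <- function(image, nu = 1745, halfwidth = 4) {
  keep <- image$wavenumber >= nu - halfwidth & image$wavenumber <= nu + halfwidth
  if (!any(keep)) stop("window lies outside the image axis")
  apply(image$cube[, , keep, drop = FALSE], c(1, 2), max)
}
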