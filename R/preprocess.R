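#' Spectral preprocessing primitives
#'
#' Each primitive accepts either a \code{spectrum} or a
#' \code{spectral_dataset} and returns the same class. All operations are
#' deterministic; recipes chain them in a fixed printed order (see
#' [packaged_recipes()]).
#'
#' @name preprocess-primitives
NULL

## ---------------------------------------------------------------- truncate

#' Truncate a spectrum to one or more wavenumber regions
#'
#' Keeps grid points with lo <= nu <= hi in any region (boundaries
#' inclusive); regions are concatenated in ascending wavenumber order and
#' the original grid values are preserved.
#'
#' @param x spectrum or spectral_dataset
#' @param regions list of c(lo, hi) pairs (given in either order)
#' @return truncated object
#' @export
truncate_regions <- function(x, regions) {
  dispatch_spectral(x, function(ds) {
    if (is.numeric(regions) && length(regions) == 2) regions <- list(regions)
    regs <- lapply(regions, sort)
    regs <- regs[order(vapply(regs, `[`, numeric(1), 1))]
    for (i in seq_along(regs)[-1]) {
      if (regs[[i]][1] <= regs[[i - 1]][2]) stop("regions overlap")
    }
    keep <- rep(FALSE, length(ds$wavenumber))
    for (r in regs) keep <- keep | (ds$wavenumber >= r[1] & ds$wavenumber <= r[2])
    if (!any(keep)) stop("truncation produced an empty result")
    spectral_dataset(ds$wavenumber[keep], ds$intensity[, keep, drop = FALSE],
                     ds$meta, ds$modality, ds$derivative_order, ds$truth)
  })
}

## ------------------------------------------------------- Savitzky-Golay

# Coefficient row evaluating the d-th derivative of the fitted polynomial
# at in-window position t (0-based), for window length w and degree p.
sg_coef_row <- function(w, p, d, t) {
  x <- (0:(w - 1)) - t
  A <- outer(x, 0:p, "^")
  H <- solve(crossprod(A), t(A))      # (p+1) x w
  factorial(d) * H[d + 1, ]
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Local least-squares polynomial filtering on the uniform grid.
#' Differentiation is with respect to the point index; multiply by
#' \code{(1/spacing)^deriv} for per-cm^-1 units (only relative intensities
#' are used downstream, so the index convention -- the one used by vendor
#' chemometrics software -- is the default). Edge points are produced by
#' evaluating the polynomial fit of the first (or last) full window at the
#' edge positions, so the output has the input length.
#'
#' @param x spectrum or spectral_dataset (uniform axis required)
#' @param window odd window length in points
#' @param polyorder polynomial degree (< window)
#' @param deriv derivative order (<= polyorder)
#' @return filtered object with updated \code{derivative_order}
#' @export
savgol <- function(x, window = 15, polyorder = 2, deriv = 2) {
  stopifnot(window %% 2 == 1, polyorder < window, deriv <= polyorder)
  dispatch_spectral(x, function(ds) {
    if (!is_uniform_axis(ds$wavenumber)) stop("savgol needs a uniform axis")
    n <- length(ds$wavenumber)
    if (n < window) stop("spectrum shorter than the filter window")
    h <- (window - 1L) %/% 2L
    Y <- ds$intensity
    out <- matrix(0, nrow(Y), n)
    cc <- sg_coef_row(window, polyorder, deriv, h)
    for (k in seq_len(window)) {
      out[, (h + 1):(n - h)] <- out[, (h + 1):(n - h), drop = FALSE] +
        cc[k] * Y[, k:(n - window + k), drop = FALSE]
    }
    C_head <- t(vapply(0:(h - 1), function(t) sg_coef_row(window, polyorder, deriv, t),
                       numeric(window)))
    C_tail <- t(vapply((window - h):(window - 1),
                       function(t) sg_coef_row(window, polyorder, deriv, t),
                       numeric(window)))
    out[, 1:h] <- Y[, 1:window, drop = FALSE] %*% t(C_head)
    out[, (n - h + 1):n] <- Y[, (n - window + 1):n, drop = FALSE] %*% t(C_tail)
    spectral_dataset(ds$wavenumber, out, ds$meta, ds$modality,
                     derivative_order = as.integer(deriv), truth = ds$truth)
  })
}

## ------------------------------------------------------------- baselines

lower_hull_indices <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Rubberband (lower convex hull) baseline correction
#'
#' The baseline is the lower convex hull of the (wavenumber, intensity)
#' points, evaluated by linear interpolation between hull vertices; the
#' corrected spectrum touches zero at the hull vertices and is nonnegative
#' up to numerical round-off.
#'
#' @param x spectrum or spectral_dataset
#' @param return_baseline also return the baseline (spectrum input only)
#' @return corrected object; with \code{return_baseline = TRUE} a list
#'   \code{list(corrected, baseline)}
#' @export
rubberband_baseline <- function(x, return_baseline = FALSE) {
  correct_one <- function(nu, y) {
    idx <- lower_hull_indices(nu, y)
    stats::approx(nu[idx], y[idx], xout = nu)$y
  }
  if (inherits(x, "spectrum") && return_baseline) {
    b <- correct_one(x$wavenumber, x$intensity)
    return(list(
      corrected = spectrum(x$wavenumber, x$intensity - b, x$modality,
                           x$derivative_order, x$meta),
      baseline = spectrum(x$wavenumber, b, x$modality, x$derivative_order,
                          x$meta)))
  }
  dispatch_spectral(x, function(ds) {
    if (length(ds$wavenumber) < 3) stop("rubberband needs >= 3 points")
    Y <- ds$intensity
    for (i in seq_len(nrow(Y))) {
      Y[i, ] <- Y[i, ] - correct_one(ds$wavenumber, Y[i, ])
    }
    spectral_dataset(ds$wavenumber, Y, ds$meta, ds$modality,
                     ds$derivative_order, ds$truth)
  })
}

#' Linear (two-point) baseline correction
#'
#' Subtracts the straight line through the first and last points of the
#' (already truncated) spectrum; both endpoints map to exactly zero.
#'
#' @param x spectrum or spectral_dataset
#' @return corrected object
#' @export
linear_baseline <- function(x) {
  dispatch_spectral(x, function(ds) {
    nu <- ds$wavenumber
    n <- length(nu)
    if (n < 2) stop("linear baseline needs >= 2 points")
    w <- (nu - nu[1]) / (nu[n] - nu[1])
    Y <- ds$intensity
    line <- outer(Y[, 1], 1 - w) + outer(Y[, n], w)
    spectral_dataset(nu, Y - line, ds$meta, ds$modality,
                     ds$derivative_order, ds$truth)
  })
}

#' Iterative polynomial baseline correction
#'
#' Fits a least-squares polynomial of the given degree, then iteratively
#' re-fits after excluding points lying above the current fit (so peaks do
#' not drag the baseline up), until the retained point set stabilises or
#' \code{max_iter} passes are reached; the final polynomial is subtracted.
#'
#' @param x spectrum or spectral_dataset
#' @param degree polynomial degree >= 0
#' @param max_iter maximum re-fitting passes
#' @return corrected object
#' @export
polynomial_baseline <- function(x, degree = 3, max_iter = 20) {
  stopifnot(degree >= 0)
  dispatch_spectral(x, function(ds) {
    nu <- ds$wavenumber
    if (degree >= length(nu)) stop("degree must be below the point count")
    xs <- 2 * (nu - min(nu)) / (max(nu) - min(nu)) - 1
    A <- outer(xs, 0:degree, "^")
    Y <- ds$intensity
    for (i in seq_len(nrow(Y))) {
      y <- Y[i, ]
      keep <- rep(TRUE, length(y))
      fit <- NULL
      for (it in seq_len(max_iter)) {
        co <- qr.solve(A[keep, , drop = FALSE], y[keep])
        fit <- drop(A %*% co)
        newkeep <- y <= fit
        if (sum(newkeep) < degree + 2) break
        if (identical(newkeep, keep)) break
        keep <- newkeep
      }
      Y[i, ] <- y - fit
    }
    spectral_dataset(nu, Y, ds$meta, ds$modality, ds$derivative_order,
                     ds$truth)
  })
}

## ------------------------------------------------------------ MSC / EMSC

#' Multiplicative signal correction
#'
#' Per spectrum, fits y ~ a + b * ref by least squares and returns
#' (y - a) / b; with \code{reference = "mean"} the reference is the dataset
#' mean spectrum.
#'
#' @param x spectral_dataset (or spectrum, together with an explicit
#'   reference)
#' @param reference \code{"mean"} or a spectrum / numeric vector on the same
#'   axis
#' @return corrected object with attribute \code{msc_coefficients}
#'   (data frame with columns a, b)
#' @export
msc <- function(x, reference = "mean") {
  dispatch_spectral(x, function(ds) {
    ref <- resolve_reference(ds, reference)
    n <- length(ref)
    a <- b <- numeric(nrow(ds$intensity))
    Y <- ds$intensity
    sx <- sum(ref); sxx <- sum(ref^2)
    den <- n * sxx - sx^2
    for (i in seq_len(nrow(Y))) {
      y <- Y[i, ]
      bi <- (n * sum(ref * y) - sx * sum(y)) / den
      ai <- (sum(y) - bi * sx) / n
      if (abs(bi) < 1e-12) stop("MSC slope is numerically zero for spectrum ", i)
      Y[i, ] <- (y - ai) / bi
      a[i] <- ai; b[i] <- bi
    }
    out <- spectral_dataset(ds$wavenumber, Y, ds$meta, ds$modality,
                            ds$derivative_order, ds$truth)
    attr(out, "msc_coefficients") <- data.frame(a = a, b = b)
    out
  })
}

#' Extended multiplicative signal correction
#'
#' Per spectrum, fits y ~ b * ref + sum_k c_k P_k(nu~) where nu~ is the
#' axis mapped affinely to [-1, 1] and P_k are monomials up to
#' \code{poly_degree}; the polynomial part is subtracted and the result
#' divided by b.
#'
#' @param x spectral_dataset or spectrum
#' @param reference \code{"mean"} or a spectrum / numeric vector
#' @param poly_degree polynomial degree, 1-3 (2 for the infrared
#'   microspectroscopy variant, 3 for the FT-Raman PLSR recipe)
#' @return corrected object with attribute \code{emsc_coefficients}
#'   (data frame: b then c_0..c_d)
#' @export
emsc <- function(x, reference = "mean", poly_degree = 2) {
  stopifnot(poly_degree %in% 1:3)
  dispatch_spectral(x, function(ds) {
    ref <- resolve_reference(ds, reference)
    nu <- ds$wavenumber
    xs <- 2 * (nu - min(nu)) / (max(nu) - min(nu)) - 1
    P <- outer(xs, 0:poly_degree, "^")
    D <- cbind(ref = ref, P)
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) stop("EMSC design matrix is rank deficient")
    co <- qr.coef(qrD, t(ds$intensity))      # (1 + d + 1) x nspec
    b <- co[1, ]
    if (any(abs(b) < 1e-12)) stop("EMSC multiplicative coefficient is numerically zero")
    Y <- ds$intensity - t(P %*% co[-1, , drop = FALSE])
    Y <- Y / b
    out <- spectral_dataset(nu, Y, ds$meta, ds$modality,
                            ds$derivative_order, ds$truth)
    cf <- as.data.frame(t(co))
    names(cf) <- c("b", paste0("c", 0:poly_degree))
    attr(out, "emsc_coefficients") <- cf
    out
  })
}

resolve_reference <- function(ds, reference) {
  if (identical(reference, "mean")) return(colMeans(ds$intensity))
  if (inherits(reference, "spectrum")) reference <- reference$intensity
  reference <- as.numeric(reference)
  if (length(reference) != length(ds$wavenumber)) {
    stop("reference must lie on the dataset axis")
  }
  reference
}

## --------------------------------------------------------- normalisations

trapz_area <- function(nu, y) sum(diff(nu) * (y[-1] + y[-length(y)]) / 2)

#' Normalisations
#'
#' \code{vector_normalize} divides each spectrum by its Euclidean norm;
#' \code{area_normalize} by the trapezoidal area of its absolute intensity;
#' \code{band_area_normalize} by the trapezoidal area over a stated region
#' (default the amide I protein band, 1670-1600 cm^-1, giving
#' protein-relative intensities).
#'
#' @param x spectrum or spectral_dataset
#' @param region c(lo, hi) region for band-area normalisation
#' @param tol divisors smaller than this raise an error
#' @return normalised object
#' @export
vector_normalize <- function(x, tol = 1e-12) {
  dispatch_spectral(x, function(ds) {
    nrm <- sqrt(rowSums(ds$intensity^2))
    if (any(nrm < tol)) stop("zero-norm spectrum cannot be vector normalized")
    spectral_dataset(ds$wavenumber, ds$intensity / nrm, ds$meta, ds$modality,
                     ds$derivative_order, ds$truth)
  })
}

#' @rdname vector_normalize
#' @export
area_normalize <- function(x, tol = 1e-12) {
  dispatch_spectral(x, function(ds) {
    a <- apply(ds$intensity, 1, function(y) trapz_area(ds$wavenumber, abs(y)))
    if (any(a < tol)) stop("zero-area spectrum cannot be area normalized")
    spectral_dataset(ds$wavenumber, ds$intensity / a, ds$meta, ds$modality,
                     ds$derivative_order, ds$truth)
  })
}

#' @rdname vector_normalize
#' @export
band_area_normalize <- function(x, region = c(1600, 1670), tol = 1e-12) {
  dispatch_spectral(x, function(ds) {
    region <- sort(region)
    keep <- ds$wavenumber >= region[1] & ds$wavenumber <= region[2]
    if (sum(keep) < 2) stop("normalisation region lies outside the axis")
    nu <- ds$wavenumber[keep]
    a <- apply(ds$intensity[, keep, drop = FALSE], 1,
               function(y) trapz_area(nu, y))
    if (any(abs(a) < tol)) stop("band area is numerically zero")
    spectral_dataset(ds$wavenumber, ds$intensity / a, ds$meta, ds$modality,
                     ds$derivative_order, ds$truth)
  })
}

## ------------------------------------------------------ cosmic ray removal

#' Cosmic ray (spike) removal
#'
#' Spikes are detected on the second-difference signal
#' s_i = y_i - (y_{i-1} + y_{i+1}) / 2 using a modified z-score
#' (median/MAD); flagged points additionally must exceed a small fraction
#' of the spectrum's intensity range, so smooth band curvature in
#' low-noise spectra is never "removed". Flagged points are replaced by
#' linear interpolation between the nearest unflagged neighbours; at most
#' two passes are made (a second pass catches spikes that masked their
#' neighbours' statistics).
#'
#' @param x spectrum or spectral_dataset
#' @param z_thresh modified z-score threshold (default 8)
#' @param rel_floor minimum spike height as a fraction of the intensity
#'   range (default 0.01)
#' @return despiked object
#' @export
cosmic_ray_remove <- function(x, z_thresh = 8, rel_floor = 0.01) {
  despike_one <- function(nu, y) {
    for (pass in 1:2) {
      n <- length(y)
      s <- numeric(n)
      s[2:(n - 1)] <- y[2:(n - 1)] - (y[1:(n - 2)] + y[3:n]) / 2
      md <- stats::median(s)
      mad0 <- stats::mad(s)
      if (mad0 <= 0) mad0 <- stats::sd(s)
      if (!is.finite(mad0) || mad0 <= 0) return(y)
      flag <- (abs(s - md) / mad0 > z_thresh) &
        (abs(s) > rel_floor * diff(range(y)))
      flag[c(1, n)] <- FALSE
      if (!any(flag)) break
      good <- which(!flag)
      y[flag] <- stats::approx(nu[good], y[good], xout = nu[flag],
                               rule = 2)$y
    }
    y
  }
  dispatch_spectral(x, function(ds) {
    if (length(ds$wavenumber) < 5) stop("cosmic ray removal needs >= 5 points")
    Y <- ds$intensity
    for (i in seq_len(nrow(Y))) Y[i, ] <- despike_one(ds$wavenumber, Y[i, ])
    spectral_dataset(ds$wavenumber, Y, ds$meta, ds$modality,
                     ds$derivative_order, ds$truth)
  })
}
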