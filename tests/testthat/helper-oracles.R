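# Independent brute-force oracles used across the suite. Each is written
# directly from the defining property of the operation it checks and shares
# no code with the package implementation.

# Savitzky-Golay: per-point least-squares polynomial fit and differentiate.
# Interior points use the centred window; edge points the first/last full
# window, evaluated at the edge offset.
sg_oracle <- function(y, window, polyorder, deriv) {
  n <- length(y)
  h <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    start <- min(max(1, i - h), n - window + 1)
    idx <- start:(start + window - 1)
    x <- idx - i                      # local coordinate, evaluation at 0
    fit <- stats::lm.fit(outer(x, 0:polyorder, "^"), y[idx])
    out[i] <- factorial(deriv) * fit$coefficients[deriv + 1]
  }
  out
}

# Lower convex hull by O(n^2) gift wrapping: from each hull vertex the next
# vertex is the point of minimum slope (farthest point on slope ties, so
# collinear interior points are not vertices).
hull_oracle <- function(x, y) {
  n <- length(x)
  verts <- 1L
  i <- 1L
  while (i < n) {
    sl <- (y[(i + 1):n] - y[i]) / (x[(i + 1):n] - x[i])
    cand <- which(sl <= min(sl) + 1e-12)
    nxt <- i + cand[length(cand)]
    verts <- c(verts, nxt)
    i <- nxt
  }
  verts
}

# NNLS by subset enumeration: solve unconstrained LS on every subset of
# columns, keep the best feasible (all coefficients >= 0) solution.
nnls_oracle <- function(B, y) {
  K <- ncol(B)
  best <- list(rss = sum(y^2), x = numeric(K))
  subsets <- unlist(lapply(seq_len(K), function(m)
    utils::combn(K, m, simplify = FALSE)), recursive = FALSE)
  for (ss in subsets) {
    co <- tryCatch(qr.solve(B[, ss, drop = FALSE], y), error = function(e) NULL)
    if (is.null(co) || any(co < -1e-12)) next
    x <- numeric(K); x[ss] <- pmax(co, 0)
    rss <- sum((y - B %*% x)^2)
    if (rss < best$rss - 1e-14) best <- list(rss = rss, x = x)
  }
  best$x
}

# PCA via eigendecomposition of the covariance matrix.
pca_eigen_oracle <- function(X, ncomp) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  scores <- Xc %*% ev$vectors[, seq_len(ncomp), drop = FALSE]
  list(scores = scores,
       loadings = ev$vectors[, seq_len(ncomp), drop = FALSE],
       pct = 100 * ev$values[seq_len(ncomp)] / sum(ev$values))
}

# MSC coefficients from the closed-form 2x2 normal equations.
msc_oracle <- function(y, ref) {
  A <- cbind(1, ref)
  drop(solve(crossprod(A), crossprod(A, y)))
}

# Absolute-difference up to per-column sign flips (for score/loading
# comparisons).
max_abs_diff_signflip <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  max(vapply(seq_len(ncol(A)), function(k) {
    min(max(abs(A[, k] - B[, k])), max(abs(A[, k] + B[, k])))
  }, numeric(1)))
}

# Rank-based AUC (Mann-Whitney) of a score separating truth labels.
auc_score <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small uniform test axis
toy_axis <- function(n = 50, lo = 1000, hi = 1800) seq(lo, hi, length.out = n)
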