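#' Principal component analysis (mean-centred SVD)
#'
#' Columns are mean-centred (no variable scaling -- standard chemometric
#' practice for derivative spectra); components come from the singular
#' value decomposition. Percent variance per component is
#' 100 sigma_k^2 / sum(sigma^2) over all components. The component sign is
#' fixed deterministically: the loading element of largest magnitude is
#' made positive.
#'
#' @param X samples x variables matrix
#' @param ncomp number of components (<= min(samples - 1, variables))
#' @return object of class \code{pca_model}: \code{mean}, \code{loadings}
#'   (variables x ncomp), \code{scores} (samples x ncomp),
#'   \code{pct_variance}
#' @export
pca_fit <- function(X, ncomp = 5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (ncomp > min(n - 1, p)) stop("ncomp exceeds min(samples - 1, variables)")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) == 0) stop("constant matrix has no principal components")
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  S <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  for (k in seq_len(ncomp)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) { V[, k] <- -V[, k]; S[, k] <- -S[, k] }
  }
  structure(list(mean = mu, loadings = V, scores = S,
                 pct_variance = 100 * sv$d[seq_len(ncomp)]^2 / tot,
                 singular_values = sv$d),
            class = "pca_model")
}

#' Project new data onto a fitted PCA space
#'
#' @param model pca_model
#' @param X samples x variables matrix on the same variables
#' @return scores matrix
#' @export
pca_project <- function(model, X) {
  sweep(as.matrix(X), 2, model$mean) %*% model$loadings
}

#' Multiblock consensus PCA
#'
#' Each block (samples x variables; all blocks share the sample order) is
#' column-mean-centred and divided by its block weight -- the Frobenius
#' norm by default, so no block dominates by sheer size or unit. The
#' global (consensus) solution is the PCA of the column-concatenated scaled
#' super-matrix. Block scores are the projections of each scaled block onto
#' its own (renormalised) loading sub-vectors; the per-block explained
#' variance of component k is 100 d_k^2 ||v_bk||^2 / ||X_b||_F^2.
#' Replicates must be averaged beforehand so blocks have sample-to-sample
#' correspondence (see [average_replicates()]).
#'
#' @param blocks named list of matrices with equal row counts
#' @param ncomp number of global components
#' @param scaling \code{"frobenius"} (default) or \code{"none"}
#' @return object of class \code{cpca_model}: \code{global_scores},
#'   \code{block_loadings}, \code{block_scores}, \code{block_weights},
#'   \code{pct_variance_global}, \code{pct_variance_per_block},
#'   \code{block_means}, \code{block_cols}
#' @export
cpca_fit <- function(blocks, ncomp = 5, scaling = c("frobenius", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(is.list(blocks), length(blocks) >= 1)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    names(blocks) <- paste0("block", seq_along(blocks))
  }
  blocks <- lapply(blocks, as.matrix)
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("blocks must share the sample count")
  if (any(vapply(blocks, ncol, integer(1)) == 0)) stop("empty block")
  means <- lapply(blocks, colMeans)
  Xc <- Map(function(X, m) sweep(X, 2, m), blocks, means)
  w <- vapply(Xc, function(X) {
    f <- sqrt(sum(X^2))
    if (scaling == "frobenius" && f > 0) f else 1
  }, numeric(1))
  Xs <- Map(function(X, wi) X / wi, Xc, w)
  super <- do.call(cbind, Xs)
  sv <- svd(super)
  ncomp <- min(ncomp, sum(sv$d > sv$d[1] * 1e-12))
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  S <- sv$u[, seq_len(ncomp), drop = FALSE] %*% diag(sv$d[seq_len(ncomp)], ncomp)
  for (k in seq_len(ncomp)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) { V[, k] <- -V[, k]; S[, k] <- -S[, k] }
  }
  p <- vapply(Xs, ncol, integer(1))
  stops <- cumsum(p); starts <- stops - p + 1
  block_cols <- Map(function(a, b) a:b, starts, stops)
  block_loadings <- lapply(block_cols, function(jj) V[jj, , drop = FALSE])
  block_scores <- Map(function(Xb, Pb) {
    nrm <- sqrt(colSums(Pb^2))
    nrm[nrm == 0] <- 1
    Xb %*% sweep(Pb, 2, nrm, "/")
  }, Xs, block_loadings)
  d2 <- sv$d[seq_len(ncomp)]^2
  pct_block <- do.call(rbind, lapply(seq_along(Xs), function(b) {
    100 * d2 * colSums(block_loadings[[b]]^2) / sum(Xs[[b]]^2)
  }))
  rownames(pct_block) <- names(blocks)
  structure(list(
    global_scores = S, global_loadings = V,
    block_loadings = block_loadings, block_scores = block_scores,
    block_weights = w, block_means = means, block_cols = block_cols,
    pct_variance_global = 100 * sv$d[seq_len(ncomp)]^2 / sum(sv$d^2),
    pct_variance_per_block = pct_block,
    ncomp = ncomp, scaling = scaling
  ), class = "cpca_model")
}

#' Correlation loadings for a fitted PCA or CPCA model
#'
#' For every variable, the Pearson correlation between its centred column
#' and each retained (global) score. In the customary correlation-loading
#' plot the outer circle (radius 1) marks complete correlation and the
#' inner circle marks 50% explained variance, i.e. radius sqrt(0.5).
#' Zero-variance variables get r = 0 and are flagged.
#'
#' @param model pca_model or cpca_model
#' @param X the data used in the fit: a matrix for PCA, a named list of
#'   blocks for CPCA (concatenated internally in block order)
#' @return object of class \code{correlation_loadings}: \code{r}
#'   (variables x components), \code{circle_radii}, \code{flagged}
#' @export
correlation_loadings <- function(model, X) {
  scores <- if (inherits(model, "cpca_model")) model$global_scores else model$scores
  if (is.list(X) && !is.data.frame(X)) X <- do.call(cbind, lapply(X, as.matrix))
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  sdx <- sqrt(colSums(Xc^2))
  Sc <- sweep(scores, 2, colMeans(scores))
  sds <- sqrt(colSums(Sc^2))
  r <- crossprod(Xc, Sc) / outer(sdx, sds)
  flagged <- sdx == 0
  r[flagged, ] <- 0
  r[abs(r) > 1] <- sign(r[abs(r) > 1])  # clamp round-off
  structure(list(r = r, circle_radii = c(inner = sqrt(0.5), outer = 1),
                 flagged = flagged),
            class = "correlation_loadings")
}

#' PLS1 regression (NIPALS) with prediction-residual reliability flags
#'
#' Fits a single-response partial least squares model by NIPALS. The
#' Q residual of a projected spectrum is the squared norm of what remains
#' after deflation through the model's loadings -- the spectral variation
#' the calibration cannot explain. Samples whose Q residual exceeds a
#' configurable quantile of the training residuals (default the 99th
#' percentile) are flagged as outside the calibration space, where
#' predictions are unreliable.
#'
#' @param X samples x variables calibration matrix
#' @param y numeric response
#' @param n_lv number of latent variables
#' @return object of class \code{plsr_model}
#' @export
plsr_fit <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0) stop("zero-variance response")
  x_mean <- colMeans(X); y_mean <- mean(y)
  E <- sweep(X, 2, x_mean); f <- y - y_mean
  rk <- qr(E)$rank
  if (n_lv > rk) stop("n_lv exceeds the rank of the centred X")
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w); tt <- sum(t^2)
    pa <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pa)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pa; Tm[, a] <- t; q[a] <- qa
  }
  R <- W %*% solve(crossprod(P, W))        # projection weights
  b <- drop(R %*% q)
  train_q <- rowSums((sweep(X, 2, x_mean) - Tm %*% t(P))^2)
  structure(list(n_lv = n_lv, weights = W, loadings = P, scores = Tm,
                 q_loadings = q, proj = R, coef = b,
                 x_mean = x_mean, y_mean = y_mean,
                 train_q_residuals = train_q),
            class = "plsr_model")
}

#' @rdname plsr_fit
#' @param model plsr_model
#' @param newX samples x variables matrix to predict
#' @param flag_quantile training-residual quantile above which a sample is
#'   flagged unreliable
#' @return list: \code{y_hat}, \code{q_residual}, \code{flagged} (logical),
#'   \code{threshold}
#' @export
plsr_predict <- function(model, newX, flag_quantile = 0.99) {
  newX <- as.matrix(newX)
  Xc <- sweep(newX, 2, model$x_mean)
  Tn <- Xc %*% model$proj
  y_hat <- model$y_mean + drop(Tn %*% model$q_loadings)
  qres <- rowSums((Xc - Tn %*% t(model$loadings))^2)
  thr <- stats::quantile(model$train_q_residuals, flag_quantile, names = FALSE)
  list(y_hat = y_hat, q_residual = qres, flagged = qres > thr,
       threshold = thr)
}
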