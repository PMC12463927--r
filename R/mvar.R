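#' Construct an MVAR model from known coefficients
#'
#' Mainly for analytic ground-truth work: wraps known coefficient matrices
#' into an [MVARModel-class] so the spectral transfer and DTF of a known
#' process can be computed exactly.
#'
#' @param A list of k x k coefficient matrices (lag 1..p).
#' @param resCov residual covariance (default identity).
#' @param channelLabels optional electrode names.
#' @return an [MVARModel-class].
#' @export
mvarModel <- function(A, resCov = NULL, channelLabels = character()) {
  if (!is.list(A) || !length(A)) stop("A must be a non-empty list of matrices")
  k <- nrow(A[[1]])
  if (is.null(resCov)) resCov <- diag(k)
  new("MVARModel", order = length(A), A = A, resCov = resCov,
      nSamplesUsed = 0L, stable = mvar_is_stable(A),
      channelLabels = channelLabels)
}

mvar_is_stable <- function(A) {
  p <- length(A); k <- nrow(A[[1]])
  comp <- matrix(0, k * p, k * p)
  comp[1:k, ] <- do.call(cbind, A)
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
}

#' Fit an MVAR model by multichannel least squares
#'
#' Ordinary least squares on stacked lagged regressors: every channel's
#' present is regressed on the `p` most recent past values of all channels
#' jointly. The residual covariance is the maximum-likelihood estimate
#' (residual cross-products over the number of regression rows).
#'
#' Common-average-referenced data are exactly rank-deficient (channels sum
#' to zero), so the regressor matrix is singular by construction. The
#' default contract treats this as an error; `onDeficient = "minnorm"`
#' instead returns the SVD-based minimum-norm least-squares solution, the
#' conventional choice for MVAR on average-referenced EEG (and what the
#' connectivity stage uses).
#'
#' @param x channels x samples numeric matrix (one epoch).
#' @param p model order (lags), `p >= 1`.
#' @param onDeficient `"error"` (default) or `"minnorm"`: behaviour on a
#'   rank-deficient regressor matrix.
#' @return an [MVARModel-class] with a stability flag (all eigenvalues of
#'   the companion matrix inside the unit circle).
#' @export
fitMVAR <- function(x, p, onDeficient = c("error", "minnorm")) {
  onDeficient <- match.arg(onDeficient)
  if (!is.matrix(x)) stop("x must be a channels x samples matrix")
  if (!all(is.finite(x))) stop("x contains non-finite values")
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stop("order p must be a positive integer")
  k <- nrow(x); n <- ncol(x)
  if (n <= k * p + p) stop("not enough samples (need > k*p + p = ", k * p + p, ")")
  N <- n - p
  Y <- t(x[, (p + 1L):n, drop = FALSE])                    # N x k
  Z <- matrix(0, N, k * p)
  for (lag in seq_len(p))
    Z[, ((lag - 1L) * k + 1L):(lag * k)] <- t(x[, (p + 1L - lag):(n - lag), drop = FALSE])
  qz <- qr(Z)
  if (qz$rank < k * p) {
    if (onDeficient == "error")
      stop("rank-deficient regressor matrix; MVAR fit is singular")
    sv <- svd(Z)
    pos <- sv$d > max(dim(Z)) * .Machine$double.eps * sv$d[1]
    B <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
  } else {
    B <- qr.coef(qz, Y)                                    # kp x k
  }
  E <- Y - Z %*% B
  resCov <- crossprod(E) / N
  A <- lapply(seq_len(p), function(l) {
    a <- t(B[((l - 1L) * k + 1L):(l * k), , drop = FALSE]) # k x k: a[i, j]
    dimnames(a) <- dimnames(x)[c(1, 1)]
    a
  })
  lab <- rownames(x); if (is.null(lab)) lab <- character()
  new("MVARModel", order = p, A = A, resCov = (resCov + t(resCov)) / 2,
      nSamplesUsed = as.integer(N), stable = mvar_is_stable(A),
      channelLabels = lab)
}

#' Select the MVAR order by BIC
#'
#' Fits each candidate order and returns the one minimising
#' `BIC(p) = log det(Sigma_p) + k^2 p log(N) / N`, where `Sigma_p` is the
#' ML residual covariance and `N` the number of regression rows of that
#' fit. Ties go to the smallest order; unstable fits are skipped.
#'
#' @param x channels x samples numeric matrix.
#' @param pCandidates candidate orders (default `1:6`).
#' @return the selected order (integer).
#' @export
selectOrderBIC <- function(x, pCandidates = 1:6) {
  if (!length(pCandidates)) stop("pCandidates must be non-empty")
  pCandidates <- sort(unique(as.integer(pCandidates)))
  bic <- rep(NA_real_, length(pCandidates))
  for (i in seq_along(pCandidates)) {
    p <- pCandidates[i]
    fit <- tryCatch(fitMVAR(x, p, onDeficient = "minnorm"),
                    error = function(e) NULL)
    if (is.null(fit) || !fit@stable) next
    k <- nrow(fit@resCov); N <- fit@nSamplesUsed
    # pseudo-determinant (positive eigenvalues only) so the criterion stays
    # defined on rank-deficient residuals, e.g. average-referenced data
    ev <- eigen(fit@resCov, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > k * .Machine$double.eps * max(ev, 0)]
    if (!length(ev)) next
    bic[i] <- sum(log(ev)) + k^2 * p * log(N) / N
  }
  if (all(is.na(bic))) stop("order selection failed: no stable MVAR fit among candidates")
  pCandidates[which.min(bic)]   # which.min takes the first (smallest p) on ties
}

#' Spectral transfer matrix of an MVAR model
#'
#' Evaluates `H(f) = Abar(f)^-1` with
#' `Abar(f) = I - sum_n A_n exp(-i 2 pi f n / fs)` on a frequency grid.
#'
#' @param model an [MVARModel-class].
#' @param freqs frequency grid in Hz.
#' @param fs sampling rate in Hz.
#' @return a [SpectralTransfer-class].
#' @export
transferFunction <- function(model, freqs, fs) {
  stopifnot(is(model, "MVARModel"))
  k <- nrow(model@resCov)
  H <- array(complex(real = 0), dim = c(k, k, length(freqs)))
  I <- diag(k)
  for (fi in seq_along(freqs)) {
    Abar <- I + 0i
    for (l in seq_len(model@order))
      Abar <- Abar - model@A[[l]] * exp(-2i * pi * freqs[fi] * l / fs)
    Hf <- tryCatch(solve(Abar), error = function(e) NULL)
    if (is.null(Hf) || !all(is.finite(Mod(Hf))))
      stop("transfer matrix numerically singular at f = ", freqs[fi], " Hz")
    H[, , fi] <- Hf
  }
  new("SpectralTransfer", freqs = freqs, H = H)
}

#' Normalized directed transfer function
#'
#' `gamma^2_ij(f) = |H_ij(f)|^2 / sum_m |H_im(f)|^2`: the influence of
#' source channel j on target channel i, normalized by the total inflow
#' into i, so each target row sums to 1 at every frequency. Edge semantics:
#' entry `[i, j]` is flow from j to i.
#'
#' @param H a [SpectralTransfer-class].
#' @return a [DTFResult-class].
#' @export
dtf <- function(H) {
  stopifnot(is(H, "SpectralTransfer"))
  g <- Mod(H@H)^2
  k <- dim(g)[1]
  denom <- apply(g, c(1, 3), sum)                  # k x nfreq row norms
  if (any(denom <= 0)) stop("degenerate normalization: zero total inflow for some target")
  g <- g / aperm(array(denom, dim = c(k, dim(g)[3], k)), c(1, 3, 2))
  new("DTFResult", freqs = H@freqs, gamma2 = g, k = as.integer(k))
}

#' Band- and epoch-averaged DTF
#'
#' Averages `gamma^2` over the in-band grid frequencies
#' (`lo <= f < hi`), then over epochs when several [DTFResult-class]
#' objects are supplied. The result is the scalar edge weight DTF_Mean:
#' a target x source matrix with entries in [0, 1].
#'
#' @param x a [DTFResult-class] or a list of them (one per epoch, sharing a
#'   frequency grid).
#' @param band band name or numeric `(lo, hi)` in Hz.
#' @return target x source numeric matrix.
#' @export
dtfMean <- function(x, band) {
  if (is(x, "DTFResult")) x <- list(x)
  stopifnot(length(x) > 0, all(vapply(x, is, logical(1), "DTFResult")))
  b <- resolve_band(band)
  freqs <- x[[1]]@freqs
  sel <- freqs >= b[1] & freqs < b[2]
  if (!any(sel)) stop("no grid frequencies inside band (", b[1], ", ", b[2], ")")
  mats <- lapply(x, function(d) {
    if (!identical(d@freqs, freqs)) stop("epoch results must share one frequency grid")
    apply(d@gamma2[, , sel, drop = FALSE], c(1, 2), mean)
  })
  Reduce(`+`, mats) / length(mats)
}
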