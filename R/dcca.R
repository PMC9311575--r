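#' Deep canonical correlation analysis (DCCA) configuration
#'
#' The DCCA penalty couples two projection matrices `H1, H2` (one row per
#' sample) through the whitened cross-covariance
#' `T = S11^{-1/2} S12 S22^{-1/2}`, whose singular values are the canonical
#' correlations of the two views. Two correlation functionals are
#' supported: `"frobenius"` returns `sqrt(tr(T'T)) = sqrt(sum(rho_i^2))`
#' and `"trace_norm"` returns `sum(rho_i)` (the Andrew et al. variant).
#'
#' @param d projection dimension (columns of each `H`).
#' @param r1,r2 ridge regularizers added to the two within-view
#'   covariances (default 0.001 each, the value used for training).
#' @param correlation_mode `"frobenius"` (default) or `"trace_norm"`.
#' @param eig_floor smallest admissible covariance eigenvalue; eigenvalues
#'   are clamped here before the inverse square root so small batches never
#'   produce infinite losses.
#' @return a `dcca_config` list.
#' @export
dcca_config <- function(d = 8L, r1 = 0.001, r2 = 0.001,
                        correlation_mode = c("frobenius", "trace_norm"),
                        eig_floor = 1e-8) {
  correlation_mode <- match.arg(correlation_mode)
  stopifnot(d >= 1L, r1 >= 0, r2 >= 0, eig_floor > 0)
  structure(list(d = as.integer(d), r1 = r1, r2 = r2,
                 correlation_mode = correlation_mode, eig_floor = eig_floor),
            class = "dcca_config")
}

#' Column-centre a projection matrix
#'
#' @param H `N x d` matrix, one row per sample.
#' @return matrix whose every column has mean zero.
#' @export
center_columns <- function(H) {
  stopifnot(is.matrix(H), nrow(H) >= 2L)
  sweep(H, 2L, colMeans(H))
}

#' Regularized covariance triple of two views
#'
#' Computes `S12 = H1c' H2c / (N-1)`, `S11 = H1c' H1c / (N-1) + r1 I` and
#' `S22` analogously, where `Hc` are the column-centred views. Eigenvalue
#' clamping is applied downstream, not here, so the returned matrices are
#' the literal ridge-regularized sample covariances.
#'
#' @param H1,H2 `N x d` matrices with equal dimensions.
#' @param config a [dcca_config()].
#' @return list with `S11`, `S22`, `S12`.
#' @export
dcca_covariances <- function(H1, H2, config = dcca_config(d = ncol(H1))) {
  stopifnot(is.matrix(H1), is.matrix(H2), identical(dim(H1), dim(H2)),
            nrow(H1) >= 2L)
  n <- nrow(H1)
  H1c <- center_columns(H1)
  H2c <- center_columns(H2)
  d <- ncol(H1)
  list(S11 = crossprod(H1c) / (n - 1) + config$r1 * diag(d),
       S22 = crossprod(H2c) / (n - 1) + config$r2 * diag(d),
       S12 = crossprod(H1c, H2c) / (n - 1))
}

# symmetric eigendecomposition with floor-clamped eigenvalues; returns the
# requested matrix powers (inverse and inverse square root)
.sym_powers <- function(S, eig_floor) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, eig_floor)
  list(inv = e$vectors %*% (t(e$vectors) / lam),
       isqrt = e$vectors %*% (t(e$vectors) / sqrt(lam)))
}

#' Total canonical correlation between two projected views
#'
#' Forms `T = S11^{-1/2} S12 S22^{-1/2}` via symmetric eigendecompositions
#' (with eigenvalues clamped at `config$eig_floor`) and returns
#' `sqrt(tr(T'T))` in `"frobenius"` mode or the sum of `T`'s singular
#' values in `"trace_norm"` mode. Both are nonnegative; with identical
#' views and no ridge they equal `sqrt(d)` and `d` respectively.
#'
#' @param H1,H2 `N x d` matrices, rows are samples.
#' @param config a [dcca_config()].
#' @return nonnegative scalar.
#' @export
dcca_correlation <- function(H1, H2, config = dcca_config(d = ncol(H1))) {
  S <- dcca_covariances(H1, H2, config)
  p1 <- .sym_powers(S$S11, config$eig_floor)
  p2 <- .sym_powers(S$S22, config$eig_floor)
  Tm <- p1$isqrt %*% S$S12 %*% p2$isqrt
  if (!all(is.finite(Tm)))
    stop("non-finite whitened cross-covariance; check inputs and ridge",
         call. = FALSE)
  if (config$correlation_mode == "frobenius") sqrt(sum(Tm^2))
  else sum(svd(Tm)$d)
}

#' DCCA loss across the three DANet branches
#'
#' The penalty `-corr(H_main, H_down) - corr(H_main, H_top)` rewards the
#' main branch for sharing structure with both the nuclei-only and the
#' non-nuclei view; minimizing it maximizes the two total correlations. It
#' is never positive.
#'
#' @param H_main,H_down,H_top `N x d` projection matrices.
#' @param config a [dcca_config()].
#' @return scalar `<= 0`.
#' @export
dcca_loss <- function(H_main, H_down, H_top,
                      config = dcca_config(d = ncol(H_main))) {
  if (nrow(H_main) < 4L)
    stop("dcca_loss needs a batch of at least 4 samples", call. = FALSE)
  if (nrow(H_main) <= ncol(H_main))
    warning("batch size <= projection dimension: canonical correlations ",
            "are rank-deficient; rely on the ridge", call. = FALSE)
  -dcca_correlation(H_main, H_down, config) -
    dcca_correlation(H_main, H_top, config)
}

#' Gradient of the total correlation with respect to both views
#'
#' Analytic gradient of [dcca_correlation()]. In `"frobenius"` mode the
#' objective simplifies to `sqrt(f)` with
#' `f = tr(S11^{-1} S12 S22^{-1} S12')`, differentiated by direct matrix
#' calculus; in `"trace_norm"` mode the gradient follows the singular value
#' decomposition of `T` (Andrew et al.'s construction). Eigenvalue clamping
#' is treated as inactive, which holds whenever the ridge keeps all
#' eigenvalues above `eig_floor`.
#'
#' @param H1,H2 `N x d` matrices.
#' @param config a [dcca_config()].
#' @return list with `value` and gradients `dH1`, `dH2` (same shapes as
#'   the inputs).
#' @export
dcca_correlation_grad <- function(H1, H2, config = dcca_config(d = ncol(H1))) {
  n <- nrow(H1)
  S <- dcca_covariances(H1, H2, config)
  p1 <- .sym_powers(S$S11, config$eig_floor)
  p2 <- .sym_powers(S$S22, config$eig_floor)
  H1c <- center_columns(H1)
  H2c <- center_columns(H2)

  if (config$correlation_mode == "frobenius") {
    A <- p1$inv %*% S$S12 %*% p2$inv      # S11^{-1} S12 S22^{-1}
    f <- sum(A * S$S12)                   # tr(S11^{-1} S12 S22^{-1} S12')
    value <- sqrt(max(f, 0))
    sc <- 1 / (2 * max(value, 1e-12))
    G12 <- sc * 2 * A
    G11 <- -sc * A %*% t(S$S12) %*% p1$inv
    G22 <- -sc * p2$inv %*% t(S$S12) %*% A
  } else {
    Tm <- p1$isqrt %*% S$S12 %*% p2$isqrt
    sv <- svd(Tm)
    value <- sum(sv$d)
    G12 <- p1$isqrt %*% sv$u %*% t(sv$v) %*% p2$isqrt
    G11 <- -0.5 * p1$isqrt %*% sv$u %*% (sv$d * t(sv$u)) %*% p1$isqrt
    G22 <- -0.5 * p2$isqrt %*% sv$v %*% (sv$d * t(sv$v)) %*% p2$isqrt
  }
  G11 <- (G11 + t(G11)) / 2
  G22 <- (G22 + t(G22)) / 2
  # chain through S11 = H1c'H1c/(n-1) + r I, S12 = H1c'H2c/(n-1); the
  # results are linear in the centred views, hence already column-centred
  dH1 <- (2 * H1c %*% G11 + H2c %*% t(G12)) / (n - 1)
  dH2 <- (2 * H2c %*% G22 + H1c %*% G12) / (n - 1)
  list(value = value, dH1 = dH1, dH2 = dH2)
}

#' Value and gradients of the three-branch DCCA loss
#'
#' @inheritParams dcca_loss
#' @return list with `value` and gradients `dH_main`, `dH_down`, `dH_top`.
#' @export
dcca_loss_grad <- function(H_main, H_down, H_top,
                           config = dcca_config(d = ncol(H_main))) {
  g1 <- dcca_correlation_grad(H_main, H_down, config)
  g2 <- dcca_correlation_grad(H_main, H_top, config)
  list(value = -g1$value - g2$value,
       dH_main = -g1$dH1 - g2$dH1,
       dH_down = -g1$dH2,
       dH_top = -g2$dH2)
}
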