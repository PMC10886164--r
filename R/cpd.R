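# Rigid coherent point drift registration.
#
# EM over a Gaussian mixture with isotropic variance and a uniform outlier
# component; the rotation is recovered in closed form at each M-step from
# the SVD of the weighted cross-covariance. Scale is fixed to 1 (same-scale
# anatomy). Converges when the change in the mixture variance drops below
# `tol`.

#' Rigid coherent point drift registration
#'
#' Finds the rigid transform `T` such that `T(source)` matches `target`.
#'
#' @param source m x 3 moving point set.
#' @param target n x 3 fixed point set.
#' @param w outlier weight in [0, 1).
#' @param tol convergence tolerance on the variance change.
#' @param max_iter maximum EM iterations.
#' @return a `rigid_transform` with attributes `sigma2` (final variance),
#'   `iterations`, and `converged`. Non-convergence within `max_iter` is
#'   reported via a warning and `converged = FALSE`; the last iterate is
#'   returned.
#' @export
cpd_rigid <- function(source, target, w = 0, tol = 1e-8, max_iter = 100) {
  Y <- as.matrix(source); X <- as.matrix(target)
  stopifnot(ncol(Y) == 3, ncol(X) == 3)
  M <- nrow(Y); N <- nrow(X); D <- 3
  if (M < 3 || N < 3) stop("need at least 3 points in each set", call. = FALSE)
  check_noncollinear <- function(P) {
    s <- svd(sweep(P, 2, colMeans(P)))$d
    if (s[2] < 1e-9 * max(s[1], 1)) {
      stop("point set is collinear/degenerate", call. = FALSE)
    }
  }
  check_noncollinear(X); check_noncollinear(Y)
  if (w < 0 || w >= 1) stop("w must be in [0, 1)", call. = FALSE)

  R <- diag(3); t <- c(0, 0, 0)
  TY <- Y
  sigma2 <- sum(vapply(seq_len(D), function(d) {
    sum(outer(X[, d], TY[, d], `-`)^2)
  }, 0)) / (D * M * N)
  if (sigma2 <= 0) sigma2 <- 1e-12

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: responsibilities of mixture components for each target point
    d2 <- outer(rowSums(X^2), rep(1, M)) +
      outer(rep(1, N), rowSums(TY^2)) - 2 * X %*% t(TY)   # N x M
    K <- exp(-d2 / (2 * sigma2))
    cden <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    den <- rowSums(K) + cden
    den[den == 0] <- .Machine$double.eps
    P <- K / den                                           # N x M
    Np <- sum(P)
    if (Np < .Machine$double.eps) break
    p1 <- colSums(P)                                       # per source point
    pt1 <- rowSums(P)                                      # per target point

    mu_x <- as.numeric(t(X) %*% pt1) / Np
    mu_y <- as.numeric(t(Y) %*% p1) / Np
    Xh <- sweep(X, 2, mu_x)
    Yh <- sweep(Y, 2, mu_y)
    A <- t(Xh) %*% P %*% Yh                                # cross-covariance
    sv <- svd(A)
    C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
    R <- sv$u %*% C %*% t(sv$v)
    t <- mu_x - as.numeric(R %*% mu_y)

    TY <- sweep(Y %*% t(R), 2, t, `+`)
    trAR <- sum(diag(t(A) %*% R))
    trX <- sum(pt1 * rowSums(Xh^2))
    trY <- sum(p1 * rowSums(Yh^2))
    sigma2_new <- (trX - 2 * trAR + trY) / (Np * D)
    if (sigma2_new <= 0) sigma2_new <- tol / 10
    if (abs(sigma2 - sigma2_new) < tol) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }
  if (!converged) {
    warning(sprintf("cpd_rigid: no convergence in %d iterations (last dsigma2 at %g)",
                    max_iter, sigma2), call. = FALSE)
  }
  out <- rigid_transform(R, t)
  attr(out, "sigma2") <- sigma2
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}
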