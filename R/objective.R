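#' Map cells into the shared latent space
#'
#' The latent coordinates of domain I are `K %*% alpha`: by the representer
#' theorem each latent coordinate is a kernel expansion over the domain's
#' own cells, so the n-by-p embedding is the kernel Gram matrix times the
#' coefficient matrix.
#'
#' @param K n-by-n kernel Gram matrix.
#' @param alpha n-by-p coefficient matrix.
#' @return n-by-p matrix of latent coordinates.
#' @export
embed <- function(K, alpha) {
  check_matrix(K); check_matrix(alpha)
  if (ncol(K) != nrow(alpha))
    stop(sprintf("non-conforming shapes: K is %dx%d, alpha is %dx%d",
                 nrow(K), ncol(K), nrow(alpha), ncol(alpha)), call. = FALSE)
  K %*% alpha
}

## Squared Euclidean cross-distances between rows of U1 and rows of U2.
cross_sqdist <- function(U1, U2) {
  D <- outer(rowSums(U1^2), rowSums(U2^2), "+") - 2 * tcrossprod(U1, U2)
  D[D < 0] <- 0
  D
}

#' Squared maximum mean discrepancy between two embedded point sets
#'
#' Computes MMD^2 between the empirical distributions of two point clouds in
#' the shared latent space, using a Gaussian RBF kernel
#' `exp(-||u - v||^2 / (2 sigma^2))`. The default `"quadratic"` estimator is
#' the plug-in V-statistic summing the kernel over all within- and
#' cross-set pairs:
#' `1/n1^2 sum K(u_i, u_j) - 2/(n1 n2) sum K(u_i, v_j) + 1/n2^2 sum K(v_i, v_j)`.
#' It is nonnegative up to floating-point error and zero when the two sets
#' coincide. The `"linear"` estimator is a streaming O(n) approximation:
#' points are consumed in fixed consecutive pairs
#' `h_i = K(u_{2i-1}, u_{2i}) + K(v_{2i-1}, v_{2i}) - K(u_{2i-1}, v_{2i}) -
#' K(u_{2i}, v_{2i-1})` and averaged; it agrees with the quadratic
#' estimator only in expectation over the ordering of the points.
#'
#' @param U1,U2 Numeric matrices of latent coordinates (rows are points);
#'   must share the number of columns.
#' @param sigma Positive bandwidth of the Gaussian RBF kernel.
#' @param estimator `"quadratic"` (default) or `"linear"`.
#' @return A single number, the estimated squared MMD.
#' @export
mmd_squared <- function(U1, U2, sigma, estimator = c("quadratic", "linear")) {
  estimator <- match.arg(estimator)
  check_matrix(U1); check_matrix(U2)
  check_scalar(sigma, "sigma", positive = TRUE)
  if (ncol(U1) != ncol(U2))
    stop(sprintf("latent dimensions differ: %d vs %d", ncol(U1), ncol(U2)),
         call. = FALSE)
  s2 <- 2 * sigma^2
  if (estimator == "quadratic") {
    n1 <- nrow(U1); n2 <- nrow(U2)
    g11 <- sum(exp(-cross_sqdist(U1, U1) / s2))
    g22 <- sum(exp(-cross_sqdist(U2, U2) / s2))
    g12 <- sum(exp(-cross_sqdist(U1, U2) / s2))
    g11 / n1^2 - 2 * g12 / (n1 * n2) + g22 / n2^2
  } else {
    m <- floor(min(nrow(U1), nrow(U2)) / 2)
    if (m < 1L)
      stop("linear estimator needs at least 2 points per set", call. = FALSE)
    o <- seq_len(m) * 2L - 1L  # odd members of each consecutive pair
    k <- function(A, B) exp(-rowSums((A - B)^2) / s2)
    mean(k(U1[o, , drop = FALSE], U1[o + 1L, , drop = FALSE]) +
         k(U2[o, , drop = FALSE], U2[o + 1L, , drop = FALSE]) -
         k(U1[o, , drop = FALSE], U2[o + 1L, , drop = FALSE]) -
         k(U1[o + 1L, , drop = FALSE], U2[o, , drop = FALSE]))
  }
}

#' Orthogonality penalty of a kernel-expansion mapping
#'
#' `||alpha' K alpha - I_p||_F^2`: the squared Frobenius distance between
#' the p-by-p matrix of RKHS inner products of the p latent coordinate
#' functions and the identity. Zero exactly when the learned mapping is a
#' projection onto a p-dimensional subspace of the RKHS; penalizing it keeps
#' the optimization away from the trivial all-zero map.
#'
#' @param alpha n-by-p coefficient matrix.
#' @param K n-by-n kernel Gram matrix.
#' @return A nonnegative number.
#' @export
penalty_term <- function(alpha, K) {
  check_matrix(alpha); check_matrix(K)
  if (nrow(alpha) != nrow(K))
    stop("alpha and K have incompatible shapes", call. = FALSE)
  M <- crossprod(alpha, K %*% alpha)
  diag(M) <- diag(M) - 1
  sum(M^2)
}

#' Distortion of within-domain structure under the latent mapping
#'
#' `||K - K alpha alpha' K||_F^2`: how much the matrix of latent-space inner
#' products `(K alpha)(K alpha)'` differs from the input-space similarities
#' `K`. Penalizing distortion stops the optimizer from learning arbitrary
#' mappings that scramble the relative positions of cells just to make the
#' two domains overlap.
#'
#' @inheritParams penalty_term
#' @return A nonnegative number.
#' @export
distortion_term <- function(alpha, K) {
  check_matrix(alpha); check_matrix(K)
  if (nrow(alpha) != nrow(K))
    stop("alpha and K have incompatible shapes", call. = FALSE)
  B <- K %*% alpha
  R <- K - tcrossprod(B)
  sum(R^2)
}

#' Full alignment objective and its components
#'
#' Evaluates `MMD^2(K1 a1, K2 a2) + lambda1 (pen(a1) + pen(a2)) +
#' lambda2 (dis(a1) + dis(a2))`, returning every component so the relative
#' magnitude of the three terms can be monitored (the recommended way to
#' choose the trade-off weights).
#'
#' @param alpha1,alpha2 Coefficient matrices for the two domains.
#' @param K1,K2 Kernel Gram matrices for the two domains.
#' @param lambda1 Nonnegative weight of the orthogonality penalty.
#' @param lambda2 Nonnegative weight of the distortion term.
#' @param sigma Positive bandwidth of the MMD Gaussian kernel.
#' @param estimator MMD estimator, `"quadratic"` or `"linear"`.
#' @return An object of class `"mmdma_objective"`: a list with elements
#'   `total`, `mmd2`, `pen1`, `pen2`, `dis1`, `dis2`, `lambda1`, `lambda2`.
#' @export
mmdma_objective <- function(alpha1, alpha2, K1, K2, lambda1, lambda2, sigma,
                            estimator = c("quadratic", "linear")) {
  estimator <- match.arg(estimator)
  check_scalar(lambda1, "lambda1", nonneg = TRUE)
  check_scalar(lambda2, "lambda2", nonneg = TRUE)
  mmd2 <- mmd_squared(embed(K1, alpha1), embed(K2, alpha2), sigma,
                      estimator = estimator)
  pen1 <- penalty_term(alpha1, K1); pen2 <- penalty_term(alpha2, K2)
  dis1 <- distortion_term(alpha1, K1); dis2 <- distortion_term(alpha2, K2)
  structure(list(total = mmd2 + lambda1 * (pen1 + pen2) +
                   lambda2 * (dis1 + dis2),
                 mmd2 = mmd2, pen1 = pen1, pen2 = pen2,
                 dis1 = dis1, dis2 = dis2,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "mmdma_objective")
}

#' @export
print.mmdma_objective <- function(x, ...) {
  cat(sprintf("total     %.6g\n", x$total))
  cat(sprintf("  MMD^2      %.6g\n", x$mmd2))
  cat(sprintf("  penalty    %.6g + %.6g  (lambda1 = %.3g)\n",
              x$pen1, x$pen2, x$lambda1))
  cat(sprintf("  distortion %.6g + %.6g  (lambda2 = %.3g)\n",
              x$dis1, x$dis2, x$lambda2))
  invisible(x)
}

## Gradient of the quadratic-estimator MMD^2 with respect to the two
## embeddings. d/du exp(-||u-v||^2/(2s^2)) = -exp(.) (u-v)/s^2.
mmd_gradient_embeddings <- function(U1, U2, sigma) {
  n1 <- nrow(U1); n2 <- nrow(U2); s2 <- sigma^2
  G11 <- exp(-cross_sqdist(U1, U1) / (2 * s2))
  G22 <- exp(-cross_sqdist(U2, U2) / (2 * s2))
  G12 <- exp(-cross_sqdist(U1, U2) / (2 * s2))
  gU1 <- -(2 / (n1^2 * s2)) * (rowSums(G11) * U1 - G11 %*% U1) +
          (2 / (n1 * n2 * s2)) * (rowSums(G12) * U1 - G12 %*% U2)
  gU2 <- -(2 / (n2^2 * s2)) * (rowSums(G22) * U2 - G22 %*% U2) +
          (2 / (n1 * n2 * s2)) * (colSums(G12) * U2 - crossprod(G12, U1))
  list(gU1 = gU1, gU2 = gU2)
}

## Gradient of the linear-estimator MMD^2 (fixed consecutive pairing).
mmd_gradient_embeddings_linear <- function(U1, U2, sigma) {
  m <- floor(min(nrow(U1), nrow(U2)) / 2)
  o <- seq_len(m) * 2L - 1L
  s2 <- sigma^2
  gU1 <- matrix(0, nrow(U1), ncol(U1))
  gU2 <- matrix(0, nrow(U2), ncol(U2))
  add_pair <- function(g, rows_a, A, B, sign) {
    d <- A - B
    w <- sign * exp(-rowSums(d^2) / (2 * s2)) / (m * s2)
    g[rows_a, ] <- g[rows_a, ] - w * d
    g
  }
  x1 <- U1[o, , drop = FALSE];  x2 <- U1[o + 1L, , drop = FALSE]
  y1 <- U2[o, , drop = FALSE];  y2 <- U2[o + 1L, , drop = FALSE]
  ## within-set terms touch both members of each pair
  gU1 <- add_pair(gU1, o, x1, x2, +1);  gU1 <- add_pair(gU1, o + 1L, x2, x1, +1)
  gU2 <- add_pair(gU2, o, y1, y2, +1);  gU2 <- add_pair(gU2, o + 1L, y2, y1, +1)
  ## cross terms (negative sign in the estimator)
  gU1 <- add_pair(gU1, o, x1, y2, -1);  gU2 <- add_pair(gU2, o + 1L, y2, x1, -1)
  gU1 <- add_pair(gU1, o + 1L, x2, y1, -1); gU2 <- add_pair(gU2, o, y1, x2, -1)
  list(gU1 = gU1, gU2 = gU2)
}

#' Analytic gradient of the alignment objective
#'
#' Hand-derived gradient of the full objective with respect to both
#' coefficient matrices, using (for symmetric `K` and
#' `M = alpha' K alpha - I`, `R = K - K alpha alpha' K`):
#' `d pen / d alpha = 4 K alpha M` and `d dis / d alpha = -4 K R K alpha`.
#' The MMD contribution is chained through the embeddings `U = K alpha`.
#' This pure-R implementation is the reference against which both finite
#' differences and the compiled optimizer path are checked.
#'
#' @inheritParams mmdma_objective
#' @return A list with matrices `g1` and `g2`, the gradients with respect
#'   to `alpha1` and `alpha2`.
#' @export
mmdma_gradient <- function(alpha1, alpha2, K1, K2, lambda1, lambda2, sigma,
                           estimator = c("quadratic", "linear")) {
  estimator <- match.arg(estimator)
  U1 <- embed(K1, alpha1); U2 <- embed(K2, alpha2)
  g <- if (estimator == "quadratic") mmd_gradient_embeddings(U1, U2, sigma)
       else mmd_gradient_embeddings_linear(U1, U2, sigma)
  pen_dis_grad <- function(K, alpha, B) {
    M <- crossprod(alpha, B); diag(M) <- diag(M) - 1
    C <- K %*% B
    list(gpen = 4 * (B %*% M),
         gdis = -4 * (K %*% C - C %*% crossprod(B)))
  }
  r1 <- pen_dis_grad(K1, alpha1, U1)
  r2 <- pen_dis_grad(K2, alpha2, U2)
  list(g1 = K1 %*% g$gU1 + lambda1 * r1$gpen + lambda2 * r1$gdis,
       g2 = K2 %*% g$gU2 + lambda1 * r2$gpen + lambda2 * r2$gdis)
}
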