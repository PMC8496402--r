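# Shared fixture builders; everything is generated in code under fixed seeds.

# random symmetric positive semidefinite kernel with O(1) entries
random_kernel <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * (n + 5)), n)
  tcrossprod(x) / ncol(x)
}

random_alpha <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p, sd = 1 / sqrt(n)), n, p)
}

# small complete two-domain problem (kernels + hyperparameters)
small_problem <- function(n = 30, p = 2, seed = 1) {
  list(K1 = random_kernel(n, seed), K2 = random_kernel(n, seed + 100),
       a1 = random_alpha(n, p, seed + 200),
       a2 = random_alpha(n, p, seed + 300),
       lambda1 = 0.3, lambda2 = 0.05, sigma = 0.8)
}

# independently coded triple-double-loop MMD^2 (the V-statistic written
# exactly as the defining double sums; deliberately naive)
mmd2_loops <- function(U1, U2, sigma) {
  n1 <- nrow(U1); n2 <- nrow(U2)
  km <- function(u, v) exp(-sum((u - v)^2) / (2 * sigma^2))
  s11 <- 0
  for (i in 1:n1) for (j in 1:n1) s11 <- s11 + km(U1[i, ], U1[j, ])
  s12 <- 0
  for (i in 1:n1) for (j in 1:n2) s12 <- s12 + km(U1[i, ], U2[j, ])
  s22 <- 0
  for (i in 1:n2) for (j in 1:n2) s22 <- s22 + km(U2[i, ], U2[j, ])
  s11 / n1^2 - 2 * s12 / (n1 * n2) + s22 / n2^2
}

# naive elementwise penalty and distortion evaluations
penalty_loops <- function(alpha, K) {
  M <- t(alpha) %*% K %*% alpha - diag(ncol(alpha))
  s <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) s <- s + M[i, j]^2
  s
}

distortion_loops <- function(alpha, K) {
  R <- K - K %*% alpha %*% t(alpha) %*% t(K)
  s <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) s <- s + R[i, j]^2
  s
}

# brute-force per-point FOSCTTM by explicit sort-free counting
foscttm_loops <- function(E1, E2) {
  n1 <- nrow(E1); n2 <- nrow(E2)
  f1 <- numeric(n1); f2 <- numeric(n2)
  for (i in 1:n1) {
    d <- sqrt(rowSums((E2 - matrix(E1[i, ], n2, ncol(E1), byrow = TRUE))^2))
    f1[i] <- sum(d < d[i]) / (n2 - 1)
  }
  for (j in 1:n2) {
    d <- sqrt(rowSums((E1 - matrix(E2[j, ], n1, ncol(E1), byrow = TRUE))^2))
    f2[j] <- sum(d < d[j]) / (n1 - 1)
  }
  list(f1 = f1, f2 = f2, average = (mean(f1) + mean(f2)) / 2)
}

# central finite-difference gradient of the full objective w.r.t. both alphas
fd_gradient <- function(a1, a2, K1, K2, lambda1, lambda2, sigma, h = 1e-5) {
  f <- function(x1, x2)
    mmdma_objective(x1, x2, K1, K2, lambda1, lambda2, sigma)$total
  g1 <- a1 * 0; g2 <- a2 * 0
  for (i in seq_along(a1)) {
    ap <- a1; am <- a1
    ap[i] <- ap[i] + h; am[i] <- am[i] - h
    g1[i] <- (f(ap, a2) - f(am, a2)) / (2 * h)
  }
  for (i in seq_along(a2)) {
    ap <- a2; am <- a2
    ap[i] <- ap[i] + h; am[i] <- am[i] - h
    g2[i] <- (f(a1, ap) - f(a1, am)) / (2 * h)
  }
  list(g1 = g1, g2 = g2)
}
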