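test_that("embed is the kernel-coefficient product", {
  K <- random_kernel(6, 2)
  a <- random_alpha(6, 3, 3)
  expect_equal(embed(diag(6), a), a)
  expect_equal(embed(K, a * 0), matrix(0, 6, 3))
  loop <- matrix(0, 6, 3)
  for (i in 1:6) for (j in 1:3) loop[i, j] <- sum(K[i, ] * a[, j])
  expect_equal(embed(K, a), loop, tolerance = 1e-12)
  expect_error(embed(K, matrix(0, 5, 2)), "shapes")
})

test_that("mmd_squared matches the brute-force double-sum oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    U1 <- matrix(rnorm(7 * 3), 7, 3)
    U2 <- matrix(rnorm(5 * 3), 5, 3)
    expect_equal(mmd_squared(U1, U2, 0.8), mmd2_loops(U1, U2, 0.8),
                 tolerance = 1e-12)
  }
})

test_that("mmd_squared is zero on identical clouds and symmetric", {
  set.seed(9)
  U <- matrix(rnorm(20), 10, 2)
  expect_equal(mmd_squared(U, U, 0.7), 0, tolerance = 1e-12)
  expect_equal(mmd_squared(matrix(0, 1, 2), matrix(0, 1, 2), 2), 0)
  V <- matrix(rnorm(12), 6, 2)
  expect_equal(mmd_squared(U, V, 0.5), mmd_squared(V, U, 0.5),
               tolerance = 1e-14)
  # joint rigid translation leaves it unchanged
  sh <- matrix(c(3, -2), 1)
  expect_equal(mmd_squared(U + sh[rep(1, 10), ], V + sh[rep(1, 6), ], 0.5),
               mmd_squared(U, V, 0.5), tolerance = 1e-10)
  expect_gte(mmd_squared(U, V, 0.5), 0)
  expect_error(mmd_squared(U, matrix(0, 3, 3), 1), "dimensions differ")
  expect_error(mmd_squared(U, V, -1), "sigma")
})

test_that("mmd_squared decreases to zero as the bandwidth grows", {
  set.seed(4)
  U <- matrix(rnorm(16), 8, 2)
  V <- matrix(rnorm(16), 8, 2) + 1
  vals <- sapply(c(2, 8, 32, 128), function(s) mmd_squared(U, V, s))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], vals[1] / 50)
})

test_that("linear-estimator MMD agrees with the quadratic one in expectation", {
  set.seed(11)
  n <- 400
  U1 <- matrix(rnorm(n * 2), n, 2)
  U2 <- matrix(rnorm(n * 2, mean = 0.5), n, 2)
  quad <- mmd_squared(U1, U2, 1)
  lins <- replicate(200, {
    i <- sample(n); j <- sample(n)
    mmd_squared(U1[i, ], U2[j, ], 1, estimator = "linear")
  })
  # the streaming estimator is unbiased for the U-statistic, which differs
  # from the V-statistic by O(1/n)
  expect_equal(mean(lins), quad, tolerance = 0.15)
})

test_that("penalty_term matches its loop oracle and analytic zeros", {
  expect_equal(penalty_term(diag(5)[, 1:2], diag(5)), 0)
  expect_equal(penalty_term(matrix(0, 4, 3), random_kernel(4, 7)), 3)
  for (seed in 1:4) {
    K <- random_kernel(5, seed)
    a <- random_alpha(5, 2, seed + 50)
    expect_equal(penalty_term(a, K), penalty_loops(a, K), tolerance = 1e-12)
  }
  # exact zero whenever alpha' K alpha = I: use an eigenbasis construction
  K <- random_kernel(6, 3)
  e <- eigen(K, symmetric = TRUE)
  a <- e$vectors[, 1:2] %*% diag(1 / sqrt(e$values[1:2]))
  expect_lt(penalty_term(a, K), 1e-10)
})

test_that("distortion_term matches its loop oracle and analytic zeros", {
  expect_equal(distortion_term(diag(4), diag(4)), 0)
  K <- random_kernel(5, 12)
  expect_equal(distortion_term(matrix(0, 5, 2), K), sum(K^2),
               tolerance = 1e-10)
  for (seed in 1:4) {
    K <- random_kernel(6, seed + 20)
    a <- random_alpha(6, 2, seed + 70)
    expect_equal(distortion_term(a, K), distortion_loops(a, K),
                 tolerance = 1e-10 * max(1, distortion_loops(a, K)))
  }
  # K alpha alpha' K = K exactly when alpha spans the whole eigenbasis
  K <- random_kernel(4, 9)
  e <- eigen(K, symmetric = TRUE)
  a <- e$vectors %*% diag(1 / sqrt(e$values))
  expect_lt(distortion_term(a, K), 1e-8)
})

test_that("objective assembles its components consistently", {
  pr <- small_problem(n = 12, p = 2, seed = 6)
  o <- mmdma_objective(pr$a1, pr$a2, pr$K1, pr$K2, pr$lambda1, pr$lambda2,
                       pr$sigma)
  # recomputation from independently coded component oracles
  U1 <- pr$K1 %*% pr$a1; U2 <- pr$K2 %*% pr$a2
  expect_equal(o$mmd2, mmd2_loops(U1, U2, pr$sigma), tolerance = 1e-12)
  expect_equal(o$pen1, penalty_loops(pr$a1, pr$K1), tolerance = 1e-12)
  expect_equal(o$dis2, distortion_loops(pr$a2, pr$K2), tolerance = 1e-10)
  expect_equal(o$total,
               o$mmd2 + pr$lambda1 * (o$pen1 + o$pen2) +
                 pr$lambda2 * (o$dis1 + o$dis2), tolerance = 1e-10)
  # degenerate weights reduce to MMD alone
  o0 <- mmdma_objective(pr$a1, pr$a2, pr$K1, pr$K2, 0, 0, pr$sigma)
  expect_equal(o0$total, o0$mmd2)
  # zero coefficients with equal kernels: closed form
  p <- 2
  oz <- mmdma_objective(pr$a1 * 0, pr$a1 * 0, pr$K1, pr$K1, 0.3, 0.05, 1)
  expect_equal(oz$mmd2, 0, tolerance = 1e-12)
  expect_equal(oz$total, 0.3 * 2 * p + 0.05 * 2 * sum(pr$K1^2),
               tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:3) {
    pr <- small_problem(n = 10, p = 2, seed = seed)
    g <- mmdma_gradient(pr$a1, pr$a2, pr$K1, pr$K2, pr$lambda1, pr$lambda2,
                        pr$sigma)
    fd <- fd_gradient(pr$a1, pr$a2, pr$K1, pr$K2, pr$lambda1, pr$lambda2,
                      pr$sigma)
    expect_equal(g$g1, fd$g1, tolerance = 1e-4)
    expect_equal(g$g2, fd$g2, tolerance = 1e-4)
  }
})

test_that("compiled gradients agree with the pure-R reference", {
  for (seed in 1:3) {
    pr <- small_problem(n = 14, p = 3, seed = seed + 40)
    gr <- mmdma_gradient(pr$a1, pr$a2, pr$K1, pr$K2, pr$lambda1, pr$lambda2,
                         pr$sigma)
    gc <- mmdma:::.mmdma_gradient_cpp(pr$K1, pr$K2, pr$a1, pr$a2, pr$sigma,
                                      pr$lambda1, pr$lambda2)
    expect_equal(gc$g1, gr$g1, tolerance = 1e-10)
    expect_equal(gc$g2, gr$g2, tolerance = 1e-10)
    o <- mmdma_objective(pr$a1, pr$a2, pr$K1, pr$K2, pr$lambda1, pr$lambda2,
                         pr$sigma)
    expect_equal(gc$total, o$total, tolerance = 1e-12)
  }
})

test_that("linear-estimator gradients also match finite differences", {
  pr <- small_problem(n = 10, p = 2, seed = 77)
  f <- function(x1, x2)
    mmdma_objective(x1, x2, pr$K1, pr$K2, pr$lambda1, pr$lambda2, pr$sigma,
                    estimator = "linear")$total
  g <- mmdma_gradient(pr$a1, pr$a2, pr$K1, pr$K2, pr$lambda1, pr$lambda2,
                      pr$sigma, estimator = "linear")
  h <- 1e-5
  for (idx in c(1, 7, 15)) {
    ap <- pr$a1; am <- pr$a1
    ap[idx] <- ap[idx] + h; am[idx] <- am[idx] - h
    expect_equal(g$g1[idx], (f(ap, pr$a2) - f(am, pr$a2)) / (2 * h),
                 tolerance = 1e-4)
  }
})
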