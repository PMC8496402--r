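test_that("init_alpha is seeded, scaled and leaves the RNG alone", {
  a <- init_alpha(300, 5, seed = 4)
  expect_equal(dim(a), c(300, 5))
  expect_identical(init_alpha(300, 5, seed = 4), a)
  expect_false(identical(init_alpha(300, 5, seed = 5), a))
  # zero-mean Gaussian with scale 1/sqrt(n)
  expect_lt(abs(mean(a)), 3 * (1 / sqrt(300)) / sqrt(300 * 5))
  expect_equal(sd(a), 1 / sqrt(300), tolerance = 0.05)
  # caller's RNG stream is not consumed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(init_alpha(10, 2, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("fit is deterministic: identical seeds give identical results", {
  pr <- small_problem(n = 25, p = 2, seed = 3)
  f1 <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
              sigma = 0.8, n_iterations = 300, n_restarts = 2, seed = 10,
              trace_every = 50)
  f2 <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
              sigma = 0.8, n_iterations = 300, n_restarts = 2, seed = 10,
              trace_every = 50)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$alpha1, f2$alpha1)
  expect_identical(f1$embedding2, f2$embedding2)
  expect_identical(f1$restart_objectives, f2$restart_objectives)
})

test_that("optimization decreases the objective from iteration zero", {
  for (seed in c(2, 5)) {
    pr <- small_problem(n = 30, p = 2, seed = seed)
    fit <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
                 sigma = 0.8, n_iterations = 500, n_restarts = 1,
                 seed = seed, trace_every = 50)
    tr <- trace_of(fit)
    expect_equal(tr$iteration[1], 0)
    expect_lt(min(tr$total), tr$total[1])
    expect_lte(fit$objective$total, tr$total[1] + 1e-6)
  }
})

test_that("the solution's objective is recomputable from its coefficients", {
  pr <- small_problem(n = 20, p = 2, seed = 8)
  fit <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-3, lambda2 = 1e-2,
               sigma = 0.6, n_iterations = 200, n_restarts = 1, seed = 1)
  redo <- mmdma_objective(fit$alpha1, fit$alpha2, pr$K1, pr$K2,
                          1e-3, 1e-2, 0.6)
  expect_equal(fit$objective$total, redo$total,
               tolerance = 1e-8 * max(1, abs(redo$total)))
  expect_equal(fit$embedding1, pr$K1 %*% fit$alpha1, ignore_attr = TRUE)
})

test_that("multiple restarts keep the lowest final objective", {
  pr <- small_problem(n = 20, p = 2, seed = 13)
  one <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
               sigma = 0.7, n_iterations = 150, n_restarts = 1, seed = 21)
  multi <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
                 sigma = 0.7, n_iterations = 150, n_restarts = 3, seed = 21)
  expect_equal(multi$restart_objectives[1], one$objective$total)
  expect_equal(multi$objective$total, min(multi$restart_objectives))
  expect_equal(multi$seed_used,
               20 + which.min(multi$restart_objectives))
})

test_that("MMD-only objective starting at a shared optimum stays there", {
  K <- random_kernel(15, 44)
  # lambda1 = lambda2 = 0 and alpha1 = alpha2 with K1 = K2: MMD is 0, a
  # global minimum, and gradients vanish identically
  a <- random_alpha(15, 2, 45)
  # gradients at the optimum are pure cancellation noise (~1e-17); Adam's
  # normalization can amplify them, so "stays" means float-noise scale
  r <- mmdma:::.adam_optimize_cpp(K, K, a, a, 0.5, 0, 0, 1e-3, 100L, 10L,
                                  0.9, 0.999, 1e-8)
  expect_equal(r$final$total, 0, tolerance = 1e-8)
  expect_lt(max(abs(r$trace$total)), 1e-4)
  g <- mmdma:::.mmdma_gradient_cpp(K, K, a, a, 0.5, 0, 0)
  expect_lt(max(abs(g$g1)), 1e-12)
})

test_that("exchanging the two domains yields matching objective spreads", {
  pr <- small_problem(n = 20, p = 2, seed = 17)
  K2 <- random_kernel(26, 18)  # different sizes on purpose
  direct <- swapped <- numeric(5)
  for (k in 1:5) {
    fd <- mmdma(pr$K1, K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
                sigma = 0.7, n_iterations = 300, n_restarts = 1,
                seed = 30 + k)
    fs <- mmdma(K2, pr$K1, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
                sigma = 0.7, n_iterations = 300, n_restarts = 1,
                seed = 30 + k)
    direct[k] <- fd$objective$total
    swapped[k] <- fs$objective$total
  }
  # statistical agreement of the attained objective distributions
  spread <- sd(c(direct, swapped)) + 0.01
  expect_lt(abs(mean(direct) - mean(swapped)), spread)
  expect_lt(abs(median(direct) - median(swapped)), spread)
})

test_that("the pure-R optimizer path mirrors the compiled one", {
  pr <- small_problem(n = 12, p = 2, seed = 23)
  a1 <- random_alpha(12, 2, 1); a2 <- random_alpha(12, 2, 2)
  rc <- mmdma:::.adam_optimize_cpp(pr$K1, pr$K2, a1, a2, 0.8, 1e-3, 1e-3,
                                   1e-3, 50L, 10L, 0.9, 0.999, 1e-8)
  rr <- mmdma:::adam_r(pr$K1, pr$K2, a1, a2, 0.8, 1e-3, 1e-3, 1e-3, 50L,
                       10L, 0.9, 0.999, 1e-8, "quadratic")
  expect_equal(rr$alpha1, rc$alpha1, tolerance = 1e-10)
  expect_equal(rr$trace$total, rc$trace$total, tolerance = 1e-10)
})

test_that("linear-estimator fits run through the pure-R path", {
  pr <- small_problem(n = 16, p = 2, seed = 29)
  fit <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
               sigma = 0.8, n_iterations = 60, n_restarts = 1, seed = 2,
               estimator = "linear", trace_every = 20)
  expect_s3_class(fit, "mmdma")
  expect_lte(min(fit$trace$total), fit$trace$total[1] + 1e-8)
})

test_that("fit methods expose coefficients, embeddings and predictions", {
  pr <- small_problem(n = 18, p = 2, seed = 31)
  fit <- mmdma(pr$K1, pr$K2, p = 2, lambda1 = 1e-4, lambda2 = 1e-3,
               sigma = 0.8, n_iterations = 100, n_restarts = 1, seed = 5)
  expect_named(coef(fit), c("alpha1", "alpha2"))
  expect_equal(coef(fit, domain = 2), fit$alpha2)
  expect_equal(fitted(fit, domain = 1), fit$embedding1)
  # embedding training cells through predict reproduces fitted values
  expect_equal(predict(fit, pr$K1, domain = 1), fit$embedding1,
               ignore_attr = TRUE)
  expect_error(predict(fit, matrix(0, 2, 5), domain = 1), "columns")
  expect_output(print(fit), "manifold alignment")
  expect_output(print(summary(fit)), "Hyperparameters")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, type = "trace"))
  expect_silent(plot(fit, type = "embedding"))
})

test_that("multi-domain alignment generalizes the pairwise objective", {
  set.seed(50)
  Ks <- lapply(1:3, function(i) random_kernel(15, 60 + i))
  fit <- mmdma_multi(Ks, p = 2, lambda1 = 1e-3, lambda2 = 1e-3, sigma = 0.8,
                     learning_rate = 1e-3, n_iterations = 150,
                     n_restarts = 1, seed = 3, trace_every = 50)
  expect_length(fit$embeddings, 3)
  expect_lt(min(fit$trace$total), fit$trace$total[1])
  # total matches a hand assembly of pairwise MMD plus per-domain terms
  U <- fit$embeddings
  mmd <- mmd_squared(U[[1]], U[[2]], 0.8) + mmd_squared(U[[1]], U[[3]], 0.8) +
    mmd_squared(U[[2]], U[[3]], 0.8)
  pen <- sum(sapply(1:3, function(i) penalty_term(fit$alphas[[i]], Ks[[i]])))
  dis <- sum(sapply(1:3, function(i) distortion_term(fit$alphas[[i]], Ks[[i]])))
  expect_equal(fit$total, mmd + 1e-3 * pen + 1e-3 * dis, tolerance = 1e-8)
  # with two domains the multi-domain objective is the standard one
  fit2 <- mmdma_multi(Ks[1:2], p = 2, lambda1 = 1e-3, lambda2 = 1e-3,
                      sigma = 0.8, learning_rate = 1e-3, n_iterations = 50,
                      n_restarts = 1, seed = 3, trace_every = 25)
  o <- mmdma_objective(fit2$alphas[[1]], fit2$alphas[[2]], Ks[[1]], Ks[[2]],
                       1e-3, 1e-3, 0.8)
  expect_equal(fit2$total, o$total, tolerance = 1e-10)
})

test_that("invalid hyperparameters are rejected", {
  pr <- small_problem(n = 10, p = 2, seed = 40)
  expect_error(mmdma(pr$K1, pr$K2, sigma = 0), "sigma")
  expect_error(mmdma(pr$K1, pr$K2, lambda1 = -1), "lambda1")
  expect_error(mmdma(pr$K1, pr$K2, p = 0), "p")
  expect_error(mmdma(pr$K1, matrix(1, 3, 4)), "square")
  expect_warning(mmdma(pr$K1, pr$K2, p = 50, n_iterations = 1,
                       n_restarts = 1), "exceeds")
})
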