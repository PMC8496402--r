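#' Random initial coefficient matrix
#'
#' Draws an n-by-p matrix with i.i.d. zero-mean Gaussian entries of
#' standard deviation `1/sqrt(n)`, so initial embeddings `K %*% alpha` have
#' O(1) coordinates regardless of the number of cells. Deterministic given
#' the seed; the caller's RNG state is untouched.
#'
#' @param n Number of cells (rows).
#' @param p Latent dimensionality (columns).
#' @param seed Integer seed.
#' @return An n-by-p numeric matrix.
#' @export
init_alpha <- function(n, p, seed) {
  check_scalar(n, "n", positive = TRUE, integer = TRUE)
  check_scalar(p, "p", positive = TRUE, integer = TRUE)
  with_seed(seed, matrix(rnorm(n * p, sd = 1 / sqrt(n)), n, p))
}

## Pure-R Adam loop; reference/fallback path (linear MMD estimator).
## Mirrors the compiled loop including trace layout.
adam_r <- function(K1, K2, a1, a2, sigma, lambda1, lambda2, lr, n_iter,
                   trace_every, beta1, beta2, eps, estimator) {
  m1 <- v1 <- a1 * 0; m2 <- v2 <- a2 * 0
  rec <- list()
  obj <- function(x1, x2)
    mmdma_objective(x1, x2, K1, K2, lambda1, lambda2, sigma,
                    estimator = estimator)
  finite <- TRUE
  it_done <- 0L
  for (it in seq_len(n_iter)) {
    o <- obj(a1, a2)
    if (!is.finite(o$total)) { finite <- FALSE; break }
    if ((it - 1L) %% trace_every == 0L)
      rec[[length(rec) + 1L]] <- c(it - 1L, o$total, o$mmd2,
                                   o$pen1 + o$pen2, o$dis1 + o$dis2)
    g <- mmdma_gradient(a1, a2, K1, K2, lambda1, lambda2, sigma,
                        estimator = estimator)
    m1 <- beta1 * m1 + (1 - beta1) * g$g1
    v1 <- beta2 * v1 + (1 - beta2) * g$g1^2
    m2 <- beta1 * m2 + (1 - beta1) * g$g2
    v2 <- beta2 * v2 + (1 - beta2) * g$g2^2
    bc1 <- 1 - beta1^it; bc2 <- 1 - beta2^it
    a1 <- a1 - lr * (m1 / bc1) / (sqrt(v1 / bc2) + eps)
    a2 <- a2 - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps)
    it_done <- it
  }
  fin <- obj(a1, a2)
  if (finite && is.finite(fin$total))
    rec[[length(rec) + 1L]] <- c(n_iter, fin$total, fin$mmd2,
                                 fin$pen1 + fin$pen2, fin$dis1 + fin$dis2)
  else finite <- FALSE
  tr <- do.call(rbind, rec)
  trace <- if (is.null(tr)) data.frame(iteration = numeric(0),
                                       total = numeric(0), mmd2 = numeric(0),
                                       penalty = numeric(0),
                                       distortion = numeric(0))
           else data.frame(iteration = tr[, 1], total = tr[, 2],
                           mmd2 = tr[, 3], penalty = tr[, 4],
                           distortion = tr[, 5])
  list(alpha1 = a1, alpha2 = a2, finite = finite,
       iterations_run = it_done,
       final = fin[c("total", "mmd2", "pen1", "pen2", "dis1", "dis2")],
       trace = trace)
}

## One optimization run from a seeded random start.
optimize_once <- function(K1, K2, p, lambda1, lambda2, sigma, learning_rate,
                          n_iterations, trace_every, seed, estimator,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  sub <- derive_seeds(seed, 2L)
  a1 <- init_alpha(nrow(K1), p, sub[1])
  a2 <- init_alpha(nrow(K2), p, sub[2])
  res <- if (estimator == "quadratic")
    .adam_optimize_cpp(K1, K2, a1, a2, sigma, lambda1, lambda2,
                       learning_rate, as.integer(n_iterations),
                       as.integer(trace_every), beta1, beta2, eps)
  else
    adam_r(K1, K2, a1, a2, sigma, lambda1, lambda2, learning_rate,
           n_iterations, trace_every, beta1, beta2, eps, estimator)
  res$seed_used <- seed
  res
}

#' Fit an unsupervised two-domain alignment
#'
#' Learns kernel-expansion coefficient matrices `alpha1`, `alpha2` mapping
#' the cells of two independently measured domains into a shared
#' p-dimensional latent space, by minimizing
#' \deqn{MMD^2(K_1\alpha_1, K_2\alpha_2) +
#'       \lambda_1(pen(\alpha_1) + pen(\alpha_2)) +
#'       \lambda_2(dis(\alpha_1) + dis(\alpha_2))}
#' with Adam gradient descent. The objective is non-convex, so the
#' optimization is restarted from `n_restarts` seeded random
#' initializations (seeds `seed, seed + 1, ...`) and the solution with the
#' lowest final objective is kept. Everything is deterministic given
#' `seed` and the configuration.
#'
#' No correspondence between cells or features of the two domains is used;
#' the only assumption is that both kernels reflect a shared latent
#' structure with enough geometric variability for the distributions to be
#' matched. Choose `lambda1`, `lambda2` so the three objective components
#' (reported by `summary()`) have comparable magnitudes at convergence.
#'
#' @param k1,k2 Symmetric kernel Gram matrices for the two domains (e.g.
#'   from [linear_kernel()] or [load_kernel()]); they may have different
#'   sizes.
#' @param p Latent dimensionality.
#' @param lambda1 Weight of the orthogonality penalty ([penalty_term()]).
#' @param lambda2 Weight of the distortion term ([distortion_term()]).
#' @param sigma Bandwidth of the Gaussian MMD kernel in the latent space.
#' @param learning_rate Adam step size.
#' @param n_iterations Gradient steps per restart.
#' @param n_restarts Number of seeded random restarts.
#' @param seed Master integer seed.
#' @param estimator MMD estimator, `"quadratic"` (exact V-statistic,
#'   default) or `"linear"` (streaming approximation; optimized via the
#'   pure-R path).
#' @param trace_every Record objective components every this many
#'   iterations (iteration 0 and the final iterate are always recorded).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabilizer.
#' @param verbose Print a line per restart.
#' @return An object of class `"mmdma"` with components `alpha1`, `alpha2`
#'   (coefficients of the best restart), `embedding1`, `embedding2`
#'   (`K %*% alpha`), `objective` (an [mmdma_objective()] breakdown),
#'   `trace` (data.frame of objective components along the best run),
#'   `seed_used`, `restart_objectives`, `failed_restarts`, the matched
#'   call and the full hyperparameter list.
#' @examples
#' sim <- mmdma_simulation("branch", n = 60, p1 = 40, p2 = 50, seed = 3)
#' K1 <- linear_kernel(z_normalize(sim$X1))
#' K2 <- linear_kernel(z_normalize(sim$X2))
#' fit <- mmdma(K1, K2, n_iterations = 200, n_restarts = 2, seed = 1)
#' fit
#' foscttm(fitted(fit)$embedding1, fitted(fit)$embedding2)$average
#' @export
mmdma <- function(k1, k2, p = 5L, lambda1 = 1e-6, lambda2 = 1e-2,
                  sigma = 0.5, learning_rate = 5e-4, n_iterations = 10000L,
                  n_restarts = 100L, seed = 1L,
                  estimator = c("quadratic", "linear"), trace_every = 100L,
                  adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
                  verbose = FALSE) {
  estimator <- match.arg(estimator)
  k1 <- as_kernel(k1); k2 <- as_kernel(k2)
  check_scalar(p, "p", positive = TRUE, integer = TRUE)
  check_scalar(lambda1, "lambda1", nonneg = TRUE)
  check_scalar(lambda2, "lambda2", nonneg = TRUE)
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(learning_rate, "learning_rate", positive = TRUE)
  check_scalar(n_iterations, "n_iterations", positive = TRUE, integer = TRUE)
  check_scalar(n_restarts, "n_restarts", positive = TRUE, integer = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (p > min(nrow(k1), nrow(k2)))
    warning("latent dimension p exceeds the number of cells", call. = FALSE)

  best <- NULL
  finals <- rep(NA_real_, n_restarts)
  failed <- integer(0)
  for (k in seq_len(n_restarts)) {
    s <- seed + k - 1L
    run <- optimize_once(k1, k2, p, lambda1, lambda2, sigma, learning_rate,
                         n_iterations, trace_every, s, estimator,
                         adam_beta1, adam_beta2, adam_eps)
    if (!run$finite) {
      warning(sprintf(
        "restart with seed %d diverged (non-finite objective at iteration %d)",
        s, run$iterations_run), call. = FALSE)
      failed <- c(failed, s)
      next
    }
    finals[k] <- run$final$total
    if (verbose)
      message(sprintf("restart %d/%d (seed %d): final objective %.6g",
                      k, n_restarts, s, run$final$total))
    if (is.null(best) || run$final$total < best$final$total) best <- run
  }
  if (is.null(best))
    stop("all restarts diverged to a non-finite objective; ",
         "reduce the learning rate", call. = FALSE)

  obj <- structure(list(total = best$final$total, mmd2 = best$final$mmd2,
                        pen1 = best$final$pen1, pen2 = best$final$pen2,
                        dis1 = best$final$dis1, dis2 = best$final$dis2,
                        lambda1 = lambda1, lambda2 = lambda2),
                   class = "mmdma_objective")
  e1 <- embed(k1, best$alpha1); e2 <- embed(k2, best$alpha2)
  rownames(e1) <- rownames(k1); rownames(e2) <- rownames(k2)
  structure(list(
    alpha1 = best$alpha1, alpha2 = best$alpha2,
    embedding1 = e1, embedding2 = e2,
    objective = obj, trace = best$trace,
    seed_used = best$seed_used, restart_objectives = finals,
    failed_restarts = failed,
    hyperparameters = list(p = p, lambda1 = lambda1, lambda2 = lambda2,
                           sigma = sigma, learning_rate = learning_rate,
                           n_iterations = n_iterations,
                           n_restarts = n_restarts, seed = seed,
                           estimator = estimator, trace_every = trace_every,
                           adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                           adam_eps = adam_eps),
    n1 = nrow(k1), n2 = nrow(k2),
    call = match.call()), class = "mmdma")
}

#' @export
print.mmdma <- function(x, ...) {
  hp <- x$hyperparameters
  cat("Unsupervised kernel manifold alignment\n")
  cat(sprintf("  %d + %d cells embedded in %d latent dimensions\n",
              x$n1, x$n2, hp$p))
  cat(sprintf("  best of %d restart(s) (seed %d): objective %.6g\n",
              hp$n_restarts, x$seed_used, x$objective$total))
  cat(sprintf("  MMD^2 %.4g | penalty %.4g | distortion %.4g\n",
              x$objective$mmd2, x$objective$pen1 + x$objective$pen2,
              x$objective$dis1 + x$objective$dis2))
  invisible(x)
}

#' @export
summary.mmdma <- function(object, ...) {
  structure(list(fit = object), class = "summary.mmdma")
}

#' @export
print.summary.mmdma <- function(x, ...) {
  f <- x$fit; hp <- f$hyperparameters
  print(f)
  cat(sprintf("\nHyperparameters: lambda1 = %.3g, lambda2 = %.3g, sigma = %.3g\n",
              hp$lambda1, hp$lambda2, hp$sigma))
  cat(sprintf("Optimizer: Adam, lr %.3g, %d iterations, %s MMD estimator\n",
              hp$learning_rate, hp$n_iterations, hp$estimator))
  ok <- f$restart_objectives[is.finite(f$restart_objectives)]
  if (length(ok) > 1L)
    cat(sprintf("Restart final objectives: min %.6g, median %.6g, max %.6g\n",
                min(ok), stats::median(ok), max(ok)))
  if (length(f$failed_restarts))
    cat(sprintf("Diverged restarts: %d\n", length(f$failed_restarts)))
  cat("\nObjective components of the kept solution:\n")
  print(f$objective)
  invisible(x)
}

#' Extract coefficient matrices from an alignment fit
#'
#' @param object An object of class `"mmdma"`.
#' @param domain 1, 2 or `NULL` (both, as a list).
#' @param ... Unused.
#' @return A matrix, or a list of two matrices.
#' @export
coef.mmdma <- function(object, domain = NULL, ...) {
  if (is.null(domain)) list(alpha1 = object$alpha1, alpha2 = object$alpha2)
  else if (domain == 1) object$alpha1
  else if (domain == 2) object$alpha2
  else stop("domain must be 1 or 2", call. = FALSE)
}

#' Extract latent embeddings from an alignment fit
#'
#' @inheritParams coef.mmdma
#' @return A matrix of latent coordinates, or a list of two.
#' @export
fitted.mmdma <- function(object, domain = NULL, ...) {
  if (is.null(domain))
    list(embedding1 = object$embedding1, embedding2 = object$embedding2)
  else if (domain == 1) object$embedding1
  else if (domain == 2) object$embedding2
  else stop("domain must be 1 or 2", call. = FALSE)
}

#' Embed new cells with a fitted alignment
#'
#' Maps held-out cells of one domain into the learned latent space. The
#' mapping is the kernel expansion over the training cells, so all that is
#' needed is the cross-kernel between the new cells and the cells the
#' model was fitted on (same kernel function, same preprocessing).
#'
#' @param object An object of class `"mmdma"`.
#' @param k_new m-by-n matrix of kernel values between the m new cells
#'   (rows) and the n training cells of `domain`.
#' @param domain Which domain the new cells belong to (1 or 2).
#' @param ... Unused.
#' @return An m-by-p matrix of latent coordinates.
#' @export
predict.mmdma <- function(object, k_new, domain = 1, ...) {
  check_matrix(k_new)
  alpha <- coef(object, domain = domain)
  if (ncol(k_new) != nrow(alpha))
    stop(sprintf("k_new must have %d columns (one per training cell)",
                 nrow(alpha)), call. = FALSE)
  k_new %*% alpha
}

#' Plot an alignment fit
#'
#' `type = "trace"` draws the objective components along the kept
#' optimization run (log-scaled y axis); `type = "embedding"` draws the
#' two aligned point clouds in two selected latent dimensions.
#'
#' @param x An object of class `"mmdma"`.
#' @param type `"trace"` or `"embedding"`.
#' @param dims Length-2 integer vector of latent dimensions to draw when
#'   `type = "embedding"`.
#' @param ... Passed on to the underlying plotting calls.
#' @export
plot.mmdma <- function(x, type = c("trace", "embedding"), dims = c(1, 2),
                       ...) {
  type <- match.arg(type)
  if (type == "trace") {
    tr <- x$trace
    keep <- tr$total > 0
    graphics::plot(tr$iteration[keep], tr$total[keep], type = "l", log = "y",
                   xlab = "iteration", ylab = "objective (log scale)",
                   col = "black", ...)
    pos <- function(v) ifelse(v > 0, v, NA)
    graphics::lines(tr$iteration, pos(tr$mmd2), col = "firebrick")
    graphics::lines(tr$iteration, pos(x$objective$lambda1 * tr$penalty),
                    col = "steelblue")
    graphics::lines(tr$iteration, pos(x$objective$lambda2 * tr$distortion),
                    col = "darkgreen")
    graphics::legend("topright", bty = "n", lty = 1,
                     col = c("black", "firebrick", "steelblue", "darkgreen"),
                     legend = c("total", "MMD^2", "lambda1 * penalty",
                                "lambda2 * distortion"))
  } else {
    e1 <- x$embedding1[, dims, drop = FALSE]
    e2 <- x$embedding2[, dims, drop = FALSE]
    rng <- apply(rbind(e1, e2), 2, range)
    graphics::plot(e1, xlim = rng[, 1], ylim = rng[, 2], pch = 1,
                   col = "firebrick",
                   xlab = sprintf("latent dim %d", dims[1]),
                   ylab = sprintf("latent dim %d", dims[2]), ...)
    graphics::points(e2, pch = 3, col = "steelblue")
    graphics::legend("topright", bty = "n", pch = c(1, 3),
                     col = c("firebrick", "steelblue"),
                     legend = c("domain 1", "domain 2"))
  }
  invisible(x)
}

#' Per-checkpoint objective trace of a fit
#'
#' @param object An object of class `"mmdma"`.
#' @param ... Unused.
#' @return A data.frame with columns `iteration`, `total`, `mmd2`,
#'   `penalty`, `distortion` for the kept restart.
#' @export
trace_of <- function(object, ...) {
  stopifnot(inherits(object, "mmdma"))
  object$trace
}
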