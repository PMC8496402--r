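#' Align more than two domains
#'
#' Extension of [mmdma()] to an arbitrary number of domains: the objective
#' becomes the sum of the squared MMD over all pairs of embedded domains
#' plus per-domain penalty and distortion terms,
#' \deqn{\sum_{a<b} MMD^2(K_a\alpha_a, K_b\alpha_b) +
#'       \lambda_1 \sum_a pen(\alpha_a) + \lambda_2 \sum_a dis(\alpha_a).}
#' With exactly two domains this is the standard two-domain objective.
#' The optimization runs through a pure-R Adam loop, which is adequate for
#' the modest numbers of cells where more than two unmatched modalities
#' are typically integrated.
#'
#' @param kernels List (length >= 2) of symmetric kernel Gram matrices.
#' @inheritParams mmdma
#' @return An object of class `"mmdma_multi"`: a list with `alphas` and
#'   `embeddings` (lists, one element per domain), `total` (final
#'   objective), `trace`, `seed_used`, `restart_objectives` and the
#'   hyperparameter list.
#' @export
mmdma_multi <- function(kernels, p = 5L, lambda1 = 1e-6, lambda2 = 1e-2,
                        sigma = 0.5, learning_rate = 5e-4,
                        n_iterations = 2000L, n_restarts = 1L, seed = 1L,
                        trace_every = 100L, adam_beta1 = 0.9,
                        adam_beta2 = 0.999, adam_eps = 1e-8) {
  if (!is.list(kernels) || length(kernels) < 2L)
    stop("'kernels' must be a list of at least two kernel matrices",
         call. = FALSE)
  kernels <- lapply(kernels, as_kernel)
  d <- length(kernels)
  pairs <- utils::combn(d, 2L)

  objective_and_grad <- function(alphas) {
    U <- Map(embed, kernels, alphas)
    g <- lapply(U, function(u) u * 0)
    mmd2 <- 0
    for (q in seq_len(ncol(pairs))) {
      a <- pairs[1L, q]; b <- pairs[2L, q]
      mmd2 <- mmd2 + mmd_squared(U[[a]], U[[b]], sigma)
      gp <- mmd_gradient_embeddings(U[[a]], U[[b]], sigma)
      g[[a]] <- g[[a]] + gp$gU1
      g[[b]] <- g[[b]] + gp$gU2
    }
    pen <- dis <- 0
    galpha <- vector("list", d)
    for (a in seq_len(d)) {
      K <- kernels[[a]]; B <- U[[a]]
      M <- crossprod(alphas[[a]], B); diag(M) <- diag(M) - 1
      C <- K %*% B
      pen <- pen + sum(M^2)
      dis <- dis + sum(K^2) - 2 * sum(B * C) + sum(crossprod(B)^2)
      galpha[[a]] <- K %*% g[[a]] + lambda1 * 4 * (B %*% M) -
        lambda2 * 4 * (K %*% C - C %*% crossprod(B))
    }
    list(total = mmd2 + lambda1 * pen + lambda2 * dis,
         mmd2 = mmd2, pen = pen, dis = dis, g = galpha)
  }

  run_one <- function(s) {
    sub <- derive_seeds(s, d)
    alphas <- Map(function(K, sd) init_alpha(nrow(K), p, sd), kernels,
                  as.list(sub))
    m <- lapply(alphas, function(a) a * 0)
    v <- lapply(alphas, function(a) a * 0)
    rec <- list()
    for (it in seq_len(n_iterations)) {
      og <- objective_and_grad(alphas)
      if (!is.finite(og$total)) return(list(finite = FALSE, seed_used = s))
      if ((it - 1L) %% trace_every == 0L)
        rec[[length(rec) + 1L]] <- c(it - 1L, og$total, og$mmd2, og$pen,
                                     og$dis)
      for (a in seq_len(d)) {
        m[[a]] <- adam_beta1 * m[[a]] + (1 - adam_beta1) * og$g[[a]]
        v[[a]] <- adam_beta2 * v[[a]] + (1 - adam_beta2) * og$g[[a]]^2
        alphas[[a]] <- alphas[[a]] -
          learning_rate * (m[[a]] / (1 - adam_beta1^it)) /
            (sqrt(v[[a]] / (1 - adam_beta2^it)) + adam_eps)
      }
    }
    og <- objective_and_grad(alphas)
    if (!is.finite(og$total)) return(list(finite = FALSE, seed_used = s))
    rec[[length(rec) + 1L]] <- c(n_iterations, og$total, og$mmd2, og$pen,
                                 og$dis)
    tr <- do.call(rbind, rec)
    list(finite = TRUE, alphas = alphas, total = og$total, seed_used = s,
         trace = data.frame(iteration = tr[, 1], total = tr[, 2],
                            mmd2 = tr[, 3], penalty = tr[, 4],
                            distortion = tr[, 5]))
  }

  best <- NULL
  finals <- rep(NA_real_, n_restarts)
  for (k in seq_len(n_restarts)) {
    run <- run_one(seed + k - 1L)
    if (!run$finite) {
      warning(sprintf("restart with seed %d diverged", seed + k - 1L),
              call. = FALSE)
      next
    }
    finals[k] <- run$total
    if (is.null(best) || run$total < best$total) best <- run
  }
  if (is.null(best))
    stop("all restarts diverged to a non-finite objective", call. = FALSE)
  structure(list(alphas = best$alphas,
                 embeddings = Map(embed, kernels, best$alphas),
                 total = best$total, trace = best$trace,
                 seed_used = best$seed_used, restart_objectives = finals,
                 hyperparameters = list(p = p, lambda1 = lambda1,
                                        lambda2 = lambda2, sigma = sigma,
                                        learning_rate = learning_rate,
                                        n_iterations = n_iterations,
                                        n_restarts = n_restarts,
                                        seed = seed)),
            class = "mmdma_multi")
}

#' @export
print.mmdma_multi <- function(x, ...) {
  cat(sprintf("Multi-domain kernel manifold alignment: %d domains (%s cells)\n",
              length(x$alphas),
              paste(vapply(x$alphas, nrow, 1L), collapse = " + ")))
  cat(sprintf("  final objective %.6g (seed %d)\n", x$total, x$seed_used))
  invisible(x)
}
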