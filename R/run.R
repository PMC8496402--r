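## File-based workflow: each run_* function reads/writes delimited text and
## records a JSON manifest from which the run can be reproduced exactly.

write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic benchmark and write it to disk
#'
#' Runs [mmdma_simulation()] and writes `X1.tsv`, `X2.tsv`, `Z.tsv`,
#' `labels.tsv` and a `manifest.json` recording every parameter and seed,
#' so the data set can be regenerated exactly.
#'
#' @param out_dir Output directory (created if missing).
#' @inheritParams mmdma_simulation
#' @return Invisibly, the simulated data set.
#' @export
run_simulate <- function(out_dir, type = "branch", n = 300L, p1 = 1000L,
                         p2 = 2000L, noise_sigma = 0.05, seed = 1L,
                         jitter = 0.02) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- mmdma_simulation(type, n = n, p1 = p1, p2 = p2,
                          noise_sigma = noise_sigma, seed = seed,
                          jitter = jitter)
  write_matrix(sim$X1, file.path(out_dir, "X1.tsv"))
  write_matrix(sim$X2, file.path(out_dir, "X2.tsv"))
  write_matrix(sim$Z, file.path(out_dir, "Z.tsv"), rownames = FALSE)
  write.table(sim$labels, file.path(out_dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(list(command = "simulate", type = sim$type, n = n, p1 = p1,
                      p2 = p2, noise_sigma = noise_sigma, jitter = jitter,
                      seed = seed),
                 file.path(out_dir, "manifest.json"))
  invisible(sim)
}

#' Fit an alignment from matrices on disk
#'
#' Reads either two observation matrices (`x1`/`x2`; z-normalized per
#' feature and turned into linear kernels) or two precomputed kernel
#' matrices (`k1`/`k2`), fits [mmdma()], and writes `alpha1.tsv`,
#' `alpha2.tsv`, `embedding1.tsv`, `embedding2.tsv`, `trace.tsv`, an
#' `objective.json` summary and a `manifest.json` with the resolved
#' configuration.
#'
#' @param out_dir Output directory (created if missing).
#' @param x1,x2 Paths to cells-by-features observation matrices (TSV/CSV).
#' @param k1,k2 Paths to precomputed square kernel matrices; provide
#'   either both `x` paths or both `k` paths, not a mixture.
#' @param kernel_scale Passed to [linear_kernel()] when building kernels
#'   from observations.
#' @inheritParams mmdma
#' @return Invisibly, the fitted `"mmdma"` object.
#' @export
run_fit <- function(out_dir, x1 = NULL, x2 = NULL, k1 = NULL, k2 = NULL,
                    p = 5L, lambda1 = 1e-6, lambda2 = 1e-2, sigma = 0.5,
                    learning_rate = 5e-4, n_iterations = 10000L,
                    n_restarts = 100L, seed = 1L, estimator = "quadratic",
                    trace_every = 100L, kernel_scale = "features",
                    verbose = FALSE) {
  use_x <- !is.null(x1) || !is.null(x2)
  use_k <- !is.null(k1) || !is.null(k2)
  if (use_x == use_k || (use_x && (is.null(x1) || is.null(x2))) ||
      (use_k && (is.null(k1) || is.null(k2))))
    stop("provide exactly one complete input pair: (x1, x2) or (k1, k2)",
         call. = FALSE)
  if (use_x) {
    K1 <- linear_kernel(z_normalize(read_matrix(x1)), scale = kernel_scale)
    K2 <- linear_kernel(z_normalize(read_matrix(x2)), scale = kernel_scale)
  } else {
    K1 <- load_kernel(k1)
    K2 <- load_kernel(k2)
  }
  fit <- mmdma(K1, K2, p = p, lambda1 = lambda1, lambda2 = lambda2,
               sigma = sigma, learning_rate = learning_rate,
               n_iterations = n_iterations, n_restarts = n_restarts,
               seed = seed, estimator = estimator,
               trace_every = trace_every, verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(fit$alpha1, file.path(out_dir, "alpha1.tsv"),
               rownames = FALSE)
  write_matrix(fit$alpha2, file.path(out_dir, "alpha2.tsv"),
               rownames = FALSE)
  write_matrix(fit$embedding1, file.path(out_dir, "embedding1.tsv"))
  write_matrix(fit$embedding2, file.path(out_dir, "embedding2.tsv"))
  write.table(fit$trace, file.path(out_dir, "trace.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(unclass(fit$objective), file.path(out_dir, "objective.json"))
  write_manifest(c(list(command = "fit",
                        inputs = if (use_x) list(x1 = x1, x2 = x2)
                                 else list(k1 = k1, k2 = k2),
                        kernel_scale = if (use_x) kernel_scale else NULL,
                        seed_used = fit$seed_used),
                   fit$hyperparameters),
                 file.path(out_dir, "manifest.json"))
  invisible(fit)
}

#' Evaluate alignment quality of embeddings on disk
#'
#' Reads two embedding matrices, computes [foscttm()] under the identity
#' (row-order) correspondence or one read from a two-column TSV, and
#' writes `foscttm_per_point.tsv` and `foscttm_summary.tsv`.
#'
#' @param out_dir Output directory (created if missing).
#' @param embedding1,embedding2 Paths to latent coordinate matrices.
#' @param correspondence Optional path to a headerless two-column TSV of
#'   matched (row in domain 1, row in domain 2) indices; `NULL` uses the
#'   identity correspondence.
#' @return Invisibly, the `"foscttm"` object.
#' @export
run_eval <- function(out_dir, embedding1, embedding2,
                     correspondence = NULL) {
  e1 <- read_matrix(embedding1)
  e2 <- read_matrix(embedding2)
  corr <- if (!is.null(correspondence)) read_matrix(correspondence)
  res <- foscttm(e1, e2, corr)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(res$per_point, file.path(out_dir, "foscttm_per_point.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary_df <- data.frame(mean_domain1 = res$mean1,
                           mean_domain2 = res$mean2,
                           average = res$average,
                           n_unmatched1 = res$n_unmatched[1],
                           n_unmatched2 = res$n_unmatched[2])
  write.table(summary_df, file.path(out_dir, "foscttm_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Plot fit artifacts from disk
#'
#' Convenience visualization of a [run_fit()] output directory: draws the
#' aligned embeddings (first two latent dimensions) and the objective
#' trace into a PDF.
#'
#' @param fit_dir Directory written by [run_fit()].
#' @param file Output PDF path; defaults to `plots.pdf` inside `fit_dir`.
#' @return Invisibly, the output path.
#' @export
run_plot <- function(fit_dir, file = file.path(fit_dir, "plots.pdf")) {
  e1 <- read_matrix(file.path(fit_dir, "embedding1.tsv"))
  e2 <- read_matrix(file.path(fit_dir, "embedding2.tsv"))
  tr <- read.table(file.path(fit_dir, "trace.tsv"), header = TRUE,
                   sep = "\t")
  grDevices::pdf(file, width = 10, height = 5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  rng <- apply(rbind(e1[, 1:2], e2[, 1:2]), 2, range)
  graphics::plot(e1[, 1:2], xlim = rng[, 1], ylim = rng[, 2], pch = 1,
                 col = "firebrick", xlab = "latent dim 1",
                 ylab = "latent dim 2", main = "aligned embeddings")
  graphics::points(e2[, 1:2], pch = 3, col = "steelblue")
  keep <- tr$total > 0
  graphics::plot(tr$iteration[keep], tr$total[keep], type = "l", log = "y",
                 xlab = "iteration", ylab = "objective",
                 main = "optimization trace")
  invisible(file)
}
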