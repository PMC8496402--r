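#' Fraction of samples closer than the true match (FOSCTTM)
#'
#' Given latent embeddings of two domains and a known 1-to-1 cell
#' correspondence, computes for each matched cell the fraction of cells in
#' the *other* domain that are embedded strictly closer (Euclidean) than
#' its true counterpart. Fractions are averaged within each domain and the
#' two domain means are averaged into a single summary. Perfect alignment
#' gives 0; unrelated embeddings give about 0.5.
#'
#' The strict-closer count is divided by `n_other - 1`, so the metric spans
#' exactly \[0, 1\]: 0 when every cell's nearest other-domain neighbour is
#' its true match, 1 when the true match is always the farthest point.
#' Ties in distance count as "not closer". Cells absent from the
#' correspondence are excluded from the averages and reported in the
#' `n_unmatched` field.
#'
#' @param e1,e2 Numeric matrices of latent coordinates (cells in rows) with
#'   the same number of columns.
#' @param correspondence Two-column integer matrix of matched (row in
#'   `e1`, row in `e2`) pairs; `NULL` (default) uses the identity
#'   correspondence by row order, which requires `nrow(e1) == nrow(e2)`.
#' @return An object of class `"foscttm"`: a list with `per_point` (a
#'   data.frame with columns `domain`, `index`, `match`, `fraction`),
#'   per-domain means `mean1` and `mean2`, their average `average`, and
#'   `n_unmatched = c(domain1, domain2)`.
#' @examples
#' e <- matrix(rnorm(40), 20, 2)
#' foscttm(e, e)$average            # perfectly aligned -> 0
#' @export
foscttm <- function(e1, e2, correspondence = NULL) {
  check_matrix(e1); check_matrix(e2)
  if (ncol(e1) != ncol(e2))
    stop(sprintf("latent dimensions differ: %d vs %d", ncol(e1), ncol(e2)),
         call. = FALSE)
  n1 <- nrow(e1); n2 <- nrow(e2)
  if (is.null(correspondence)) {
    if (n1 != n2)
      stop("identity correspondence needs equal numbers of cells", call. = FALSE)
    correspondence <- cbind(seq_len(n1), seq_len(n1))
  }
  correspondence <- as.matrix(correspondence)
  if (ncol(correspondence) != 2L || nrow(correspondence) < 1L)
    stop("correspondence must be a non-empty two-column matrix", call. = FALSE)
  storage.mode(correspondence) <- "integer"
  i1 <- correspondence[, 1L]; i2 <- correspondence[, 2L]
  if (any(i1 < 1L | i1 > n1) || any(i2 < 1L | i2 > n2))
    stop("correspondence indices out of range", call. = FALSE)
  if (anyDuplicated(i1) || anyDuplicated(i2))
    stop("each cell may appear at most once in the correspondence", call. = FALSE)
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 cells per domain", call. = FALSE)

  ## squared distances preserve the ordering used by the strict comparison
  D <- cross_sqdist(e1, e2)
  dtrue <- D[cbind(i1, i2)]
  f1 <- (rowSums(D[i1, , drop = FALSE] < dtrue) ) / (n2 - 1L)
  f2 <- (colSums(D[, i2, drop = FALSE] < rep(dtrue, each = n1))) / (n1 - 1L)
  per_point <- data.frame(
    domain = rep(1:2, each = length(i1)),
    index = c(i1, i2),
    match = c(i2, i1),
    fraction = c(f1, f2))
  structure(list(per_point = per_point,
                 mean1 = mean(f1), mean2 = mean(f2),
                 average = (mean(f1) + mean(f2)) / 2,
                 n_unmatched = c(n1 - length(i1), n2 - length(i2))),
            class = "foscttm")
}

#' @export
print.foscttm <- function(x, ...) {
  cat("Fraction of samples closer than the true match\n")
  cat(sprintf("  domain 1 mean: %.4f   domain 2 mean: %.4f\n",
              x$mean1, x$mean2))
  cat(sprintf("  average:       %.4f   (0 = perfect, ~0.5 = random)\n",
              x$average))
  if (any(x$n_unmatched > 0))
    cat(sprintf("  unmatched cells excluded: %d (domain 1), %d (domain 2)\n",
                x$n_unmatched[1], x$n_unmatched[2]))
  invisible(x)
}
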