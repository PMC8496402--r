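#' Z-score normalize a data matrix
#'
#' Centers and scales a cells-by-features matrix so that every feature
#' (column) has mean 0 and population standard deviation 1 across cells.
#' This is the standard preprocessing applied to each domain (e.g. gene
#' expression levels, methylation rates) before the linear similarity kernel
#' is formed.
#'
#' Zero-variance features cannot be scaled; they are set to all-zero columns
#' (with a warning) rather than raising an error, since real single-cell
#' matrices routinely retain constant features after filtering. The
#' population (1/n) standard deviation is used throughout; with `margin =
#' "samples"` each row is standardized across its features instead.
#'
#' @param x Numeric matrix, cells in rows, features in columns.
#' @param margin Either `"features"` (default; standardize each column over
#'   cells) or `"samples"` (standardize each row over features).
#' @return A numeric matrix of the same dimensions, dimnames preserved.
#' @examples
#' z_normalize(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @seealso [linear_kernel()]
#' @export
z_normalize <- function(x, margin = c("features", "samples")) {
  margin <- match.arg(margin)
  if (is.data.frame(x)) x <- as.matrix(x)
  check_matrix(x)
  if (nrow(x) < 2L)
    stop("need at least 2 samples to normalize", call. = FALSE)
  if (margin == "samples")
    return(t(z_normalize(t(x), margin = "features")))
  m <- colMeans(x)
  xc <- sweep(x, 2L, m, "-")
  s <- sqrt(colMeans(xc^2))
  zero <- s == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s) set to all-zero columns",
                    sum(zero)), call. = FALSE)
    s[zero] <- 1
  }
  sweep(xc, 2L, s, "/")
}

#' Linear similarity kernel between cells
#'
#' Computes the cell-by-cell Gram matrix of inner products between rows of a
#' (typically z-normalized) observation matrix. By default the inner product
#' is averaged over features (`scale = "features"`, i.e. divided by the
#' number of columns), so that kernel entries are O(1) regardless of how
#' many features were assayed and a single latent-space bandwidth is
#' comparable across domains of different dimensionality; `scale = "none"`
#' gives the raw inner product.
#'
#' @param x Numeric matrix, cells in rows (usually the output of
#'   [z_normalize()]).
#' @param scale `"features"` (divide by the number of columns, default) or
#'   `"none"`.
#' @return An n-by-n symmetric kernel matrix with `sample_ids` taken from
#'   `rownames(x)`.
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' K <- linear_kernel(z_normalize(x))
#' @export
linear_kernel <- function(x, scale = c("features", "none")) {
  scale <- match.arg(scale)
  if (is.data.frame(x)) x <- as.matrix(x)
  check_matrix(x)
  K <- tcrossprod(x)
  if (scale == "features") K <- K / ncol(x)
  as_kernel((K + t(K)) / 2)
}

#' Validate (and symmetrize) a kernel Gram matrix
#'
#' Checks that a user-supplied matrix is square, finite and symmetric within
#' tolerance, then enforces exact symmetry by averaging with its transpose.
#' Any positive definite kernel (graph, string, RBF, ...) computed outside
#' the package can enter the pipeline this way. Positive semidefiniteness is
#' only verified on request because a full eigendecomposition is O(n^3).
#'
#' @param K Square numeric matrix of similarities.
#' @param tol Maximum tolerated asymmetry before a warning is issued.
#' @param check_psd If `TRUE`, eigendecompose and warn when the smallest
#'   eigenvalue is materially negative.
#' @return The symmetrized kernel matrix.
#' @export
as_kernel <- function(K, tol = 1e-6, check_psd = FALSE) {
  if (is.data.frame(K)) K <- as.matrix(K)
  check_matrix(K)
  if (nrow(K) != ncol(K))
    stop(sprintf("kernel matrix must be square, got %d x %d",
                 nrow(K), ncol(K)), call. = FALSE)
  asym <- max(abs(K - t(K)))
  if (asym > tol)
    warning(sprintf("kernel asymmetry %.3g exceeds %.1g; symmetrizing", asym,
                    tol), call. = FALSE)
  K <- (K + t(K)) / 2
  rn <- rownames(K)
  dimnames(K) <- if (is.null(rn)) NULL else list(rn, rn)
  if (check_psd) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      warning(sprintf("kernel is not positive semidefinite (min eigenvalue %.3g)",
                      min(ev)), call. = FALSE)
  }
  K
}

#' Read a delimited numeric matrix
#'
#' Reads a TSV/CSV matrix of cells by features (or a square kernel). The
#' delimiter (tab, comma or whitespace) is auto-detected from the first
#' line; an optional header row and an optional leading row-label column are
#' detected by checking whether they parse as numbers. Row order defines
#' sample order.
#'
#' @param path Path to a delimited text file.
#' @return A numeric matrix; row labels, when present, become rownames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop(sprintf("empty file: %s", path), call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  split1 <- if (sep == "") strsplit(trimws(first), "[[:space:]]+")[[1]]
            else strsplit(first, sep, fixed = TRUE)[[1]]
  is_num <- function(v) !any(is.na(suppressWarnings(as.numeric(v))))
  header <- !is_num(split1[-1L])   # first field may be a label-column title
  tab <- read.table(path, sep = sep, header = header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
  rn <- NULL
  if (ncol(tab) > 1L && !is_num(tab[[1L]])) {
    rn <- as.character(tab[[1L]])
    tab <- tab[, -1L, drop = FALSE]
  }
  m <- as.matrix(tab)
  if (!is.numeric(m))
    stop(sprintf("non-numeric entries in %s", path), call. = FALSE)
  if (anyNA(m))
    stop(sprintf("missing values in %s", path), call. = FALSE)
  dimnames(m) <- if (is.null(rn)) NULL else list(rn, NULL)
  m
}

#' Load a precomputed kernel matrix from a delimited file
#'
#' Convenience wrapper around [read_matrix()] + [as_kernel()]: reads a
#' square similarity matrix, errors on non-square input, warns and
#' symmetrizes when the stored matrix is asymmetric beyond tolerance.
#'
#' @inheritParams read_matrix
#' @inheritParams as_kernel
#' @return A symmetric kernel matrix.
#' @export
load_kernel <- function(path, tol = 1e-6, check_psd = FALSE) {
  m <- read_matrix(path)
  if (nrow(m) != ncol(m))
    stop(sprintf("kernel file %s is not square (%d x %d)", path,
                 nrow(m), ncol(m)), call. = FALSE)
  as_kernel(m, tol = tol, check_psd = check_psd)
}

#' Write a numeric matrix as tab-separated text
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @param rownames Write rownames as a leading column when present.
#' @export
write_matrix <- function(x, path, rownames = !is.null(base::rownames(x))) {
  write.table(x, path, sep = "\t", quote = FALSE,
              row.names = rownames, col.names = FALSE)
  invisible(path)
}
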