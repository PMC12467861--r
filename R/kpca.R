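#' Radial basis function kernel
#'
#' `rbf_kernel()` evaluates `exp(-||x - y||^2 / (2 sigma^2))` for a pair of
#' vectors; `kernel_matrix()` evaluates the full Gram matrix between the rows of
#' two matrices (`kernel = "linear"` gives the plain inner-product Gram matrix
#' used for the PCA-equivalence cross-check).
#'
#' @param x,y Numeric vectors of equal length (matrices of features for
#'   `kernel_matrix()`).
#' @param sigma Kernel bandwidth, > 0.
#' @return A number in (0, 1] (`rbf_kernel`), or an `nrow(x)` by `nrow(y)`
#'   matrix (`kernel_matrix`).
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (length(x) != length(y)) abort("x and y must have equal dimension")
  if (sigma <= 0) abort("sigma must be > 0")
  exp(-sum((x - y)^2) / (2 * sigma^2))
}

#' @rdname rbf_kernel
#' @param kernel `"rbf"` or `"linear"`.
#' @export
kernel_matrix <- function(x, y = x, sigma = 1, kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) abort("x and y must have equal dimension")
  if (kernel == "linear") return(x %*% t(y))
  if (sigma <= 0) abort("sigma must be > 0")
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Double-centre a kernel matrix
#'
#' Kernel PCA assumes the mapped data are mean-centred in feature space; the
#' Gram matrix must therefore be double-centred. In `"train"` mode this is
#' `K - 1K - K1 + 1K1` with `1` the n x n matrix of `1/n`, after which every row
#' sum is ~0. In `"cross"` mode a rectangular test-against-training kernel is
#' centred against the stored training statistics (training row means and grand
#' mean).
#'
#' @param K Kernel matrix (square in train mode; m x n in cross mode).
#' @param mode `"train"` or `"cross"`.
#' @param stats For cross mode, the `centering` element of a fitted [kpca()]
#'   model (training column means and grand mean).
#' @return The centred matrix; in train mode with attribute `"centering"`
#'   holding the statistics needed for cross mode.
#' @export
center_kernel <- function(K, mode = c("train", "cross"), stats = NULL) {
  mode <- match.arg(mode)
  K <- as.matrix(K)
  if (mode == "train") {
    if (nrow(K) != ncol(K)) abort("training kernel matrix must be square")
    col_means <- colMeans(K)
    grand <- mean(K)
    Kc <- K - matrix(rowMeans(K), nrow(K), ncol(K)) -
      matrix(col_means, nrow(K), ncol(K), byrow = TRUE) + grand
    attr(Kc, "centering") <- list(col_means = col_means, grand = grand)
    Kc
  } else {
    if (is.null(stats)) abort("cross-mode centering requires training statistics")
    K - matrix(rowMeans(K), nrow(K), ncol(K)) -
      matrix(stats$col_means, nrow(K), ncol(K), byrow = TRUE) + stats$grand
  }
}

#' Median-heuristic RBF bandwidth
#'
#' The median pairwise Euclidean distance over (a subsample of) the rows of
#' `x` — a standard default bandwidth for RBF kernels.
#'
#' @param x Feature matrix.
#' @param max_rows Subsample cap for the pairwise-distance computation.
#' @param seed Seed for the subsample draw.
#' @return A positive bandwidth.
#' @export
median_heuristic <- function(x, max_rows = 500, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) > max_rows) {
    idx <- withr::with_seed(seed, sample.int(nrow(x), max_rows))
    x <- x[idx, , drop = FALSE]
  }
  d <- stats::dist(x)
  m <- median(d)
  if (!is.finite(m) || m <= 0) m <- 1
  m
}

#' Kernel principal component analysis
#'
#' Fits kernel PCA by eigendecomposition of the double-centred Gram matrix
#' `K alpha = n lambda alpha`: eigenvalues sorted non-increasing, coefficient
#' vectors scaled so each feature-space eigenvector has unit norm
#' (`lambda_k * alpha_k' alpha_k = 1`), and per-component contribution rates
#' `100 * lambda_j / sum(lambda)`. The number of retained components is either
#' given directly (`n_components`) or chosen as the smallest p whose cumulative
#' contribution reaches `variance_threshold`. Tiny negative eigenvalues (above
#' `-1e-8` relative to the largest) are clamped to zero; anything more negative
#' signals a numerical failure and errors.
#'
#' @param x Feature matrix or data frame (rows = observations). Non-numeric
#'   columns `.label`/`.trial` are dropped automatically.
#' @param sigma RBF bandwidth; `NULL` (default) uses [median_heuristic()].
#' @param n_components Number of components to retain, or `NULL` to use the
#'   variance threshold.
#' @param variance_threshold Cumulative contribution target in (0, 100].
#' @param kernel `"rbf"` or `"linear"` (linear reproduces standard PCA scores up
#'   to component sign).
#' @return An object of class `lir_kpca` with elements `x_train`, `sigma`,
#'   `kernel`, `alphas` (n x p), `lambdas` (all n eigenvalues of K, descending),
#'   `contribution` (percent), `centering`, `p` and `scores` (training scores,
#'   n x p).
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' km <- kpca(X, sigma = 2, variance_threshold = 95)
#' km$p
#' @export
kpca <- function(x, sigma = NULL, n_components = NULL, variance_threshold = 95,
                 kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  x <- drop_meta_cols(x)
  n <- nrow(x)
  if (n < 2) abort("kernel PCA needs at least 2 observations")
  if (any(!is.finite(x))) abort("non-finite values in feature matrix")
  if (is.null(sigma)) sigma <- if (kernel == "rbf") median_heuristic(x) else 1
  if (sigma <= 0) abort("sigma must be > 0")
  if (!is.null(n_components) && n_components > n) {
    abort("cannot retain more components than observations")
  }

  K <- kernel_matrix(x, x, sigma = sigma, kernel = kernel)
  Kc <- center_kernel(K, "train")
  centering <- attr(Kc, "centering")

  eig <- eigen(Kc, symmetric = TRUE)
  lam <- eig$values
  if (any(lam < -1e-8 * max(abs(lam[1]), 1))) {
    abort("eigendecomposition failed: significantly negative eigenvalues")
  }
  lam <- pmax(lam, 0)

  contribution <- if (sum(lam) > 0) 100 * lam / sum(lam) else rep(0, n)
  p <- if (!is.null(n_components)) {
    n_components
  } else {
    max(1L, which(cumsum(contribution) >= variance_threshold - 1e-9)[1])
  }
  if (is.na(p)) p <- n

  # unit-norm feature-space eigenvectors: lambda_k * (alpha' alpha) = 1
  alphas <- eig$vectors[, seq_len(p), drop = FALSE]
  for (k in seq_len(p)) {
    if (lam[k] > 0) alphas[, k] <- alphas[, k] / sqrt(lam[k])
  }
  scores <- Kc %*% alphas

  structure(list(x_train = x, sigma = sigma, kernel = kernel,
                 alphas = alphas, lambdas = lam, contribution = contribution,
                 centering = centering, p = p, scores = scores),
            class = "lir_kpca")
}

drop_meta_cols <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), c(".label", ".trial")), drop = FALSE]
  }
  as.matrix(x)
}

#' Project new observations onto kernel principal components
#'
#' Computes the test-against-training kernel, centres it against the stored
#' training statistics and applies the coefficient vectors:
#' `t_k(x) = sum_j alpha_jk k_centred(x_j, x)`. Projecting the training data
#' reproduces the scores recorded at fit time.
#'
#' @param object A fitted `lir_kpca` model.
#' @param newdata Matrix or data frame with the training feature dimension.
#' @param ... Unused.
#' @return An m x p score matrix.
#' @export
predict.lir_kpca <- function(object, newdata, ...) {
  newdata <- drop_meta_cols(newdata)
  if (ncol(newdata) != ncol(object$x_train)) {
    abort("feature dimension does not match the training data")
  }
  K <- kernel_matrix(newdata, object$x_train, sigma = object$sigma,
                     kernel = object$kernel)
  Kc <- center_kernel(K, "cross", stats = object$centering)
  Kc %*% object$alphas
}

#' @export
print.lir_kpca <- function(x, ...) {
  cat("<lir_kpca> ", x$kernel, " kernel, sigma = ", signif(x$sigma, 4),
      ", n = ", nrow(x$x_train), ", retained p = ", x$p,
      " (", round(sum(x$contribution[seq_len(x$p)]), 1), "% contribution)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.lir_kpca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$lambdas),
    eigenvalue = x$lambdas,
    contribution = x$contribution,
    cumulative = cumsum(x$contribution),
    retained = seq_along(x$lambdas) <= x$p
  )
}

#' @export
glance.lir_kpca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$x_train), kernel = x$kernel, sigma = x$sigma, p = x$p,
    contribution_retained = sum(x$contribution[seq_len(x$p)])
  )
}
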