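#' Default hyperparameter search space for the RBF-kernel SVM
#'
#' The optimizer works on log10 scale: `log10(C) in [-2, 3]`,
#' `log10(g) in [-4, 2]`, the standard decade ranges for scale parameters.
#'
#' @return A [search_space()] with `log10` flags set.
#' @export
svm_search_space <- function() {
  search_space(lower = c(-2, -4), upper = c(3, 2), log10 = c(TRUE, TRUE))
}

#' Decode an optimizer position into SVM hyperparameters
#'
#' @param position Numeric vector in the search space.
#' @param space The [search_space()] the position lives in; coordinates flagged
#'   `log10` are exponentiated.
#' @return Named list with `C` and `g`.
#' @export
decode_hyperparams <- function(position, space = svm_search_space()) {
  stopifnot(length(position) == space$dim)
  v <- ifelse(space$log10, 10^position, position)
  list(C = v[1], g = v[2])
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Solves the soft-margin dual with kernel `k(x1, x2) = exp(-g ||x1 - x2||^2)`
#' (the quadratic program is delegated to libsvm via e1071). Multiclass
#' problems use one-vs-one pairwise machines with majority voting and a
#' deterministic tie-break (first class in the training class order).
#'
#' @param features Tibble/data frame with a `.label` column and numeric feature
#'   columns (`.trial` is ignored), or a plain numeric matrix if `y` is given.
#' @param C Regularization strength, > 0.
#' @param g RBF width parameter, > 0.
#' @param y Labels, only when `features` is a bare matrix.
#' @return An object of class `lir_svm`.
#' @examples
#' xor <- data.frame(.label = c("a", "a", "b", "b"),
#'                   x1 = c(0, 1, 0, 1), x2 = c(0, 1, 1, 0))
#' m <- svm_train(xor, C = 100, g = 1)
#' predict(m, xor)
#' @export
svm_train <- function(features, C, g, y = NULL) {
  stopifnot(C > 0, g > 0)
  if (is.null(y)) {
    y <- features$.label
    x <- drop_meta_cols(features)
  } else {
    x <- as.matrix(features)
  }
  if (is.null(y)) abort("no labels: provide a .label column or y")
  if (any(!is.finite(x))) abort("non-finite feature values")
  classes <- unique(as.character(y))
  if (length(classes) < 2) abort("training needs at least 2 classes")
  yf <- factor(as.character(y), levels = classes)
  fit <- e1071::svm(x = x, y = yf, type = "C-classification",
                    kernel = "radial", gamma = g, cost = C, scale = FALSE)
  structure(list(model = fit, classes = classes, C = C, g = g,
                 d = ncol(x), feat_names = colnames(x)),
            class = "lir_svm")
}

#' Predict locomotion-mode labels
#'
#' @param object A fitted `lir_svm`.
#' @param newdata Tibble or matrix with the training feature dimension.
#' @param ... Unused.
#' @return Character vector of predicted labels (empty input gives an empty
#'   vector).
#' @export
predict.lir_svm <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) drop_meta_cols(newdata) else as.matrix(newdata)
  if (ncol(x) != object$d) abort("feature dimension does not match training")
  if (nrow(x) == 0) return(character(0))
  as.character(predict(object$model, x))
}

#' @export
print.lir_svm <- function(x, ...) {
  cat("<lir_svm> RBF kernel, C = ", signif(x$C, 4), ", g = ", signif(x$g, 4),
      ", ", length(x$classes), " classes, ", nrow(x$model$SV),
      " support vectors\n", sep = "")
  invisible(x)
}

#' @export
glance.lir_svm <- function(x, ...) {
  tibble::tibble(C = x$C, g = x$g, n_classes = length(x$classes),
                 n_support = nrow(x$model$SV))
}

stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  min_class <- min(table(y))
  if (min_class < k) {
    warn(paste0("reducing CV folds from ", k, " to ", max(2, min_class),
                ": smallest class has ", min_class, " samples"))
    k <- max(2, min_class)
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  attr(folds, "k") <- k
  folds
}

#' Cross-validated classification-accuracy fitness
#'
#' The objective the sparrow search maximises when tuning `(C, g)`: mean
#' held-out accuracy over `k_folds` class-stratified folds. If the smallest
#' class cannot populate every fold, `k` is reduced (with a warning). Fully
#' deterministic for a fixed seed and invariant to sample order.
#'
#' @param features Feature tibble with `.label` (and optionally `.trial`).
#' @param position Optimizer position, decoded by [decode_hyperparams()].
#' @param space Search space of the position.
#' @param k_folds Number of stratified folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param max_rows Optional cap: a class-stratified subsample of at most this
#'   many windows is used, keeping the fitness affordable inside the optimizer
#'   loop.
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(features, position, space = svm_search_space(),
                       k_folds = 5, seed = 1L, max_rows = NULL) {
  hp <- decode_hyperparams(position, space)
  y <- as.character(features$.label)
  x <- drop_meta_cols(features)
  ord <- order(y, apply(x, 1, function(r) sum(r * seq_along(r)))) # order-invariance
  x <- x[ord, , drop = FALSE]; y <- y[ord]
  if (!is.null(max_rows) && nrow(x) > max_rows) {
    idx <- stratified_subsample(y, max_rows, seed)
    x <- x[idx, , drop = FALSE]; y <- y[idx]
  }
  folds <- stratified_folds(y, k_folds, seed)
  k <- attr(folds, "k")
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- svm_train(x[tr, , drop = FALSE], C = hp$C, g = hp$g, y = y[tr])
    mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(acc)
}

stratified_subsample <- function(y, max_rows, seed) {
  withr::with_seed(seed, {
    classes <- unique(y)
    per <- ceiling(max_rows / length(classes))
    idx <- unlist(lapply(classes, function(cl) {
      i <- which(y == cl)
      if (length(i) > per) sample(i, per) else i
    }))
    sort(idx)
  })
}
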