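#' Pipeline control parameters
#'
#' Desk-scale defaults for the training pipeline. `tau` is the cumulative
#' contribution (percent) retained by the dimensionality-reduction step, shared
#' by the kernel and linear PCA variants. The sparrow-search budget, the CV
#' fitness folds and the stratified subsample caps (`cv_max_rows` windows for
#' the fitness, `kpca_ref_max` windows as the kernel-PCA reference set) keep a
#' full bootstrap affordable on one CPU; raise them for full-size runs.
#'
#' @param tau Retained cumulative contribution, percent.
#' @param kpca_sigma RBF bandwidth for kernel PCA; `NULL` = median heuristic.
#' @param kpca_ref_max Cap on the kernel-PCA training reference set.
#' @param issa An [ssa_control()] for hyperparameter tuning.
#' @param cv_folds Stratified CV folds inside the tuning fitness.
#' @param cv_max_rows Stratified subsample cap for the tuning fitness.
#' @param grid_log10C,grid_log10g Grid-search decades for the baseline
#'   variants.
#' @return A `pipeline_control` list.
#' @export
pipeline_control <- function(tau = 95, kpca_sigma = NULL, kpca_ref_max = 800,
                             issa = ssa_control(pop_size = 6, max_iter = 5),
                             cv_folds = 3, cv_max_rows = 600,
                             grid_log10C = -2:3, grid_log10g = -4:2) {
  structure(list(tau = tau, kpca_sigma = kpca_sigma,
                 kpca_ref_max = kpca_ref_max, issa = issa,
                 cv_folds = cv_folds, cv_max_rows = cv_max_rows,
                 grid_log10C = grid_log10C, grid_log10g = grid_log10g,
                 svm_space = svm_search_space()),
            class = "pipeline_control")
}

fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}

apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2, std$mean, "-"), 2, std$sd, "/")
}

#' Train a locomotion-mode recognition pipeline
#'
#' Fits the full classification stack on a training dataset:
#' `"kpca_issa_svm"` standardizes the bidomain features (z-score per column),
#' reduces them with RBF kernel PCA (bandwidth from the median heuristic,
#' components retained to `tau` percent cumulative contribution) and trains an
#' RBF SVM whose `(C, g)` are tuned by the improved sparrow search maximising
#' stratified CV accuracy. `"pca_svm"` substitutes linear PCA (same `tau` rule)
#' and decade grid search; `"svm"` grid-searches on the standardized raw
#' features. Every stage is fitted strictly on the data passed in — no test
#' statistics leak into the standardizer, the reduction or the tuning.
#'
#' @param dataset List of `lir_recording` (or `NULL` if `features` given).
#' @param modality `"fusion"`, `"semg"` or `"imu"`.
#' @param variant `"kpca_issa_svm"`, `"pca_svm"` or `"svm"`.
#' @param seed Integer seed; a fixed seed reproduces the fitted `(C, g)`
#'   exactly.
#' @param control A [pipeline_control()].
#' @param features Optional precomputed feature tibble (from
#'   [dataset_features()]) to avoid re-extraction.
#' @return An object of class `lir_pipeline`.
#' @export
train_pipeline <- function(dataset, modality = c("fusion", "semg", "imu"),
                           variant = c("kpca_issa_svm", "pca_svm", "svm"),
                           seed = 1L, control = pipeline_control(),
                           features = NULL) {
  modality <- match.arg(modality)
  variant <- match.arg(variant)
  if (is.null(features)) {
    if (length(dataset) == 0) abort("empty dataset")
    features <- dataset_features(dataset, modality = modality)
  }
  y <- as.character(features$.label)
  if (length(unique(y)) < 2) abort("training data must cover at least 2 modes")
  x <- drop_meta_cols(features)

  std <- fit_standardizer(x)
  xs <- apply_standardizer(x, std)

  reducer <- NULL
  if (variant == "kpca_issa_svm") {
    ref_idx <- if (nrow(xs) > control$kpca_ref_max) {
      stratified_subsample(y, control$kpca_ref_max, seed)
    } else {
      seq_len(nrow(xs))
    }
    sigma <- control$kpca_sigma
    if (is.null(sigma)) sigma <- median_heuristic(xs[ref_idx, , drop = FALSE])
    reducer <- kpca(xs[ref_idx, , drop = FALSE], sigma = sigma,
                    variance_threshold = control$tau)
    z <- predict(reducer, xs)
  } else if (variant == "pca_svm") {
    pc <- prcomp(xs, center = FALSE, scale. = FALSE)
    contrib <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    p <- max(1L, which(cumsum(contrib) >= control$tau - 1e-9)[1])
    reducer <- list(rotation = pc$rotation[, seq_len(p), drop = FALSE], p = p,
                    contribution = contrib)
    class(reducer) <- "lir_pca"
    z <- xs %*% reducer$rotation
  } else {
    z <- xs
  }

  zt <- dplyr::bind_cols(tibble::tibble(.label = y),
                         tibble::as_tibble(as.data.frame(z)))
  if (variant == "kpca_issa_svm") {
    fitness <- function(pos) {
      cv_fitness(zt, pos, space = control$svm_space, k_folds = control$cv_folds,
                 seed = seed, max_rows = control$cv_max_rows)
    }
    opt <- ssa_optimize(fitness, control$svm_space, control$issa,
                        variant = "issa", seed = seed)
    hp <- decode_hyperparams(opt$best_position, control$svm_space)
    tuning <- opt
  } else {
    grid <- expand.grid(log10C = control$grid_log10C, log10g = control$grid_log10g)
    grid$fitness <- vapply(seq_len(nrow(grid)), function(i) {
      cv_fitness(zt, c(grid$log10C[i], grid$log10g[i]),
                 space = control$svm_space, k_folds = control$cv_folds,
                 seed = seed, max_rows = control$cv_max_rows)
    }, numeric(1))
    best <- which.max(grid$fitness)
    hp <- list(C = 10^grid$log10C[best], g = 10^grid$log10g[best])
    tuning <- tibble::as_tibble(grid)
  }

  model <- svm_train(as.matrix(z), C = hp$C, g = hp$g, y = y)
  train_acc <- mean(predict(model, as.matrix(z)) == y)

  structure(list(modality = modality, variant = variant, standardizer = std,
                 reducer = reducer, svm = model, hp = hp, tuning = tuning,
                 seed = seed, control = control,
                 feature_names = colnames(x), n_train = nrow(x),
                 train_accuracy = train_acc),
            class = "lir_pipeline")
}

reduce_features <- function(pipe, features) {
  x <- drop_meta_cols(features)
  if (!identical(colnames(x), pipe$feature_names)) {
    if (!all(pipe$feature_names %in% colnames(x))) {
      abort("feature layout does not match the trained pipeline")
    }
    x <- x[, pipe$feature_names, drop = FALSE]
  }
  xs <- apply_standardizer(x, pipe$standardizer)
  if (is.null(pipe$reducer)) {
    xs
  } else if (inherits(pipe$reducer, "lir_kpca")) {
    predict(pipe$reducer, xs)
  } else {
    xs %*% pipe$reducer$rotation
  }
}

#' Predict locomotion modes with a trained pipeline
#'
#' @param object An `lir_pipeline`.
#' @param newdata A `lir_recording` (features are extracted with the pipeline's
#'   modality) or a feature tibble.
#' @param ... Unused.
#' @return Character vector of predicted mode codes, one per window.
#' @export
predict.lir_pipeline <- function(object, newdata, ...) {
  features <- if (inherits(newdata, "lir_recording")) {
    extract_features(newdata, modality = object$modality)
  } else {
    newdata
  }
  as.character(predict(object$svm, reduce_features(object, features)))
}

#' @export
print.lir_pipeline <- function(x, ...) {
  cat("<lir_pipeline> ", x$variant, " / ", x$modality, ": ",
      length(x$feature_names), " features -> ",
      if (is.null(x$reducer)) length(x$feature_names) else
        if (inherits(x$reducer, "lir_kpca")) x$reducer$p else x$reducer$p,
      " components; C = ", signif(x$hp$C, 4), ", g = ", signif(x$hp$g, 4),
      "; training accuracy ", round(100 * x$train_accuracy, 2), "%\n", sep = "")
  invisible(x)
}

#' @export
glance.lir_pipeline <- function(x, ...) {
  tibble::tibble(variant = x$variant, modality = x$modality,
                 n_train = x$n_train, n_features = length(x$feature_names),
                 n_components = if (is.null(x$reducer)) length(x$feature_names)
                 else x$reducer$p,
                 C = x$hp$C, g = x$hp$g, train_accuracy = x$train_accuracy)
}

#' Row-normalized confusion matrix
#'
#' Rows are true modes, columns predicted modes, in the canonical taxonomy
#' ordering; each non-empty row is normalized to sum to 1. The raw counts are
#' attached as attribute `"counts"`, so overall accuracy equals
#' `sum(diag(counts)) / sum(counts)`.
#'
#' @param truth,predicted Equal-length label vectors; every label must belong
#'   to `levels`.
#' @param levels Class ordering (defaults to the 13-mode taxonomy).
#' @return A row-normalized matrix of class `lir_confusion`.
#' @examples
#' confusion_matrix(c("LW", "SA"), c("LW", "SA"))["LW", "LW"]
#' @export
confusion_matrix <- function(truth, predicted, levels = mode_codes()) {
  if (length(truth) != length(predicted)) abort("length mismatch")
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad) > 0) abort(paste0("labels outside the taxonomy: ",
                                    paste(bad, collapse = ", ")))
  counts <- table(factor(truth, levels = levels),
                  factor(predicted, levels = levels))
  counts <- matrix(as.numeric(counts), nrow = length(levels),
                   dimnames = list(truth = levels, predicted = levels))
  rs <- rowSums(counts)
  norm <- counts / ifelse(rs == 0, 1, rs)
  structure(norm, counts = counts, class = c("lir_confusion", "matrix"))
}

trial_strata <- function(features) {
  trials <- unique(features$.trial)
  codes <- mode_codes()
  vapply(trials, function(id) {
    m <- regmatches(id, regexec("^(.*)-[0-9]+$", id))[[1]]
    if (length(m) == 2 && m[2] %in% codes) return(m[2])
    labs <- features$.label[features$.trial == id]
    names(sort(table(labs), decreasing = TRUE))[1]
  }, character(1))
}

split_trials <- function(features, train_frac, seed, with_replacement = FALSE) {
  strata <- trial_strata(features)
  trials <- names(strata)
  withr::with_seed(seed, {
    train <- character(0)
    for (s in unique(strata)) {
      ids <- trials[strata == s]
      n_tr <- min(length(ids) - 1, max(1, round(train_frac * length(ids))))
      if (length(ids) == 1) n_tr <- 1 # degenerate stratum: train side
      picked <- if (with_replacement) {
        sample(ids, size = max(1, round(train_frac * length(ids))), replace = TRUE)
      } else {
        sample(ids, n_tr)
      }
      train <- c(train, picked)
    }
  })
  list(train = unique(train), test = setdiff(trials, unique(train)))
}

#' Bootstrap evaluation with percentile confidence intervals
#'
#' Repeats a stratified trial-level train/test split `n_iter` times: in each
#' iteration `train_frac` of the trials of each mode are drawn for training
#' (without replacement by default; `with_replacement = TRUE` draws with
#' replacement and tests on the never-drawn trials), the full pipeline is
#' refitted on the training windows only, and held-out window accuracy is
#' recorded. Reported are the median accuracy, the nonparametric 95% interval
#' (2.5th/97.5th percentiles of the bootstrap distribution), per-mode
#' accuracies and the aggregated row-normalized confusion matrix.
#'
#' Splitting at the trial level (not the window level) keeps temporally
#' adjacent windows of one recording on one side of the split.
#'
#' @inheritParams train_pipeline
#' @param n_iter Number of bootstrap iterations.
#' @param train_frac Fraction of trials per mode used for training.
#' @param with_replacement Draw training trials with replacement.
#' @param predict_override Optional function `(train_features, test_features)`
#'   returning predicted labels for the test windows — substitutes the trained
#'   pipeline (used to validate the protocol against reference classifiers).
#' @return An `lir_eval` report.
#' @export
bootstrap_evaluate <- function(dataset, modality = c("fusion", "semg", "imu"),
                               variant = c("kpca_issa_svm", "pca_svm", "svm"),
                               n_iter = 100, train_frac = 0.8, seed = 1L,
                               control = pipeline_control(), features = NULL,
                               with_replacement = FALSE,
                               predict_override = NULL) {
  modality <- match.arg(modality)
  variant <- match.arg(variant)
  if (is.null(features)) features <- dataset_features(dataset, modality = modality)
  classes <- unique(features$.label)
  levels_present <- intersect(mode_codes(), classes)

  acc <- numeric(n_iter)
  counts <- matrix(0, length(mode_codes()), length(mode_codes()),
                   dimnames = list(truth = mode_codes(), predicted = mode_codes()))
  for (i in seq_len(n_iter)) {
    split <- NULL
    for (try in 1:10) {
      cand <- split_trials(features, train_frac, seed + i * 101 + try,
                           with_replacement = with_replacement)
      tr <- features[features$.trial %in% cand$train, , drop = FALSE]
      te <- features[features$.trial %in% cand$test, , drop = FALSE]
      if (length(cand$test) > 0 && all(classes %in% tr$.label)) {
        split <- cand
        break
      }
      warn("a class was missing from the training split; resampling")
    }
    if (is.null(split)) abort("could not build a split covering every class")

    pred <- if (is.null(predict_override)) {
      pipe <- train_pipeline(NULL, modality = modality, variant = variant,
                             seed = seed + i, control = control, features = tr)
      predict(pipe, te)
    } else {
      predict_override(tr, te)
    }
    acc[i] <- mean(pred == te$.label)
    cm <- confusion_matrix(te$.label, pred)
    counts <- counts + attr(cm, "counts")
  }

  rs <- rowSums(counts)
  confusion <- counts / ifelse(rs == 0, 1, rs)
  per_mode <- tibble::tibble(
    mode = levels_present,
    accuracy = diag(confusion)[levels_present],
    n_windows = rs[levels_present]
  )
  structure(list(
    accuracies = tibble::tibble(iteration = seq_len(n_iter), accuracy = acc),
    median = median(acc),
    ci = unname(quantile(acc, c(0.025, 0.975), type = 7)),
    per_mode = per_mode,
    confusion = structure(confusion, counts = counts,
                          class = c("lir_confusion", "matrix")),
    overall_accuracy = sum(diag(counts)) / max(1, sum(counts)),
    n_iter = n_iter, train_frac = train_frac, modality = modality,
    variant = variant, seed = seed
  ), class = "lir_eval")
}

#' @export
print.lir_eval <- function(x, ...) {
  cat("<lir_eval> ", x$variant, " / ", x$modality, ", ", x$n_iter,
      " bootstrap iterations\n  median accuracy ",
      round(100 * x$median, 2), "%  (95% CI ",
      round(100 * x$ci[1], 2), "-", round(100 * x$ci[2], 2), "%)\n", sep = "")
  invisible(x)
}

#' @export
tidy.lir_eval <- function(x, ...) x$accuracies

#' @export
glance.lir_eval <- function(x, ...) {
  tibble::tibble(variant = x$variant, modality = x$modality, n_iter = x$n_iter,
                 median_accuracy = x$median, ci_low = x$ci[1], ci_high = x$ci[2],
                 overall_accuracy = x$overall_accuracy)
}

#' Noise-robustness sweep
#'
#' Trains on clean signals (one stratified trial split), then evaluates the
#' held-out trials with additive white Gaussian noise injected into the test
#' sEMG channels at each requested SNR. `Inf` reproduces the clean test
#' accuracy exactly. Labels are never altered by the injection.
#'
#' @inheritParams train_pipeline
#' @param snr_db_list SNR levels in dB (`Inf` = clean, prepended
#'   automatically).
#' @param train_frac Fraction of trials per mode used for training.
#' @return A tibble with `snr_db` and `accuracy`.
#' @export
snr_sweep <- function(dataset, modality = c("fusion", "semg", "imu"),
                      variant = c("kpca_issa_svm", "pca_svm", "svm"),
                      snr_db_list = c(10, 5, 0), train_frac = 0.8, seed = 1L,
                      control = pipeline_control()) {
  modality <- match.arg(modality)
  variant <- match.arg(variant)
  features <- dataset_features(dataset, modality = modality)
  split <- split_trials(features, train_frac, seed)
  tr <- features[features$.trial %in% split$train, , drop = FALSE]
  pipe <- train_pipeline(NULL, modality = modality, variant = variant,
                         seed = seed, control = control, features = tr)

  test_recs <- Filter(function(r) r$meta$trial %in% split$test, dataset)
  levels_all <- c(Inf, snr_db_list)
  acc <- vapply(seq_along(levels_all), function(k) {
    snr <- levels_all[k]
    te <- dataset_features(
      lapply(seq_along(test_recs), function(j) {
        inject_awgn(test_recs[[j]], snr_db = snr, seed = seed + 7919 * k + j)
      }),
      modality = modality
    )
    mean(predict(pipe, te) == te$.label)
  }, numeric(1))
  tibble::tibble(snr_db = levels_all, accuracy = acc)
}

#' Single-modality vs fusion ablation
#'
#' Trains three pipelines under an identical protocol (same trial split, same
#' seed, same variant and control) differing only in the feature subset: sEMG
#' only (30 features), IMU only (36) and fused (66). Reported accuracy is on
#' the common held-out trials.
#'
#' @inheritParams snr_sweep
#' @return A tibble with `modality`, `n_features` and `accuracy`.
#' @export
modality_ablation <- function(dataset, variant = c("kpca_issa_svm", "pca_svm", "svm"),
                              train_frac = 0.8, seed = 1L,
                              control = pipeline_control()) {
  variant <- match.arg(variant)
  fused <- dataset_features(dataset, modality = "fusion")
  split <- split_trials(fused, train_frac, seed)
  purrr::map_dfr(c("semg", "imu", "fusion"), function(mod) {
    ft <- if (mod == "fusion") {
      fused
    } else {
      fused[, c(".trial", ".label",
                grep(paste0("^", mod, "\\."), names(fused), value = TRUE))]
    }
    tr <- ft[ft$.trial %in% split$train, , drop = FALSE]
    te <- ft[ft$.trial %in% split$test, , drop = FALSE]
    pipe <- train_pipeline(NULL, modality = mod, variant = variant,
                           seed = seed, control = control, features = tr)
    tibble::tibble(modality = mod,
                   n_features = length(feature_columns(ft)),
                   accuracy = mean(predict(pipe, te) == te$.label))
  })
}

#' Streaming window-by-window prediction
#'
#' Emulates online use: the incoming stream is preprocessed, cut into 100 ms
#' non-overlapping windows, and each window is classified in arrival order,
#' one at a time, with its wall-clock latency recorded. The emitted labels are
#' identical to batch prediction on the same recording.
#'
#' @param pipe A trained `lir_pipeline`.
#' @param stream A `lir_recording` with the channel layout the pipeline was
#'   trained on.
#' @return A tibble with `window`, `time_s` (window end time), `label` and
#'   `latency_ms`.
#' @export
stream_predict <- function(pipe, stream) {
  stopifnot(inherits(pipe, "lir_pipeline"), inherits(stream, "lir_recording"))
  features <- extract_features(stream, modality = pipe$modality)
  z <- reduce_features(pipe, features)
  n <- nrow(z)
  labels <- character(n)
  latency <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    labels[i] <- as.character(predict(pipe$svm, z[i, , drop = FALSE]))
    latency[i] <- 1000 * (proc.time()[["elapsed"]] - t0)
  }
  tibble::tibble(window = seq_len(n), time_s = seq_len(n) * 0.1,
                 label = labels, latency_ms = latency)
}
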