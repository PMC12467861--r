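test_that("a separable two-point problem is fit perfectly with both SVs", {
  d <- data.frame(.label = c("a", "b"), x1 = c(0, 1), x2 = c(0, 1))
  m <- svm_train(d, C = 1e3, g = 1)
  expect_equal(predict(m, d), c("a", "b"))
  expect_equal(nrow(m$model$SV), 2)
})

test_that("the RBF kernel separates XOR where a linear machine cannot", {
  xor <- data.frame(.label = c("p", "p", "n", "n"),
                    x1 = c(0, 1, 0, 1), x2 = c(0, 1, 1, 0))
  m <- svm_train(xor, C = 100, g = 1)
  expect_equal(predict(m, xor), xor$.label)
})

test_that("training rejects degenerate inputs", {
  one <- data.frame(.label = c("a", "a"), x1 = c(0, 1), x2 = c(1, 0))
  expect_error(svm_train(one, C = 1, g = 1), "2 classes")
  bad <- data.frame(.label = c("a", "b"), x1 = c(NA, 1), x2 = c(1, 0))
  expect_error(svm_train(bad, C = 1, g = 1), "finite")
  expect_error(svm_train(one, C = -1, g = 1))
})

test_that("prediction is deterministic, shape-safe and order-equivariant", {
  ft <- blob_features()
  m <- svm_train(ft, C = 10, g = 1)
  p1 <- predict(m, ft)
  expect_true(all(p1 %in% c("a", "b", "c")))
  expect_identical(p1, predict(m, ft))
  expect_equal(predict(m, ft[0, ]), character(0))

  perm <- sample(nrow(ft))
  expect_identical(predict(m, ft[perm, ]), p1[perm])
  expect_error(predict(m, as.matrix(ft[, "f1"])), "dimension")
})

test_that("duplicating every training point leaves the decision function alone", {
  ft <- blob_features(n_per = 15)
  m1 <- svm_train(ft, C = 10, g = 0.5)
  m2 <- svm_train(dplyr::bind_rows(ft, ft), C = 10, g = 0.5)
  withr::with_seed(1, grid <- tibble::tibble(f1 = runif(50, -1, 4),
                                             f2 = runif(50, -1, 4)))
  expect_identical(predict(m1, grid), predict(m2, grid))
})

test_that("dual coefficients agree with a brute-force QP oracle", {
  withr::with_seed(21, {
    n <- 20
    x <- rbind(matrix(rnorm(n, 0, 0.8), n / 2, 2),
               matrix(rnorm(n, 2, 0.8), n / 2, 2))
    y <- rep(c(1, -1), each = n / 2)
  })
  for (C in c(0.5, 10)) {
    g <- 0.5
    m <- e1071::svm(x, factor(y), type = "C-classification", kernel = "radial",
                    gamma = g, cost = C, scale = FALSE, tolerance = 1e-8)
    # libsvm stores y_i * alpha_i for the support vectors
    alpha_lib <- numeric(nrow(x))
    alpha_lib[m$index] <- abs(m$coefs)
    expect_true(all(alpha_lib >= -1e-8 & alpha_lib <= C + 1e-8))

    oracle <- withr::with_seed(3, smo_solve(x, y, C = C, g = g))
    expect_true(all(oracle$alpha >= -1e-8 & oracle$alpha <= C + 1e-8))

    # equality constraint and matching dual objectives
    expect_lt(abs(sum(alpha_lib * y)), 1e-6)
    obj_lib <- dual_objective(alpha_lib, y, oracle$K)
    obj_smo <- dual_objective(oracle$alpha, y, oracle$K)
    expect_lt(abs(obj_lib - obj_smo) / max(abs(obj_lib), 1), 0.01)

    # KKT: margin violations only where alpha is at the box bound C
    # (bias recovered from the free support vectors, avoiding sign conventions)
    wk <- as.numeric(oracle$K %*% (alpha_lib * y))
    free <- which(alpha_lib > 1e-6 & alpha_lib < C - 1e-6)
    if (length(free) > 0) {
      b <- mean(y[free] - wk[free])
      f <- wk + b
      viol <- which(y * f < 1 - 1e-3)
      expect_true(all(alpha_lib[viol] > C * (1 - 1e-3)))
      # free support vectors sit on the margin
      expect_lt(max(abs(y[free] * f[free] - 1)), 1e-2)
    }
  }
})

test_that("training accuracy is non-decreasing in C on a fixed small problem", {
  withr::with_seed(31, {
    x <- matrix(rnorm(60), 30, 2)
    y <- ifelse(x[, 1] + 0.6 * rnorm(30) > 0, "a", "b")
  })
  d <- data.frame(.label = y, x)
  accs <- vapply(10^seq(-2, 3), function(C) {
    m <- svm_train(d, C = C, g = 1)
    mean(predict(m, d) == y)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))
})

test_that("cv fitness is perfect on separable blobs and chance on shuffles", {
  ft <- blob_features(n_per = 30)
  space <- svm_search_space()
  expect_equal(cv_fitness(ft, c(1, 0), space, k_folds = 5, seed = 1), 1)

  withr::with_seed(8, shuffled <- transform(ft, .label = sample(.label)))
  null_fit <- cv_fitness(shuffled, c(1, 0), space, k_folds = 5, seed = 1)
  expect_lt(abs(null_fit - 1 / 3), 0.1)

  # invariant to sample order for the same seed
  perm <- withr::with_seed(9, sample(nrow(ft)))
  expect_equal(cv_fitness(ft[perm, ], c(0.5, -1), space, seed = 4),
               cv_fitness(ft, c(0.5, -1), space, seed = 4))
})

test_that("fold stratification degrades gracefully for tiny classes", {
  ft <- dplyr::bind_rows(blob_features(n_per = 10),
                         tibble::tibble(.label = "d", f1 = 9, f2 = c(9, 9.1, 8.9)))
  expect_warning(f <- cv_fitness(ft, c(1, 0), k_folds = 5, seed = 1),
                 "reducing")
  expect_true(f >= 0 && f <= 1)
})

test_that("positions decode to hyperparameters on the log scale", {
  hp <- decode_hyperparams(c(2, -3))
  expect_equal(hp$C, 100)
  expect_equal(hp$g, 1e-3)
})
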