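# minimal SMO solver for the 2-class soft-margin RBF dual: an independent
# quadratic-programming oracle for small problems (n <= 50)
smo_solve <- function(x, y, C, g, tol = 1e-8, max_passes = 200) {
  n <- nrow(x)
  K <- exp(-g * (outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)))
  alpha <- numeric(n)
  b <- 0
  fcache <- function(i) sum(alpha * y * K[, i]) + b
  passes <- 0
  sweeps <- 0
  while (passes < 20 && sweeps < max_passes) {
    sweeps <- sweeps + 1
    changed <- 0
    for (i in seq_len(n)) {
      Ei <- fcache(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample(setdiff(seq_len(n), i), 1)
        Ej <- fcache(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- min(max(aj_old - y[j] * (Ei - Ej) / eta, L), H)
        if (abs(aj - aj_old) < 1e-12) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  list(alpha = alpha, b = b, K = K)
}

dual_objective <- function(alpha, y, K) {
  sum(alpha) - 0.5 * sum((alpha * y) %o% (alpha * y) * K)
}
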