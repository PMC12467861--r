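# shared fixtures, built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_cfg <- function(...) sim_config(...)

# 2 trials per mode, short trials: enough windows for end-to-end checks
small_dataset <- function() {
  fixture("small_dataset", function() {
    generate_dataset(small_cfg(), trials_per_mode = 2, seed = 101,
                     steady_duration = 2, transition_pad = 1)
  })
}

small_features <- function() {
  fixture("small_features", function() dataset_features(small_dataset()))
}

# well-separated 3-class gaussian blobs for classifier contracts
blob_features <- function(n_per = 30, sd = 0.2, seed = 5) {
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(k) {
      cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))
    }))
    tibble::tibble(.label = rep(c("a", "b", "c"), each = n_per),
                   f1 = x[, 1], f2 = x[, 2])
  })
}

# full-size synthetic benchmark: 13 modes x 10 trials (shared by the
# end-to-end acceptance checks)
bench_dataset <- function() {
  fixture("bench_dataset", function() {
    generate_dataset(sim_config(), trials_per_mode = 10, seed = 20260929)
  })
}

bench_features <- function() {
  fixture("bench_features", function() dataset_features(bench_dataset()))
}

# optimizer benchmark runs at equal evaluation budgets, 20 seeds per function
# (improved variant: 2n + T(n+2) evals at T = 100; baseline matched with T')
issa_benchmark <- function() {
  fixture("issa_benchmark", function() {
    spaces <- list(
      sphere = search_space(c(-5, -5), c(5, 5)),
      rastrigin = search_space(c(-5.12, -5.12), c(5.12, 5.12)),
      ackley = search_space(c(-5, -5), c(5, 5))
    )
    n <- 30; t_issa <- 100
    budget <- 2 * n + t_issa * (n + 2)
    t_ssa <- ceiling((budget - n) / n)
    out <- list()
    for (fn in names(spaces)) {
      f <- benchmark_function(fn)
      out[[fn]] <- list(
        issa = vapply(1:20, function(s) {
          ssa_optimize(f, spaces[[fn]], ssa_control(n, t_issa), "issa",
                       seed = s)$best_fitness
        }, numeric(1)),
        ssa = vapply(1:20, function(s) {
          ssa_optimize(f, spaces[[fn]], ssa_control(n, t_ssa), "ssa",
                       seed = s)$best_fitness
        }, numeric(1))
      )
    }
    out
  })
}

# concentric rings: linearly inseparable, radially separable
ring_data <- function(n_per = 20, seed = 9) {
  withr::with_seed(seed, {
    theta <- runif(2 * n_per, 0, 2 * pi)
    r <- rep(c(1, 3), each = n_per)
    list(x = cbind(r * cos(theta), r * sin(theta)) +
           matrix(rnorm(4 * n_per, sd = 0.05), ncol = 2),
         ring = rep(c("inner", "outer"), each = n_per))
  })
}
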