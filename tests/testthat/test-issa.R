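test_that("the chaotic map stays in [0,1) and matches a hand-computed step", {
  x <- chaotic_sequence(0.37, 500)
  expect_true(all(x >= 0 & x < 1))
  expect_identical(chaotic_sequence(0.37, 500), x)

  # one step from x0 = 0.7: mod(0.7 + 0.2 - (0.5/2pi) sin(1.4pi), 1)
  step <- (0.7 + 0.2 - (0.5 / (2 * pi)) * sin(2 * pi * 0.7)) %% 1
  expect_equal(chaotic_sequence(0.7, 1), step)
  expect_equal(step, 0.9756827, tolerance = 1e-6)

  expect_error(chaotic_sequence(0, 5), "inside")
  expect_error(chaotic_sequence(1, 5), "inside")
})

test_that("chaotic opposition-based init spans bounds and selection helps", {
  space <- search_space(c(-2, 1), c(4, 3))
  sphere <- function(x) -sum(x^2)

  init <- withr::with_seed(1, chaotic_obl_init(space, 10, sphere, x0 = 0.3))
  expect_equal(init$evals, 20L)
  expect_equal(nrow(init$positions), 10)
  expect_true(all(t(init$positions) >= space$lower &
                    t(init$positions) <= space$upper))

  # opposite construction identity X + X^op = a + b, per dimension
  seqv <- chaotic_sequence(0.3, 10 * 2)
  chaotic <- matrix(space$upper, 10, 2, byrow = TRUE) +
    matrix(space$lower - space$upper, 10, 2, byrow = TRUE) *
    matrix(seqv, 10, 2, byrow = TRUE)
  opposite <- matrix(space$lower + space$upper, 10, 2, byrow = TRUE) - chaotic
  expect_equal(chaotic + opposite,
               matrix(space$lower + space$upper, 10, 2, byrow = TRUE))

  # keeping the fitter half of the merged pool beats the chaotic half alone
  for (s in 1:20) {
    x0 <- s / 21
    init_s <- chaotic_obl_init(space, 8, sphere, x0 = x0)
    seq_s <- chaotic_sequence(x0, 8 * 2)
    chao_s <- matrix(space$upper, 8, 2, byrow = TRUE) +
      matrix(space$lower - space$upper, 8, 2, byrow = TRUE) *
      matrix(seq_s, 8, 2, byrow = TRUE)
    expect_gte(mean(init_s$fitness), mean(apply(chao_s, 1, sphere)))
  }
})

test_that("explorer updates shrink safely and stay in bounds", {
  space <- search_space(c(-5, -5), c(5, 5))
  ctl <- ssa_control(pop_size = 6, max_iter = 50)

  # multiplicative branch: the origin is a fixed point and magnitudes shrink
  zero <- matrix(0, 3, 2)
  out <- withr::with_seed(1, update_explorers(zero, space, ctl, t = 1, risk = 0.1))
  expect_equal(out, zero)

  pos <- matrix(c(4, -3, 2, 1, -2, 3), 3, 2)
  out2 <- withr::with_seed(2, update_explorers(pos, space, ctl, t = 1, risk = 0.1))
  expect_true(all(abs(out2) <= abs(pos)))
  expect_true(all(out2 != 0))

  out3 <- withr::with_seed(3, update_explorers(pos, space, ctl, t = 1, risk = 0.99))
  expect_true(all(t(out3) >= space$lower & t(out3) <= space$upper))

  r1 <- withr::with_seed(7, update_explorers(pos, space, ctl, 4))
  r2 <- withr::with_seed(7, update_explorers(pos, space, ctl, 4))
  expect_identical(r1, r2)
})

test_that("the adaptive follower weight decreases to zero", {
  expect_equal(dynamic_weight(100, 100), 0)
  expect_equal(dynamic_weight(0, 100), sin((pi / 2) * (1 - exp(-1))))
  expect_equal(dynamic_weight(0, 100), 0.8376315, tolerance = 1e-6)
  psis <- vapply(1:100, dynamic_weight, numeric(1), max_iter = 100)
  expect_true(all(diff(psis) < 0))
  expect_error(dynamic_weight(101, 100), "max_iter")
})

test_that("follower updates have the documented fixed points", {
  space <- search_space(c(-5, -5), c(5, 5))
  x_p <- c(1, 2)
  x_worst <- c(4, -4)

  # exploitation branch: a follower sitting on the best explorer stays there
  pos <- matrix(x_p, 1, 2, byrow = TRUE)
  out <- withr::with_seed(1, update_followers(pos, ranks = 2, x_p = x_p,
                                              x_worst = x_worst, psi = 0.7,
                                              space = space, n_total = 10))
  expect_equal(out[1, ], x_p)

  # psi = 0 collapses exploitation-branch followers onto the best explorer
  pos2 <- matrix(c(3, -1), 1, 2, byrow = TRUE)
  out2 <- withr::with_seed(2, update_followers(pos2, ranks = 2, x_p = x_p,
                                               x_worst = x_worst, psi = 0,
                                               space = space, n_total = 10))
  expect_equal(out2[1, ], x_p)

  # psi = 1 is the standard rule: offset has the A+ random-sign magnitude
  out3 <- withr::with_seed(3, update_followers(pos2, ranks = 2, x_p = x_p,
                                               x_worst = x_worst, psi = 1,
                                               space = space, n_total = 10))
  expect_equal(out3[1, 1] - x_p[1], out3[1, 2] - x_p[2]) # common offset
  expect_true(all(t(out3) >= space$lower & t(out3) <= space$upper))

  # hungry branch (rank > n/2) resamples and respects bounds
  out4 <- withr::with_seed(4, update_followers(pos2, ranks = 9, x_p = x_p,
                                               x_worst = x_worst, psi = 0.5,
                                               space = space, n_total = 10))
  expect_true(all(t(out4) >= space$lower & t(out4) <= space$upper))
})

test_that("scout updates follow the vigilance rules", {
  space <- search_space(c(-5, -5), c(5, 5))
  x_best <- c(1, 1); x_worst <- c(-4, 4)

  # a scout at the best position with best fitness and X = X_worst: frozen
  pos <- matrix(x_best, 1, 2, byrow = TRUE)
  out <- withr::with_seed(1, update_scouts(pos, fit = 0.5, x_best = x_best,
                                           x_worst = x_best, f_g = 0.5,
                                           f_w = 0.1, space = space))
  expect_equal(out[1, ], x_best)

  # a worse-than-best scout lands on the segment through x_best
  pos2 <- matrix(c(4, -2), 1, 2, byrow = TRUE)
  out2 <- withr::with_seed(2, update_scouts(pos2, fit = 0.1, x_best = x_best,
                                            x_worst = x_worst, f_g = 0.9,
                                            f_w = 0.1, space = space))
  off <- out2[1, ] - x_best
  dir <- pos2[1, ] - x_best
  expect_equal(off[1] / dir[1], off[2] / dir[2], tolerance = 1e-12)

  # f_i = f_g with f_i = f_w: the epsilon guard keeps the step finite
  pos3 <- matrix(c(2, 2), 1, 2, byrow = TRUE)
  out3 <- withr::with_seed(3, update_scouts(pos3, fit = 0.5, x_best = x_best,
                                            x_worst = x_worst, f_g = 0.5,
                                            f_w = 0.5, space = space))
  expect_true(all(is.finite(out3)))
  expect_true(all(t(out3) >= space$lower & t(out3) <= space$upper))
})

test_that("hybrid mutation is greedy and can climb a quadratic", {
  space <- search_space(-5, 5)
  ctl <- ssa_control(pop_size = 6, max_iter = 100)
  quad <- function(x) -sum((x - 1)^2)

  # at the optimum nothing can improve: best is returned unchanged
  out <- withr::with_seed(1, hybrid_mutation(1, 0, quad, space, ctl, t = 10,
                                             dispersion = 0.5))
  expect_equal(out$position, 1)
  expect_equal(out$fitness, 0)
  expect_equal(out$evals, 2L)

  # offset best: improvements occur with positive frequency
  hits <- 0
  for (s in 1:100) {
    res <- withr::with_seed(s, hybrid_mutation(2, quad(2), quad, space, ctl,
                                               t = 10, dispersion = 1))
    if (res$fitness > quad(2)) hits <- hits + 1
    expect_gte(res$fitness, quad(2)) # never worse (greedy elitism)
  }
  expect_gt(hits, 0)
})

test_that("the optimizer is deterministic with exact budget accounting", {
  space <- search_space(c(-5, -5), c(5, 5))
  sphere <- benchmark_function("sphere")
  for (variant in c("issa", "ssa")) {
    r1 <- ssa_optimize(sphere, space, ssa_control(8, 15), variant, seed = 33)
    r2 <- ssa_optimize(sphere, space, ssa_control(8, 15), variant, seed = 33)
    expect_identical(r1, r2)
    expect_true(all(diff(r1$history) >= 0))
    expected <- if (variant == "issa") 2 * 8 + 15 * (8 + 2) else 8 + 15 * 8
    expect_equal(r1$evals, expected)
    expect_true(all(r1$best_position >= space$lower &
                      r1$best_position <= space$upper))
  }
})

test_that("the improved variant converges on a 2-D sphere", {
  space <- search_space(c(-5, -5), c(5, 5))
  sphere <- benchmark_function("sphere")
  ok <- 0
  for (s in 1:8) {
    res <- ssa_optimize(sphere, space, ssa_control(20, 60), "issa", seed = s)
    if (-res$best_fitness < 1e-3) ok <- ok + 1
  }
  expect_gte(ok, 7)
})

test_that("benchmark functions have their optimum at the origin", {
  for (nm in c("sphere", "rastrigin", "ackley")) {
    f <- benchmark_function(nm)
    expect_equal(f(c(0, 0)), 0)
    expect_lt(f(c(1.3, -0.7)), 0)
  }
})

test_that("result summaries expose history and evaluation counts", {
  res <- ssa_optimize(benchmark_function("ackley"),
                      search_space(c(-5, -5), c(5, 5)),
                      ssa_control(6, 10), "issa", seed = 2)
  td <- tidy(res)
  expect_equal(nrow(td), 11)
  expect_equal(td$best_fitness[11], res$best_fitness)
  expect_equal(glance(res)$evals, res$evals)
})
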