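#' Box-constrained search space
#'
#' @param lower,upper Numeric vectors of per-dimension bounds (`lower < upper`).
#' @param log10 Logical per-dimension flags marking coordinates that live on a
#'   log10 scale (used when decoding positions into hyperparameters).
#' @return A `search_space` list with `lower`, `upper`, `dim`, `log10`.
#' @examples
#' search_space(c(-5, -5), c(5, 5))
#' @export
search_space <- function(lower, upper, log10 = rep(FALSE, length(lower))) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            length(log10) == length(lower))
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 dim = length(lower), log10 = log10),
            class = "search_space")
}

clip_to_space <- function(x, space) {
  if (is.matrix(x)) {
    pmin(pmax(x, matrix(space$lower, nrow(x), space$dim, byrow = TRUE)),
         matrix(space$upper, nrow(x), space$dim, byrow = TRUE))
  } else {
    pmin(pmax(x, space$lower), space$upper)
  }
}

#' Sparrow-search control parameters
#'
#' @param pop_size Population size n (>= 4).
#' @param max_iter Iteration budget.
#' @param explorer_frac Fraction of the population acting as explorers (PD).
#' @param safety_threshold Safety threshold ST in (0.5, 1].
#' @param scout_frac_range Range from which the scout fraction is drawn
#'   uniformly each iteration.
#' @param chaos_c,chaos_d Control parameters of the chaotic map.
#' @param mutation_sigma0 Base scale of the hybrid Gaussian/Cauchy mutation as a
#'   fraction of the box width per dimension.
#' @return An `ssa_control` list.
#' @export
ssa_control <- function(pop_size = 30, max_iter = 100, explorer_frac = 0.2,
                        safety_threshold = 0.8, scout_frac_range = c(0.10, 0.20),
                        chaos_c = 0.2, chaos_d = 0.5, mutation_sigma0 = 0.1) {
  stopifnot(pop_size >= 4, max_iter >= 1,
            explorer_frac > 0, explorer_frac < 1,
            safety_threshold > 0.5, safety_threshold <= 1,
            scout_frac_range[1] >= 0.10 - 1e-12, scout_frac_range[2] <= 0.20 + 1e-12)
  structure(list(pop_size = pop_size, max_iter = max_iter,
                 explorer_frac = explorer_frac,
                 safety_threshold = safety_threshold,
                 scout_frac_range = scout_frac_range,
                 chaos_c = chaos_c, chaos_d = chaos_d,
                 mutation_sigma0 = mutation_sigma0),
            class = "ssa_control")
}

#' Chaotic mapping sequence
#'
#' Iterates the sinusoidally perturbed shift map
#' `x[k+1] = (x[k] + c - (d / 2 pi) * sin(2 pi x[k])) mod 1`, the low-discrepancy
#' generator used to seed the population. All values lie in `[0, 1)` and a fixed
#' `x0` reproduces the sequence exactly.
#'
#' @param x0 Start value in (0, 1), excluding the degenerate fixed points.
#' @param n Sequence length (>= 1).
#' @param c,d Control parameters (defaults 0.2 and 0.5).
#' @return Numeric vector of length `n`.
#' @examples
#' chaotic_sequence(0.7, 3)
#' @export
chaotic_sequence <- function(x0, n, c = 0.2, d = 0.5) {
  if (x0 <= 0 || x0 >= 1) abort("x0 must lie strictly inside (0, 1)")
  stopifnot(n >= 1)
  out <- numeric(n)
  x <- x0
  for (k in seq_len(n)) {
    x <- (x + c - (d / (2 * pi)) * sin(2 * pi * x)) %% 1
    out[k] <- x
  }
  out
}

#' Chaotic opposition-based population initialisation
#'
#' Generates `n` candidates from the chaotic sequence mapped into the box as
#' `X[i, j] = upper[j] + (lower[j] - upper[j]) * x_k`, forms their bound-reflected
#' opposites `lower + upper - X`, evaluates all `2n`, and keeps the fitter half.
#'
#' @param space A [search_space()].
#' @param n Population size.
#' @param fitness Function mapping a position vector to a fitness value
#'   (maximised).
#' @param x0 Chaotic start value; drawn from the current RNG stream if `NULL`.
#' @param c,d Chaotic map parameters.
#' @return List with `positions` (n x dim), `fitness` (length n) and `evals`
#'   (`2n`).
#' @export
chaotic_obl_init <- function(space, n, fitness, x0 = NULL,
                             c = 0.2, d = 0.5) {
  if (is.null(x0)) {
    repeat {
      x0 <- runif(1)
      if (x0 > 0 && x0 < 1 && abs(x0 - 0.5) > 1e-9) break
    }
  }
  seqv <- chaotic_sequence(x0, n * space$dim, c = c, d = d)
  chaotic <- matrix(space$upper, n, space$dim, byrow = TRUE) +
    matrix(space$lower - space$upper, n, space$dim, byrow = TRUE) *
    matrix(seqv, n, space$dim, byrow = TRUE)
  opposite <- matrix(space$lower + space$upper, n, space$dim, byrow = TRUE) - chaotic
  pool <- rbind(chaotic, opposite)
  fit <- apply(pool, 1, fitness)
  keep <- order(fit, decreasing = TRUE)[seq_len(n)]
  list(positions = pool[keep, , drop = FALSE], fitness = fit[keep], evals = 2L * n)
}

#' Adaptive follower weight
#'
#' The dynamic weighting factor `psi(t) = sin((pi / 2) (1 - exp(t / T - 1)))`,
#' strictly decreasing from ~0.838 toward 0 at `t = T`: followers disperse early
#' (exploration) and lock onto the best explorer late (exploitation).
#'
#' @param t Current iteration, `1 <= t <= max_iter`.
#' @param max_iter Iteration budget T.
#' @return The weight in `[0, 1)`.
#' @examples
#' dynamic_weight(100, 100) # 0
#' @export
dynamic_weight <- function(t, max_iter) {
  if (t > max_iter || t < 0) abort("t must lie in [0, max_iter]")
  sin((pi / 2) * (1 - exp(t / max_iter - 1)))
}

#' Population update phases of the sparrow search
#'
#' The three role-based position updates, exposed individually so each contract
#' is testable. `update_explorers()`: with a per-iteration risk draw
#' `R ~ U(0, 1]`, safe iterations shrink positions multiplicatively by
#' `exp(-i / (beta * max_iter))` (rank `i`, `beta ~ U(0.5, 1]` per bird), unsafe
#' ones take a Gaussian step `Q` along the all-ones direction.
#' `update_followers()` applies the canonical two-branch follower rule with
#' adaptive inertia weighting: low-ranked ("hungry") followers with rank
#' `i > n/2` resample around the origin-shifted worst position,
#' `Q * exp((x_worst - X) / i^2)`, while the remainder exploit the best
#' explorer's position `x_p` with a weighted random-sign offset,
#' `x_p + psi * (|X - x_p| . A+ L)` where `A` has entries drawn from
#' `{-1, +1}`. With `psi = 1` this is exactly the standard follower update (the
#' baseline variant); the improved variant anneals `psi` with
#' [dynamic_weight()], damping early over-exploitation and collapsing onto the
#' best explorer late. `update_scouts()` moves scouts that are not at the
#' global best toward it (`x_best + gamma * (X - x_best)`, `gamma ~ N(0, 1)`),
#' while scouts at the best fitness take a vigilance step
#' `X + mu * (X - x_worst) / (|f - f_w| + eps)` with `mu ~ U(-1, 1)`. Positions
#' are clipped to the box after every phase.
#'
#' @param positions Matrix of positions (rows = individuals).
#' @param space A [search_space()].
#' @param control An [ssa_control()].
#' @param t Current iteration.
#' @param risk Optional override of the risk draw R (for testing).
#' @return Updated positions matrix.
#' @export
update_explorers <- function(positions, space, control, t, risk = NULL) {
  n <- nrow(positions)
  R <- if (is.null(risk)) runif(1, .Machine$double.eps, 1) else risk
  if (R < control$safety_threshold) {
    beta <- runif(n, 0.5 + .Machine$double.eps, 1)
    fac <- exp(-(seq_len(n)) / (beta * control$max_iter))
    positions <- positions * fac
  } else {
    Q <- rnorm(n)
    positions <- positions + Q # Q . L : same Gaussian step in every dimension
  }
  clip_to_space(positions, space)
}

#' @rdname update_explorers
#' @param x_p Position of the best explorer (after its own update).
#' @param x_worst Position of the worst-ranked individual.
#' @param psi Follower weight, from [dynamic_weight()]; `1` gives the standard
#'   (baseline) follower rule.
#' @param ranks Global fitness ranks of the follower rows (explorers occupy the
#'   top ranks).
#' @param n_total Total population size n.
#' @export
update_followers <- function(positions, ranks, x_p, x_worst, psi, space,
                             n_total) {
  d <- length(x_p)
  for (r in seq_len(nrow(positions))) {
    i <- ranks[r]
    if (i > n_total / 2) {
      Q <- rnorm(1)
      positions[r, ] <- Q * exp((x_worst - positions[r, ]) / i^2)
    } else {
      A <- sample(c(-1, 1), d, replace = TRUE)
      s <- sum(abs(positions[r, ] - x_p) * A) / d
      positions[r, ] <- x_p + psi * s
    }
  }
  clip_to_space(positions, space)
}

#' @rdname update_explorers
#' @param fit Fitness of each scout row (before the update).
#' @param x_best,x_worst Current globally best/worst positions.
#' @param f_g,f_w Current globally best/worst fitness values.
#' @export
update_scouts <- function(positions, fit, x_best, x_worst, f_g, f_w, space) {
  eps <- 1e-12
  n <- nrow(positions)
  for (i in seq_len(n)) {
    if (fit[i] < f_g) {
      gamma <- rnorm(1)
      positions[i, ] <- x_best + gamma * (positions[i, ] - x_best)
    } else {
      mu <- runif(1, -1, 1)
      positions[i, ] <- positions[i, ] +
        mu * (positions[i, ] - x_worst) / (abs(fit[i] - f_w) + eps)
    }
  }
  clip_to_space(positions, space)
}

#' Hybrid Gaussian/Cauchy mutation of the incumbent best
#'
#' Two trial perturbations of the best position, each evaluated and accepted
#' only on strict improvement (greedy elitism): a Gaussian local trial whose
#' scale `sigma0 * (1 - t / T) * dispersion` combines a linear anneal with the
#' population's own spread around the best (so late-stage refinement happens at
#' the scale the swarm has actually reached), and a heavy-tailed Cauchy escape
#' trial with fixed scale `sigma0 * box width` that can jump out of local
#' basins at any iteration.
#'
#' @param x_best Best position vector.
#' @param f_best Its fitness.
#' @param fitness Fitness function.
#' @param space A [search_space()].
#' @param control An [ssa_control()].
#' @param t Current iteration.
#' @param dispersion Mean Euclidean distance of the population to `x_best`;
#'   defaults to the box diagonal if not supplied.
#' @return List `position`, `fitness`, `evals` (always 2).
#' @export
hybrid_mutation <- function(x_best, f_best, fitness, space, control, t,
                            dispersion = NULL) {
  width <- space$upper - space$lower
  if (is.null(dispersion)) dispersion <- sqrt(sum(width^2))
  sg <- control$mutation_sigma0 * (1 - t / control$max_iter) *
    max(dispersion, .Machine$double.xmin)
  trials <- rbind(
    x_best + rnorm(space$dim, sd = max(sg, .Machine$double.xmin)),
    x_best + rcauchy(space$dim, scale = control$mutation_sigma0 * width)
  )
  trials <- clip_to_space(trials, space)
  for (k in 1:2) {
    f <- fitness(trials[k, ])
    if (f > f_best) {
      x_best <- trials[k, ]
      f_best <- f
    }
  }
  list(position = x_best, fitness = f_best, evals = 2L)
}

#' Sparrow search optimisation
#'
#' Maximises `fitness` over a box. The baseline `variant = "ssa"` uses uniform
#' random initialisation, the canonical explorer/follower/scout updates and no
#' mutation. `variant = "issa"` adds the three improvements: chaotic
#' opposition-based initialisation ([chaotic_obl_init()]), the adaptive
#' follower weight ([dynamic_weight()]), and hybrid Gaussian/Cauchy mutation of
#' the incumbent best ([hybrid_mutation()]). The best-so-far is tracked
#' elitistically, so the fitness history is non-decreasing. Total fitness
#' evaluations are at most `2 n + max_iter (n + 2)`.
#'
#' @param fitness Function position -> fitness (higher is better).
#' @param space A [search_space()].
#' @param control An [ssa_control()].
#' @param variant `"issa"` or `"ssa"`.
#' @param seed Integer seed; fixed seed reproduces the result exactly.
#' @return An `ssa_result`: `best_position`, `best_fitness`, `history`
#'   (best-so-far per iteration, element 1 = after initialisation), `evals`,
#'   `variant`.
#' @examples
#' res <- ssa_optimize(function(x) -sum(x^2), search_space(c(-5, -5), c(5, 5)),
#'                     ssa_control(pop_size = 10, max_iter = 20), seed = 1)
#' res$best_fitness
#' @export
ssa_optimize <- function(fitness, space, control = ssa_control(),
                         variant = c("issa", "ssa"), seed = 1L) {
  variant <- match.arg(variant)
  n <- control$pop_size
  withr::with_seed(seed, {
    if (variant == "issa") {
      init <- chaotic_obl_init(space, n, fitness,
                               c = control$chaos_c, d = control$chaos_d)
      pos <- init$positions; fit <- init$fitness; evals <- init$evals
    } else {
      pos <- matrix(runif(n * space$dim), n, space$dim) *
        matrix(space$upper - space$lower, n, space$dim, byrow = TRUE) +
        matrix(space$lower, n, space$dim, byrow = TRUE)
      fit <- apply(pos, 1, fitness)
      evals <- n
    }

    ibest <- which.max(fit)
    x_best <- pos[ibest, ]; f_best <- fit[ibest]
    history <- numeric(control$max_iter + 1)
    history[1] <- f_best

    n_exp <- max(1L, ceiling(control$explorer_frac * n))
    for (t in seq_len(control$max_iter)) {
      ord <- order(fit, decreasing = TRUE)
      pos <- pos[ord, , drop = FALSE]; fit <- fit[ord]
      x_worst <- pos[n, ]; f_w <- fit[n]

      exp_idx <- seq_len(n_exp)
      pos[exp_idx, ] <- update_explorers(pos[exp_idx, , drop = FALSE],
                                         space, control, t)
      x_p <- pos[1, ] # best-ranked explorer, post update

      fol_idx <- setdiff(seq_len(n), exp_idx)
      if (length(fol_idx) > 0) {
        psi <- if (variant == "issa") dynamic_weight(t, control$max_iter) else 1
        pos[fol_idx, ] <- update_followers(pos[fol_idx, , drop = FALSE],
                                           ranks = fol_idx, x_p = x_p,
                                           x_worst = x_worst, psi = psi,
                                           space = space, n_total = n)
      }

      sd_frac <- runif(1, control$scout_frac_range[1], control$scout_frac_range[2])
      sc_idx <- sample.int(n, max(1L, ceiling(sd_frac * n)))
      pos[sc_idx, ] <- update_scouts(pos[sc_idx, , drop = FALSE], fit[sc_idx],
                                     x_best, x_worst, f_best, f_w, space)

      fit <- apply(pos, 1, fitness)
      evals <- evals + n
      ibest <- which.max(fit)
      if (fit[ibest] > f_best) {
        f_best <- fit[ibest]; x_best <- pos[ibest, ]
      }

      if (variant == "issa") {
        disp <- mean(sqrt(rowSums(
          (pos - matrix(x_best, n, space$dim, byrow = TRUE))^2
        )))
        mut <- hybrid_mutation(x_best, f_best, fitness, space, control, t,
                               dispersion = disp)
        x_best <- mut$position; f_best <- mut$fitness
        evals <- evals + mut$evals
      }
      history[t + 1] <- f_best
    }

    structure(list(best_position = x_best, best_fitness = f_best,
                   history = history, evals = evals, variant = variant,
                   control = control, space = space),
              class = "ssa_result")
  })
}

#' @export
print.ssa_result <- function(x, ...) {
  cat("<ssa_result> variant = ", x$variant, ", best fitness = ",
      signif(x$best_fitness, 6), " after ", x$evals, " evaluations\n", sep = "")
  invisible(x)
}

#' @export
tidy.ssa_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history) - 1L, best_fitness = x$history)
}

#' @export
glance.ssa_result <- function(x, ...) {
  tibble::tibble(variant = x$variant, best_fitness = x$best_fitness,
                 evals = x$evals, iterations = x$control$max_iter)
}

#' Benchmark objective functions
#'
#' Standard continuous test functions, negated so that the package's
#' maximisation convention applies (global optimum 0 at the origin): sphere
#' `-sum(x^2)`, Rastrigin and Ackley.
#'
#' @param name `"sphere"`, `"rastrigin"` or `"ackley"`.
#' @return A function position -> fitness.
#' @examples
#' benchmark_function("sphere")(c(0, 0))
#' @export
benchmark_function <- function(name = c("sphere", "rastrigin", "ackley")) {
  name <- match.arg(name)
  switch(name,
    sphere = function(x) -sum(x^2),
    rastrigin = function(x) {
      -(10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)))
    },
    ackley = function(x) {
      -(20 + exp(1) - 20 * exp(-0.2 * sqrt(mean(x^2))) - exp(mean(cos(2 * pi * x))))
    }
  )
}
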