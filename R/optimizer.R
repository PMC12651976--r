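#' HGWO-PSO configuration
#'
#' Hybrid grey-wolf / particle-swarm binary feature search: an elitist
#' alpha/beta/delta leader hierarchy (grey-wolf side) combined with the
#' inertia-weighted PSO velocity update toward personal and global bests.
#' Defaults follow the benchmark settings: 10 wolves, 100 iterations,
#' inertia annealed linearly 0.8 to 0.4, c1 = c2 = 2, and the wrapper
#' fitness `F = 0.9 Acc + 0.1 (1 - Fr)` where `Fr` is the fraction of
#' features selected.
#'
#' @param n_wolves Population size (>= 4: three leaders plus followers).
#' @param iterations Number of iterations T (>= 1).
#' @param w_start,w_end Inertia weight schedule endpoints.
#' @param c1,c2 Cognitive / social acceleration coefficients.
#' @param acc_weight,parsimony_weight Fitness weights (must sum to 1).
#' @param v_max Velocity clamp; keeps the sigmoid transfer responsive.
#' @param binarize `"stochastic"` (Bernoulli at the sigmoid probability) or
#'   `"threshold"` (deterministic cut at 0.5).
#' @param leader_combine Global best: `"alpha"` (the alpha wolf) or
#'   `"mean3"` (mean of the three leader positions).
#' @param seed Integer seed for the whole run.
#' @return A list of class `hgwo_pso_config`.
#' @export
hgwo_pso_config <- function(n_wolves = 10L, iterations = 100L,
                            w_start = 0.8, w_end = 0.4, c1 = 2, c2 = 2,
                            acc_weight = 0.9, parsimony_weight = 0.1,
                            v_max = 6, binarize = c("stochastic", "threshold"),
                            leader_combine = c("alpha", "mean3"), seed = 1L) {
  stopifnot(n_wolves >= 4, iterations >= 1, v_max > 0)
  if (abs(acc_weight + parsimony_weight - 1) > 1e-9) {
    abort("acc_weight and parsimony_weight must sum to 1")
  }
  structure(list(n_wolves = as.integer(n_wolves), iterations = as.integer(iterations),
                 w_start = w_start, w_end = w_end, c1 = c1, c2 = c2,
                 acc_weight = acc_weight, parsimony_weight = parsimony_weight,
                 v_max = v_max, binarize = match.arg(binarize),
                 leader_combine = match.arg(leader_combine), seed = as.integer(seed)),
            class = "hgwo_pso_config")
}

#' Wrapper fitness of a feature mask
#'
#' `F = acc_weight * Acc + parsimony_weight * (1 - Fr)` with
#' `Fr = |mask| / d`, so equal-accuracy smaller subsets score strictly
#' higher. An empty mask is never evaluated: it returns fitness 0 flagged
#' invalid.
#'
#' @param mask Logical/0-1 vector of feature inclusions.
#' @param evaluator A function `mask -> accuracy in [0, 1]`, or a
#'   [fitness_evaluator()].
#' @param acc_weight,parsimony_weight Fitness weights.
#' @return List with `f`, `acc`, `fr`, `valid`.
#' @export
fitness <- function(mask, evaluator, acc_weight = 0.9, parsimony_weight = 0.1) {
  mask <- as.logical(mask)
  d <- length(mask)
  if (!any(mask)) {
    return(list(f = 0, acc = NA_real_, fr = 0, valid = FALSE))
  }
  acc <- if (is.function(evaluator)) evaluator(mask) else evaluator_accuracy(evaluator, mask)
  fr <- sum(mask) / d
  list(f = acc_weight * acc + parsimony_weight * (1 - fr), acc = acc, fr = fr,
       valid = TRUE)
}

#' Linearly annealed inertia weight
#'
#' `w(t) = w_start + (w_end - w_start) * t / T`.
#'
#' @param t Current iteration (0 <= t <= T).
#' @param T Total iterations.
#' @param w_start,w_end Schedule endpoints.
#' @return The inertia weight at iteration `t`.
#' @export
inertia <- function(t, T, w_start = 0.8, w_end = 0.4) {
  stopifnot(t >= 0, t <= T)
  w_start + (w_end - w_start) * t / T
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Personal and global bests are stored as binary masks; in the velocity
# update they act as attractors through the same finite-logit encoding used
# at initialization (selected -> +scale, dropped -> -scale).
encode_mask <- function(mask, scale = 2) ifelse(mask, scale, -scale)

# One PSO-style update of a follower wolf. Uses the current RNG stream for
# r1, r2 and the Bernoulli binarization. `wolf` is a list with position,
# velocity, mask, pbest_mask, pbest_f.
update_wolf <- function(wolf, gbest, w, cfg) {
  d <- length(wolf$position)
  r1 <- runif(d); r2 <- runif(d)
  v <- w * wolf$velocity +
    cfg$c1 * r1 * (encode_mask(wolf$pbest_mask) - wolf$position) +
    cfg$c2 * r2 * (gbest - wolf$position)
  v <- pmin(pmax(v, -cfg$v_max), cfg$v_max)
  # the position feeds the sigmoid transfer, so it is clamped to the same
  # band; an unbounded position saturates the selection probabilities at
  # 0/1 and freezes the bits
  x <- pmin(pmax(wolf$position + v, -cfg$v_max), cfg$v_max)
  s <- sigmoid(x)
  mask <- if (cfg$binarize == "threshold") s >= 0.5 else runif(d) < s
  if (!any(mask)) {
    mask <- if (cfg$binarize == "threshold") s >= 0.5 else runif(d) < s
    if (!any(mask)) mask[which.max(s)] <- TRUE
  }
  wolf$velocity <- v
  wolf$position <- x
  wolf$mask <- mask
  wolf
}

#' Run the HGWO-PSO binary feature search
#'
#' Initializes masks Bernoulli(0.5) (empty masks resampled) with positions
#' at a finite logit of the mask bits and zero velocity. Each iteration the
#' three best wolves by fitness form the elitist alpha/beta/delta hierarchy
#' (replaced only by strictly better agents, so the best-so-far fitness
#' never decreases); all remaining wolves take an inertia-weighted velocity
#' step toward their personal-best mask and the global-best (alpha) mask,
#' both acting as attractors through the finite-logit encoding; positions
#' pass through a sigmoid transfer, and bits are resampled.
#' Fitness values are cached per mask, so the wrapper accuracy is a pure
#' function of the mask.
#'
#' @param evaluator A function `mask -> accuracy`, or a
#'   [fitness_evaluator()]; it must be bound to training rows only.
#' @param d Number of features (>= 1).
#' @param cfg An [hgwo_pso_config()].
#' @return An object of class `hgwo_pso`: `best_mask`, `best_fitness`
#'   (list `f`, `acc`, `fr`), `history` tibble (one row per iteration), the
#'   per-iteration leader masks, `cfg` and `d`.
#' @export
run_hgwo_pso <- function(evaluator, d, cfg = hgwo_pso_config()) {
  if (d < 1) abort("dimension error: d must be >= 1")
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  eval_mask <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    got <- get0(key, envir = cache)
    if (!is.null(got)) return(got)
    res <- fitness(mask, evaluator, cfg$acc_weight, cfg$parsimony_weight)
    n_evals <<- n_evals + 1L
    assign(key, res, envir = cache)
    res
  }

  withr::with_seed(cfg$seed, {
    n <- cfg$n_wolves
    wolves <- vector("list", n)
    for (i in seq_len(n)) {
      mask <- runif(d) < 0.5
      tries <- 0L
      while (!any(mask) && tries < 100L) {
        mask <- runif(d) < 0.5
        tries <- tries + 1L
      }
      if (!any(mask)) mask[1] <- TRUE
      pos <- encode_mask(mask)       # finite stand-in for logit(mask)
      fit <- eval_mask(mask)
      wolves[[i]] <- list(position = pos, velocity = rep(0, d), mask = mask,
                          fitness = fit, pbest_mask = mask, pbest_f = fit$f)
    }

    rank_leaders <- function(wolves, incumbents) {
      f <- vapply(wolves, function(wf) wf$fitness$f, numeric(1))
      # stable elitist ranking: on ties, prefer the current leaders
      pref <- match(seq_along(wolves), incumbents, nomatch = length(wolves) + 1L)
      order(-f, pref)[1:3]
    }

    leaders <- rank_leaders(wolves, integer(0))
    history <- vector("list", cfg$iterations)

    for (t in seq_len(cfg$iterations)) {
      w <- inertia(t, cfg$iterations, cfg$w_start, cfg$w_end)
      gbest <- if (cfg$leader_combine == "alpha") {
        encode_mask(wolves[[leaders[1]]]$mask)
      } else {
        (encode_mask(wolves[[leaders[1]]]$mask) +
           encode_mask(wolves[[leaders[2]]]$mask) +
           encode_mask(wolves[[leaders[3]]]$mask)) / 3
      }
      for (i in setdiff(seq_len(n), leaders)) {
        wf <- update_wolf(wolves[[i]], gbest, w, cfg)
        wf$fitness <- eval_mask(wf$mask)
        if (wf$fitness$f > wf$pbest_f) {
          wf$pbest_f <- wf$fitness$f
          wf$pbest_mask <- wf$mask
        }
        wolves[[i]] <- wf
      }
      leaders <- rank_leaders(wolves, leaders)
      best <- wolves[[leaders[1]]]$fitness
      history[[t]] <- tibble::tibble(iteration = t, inertia = w,
                                     best_f = best$f, best_acc = best$acc,
                                     best_fr = best$fr,
                                     n_selected = sum(wolves[[leaders[1]]]$mask))
    }

    alpha <- wolves[[leaders[1]]]
    structure(list(best_mask = alpha$mask, best_fitness = alpha$fitness,
                   history = dplyr::bind_rows(history), cfg = cfg, d = d,
                   n_evaluations = n_evals),
              class = "hgwo_pso")
  })
}

#' @export
print.hgwo_pso <- function(x, ...) {
  cat(sprintf("<hgwo_pso: %d/%d features selected, F = %.4f (Acc %.4f, Fr %.3f)>\n",
              sum(x$best_mask), x$d, x$best_fitness$f, x$best_fitness$acc,
              x$best_fitness$fr))
  invisible(x)
}

#' @rdname run_hgwo_pso
#' @param x An `hgwo_pso` fit.
#' @param feature_names Optional names for the `d` features.
#' @param ... Unused.
#' @export
tidy.hgwo_pso <- function(x, feature_names = NULL, ...) {
  nm <- feature_names %||% paste0("feature", seq_len(x$d))
  tibble::tibble(feature = nm, index = seq_len(x$d), selected = x$best_mask)
}

#' @rdname run_hgwo_pso
#' @export
glance.hgwo_pso <- function(x, ...) {
  tibble::tibble(fitness = x$best_fitness$f, accuracy = x$best_fitness$acc,
                 fraction_selected = x$best_fitness$fr,
                 n_selected = sum(x$best_mask), d = x$d,
                 iterations = x$cfg$iterations, n_evaluations = x$n_evaluations)
}
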