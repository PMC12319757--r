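#' Differential Evolution global optimizer
#'
#' Box-constrained global minimization by Differential Evolution with the
#' best/1/bin strategy: each trial vector is built from the current best
#' member plus a scaled difference of two random members, mixed with its
#' parent by binomial crossover, and replaces the parent only if it lowers
#' the cost. Used by the IVIM fitting routines to escape the local optima
#' of the biexponential least-squares surface; exposed because a seedable,
#' dependency-free global optimizer is occasionally useful on its own.
#'
#' The cost function is called on the whole population at once (a matrix
#' with one candidate per row) and must return one cost per row, which keeps
#' the per-generation overhead small in R.
#'
#' Convergence is declared when the population costs have collapsed:
#' \code{sd(costs) <= reltol * |mean(costs)| + abstol}.
#'
#' @param cost function taking an n x d numeric matrix of candidates and
#'   returning a length-n numeric vector of costs.
#' @param lower,upper numeric vectors of box bounds (length d). A dimension
#'   with \code{lower == upper} is held fixed.
#' @param n_pop population size; default \code{15 * d} (minimum 8).
#' @param mutation differential weight; a single value in (0, 2], or a
#'   length-2 range from which the weight is redrawn uniformly each
#'   generation (dithering, which preserves population diversity and
#'   guards against premature convergence).
#' @param crossover crossover probability, in [0, 1].
#' @param reltol,abstol convergence tolerances on the population cost spread.
#' @param max_iter maximum number of generations.
#' @param seed optional integer seed; when given, the global RNG state is
#'   saved and restored so the optimizer is reproducible without disturbing
#'   the caller's random stream.
#' @param init optional matrix (or vector) of candidates injected into the
#'   initial population, e.g. a prior estimate.
#' @return A list with elements \code{par} (best candidate), \code{value}
#'   (its cost), \code{iterations}, and \code{converged} (logical; FALSE
#'   means the generation budget was exhausted, the best member found is
#'   still returned).
#' @export
de_optimize <- function(cost, lower, upper, n_pop = NULL,
                        mutation = c(0.5, 1.0), crossover = 0.9,
                        reltol = 1e-7, abstol = 1e-14,
                        max_iter = 1000, seed = NULL, init = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  if (is.null(n_pop)) n_pop <- max(8L, 15L * d)
  n_pop <- max(8L, as.integer(n_pop))

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }

  span <- upper - lower
  pop <- matrix(runif(n_pop * d), n_pop, d) *
    matrix(span, n_pop, d, byrow = TRUE) +
    matrix(lower, n_pop, d, byrow = TRUE)
  if (!is.null(init)) {
    init <- matrix(pmin(pmax(as.numeric(t(init)), lower), upper),
                   ncol = d, byrow = TRUE)
    k <- min(nrow(init), n_pop)
    pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }

  costs <- cost(pop)
  if (length(costs) != n_pop || any(is.na(costs)))
    stop("cost function must return one finite cost per candidate", call. = FALSE)

  converged <- FALSE
  iter <- 0L
  lo <- matrix(lower, n_pop, d, byrow = TRUE)
  hi <- matrix(upper, n_pop, d, byrow = TRUE)
  while (iter < max_iter) {
    iter <- iter + 1L
    best <- pop[which.min(costs), ]

    ## best/1 mutation: random distinct pair per member
    r1 <- sample.int(n_pop, n_pop, replace = TRUE)
    r2 <- sample.int(n_pop, n_pop, replace = TRUE)
    clash <- r1 == r2
    while (any(clash)) {
      r2[clash] <- sample.int(n_pop, sum(clash), replace = TRUE)
      clash <- r1 == r2
    }
    f_gen <- if (length(mutation) == 2)
      stats::runif(1, mutation[1], mutation[2]) else mutation
    mutant <- matrix(best, n_pop, d, byrow = TRUE) +
      f_gen * (pop[r1, , drop = FALSE] - pop[r2, , drop = FALSE])

    ## binomial crossover with one guaranteed mutant dimension per member
    take <- matrix(runif(n_pop * d) < crossover, n_pop, d)
    forced <- cbind(seq_len(n_pop),
                    sample.int(d, n_pop, replace = TRUE))
    take[forced] <- TRUE
    trial <- ifelse(take, mutant, pop)
    trial <- pmin(pmax(trial, lo), hi)

    trial_costs <- cost(trial)
    improve <- trial_costs < costs
    if (any(improve)) {
      pop[improve, ] <- trial[improve, , drop = FALSE]
      costs[improve] <- trial_costs[improve]
    }

    if (stats::sd(costs) <= reltol * abs(mean(costs)) + abstol) {
      converged <- TRUE
      break
    }
  }

  i_best <- which.min(costs)
  list(par = pop[i_best, ], value = costs[i_best],
       iterations = iter, converged = converged)
}
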