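#' Fitting configuration for the IVIM algorithms
#'
#' Collects every tunable of the constrained one-step and two-step fits:
#' the physical parameter bounds enforced by the global optimizer, the
#' high-b cut-off of the mono-exponential prior fit, the fractional window
#' of the fine-tuning pass, how S0 is handled, and the Differential
#' Evolution settings (including the seed, echoed into every result for
#' provenance).
#'
#' Default bounds are the published physiological ranges for cord/brain
#' tissue: F in [0, 0.20] (fraction), D* in [0.3e-3, 50e-3] mm^2/s, D in
#' [1.5e-4, 54e-4] mm^2/s. S0 is by default fitted as a fourth free
#' parameter inside \code{s0_factor} times the observed b = 0 signal,
#' which absorbs noise in the b = 0 frames; \code{s0_mode = "fixed"} pins
#' S0 to the observed b = 0 value instead.
#'
#' The prior mono-exponential D estimate always seeds the optimizer's
#' initial population; with \code{use_prior_bounds = TRUE} it additionally
#' narrows the D search interval to \code{prior_window} times the prior,
#' intersected with the global bounds (which always remain the outer
#' constraint).
#'
#' @param algorithm \code{"one_step"} (all parameters fitted jointly over
#'   all b-values) or \code{"two_step"} (D fixed from the high-b
#'   mono-exponential fit, then F and D* fitted).
#' @param mode \code{"voxel_wise"} or \code{"roi_wise"}; carried as
#'   provenance, the fit itself is identical for a voxel or an ROI decay.
#' @param bounds named list of \code{c(low, high)} for \code{F},
#'   \code{Dstar}, \code{D}.
#' @param s0_factor multiplicative bounds on S0 relative to the observed
#'   b = 0 signal.
#' @param s0_mode \code{"fit"} or \code{"fixed"}.
#' @param cutoff_b high-b threshold (s/mm^2) for the prior D fit.
#' @param finetune_window fractional bounds of the refinement pass around
#'   the previous estimates; must bracket 1.
#' @param use_prior_bounds narrow the D interval around the prior estimate
#'   (see above).
#' @param prior_window fractional window applied to the prior D when
#'   \code{use_prior_bounds} is TRUE.
#' @param n_pop_per_par,mutation,crossover,reltol,max_iter Differential
#'   Evolution settings (population size is \code{n_pop_per_par} times the
#'   number of free parameters).
#' @param seed integer seed making every fit reproducible.
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(algorithm = c("one_step", "two_step"),
                       mode = c("voxel_wise", "roi_wise"),
                       bounds = list(F = c(0, 0.20),
                                     Dstar = c(0.3e-3, 50e-3),
                                     D = c(1.5e-4, 54e-4)),
                       s0_factor = c(0.5, 1.5),
                       s0_mode = c("fit", "fixed"),
                       cutoff_b = 400,
                       finetune_window = c(0.95, 1.05),
                       use_prior_bounds = FALSE,
                       prior_window = c(0.5, 2.0),
                       n_pop_per_par = 15L,
                       mutation = c(0.5, 1.0), crossover = 0.9,
                       reltol = 1e-7, max_iter = 1000L,
                       seed = 1234L) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  s0_mode <- match.arg(s0_mode)
  stopifnot(all(c("F", "Dstar", "D") %in% names(bounds)))
  for (p in c("F", "Dstar", "D")) {
    b <- bounds[[p]]
    if (length(b) != 2 || b[1] >= b[2] || b[1] < 0)
      stop("invalid bounds for ", p, call. = FALSE)
  }
  if (!(finetune_window[1] < 1 && 1 < finetune_window[2]))
    stop("finetune_window must bracket 1", call. = FALSE)
  structure(list(algorithm = algorithm, mode = mode, bounds = bounds,
                 s0_factor = s0_factor, s0_mode = s0_mode,
                 cutoff_b = cutoff_b, finetune_window = finetune_window,
                 use_prior_bounds = use_prior_bounds,
                 prior_window = prior_window,
                 n_pop_per_par = as.integer(n_pop_per_par),
                 mutation = mutation, crossover = crossover,
                 reltol = reltol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Mono-exponential prior estimate of D from the high-b tail
#'
#' Least-squares fit of log S against b restricted to b-values strictly
#' above the cut-off, where the perfusion compartment has decayed out and
#' the signal is mono-exponential in the tissue diffusivity. The slope
#' gives D (clipped into the physical D bounds) and the intercept the
#' back-extrapolated high-b amplitude.
#'
#' @param decay a \code{\link{signal_decay}}.
#' @param cutoff_b threshold (s/mm^2); only b > cutoff_b points are used.
#' @param d_bounds clipping interval for D (mm^2/s).
#' @return list with \code{D} (clipped slope estimate) and \code{S0_highb}
#'   (exponentiated intercept).
#' @export
estimate_D_monoexp <- function(decay, cutoff_b = 400,
                               d_bounds = c(1.5e-4, 54e-4)) {
  b <- decay$scheme$bvalues
  s <- decay$values
  use <- b > cutoff_b
  if (sum(use) < 2)
    stop("insufficient-data: need >= 2 b-values above the cutoff", call. = FALSE)
  if (any(s[use] <= 0))
    stop("log-domain: non-positive signal above the cutoff", call. = FALSE)
  bb <- b[use]
  ls <- log(s[use])
  slope <- sum((bb - mean(bb)) * (ls - mean(ls))) / sum((bb - mean(bb))^2)
  intercept <- mean(ls) - slope * mean(bb)
  list(D = min(max(-slope, d_bounds[1]), d_bounds[2]),
       S0_highb = exp(intercept))
}

## Vectorized sum-of-squared-residuals cost over a candidate population.
## `fixed` holds values for parameters not in `free` (by name).
ivim_ssr_cost <- function(b, s, free, fixed = list()) {
  force(b); force(s)
  function(pop) {
    get_par <- function(name) {
      if (name %in% free) pop[, match(name, free)]
      else rep(fixed[[name]], nrow(pop))
    }
    S0 <- get_par("S0"); F <- get_par("F")
    Dstar <- get_par("Dstar"); D <- get_par("D")
    model <- (S0 * exp(-outer(D, b))) *
      (F * exp(-outer(Dstar, b)) + (1 - F))
    rowSums((model - matrix(s, nrow(pop), length(s), byrow = TRUE))^2)
  }
}

## Shrink bounds to the fine-tuning window around an estimate, intersected
## with the outer bounds; an estimate sitting on a bound gets a one-sided
## window, and a zero estimate a width-zero (fixed) interval.
finetune_bounds <- function(est, window, outer) {
  lo <- pmax(window[1] * est, outer[1])
  hi <- pmin(window[2] * est, outer[2])
  if (hi < lo) { lo <- hi <- min(max(est, outer[1]), outer[2]) }
  c(lo, hi)
}

run_de_stage <- function(b, s, free, fixed, lower, upper, config, seed, init) {
  cost <- ivim_ssr_cost(b, s, free, fixed)
  de_optimize(cost, lower, upper,
              n_pop = config$n_pop_per_par * length(free),
              mutation = config$mutation, crossover = config$crossover,
              reltol = config$reltol, max_iter = config$max_iter,
              seed = seed, init = init)
}

validate_fit_input <- function(decay) {
  if (!inherits(decay, "signal_decay"))
    stop("decay must be a signal_decay", call. = FALSE)
  if (all(decay$values == 0))
    stop("invalid-signal: all-zero decay cannot be fitted", call. = FALSE)
}

make_fit_result <- function(par, decay, config, converged, extra = list()) {
  params <- ivim_params(S0 = par[["S0"]], F = par[["F"]],
                        Dstar = par[["Dstar"]], D = par[["D"]])
  fitted <- forward_signal(params, decay$scheme)
  structure(c(list(params = params,
                   r2 = r_squared(decay, fitted),
                   converged = converged,
                   n_points = length(decay$values),
                   provenance = list(algorithm = config$algorithm,
                                     mode = config$mode,
                                     seed = config$seed)),
              extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("IVIM %s fit (%s): R2 = %.4f, converged = %s\n",
              x$provenance$algorithm, x$provenance$mode, x$r2, x$converged))
  print(x$params)
  invisible(x)
}

#' One-step constrained IVIM fit
#'
#' Three stages, in order: (1) a prior mono-exponential estimate of D from
#' b-values above the cut-off; (2) a global Differential Evolution fit of
#' (S0, F, D*, D) over all b-values, minimizing the sum of squared
#' residuals against the biexponential model within the physical bounds,
#' with the prior seeded into the initial population; (3) a fine-tuning
#' pass in which every free parameter's bounds are shrunk to the
#' fine-tuning window (default 95--105 percent) around its stage-2
#' estimate, intersected with the global bounds, and the fit repeated.
#' The result carries the stage-3 estimates and their R^2.
#'
#' If the stage-2 perfusion fraction is numerically zero (F <= 1e-6), D*
#' is unidentifiable: it is reported at its lower bound and flagged via
#' \code{dstar_identifiable = FALSE} rather than left arbitrary.
#'
#' @param decay a \code{\link{signal_decay}}.
#' @param config a \code{\link{fit_config}}; \code{config$algorithm} is
#'   ignored here (this function is the one-step algorithm).
#' @return A \code{fit_result}: list with \code{params}
#'   (\code{\link{ivim_params}}), \code{r2}, \code{converged},
#'   \code{n_points}, \code{provenance}, \code{prior_D},
#'   \code{dstar_identifiable}.
#' @export
fit_one_step <- function(decay, config = fit_config("one_step")) {
  validate_fit_input(decay)
  b <- decay$scheme$bvalues
  s <- decay$values
  prior <- estimate_D_monoexp(decay, config$cutoff_b, config$bounds$D)

  s0_obs <- s[1]
  if (config$s0_mode == "fixed") s0_bounds <- c(s0_obs, s0_obs)
  else s0_bounds <- config$s0_factor * s0_obs
  d_bounds <- config$bounds$D
  if (config$use_prior_bounds) {
    d_bounds <- c(max(config$prior_window[1] * prior$D, d_bounds[1]),
                  min(config$prior_window[2] * prior$D, d_bounds[2]))
    if (d_bounds[2] < d_bounds[1]) d_bounds <- config$bounds$D
  }

  free <- c("S0", "F", "Dstar", "D")
  lower <- c(s0_bounds[1], config$bounds$F[1], config$bounds$Dstar[1], d_bounds[1])
  upper <- c(s0_bounds[2], config$bounds$F[2], config$bounds$Dstar[2], d_bounds[2])
  ## seed the population with the mono-exponential prior D combined with a
  ## coarse grid over the perfusion plane, so the global basin is always
  ## represented among the initial candidates
  init <- cbind(s0_obs,
                rep(c(0, 0.03, 0.08, 0.15), times = 3),
                rep(c(3e-3, 10e-3, 30e-3), each = 4),
                prior$D)
  init <- pmin(pmax(init, matrix(lower, nrow(init), 4, byrow = TRUE)),
               matrix(upper, nrow(init), 4, byrow = TRUE))

  stage2 <- run_de_stage(b, s, free, list(), lower, upper, config,
                         seed = config$seed, init = init)
  est <- stats::setNames(stage2$par, free)

  dstar_ok <- TRUE
  if (est[["F"]] <= 1e-6) {
    est[["Dstar"]] <- config$bounds$Dstar[1]
    dstar_ok <- FALSE
  }

  ft <- mapply(function(e, lo, hi) finetune_bounds(e, config$finetune_window, c(lo, hi)),
               est, lower, upper)
  stage3 <- run_de_stage(b, s, free, list(), ft[1, ], ft[2, ], config,
                         seed = config$seed + 1L, init = rbind(est))
  final <- stats::setNames(stage3$par, free)
  if (!dstar_ok) final[["Dstar"]] <- config$bounds$Dstar[1]

  make_fit_result(final, decay, config,
                  converged = stage2$converged && stage3$converged,
                  extra = list(prior_D = prior$D,
                               dstar_identifiable = dstar_ok))
}

#' Two-step (segmented) constrained IVIM fit
#'
#' D is first estimated by the mono-exponential fit on b-values above the
#' cut-off and then held fixed throughout: stage 2 fits (S0, F, D*) over
#' all b-values by Differential Evolution, and stage 3 fine-tunes F and D*
#' (and S0 when it is free) within the shrunk window, with D still fixed
#' to its initial estimate. The returned D equals the stage-1 estimate
#' exactly.
#'
#' @inheritParams fit_one_step
#' @return A \code{fit_result}; \code{params$D} is the clipped
#'   mono-exponential slope estimate.
#' @export
fit_two_step <- function(decay, config = fit_config("two_step")) {
  validate_fit_input(decay)
  b <- decay$scheme$bvalues
  s <- decay$values
  prior <- estimate_D_monoexp(decay, config$cutoff_b, config$bounds$D)

  s0_obs <- s[1]
  if (config$s0_mode == "fixed") s0_bounds <- c(s0_obs, s0_obs)
  else s0_bounds <- config$s0_factor * s0_obs

  free <- c("S0", "F", "Dstar")
  fixed <- list(D = prior$D)
  lower <- c(s0_bounds[1], config$bounds$F[1], config$bounds$Dstar[1])
  upper <- c(s0_bounds[2], config$bounds$F[2], config$bounds$Dstar[2])
  init <- cbind(s0_obs,
                rep(c(0, 0.03, 0.08, 0.15), times = 3),
                rep(c(3e-3, 10e-3, 30e-3), each = 4))
  init <- pmin(pmax(init, matrix(lower, nrow(init), 3, byrow = TRUE)),
               matrix(upper, nrow(init), 3, byrow = TRUE))

  stage2 <- run_de_stage(b, s, free, fixed, lower, upper, config,
                         seed = config$seed, init = init)
  est <- stats::setNames(stage2$par, free)

  dstar_ok <- TRUE
  if (est[["F"]] <= 1e-6) {
    est[["Dstar"]] <- config$bounds$Dstar[1]
    dstar_ok <- FALSE
  }

  ft <- mapply(function(e, lo, hi) finetune_bounds(e, config$finetune_window, c(lo, hi)),
               est, lower, upper)
  stage3 <- run_de_stage(b, s, free, fixed, ft[1, ], ft[2, ], config,
                         seed = config$seed + 1L, init = rbind(est))
  final <- stats::setNames(stage3$par, free)
  if (!dstar_ok) final[["Dstar"]] <- config$bounds$Dstar[1]
  final <- c(final, D = prior$D)

  make_fit_result(final, decay, config,
                  converged = stage2$converged && stage3$converged,
                  extra = list(prior_D = prior$D,
                               dstar_identifiable = dstar_ok))
}

#' Fit one decay with the configured algorithm
#'
#' @param decay a \code{\link{signal_decay}}.
#' @param config a \code{\link{fit_config}}; dispatches on
#'   \code{config$algorithm}.
#' @return A \code{fit_result}.
#' @export
fit_decay <- function(decay, config = fit_config()) {
  switch(config$algorithm,
         one_step = fit_one_step(decay, config),
         two_step = fit_two_step(decay, config))
}

fit_result_vector <- function(fr) {
  c(F = fr$params$F, Dstar = fr$params$Dstar, D = fr$params$D,
    FDstar = fr$params$FDstar, S0 = fr$params$S0, r2 = fr$r2)
}

## Deterministic per-voxel seed derived from the config seed and the voxel's
## linear index; independent of session and direction so identical decays in
## different sessions fit identically.
voxel_seed <- function(base_seed, idx) {
  as.integer((as.numeric(base_seed) + 7919 * as.numeric(idx)) %% 2147483563)
}

#' Voxel-wise IVIM fitting of a repetition-averaged acquisition
#'
#' Runs the configured algorithm on every masked voxel's decay, for every
#' diffusion-encoding direction, producing one parameter map per IVIM
#' parameter (plus S0 and R^2) per direction on the input grid. Unmasked
#' voxels carry NA. Identical decays (common in noiseless phantoms) are
#' fitted once and the result reused; together with per-voxel seeds derived
#' only from the configuration seed and voxel index, results are
#' independent of execution order.
#'
#' @param data a repetition-averaged \code{diffusion_dataset} (see
#'   \code{\link{average_repetitions}}); non-averaged data are averaged on
#'   the fly.
#' @param mask binary 3D array on the data grid; defaults to the dataset's
#'   cord mask.
#' @param config a \code{\link{fit_config}}.
#' @return Named list (one element per direction) of lists of 3D maps
#'   \code{F}, \code{Dstar}, \code{D}, \code{FDstar}, \code{S0}, \code{r2}.
#' @export
fit_voxelwise <- function(data, mask = data$masks$cord, config = fit_config()) {
  data <- average_repetitions(data)
  if (sum(mask) == 0) stop("empty-mask: no voxels to fit", call. = FALSE)
  idx <- which(mask > 0)
  scheme <- data$scheme
  out <- list()
  for (dir in names(data$volumes)) {
    vol <- data$volumes[[dir]]
    dm <- dim(vol)[1:3]
    maps <- lapply(1:6, function(i) array(NA_real_, dm))
    names(maps) <- c("F", "Dstar", "D", "FDstar", "S0", "r2")
    cache <- new.env(hash = TRUE, parent = emptyenv())
    flat <- matrix(vol, prod(dm), dim(vol)[4])
    for (v in idx) {
      sig <- flat[v, ]
      key <- paste(signif(sig, 12), collapse = ",")
      res <- cache[[key]]
      if (is.null(res)) {
        cfg <- config
        cfg$seed <- voxel_seed(config$seed, v)
        fr <- fit_decay(signal_decay(sig, scheme), cfg)
        res <- fit_result_vector(fr)
        cache[[key]] <- res
      }
      for (p in names(maps)) maps[[p]][v] <- res[[p]]
    }
    out[[dir]] <- maps
  }
  out
}

#' Probability-weighted ROI-average decay for one slice
#'
#' For each b-value, returns the weighted average
#' sum(p_i * s_i) / sum(p_i) of the voxel signals s_i in the slice, with
#' weights the probabilistic-mask values p_i.
#'
#' @param vol 4D array (x, y, z, b) of repetition-averaged signal for one
#'   direction.
#' @param prob_mask 3D array of probabilities in [0, 1] on the same grid.
#' @param slice_index slice (third-axis) index.
#' @param scheme the \code{\link{bvalue_scheme}} of the fourth axis.
#' @return A \code{\link{signal_decay}} whose \code{weight} is the total
#'   probability mass of the slice.
#' @export
roi_average_decay <- function(vol, prob_mask, slice_index,
                              scheme = bvalue_scheme()) {
  if (any(prob_mask < 0 | prob_mask > 1))
    stop("prob_mask values must lie in [0, 1]", call. = FALSE)
  p <- prob_mask[, , slice_index]
  wsum <- sum(p)
  if (wsum == 0)
    stop("empty-ROI: no positive probability in slice ", slice_index,
         call. = FALSE)
  nb <- dim(vol)[4]
  sl <- matrix(vol[, , slice_index, ], ncol = nb)
  vals <- as.numeric(crossprod(as.numeric(p), sl)) / wsum
  signal_decay(vals, scheme, weight = wsum)
}

#' ROI-wise IVIM fitting, per slice and direction
#'
#' Computes the probability-weighted average decay of the ROI in each slice
#' (\code{\link{roi_average_decay}}) and fits it with the configured
#' algorithm, per diffusion-encoding direction. Slices without ROI support,
#' or whose fit fails, are absent from the table (recorded in the
#' \code{skipped} attribute), never zero-filled.
#'
#' @param data a repetition-averaged \code{diffusion_dataset}.
#' @param prob_mask probabilistic ROI volume on the data grid.
#' @param config a \code{\link{fit_config}}.
#' @return data.frame with columns \code{slice}, \code{direction},
#'   \code{F}, \code{Dstar}, \code{D}, \code{FDstar}, \code{S0},
#'   \code{r2}, \code{converged}.
#' @export
fit_roiwise <- function(data, prob_mask, config = fit_config()) {
  data <- average_repetitions(data)
  nz <- dim(prob_mask)[3]
  rows <- list()
  skipped <- character()
  for (dir in names(data$volumes)) {
    vol <- data$volumes[[dir]]
    for (z in seq_len(nz)) {
      if (sum(prob_mask[, , z]) == 0) next
      row <- tryCatch({
        dec <- roi_average_decay(vol, prob_mask, z, data$scheme)
        cfg <- config
        cfg$seed <- voxel_seed(config$seed, z)
        fr <- fit_decay(dec, cfg)
        c(as.list(fit_result_vector(fr)), converged = fr$converged)
      }, error = function(e) {
        skipped <<- c(skipped, sprintf("%s slice %d: %s", dir, z,
                                       conditionMessage(e)))
        NULL
      })
      if (!is.null(row))
        rows[[length(rows) + 1L]] <- c(list(slice = z, direction = dir), row)
    }
  }
  if (length(rows) == 0)
    stop("empty-ROI: no slice with ROI support could be fitted", call. = FALSE)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  attr(out, "skipped") <- skipped
  out
}
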