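#' Specification of the synthetic cervical-cord phantom
#'
#' Defines a multi-subject, two-session, multi-direction diffusion
#' acquisition with known ground truth, emulating the statistical structure
#' a test-retest IVIM study assumes: tissue-specific parameter means with
#' between-subject spread, a zero-mean between-session perturbation,
#' direction-dependent diffusivity, and Rician magnitude noise at a
#' configurable single-repetition SNR.
#'
#' Defaults mirror the acquisition regime the generator emulates: a
#' 14-point b-scheme 0--650 s/mm^2 in steps of 50, 20 repetitions per
#' b-value, three in-plane diffusion-encoding directions, 10 subjects and
#' 9 slices; white- and grey-matter parameter means and between-subject
#' SDs set to published cervical-cord session-1 voxel-wise one-step
#' values (WM: F 5.45 +/- 0.75 percent, D* 24.41 +/- 2.61 e-3,
#' D 3.74 +/- 0.49 e-4 mm^2/s; GM: F 9.61 +/- 1.55 percent,
#' D* 17.14 +/- 2.89 e-3, D 4.17 +/- 0.42 e-4 mm^2/s); single-repetition
#' SNR 27 at b = 0, so the repetition-averaged signal sits at
#' 27 * sqrt(20) ~ 121, the regime of cord acquisitions at 3T. The
#' between-session SD defaults to 6 percent of each tissue mean, a
#' calibration placing simulated within-subject CVs in the few-percent to
#' mid-teens range typical of cord IVIM repeatability.
#'
#' @param n_subjects number of simulated subjects.
#' @param grid c(nx, ny, n_slices) voxel grid.
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @param n_repetitions repetitions per b-value per direction.
#' @param directions character labels of the in-plane diffusion-encoding
#'   directions.
#' @param anisotropy per-direction multiplicative factor on D (same length
#'   as \code{directions}); F and D* are direction-independent.
#' @param tissue_means named list (\code{wm}, \code{gm}) of
#'   \code{\link{ivim_params}} giving the population tissue means.
#' @param between_subject_sd named list (\code{wm}, \code{gm}) of named
#'   vectors \code{c(F=, Dstar=, D=)} of between-subject SDs.
#' @param session_effect_sd as \code{between_subject_sd}, the SD of the
#'   additive zero-mean session perturbation; NULL picks the 6-percent
#'   calibration described above.
#' @param snr_single_rep single-repetition SNR at b = 0 (Inf = noiseless).
#' @param noise_model \code{"rician"} (magnitude MRI) or \code{"gaussian"}
#'   (kept as an oracle-testing switch).
#' @param gm_radius_frac grey-matter ellipse radii as a fraction of the
#'   cord radii; 0 yields a homogeneous all-WM cord.
#' @param bounds physical parameter bounds used to clip sampled truths
#'   (same meaning as in \code{\link{fit_config}}).
#' @param seed integer seed; the generator is bit-reproducible under a
#'   fixed seed.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(n_subjects = 10L,
                         grid = c(16L, 16L, 9L),
                         scheme = bvalue_scheme(),
                         n_repetitions = 20L,
                         directions = c("dir60", "dir180", "dirm60"),
                         anisotropy = c(1.0, 0.9, 1.1),
                         tissue_means = list(
                           wm = ivim_params(S0 = 1, F = 0.0545,
                                            Dstar = 24.41e-3, D = 3.74e-4),
                           gm = ivim_params(S0 = 1, F = 0.0961,
                                            Dstar = 17.14e-3, D = 4.17e-4)),
                         between_subject_sd = list(
                           wm = c(F = 0.0075, Dstar = 2.61e-3, D = 0.49e-4),
                           gm = c(F = 0.0155, Dstar = 2.89e-3, D = 0.42e-4)),
                         session_effect_sd = NULL,
                         snr_single_rep = 27,
                         noise_model = c("rician", "gaussian"),
                         gm_radius_frac = 0.45,
                         bounds = list(F = c(0, 0.20),
                                       Dstar = c(0.3e-3, 50e-3),
                                       D = c(1.5e-4, 54e-4)),
                         seed = 42L) {
  noise_model <- match.arg(noise_model)
  if (!is.infinite(snr_single_rep) && snr_single_rep <= 0)
    stop("invalid-spec: snr_single_rep must be positive (or Inf for noiseless)",
         call. = FALSE)
  if (length(anisotropy) != length(directions))
    stop("invalid-spec: anisotropy must match directions in length", call. = FALSE)
  stopifnot(all(c("wm", "gm") %in% names(tissue_means)))
  if (is.null(session_effect_sd))
    session_effect_sd <- lapply(tissue_means, function(m)
      0.06 * c(F = m$F, Dstar = m$Dstar, D = m$D))
  structure(list(n_subjects = as.integer(n_subjects),
                 grid = as.integer(grid), scheme = scheme,
                 n_repetitions = as.integer(n_repetitions),
                 directions = directions, anisotropy = anisotropy,
                 tissue_means = tissue_means,
                 between_subject_sd = between_subject_sd,
                 session_effect_sd = session_effect_sd,
                 snr_single_rep = snr_single_rep,
                 noise_model = noise_model,
                 gm_radius_frac = gm_radius_frac,
                 bounds = bounds, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Cord-like phantom geometry
#'
#' Builds an elliptical cord cross-section per slice with a central
#' grey-matter region and a surrounding white-matter annulus, as
#' probabilistic masks with a soft boundary band (WM + GM probabilities
#' sum to 1 inside the cord, 0 outside), plus per-slice vertebral-level
#' labels (slices split into three consecutive level groups, a C1--C3
#' analogue). Geometry is identical across sessions, as for data
#' registered to a common template.
#'
#' @param grid c(nx, ny, n_slices).
#' @param gm_radius_frac grey-matter radii as a fraction of the cord radii
#'   (0 disables the GM compartment).
#' @return list with binary \code{cord}, probabilistic \code{wm_prob} and
#'   \code{gm_prob} 3D arrays, integer \code{labels} (0 none, 1 WM, 2 GM)
#'   and per-slice \code{levels}.
#' @export
make_geometry <- function(grid, gm_radius_frac = 0.45) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  rx <- 0.35 * nx; ry <- 0.30 * ny
  if (2 * min(rx, ry) < 5)
    stop("geometry: grid too small for a >= 5-voxel-diameter cord", call. = FALSE)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  r_cord <- sqrt(((x - cx) / rx)^2 + ((y - cy) / ry)^2)
  cord2d <- r_cord <= 1
  if (gm_radius_frac > 0) {
    r_gm <- sqrt(((x - cx) / (gm_radius_frac * rx))^2 +
                 ((y - cy) / (gm_radius_frac * ry))^2)
    ## soft band: fully GM inside r_gm <= 0.75, fully WM beyond 1.25
    gm2d <- pmin(1, pmax(0, (1.25 - r_gm) / 0.5)) * cord2d
  } else gm2d <- matrix(0, nx, ny)
  wm2d <- (1 - gm2d) * cord2d
  rep3 <- function(m) array(rep(m, nz), dim = c(nx, ny, nz))
  cord <- rep3(cord2d * 1)
  gm_prob <- rep3(gm2d)
  wm_prob <- rep3(wm2d)
  labels <- array(0L, dim = c(nx, ny, nz))
  labels[cord > 0] <- 1L
  labels[gm_prob > 0.5] <- 2L
  levels <- rep(1:3, each = ceiling(nz / 3))[seq_len(nz)]
  list(cord = cord, wm_prob = wm_prob, gm_prob = gm_prob,
       labels = labels, levels = levels)
}

clip_params <- function(p, bounds) {
  p["F"] <- min(max(p[["F"]], bounds$F[1]), bounds$F[2])
  p["Dstar"] <- min(max(p[["Dstar"]], bounds$Dstar[1]), bounds$Dstar[2])
  p["D"] <- min(max(p[["D"]], bounds$D[1]), bounds$D[2])
  p
}

#' Sample subject- and session-level ground-truth parameters
#'
#' Subject-level parameters are drawn Normal(tissue mean, between-subject
#' SD) per tissue and clipped to the physical bounds; each session adds an
#' independent zero-mean Normal(0, session SD) perturbation (clipped
#' again). D is additionally scaled per direction by the anisotropy
#' factors; F and D* are direction-independent.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return An object of class \code{ground_truth}: list with
#'   \code{geometry} (see \code{\link{make_geometry}}) and \code{params},
#'   a data.frame with one row per subject x session x tissue and columns
#'   \code{F}, \code{Dstar}, \code{D} (direction-neutral values) plus
#'   \code{S0}.
#' @export
sample_ground_truth <- function(spec) {
  geometry <- make_geometry(spec$grid, spec$gm_radius_frac)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  rows <- list()
  for (subj in seq_len(spec$n_subjects)) {
    for (tis in c("wm", "gm")) {
      m <- spec$tissue_means[[tis]]
      bsd <- spec$between_subject_sd[[tis]]
      ssd <- spec$session_effect_sd[[tis]]
      subj_val <- clip_params(
        c(F = stats::rnorm(1, m$F, bsd[["F"]]),
          Dstar = stats::rnorm(1, m$Dstar, bsd[["Dstar"]]),
          D = stats::rnorm(1, m$D, bsd[["D"]])), spec$bounds)
      for (ses in 1:2) {
        sess_val <- clip_params(
          subj_val + c(F = stats::rnorm(1, 0, ssd[["F"]]),
                       Dstar = stats::rnorm(1, 0, ssd[["Dstar"]]),
                       D = stats::rnorm(1, 0, ssd[["D"]])), spec$bounds)
        rows[[length(rows) + 1L]] <-
          data.frame(subject = subj, session = ses, tissue = tis,
                     S0 = m$S0, F = sess_val[["F"]],
                     Dstar = sess_val[["Dstar"]], D = sess_val[["D"]])
      }
    }
  }
  structure(list(geometry = geometry, params = do.call(rbind, rows),
                 spec = spec),
            class = "ground_truth")
}

acquisition_seed <- function(base, subject, session) {
  as.integer((as.numeric(base) + 1009 * subject + 101 * session) %% 2147483563)
}

#' Simulate one acquisition (one subject, one session)
#'
#' Evaluates the noiseless biexponential forward model in every cord voxel
#' from the session's ground truth (WM or GM by majority tissue label,
#' direction-scaled D) and adds complex Gaussian noise followed by the
#' magnitude operation (Rician noise), with noise SD set so the
#' single-repetition SNR at b = 0 equals \code{spec$snr_single_rep}.
#' Voxels outside the cord contain pure noise (Rayleigh background).
#' Repetitions are stored as separate frames so the pipeline can average
#' them and compute SNR maps. Bit-reproducible for a fixed spec seed.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param truth a \code{\link{sample_ground_truth}} result for this spec.
#' @param subject,session indices into the truth table.
#' @return A \code{diffusion_dataset} (see \code{\link{diffusion_dataset}})
#'   with one frame per b-value per repetition per direction.
#' @export
simulate_acquisition <- function(spec, truth, subject, session) {
  geom <- truth$geometry
  nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
  b <- spec$scheme$bvalues
  nb <- length(b); nrep <- spec$n_repetitions
  pars <- truth$params
  sel <- function(tis) pars[pars$subject == subject & pars$session == session &
                             pars$tissue == tis, , drop = FALSE]
  wm <- sel("wm"); gm <- sel("gm")
  if (nrow(wm) != 1)
    stop("truth table has no row for subject ", subject, " session ", session,
         call. = FALSE)
  sigma <- if (is.infinite(spec$snr_single_rep)) 0
           else spec$tissue_means$wm$S0 / spec$snr_single_rep

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(acquisition_seed(spec$seed, subject, session))

  volumes <- list()
  nvox <- nx * ny * nz
  lab <- as.integer(geom$labels)
  for (k in seq_along(spec$directions)) {
    aniso <- spec$anisotropy[k]
    ## noiseless signal per voxel class
    sig_wm <- ivim_signal(b, wm$S0, wm$F, wm$Dstar, wm$D * aniso)
    sig_gm <- if (nrow(gm) == 1)
      ivim_signal(b, gm$S0, gm$F, gm$Dstar, gm$D * aniso) else rep(0, nb)
    base <- matrix(0, nvox, nb)
    if (any(lab == 1L))
      base[lab == 1L, ] <- matrix(sig_wm, sum(lab == 1L), nb, byrow = TRUE)
    if (any(lab == 2L))
      base[lab == 2L, ] <- matrix(sig_gm, sum(lab == 2L), nb, byrow = TRUE)
    ## frames ordered b-major, repetitions contiguous within each b
    arr <- array(0, dim = c(nx, ny, nz, nb * nrep))
    for (ib in seq_len(nb)) {
      for (r in seq_len(nrep)) {
        frame <- (ib - 1L) * nrep + r
        s <- base[, ib]
        if (sigma > 0) {
          re <- s + stats::rnorm(nvox, 0, sigma)
          if (spec$noise_model == "rician") {
            im <- stats::rnorm(nvox, 0, sigma)
            s <- sqrt(re^2 + im^2)
          } else s <- pmax(re, 0)
        }
        arr[, , , frame] <- s
      }
    }
    volumes[[spec$directions[k]]] <- arr
  }
  btable <- data.frame(frame = seq_len(nb * nrep),
                       b = rep(b, each = nrep),
                       rep = rep(seq_len(nrep), nb))
  diffusion_dataset(volumes = volumes, btable = btable, scheme = spec$scheme,
                    masks = list(cord = geom$cord, wm = geom$wm_prob,
                                 gm = geom$gm_prob),
                    levels = geom$levels,
                    meta = list(subject = subject, session = session,
                                n_repetitions = nrep,
                                seed = acquisition_seed(spec$seed, subject, session),
                                snr_single_rep = spec$snr_single_rep,
                                noise_model = spec$noise_model))
}

#' Simulate the full phantom study
#'
#' Materializes every subject x session acquisition of the spec along with
#' the shared ground truth. Intended for small specs; large studies are
#' better generated one acquisition at a time with
#' \code{\link{simulate_acquisition}} (as \code{\link{run_study}} does) to
#' bound memory.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{truth} (a \code{ground_truth}) and
#'   \code{datasets}, a nested list \code{datasets[[subject]][[session]]}.
#' @export
simulate_dataset <- function(spec) {
  truth <- sample_ground_truth(spec)
  datasets <- lapply(seq_len(spec$n_subjects), function(subj)
    lapply(1:2, function(ses) simulate_acquisition(spec, truth, subj, ses)))
  list(truth = truth, datasets = datasets)
}

#' Analytic mean of the Rician distribution
#'
#' E|X| for X = sqrt((nu + n1)^2 + n2^2) with n1, n2 ~ N(0, sigma^2):
#' sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2)), evaluated with
#' exponentially scaled Bessel functions for numerical stability. Used to
#' quantify the positive magnitude bias of low-SNR diffusion data.
#'
#' @param nu underlying noiseless signal (>= 0).
#' @param sigma Gaussian noise SD per channel (> 0).
#' @return The expected magnitude.
#' @export
rician_mean <- function(nu, sigma) {
  x <- nu^2 / (2 * sigma^2)
  i0 <- besselI(x / 2, 0, expon.scaled = TRUE)
  i1 <- besselI(x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * ((1 + x) * i0 + x * i1)
}
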