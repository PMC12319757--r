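#' Diffusion dataset container
#'
#' One acquisition (one subject, one session): 4D signal arrays keyed by
#' diffusion-encoding direction, the b-value table describing the fourth
#' dimension (one row per frame, with its b-value and repetition index),
#' the b-value scheme, the cord binary mask and WM/GM probabilistic masks,
#' per-slice vertebral-level labels, and free-form metadata. All volumes
#' and masks must share one grid; no resampling happens inside the
#' pipeline.
#'
#' @param volumes named list of 4D arrays (x, y, z, frame), one per
#'   direction.
#' @param btable data.frame with columns \code{frame}, \code{b},
#'   \code{rep}; its length must equal the fourth-dimension extent and
#'   every scheme b-value must appear with a constant repetition count.
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @param masks list with binary \code{cord} and probabilistic \code{wm},
#'   \code{gm} 3D arrays on the volume grid.
#' @param levels integer per-slice vertebral-level labels.
#' @param meta list of metadata (subject, session, repetition count, seed,
#'   voxel geometry, ...).
#' @return An object of class \code{diffusion_dataset}.
#' @export
diffusion_dataset <- function(volumes, btable, scheme, masks,
                              levels = NULL, meta = list()) {
  if (!length(volumes) || is.null(names(volumes)))
    stop("volumes must be a named list of 4D arrays", call. = FALSE)
  dm <- dim(volumes[[1]])
  for (dir in names(volumes)) {
    dv <- dim(volumes[[dir]])
    if (length(dv) != 4 || !all(dv == dm))
      stop("dimension mismatch: volume '", dir,
           "' does not share the common 4D grid", call. = FALSE)
    if (dv[4] != nrow(btable))
      stop("dimension mismatch: b-table has ", nrow(btable),
           " entries but volumes have ", dv[4], " frames", call. = FALSE)
  }
  counts <- table(btable$b)
  if (!setequal(as.numeric(names(counts)), scheme$bvalues))
    stop("b-table b-values do not match the scheme", call. = FALSE)
  if (length(unique(as.integer(counts))) != 1)
    stop("incomplete-data: unequal repetition counts across b-values",
         call. = FALSE)
  for (m in c("cord", "wm", "gm")) {
    if (!is.null(masks[[m]]) && !all(dim(masks[[m]]) == dm[1:3]))
      stop("dimension mismatch: mask '", m, "' grid differs from volumes",
           call. = FALSE)
  }
  if (is.null(levels)) levels <- rep(1L, dm[3])
  if (length(levels) != dm[3])
    stop("levels must have one label per slice", call. = FALSE)
  structure(list(volumes = volumes, btable = btable, scheme = scheme,
                 masks = masks, levels = levels, meta = meta,
                 averaged = all(counts == 1)),
            class = "diffusion_dataset")
}

#' @export
print.diffusion_dataset <- function(x, ...) {
  dm <- dim(x$volumes[[1]])
  cat(sprintf(
    "diffusion_dataset: %dx%dx%d grid, %d frames, directions: %s%s\n",
    dm[1], dm[2], dm[3], dm[4], paste(names(x$volumes), collapse = ", "),
    if (x$averaged) " (repetition-averaged)" else ""))
  invisible(x)
}

#' Write a dataset to NIfTI + bval + manifest
#'
#' One NIfTI file per direction (4D), NIfTI masks, an FSL-dialect bval
#' text file (one space-separated row, one entry per frame) and a JSON
#' manifest recording directions, repetition structure, levels, and
#' metadata.
#'
#' @param data a \code{\link{diffusion_dataset}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. \code{"sub01_ses1"}.
#' @return Invisibly, a named list of the paths written.
#' @export
write_dataset <- function(data, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (d in names(data$volumes)) {
    p <- file.path(dir, sprintf("%s_dwi_%s.nii.gz", prefix, d))
    RNifti::writeNifti(data$volumes[[d]], p)
    paths[[paste0("dwi_", d)]] <- p
  }
  for (m in names(data$masks)) {
    p <- file.path(dir, sprintf("%s_mask_%s.nii.gz", prefix, m))
    RNifti::writeNifti(data$masks[[m]], p)
    paths[[paste0("mask_", m)]] <- p
  }
  paths$bval <- file.path(dir, paste0(prefix, ".bval"))
  writeLines(paste(data$btable$b, collapse = " "), paths$bval)
  paths$manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(
    list(prefix = prefix, directions = names(data$volumes),
         n_frames = nrow(data$btable),
         bvalues = data$scheme$bvalues, cutoff = data$scheme$cutoff,
         repetitions = max(data$btable$rep), levels = data$levels,
         meta = data$meta, files = paths[setdiff(names(paths), "manifest")]),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a dataset from NIfTI volumes and an FSL-dialect bval file
#'
#' Validates mutual consistency (frame count against b-table length,
#' common grid across volumes and masks, scheme coverage) and rebuilds the
#' repetition structure by grouping equal b-values: the repetition index
#' of a frame is its rank among the frames sharing its b-value.
#'
#' @param volume_paths named character vector of 4D NIfTI paths, one per
#'   direction (names become direction labels).
#' @param btable_path path to the bval text file: one row of
#'   space-separated b-values, one entry per fourth-dimension frame.
#' @param mask_paths optional named character vector with entries
#'   \code{cord}, \code{wm}, \code{gm}.
#' @param cutoff high-b cut-off for the scheme (s/mm^2).
#' @param levels optional per-slice level labels.
#' @param meta optional metadata list.
#' @return A \code{\link{diffusion_dataset}}.
#' @export
read_dataset <- function(volume_paths, btable_path, mask_paths = NULL,
                         cutoff = 400, levels = NULL, meta = list()) {
  if (is.null(names(volume_paths)))
    names(volume_paths) <- sprintf("dir%d", seq_along(volume_paths))
  volumes <- lapply(volume_paths, function(p) {
    if (!file.exists(p)) stop("unreadable file: ", p, call. = FALSE)
    v <- as.array(RNifti::readNifti(p))
    if (length(dim(v)) == 3) dim(v) <- c(dim(v), 1L)
    array(as.numeric(v), dim(v))  # plain array, no NIfTI attributes
  })
  if (!file.exists(btable_path))
    stop("unreadable file: ", btable_path, call. = FALSE)
  bvals <- scan(btable_path, what = numeric(), quiet = TRUE)
  nf <- dim(volumes[[1]])[4]
  if (length(bvals) != nf)
    stop("dimension mismatch: b-table has ", length(bvals),
         " entries but volumes have ", nf, " frames", call. = FALSE)
  rep_idx <- stats::ave(bvals, bvals, FUN = seq_along)
  btable <- data.frame(frame = seq_len(nf), b = bvals, rep = as.integer(rep_idx))
  scheme <- bvalue_scheme(sort(unique(bvals)), cutoff = cutoff)
  masks <- list()
  if (!is.null(mask_paths))
    masks <- lapply(mask_paths, function(p) {
      m <- as.array(RNifti::readNifti(p))
      array(as.numeric(m), dim(m))
    })
  diffusion_dataset(volumes, btable, scheme, masks, levels, meta)
}

#' Average repetitions per b-value
#'
#' Arithmetic mean across the repetition frames of each b-value, per voxel
#' and direction, producing one frame per b-value. The original repetition
#' count is recorded in \code{meta$n_repetitions} for SNR scaling.
#' Already-averaged data are returned unchanged.
#'
#' @param data a \code{\link{diffusion_dataset}}.
#' @return The repetition-averaged \code{diffusion_dataset}.
#' @export
average_repetitions <- function(data) {
  if (data$averaged) return(data)
  b <- data$scheme$bvalues
  counts <- table(data$btable$b)
  if (length(unique(as.integer(counts))) != 1)
    stop("incomplete-data: unequal repetition counts across b-values",
         call. = FALSE)
  nrep <- as.integer(counts[1])
  volumes <- lapply(data$volumes, function(vol) {
    dm <- dim(vol)
    out <- array(0, dim = c(dm[1:3], length(b)))
    for (i in seq_along(b)) {
      frames <- data$btable$frame[data$btable$b == b[i]]
      out[, , , i] <- rowMeans(matrix(vol[, , , frames, drop = FALSE],
                                      prod(dm[1:3]), length(frames)))
    }
    out
  })
  btable <- data.frame(frame = seq_along(b), b = b, rep = 1L)
  meta <- data$meta
  meta$n_repetitions <- nrep
  diffusion_dataset(volumes, btable, data$scheme, data$masks,
                    data$levels, meta)
}

#' Voxel-wise SNR map from the b = 0 repetitions
#'
#' Per masked voxel, the ratio of the mean b = 0 signal across repetitions
#' to its standard deviation across repetitions, multiplied by
#' sqrt(Nrep) to represent the repetition-averaged signal fed to the
#' fitting algorithm. Zero-SD voxels (possible in noiseless simulation)
#' are flagged non-finite and excluded from the summary, with a count.
#'
#' @param data a \code{\link{diffusion_dataset}} with >= 2 b = 0
#'   repetition frames (i.e. not yet repetition-averaged).
#' @param mask binary 3D array (typically the eroded cord mask).
#' @param direction direction label; default first.
#' @return list with the SNR \code{map} (NA outside mask, NaN at excluded
#'   voxels), \code{summary} (mean, sd, min, max over finite masked
#'   values), \code{n_excluded} and \code{nrep}.
#' @export
compute_snr_map <- function(data, mask, direction = names(data$volumes)[1]) {
  frames <- data$btable$frame[data$btable$b == 0]
  if (length(frames) < 2)
    stop("need >= 2 b = 0 repetitions for an SNR map", call. = FALSE)
  if (sum(mask) == 0) stop("empty mask", call. = FALSE)
  vol <- data$volumes[[direction]]
  dm <- dim(vol)[1:3]
  flat <- matrix(vol[, , , frames], prod(dm), length(frames))
  mu <- rowMeans(flat)
  sdv <- apply(flat, 1, stats::sd)
  snr <- mu / sdv * sqrt(length(frames))
  map <- array(NA_real_, dm)
  idx <- which(mask > 0)
  map[idx] <- snr[idx]
  vals <- map[idx]
  finite <- is.finite(vals)
  summary <- if (any(finite))
    c(mean = mean(vals[finite]), sd = stats::sd(vals[finite]),
      min = min(vals[finite]), max = max(vals[finite]))
  else c(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_)
  list(map = map, summary = summary,
       n_excluded = sum(!finite), nrep = length(frames))
}

#' Morphological erosion with a discrete spherical kernel
#'
#' Erodes a binary 3D mask with the structuring element
#' \{offsets : dx^2 + dy^2 + dz^2 <= radius^2\}; a voxel survives only if
#' the whole kernel around it lies inside the mask. Radius 0 is the
#' identity. Used to trim the cord/ROI periphery against CSF partial
#' volume before metric extraction. Erosion to the empty set raises a
#' warning, not an error.
#'
#' @param mask binary 3D array.
#' @param radius kernel radius in voxels (>= 0).
#' @return The eroded mask (always a subset of the input).
#' @export
erode_mask <- function(mask, radius = 1) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  if (radius == 0) return(mask)
  dm <- dim(mask)
  r <- floor(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  out <- array(TRUE, dm)
  for (i in seq_len(nrow(offs))) {
    shifted <- array(FALSE, dm)
    sx <- offs$dx[i]; sy <- offs$dy[i]; sz <- offs$dz[i]
    xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zs <- seq_len(dm[3])
    xv <- xs + sx; yv <- ys + sy; zv <- zs + sz
    okx <- xv >= 1 & xv <= dm[1]; oky <- yv >= 1 & yv <= dm[2]
    okz <- zv >= 1 & zv <= dm[3]
    shifted[xs[okx], ys[oky], zs[okz]] <-
      mask[xv[okx], yv[oky], zv[okz]] > 0
    out <- out & shifted
  }
  if (!any(out))
    warning("empty-result: erosion removed every voxel", call. = FALSE)
  array(as.numeric(out), dm)
}

#' Average parameter maps across diffusion-encoding directions
#'
#' Voxel-wise arithmetic mean of per-direction maps; a voxel missing (NA)
#' in any direction is missing in the output.
#'
#' @param maps list (one element per direction) of lists of 3D parameter
#'   maps, as returned by \code{\link{fit_voxelwise}}.
#' @param n_directions expected number of directions (guards against a
#'   silently dropped direction).
#' @return A single list of 3D maps, one per parameter.
#' @export
average_maps_across_directions <- function(maps, n_directions = length(maps)) {
  if (length(maps) != n_directions)
    stop("configuration error: expected ", n_directions, " directions, got ",
         length(maps), call. = FALSE)
  params <- names(maps[[1]])
  out <- list()
  for (p in params) {
    acc <- maps[[1]][[p]]
    for (k in seq_along(maps)[-1]) acc <- acc + maps[[k]][[p]]
    out[[p]] <- acc / length(maps)
  }
  out
}

#' Extract per-ROI scalar metrics from maps or slice tables
#'
#' Voxel-wise mode: the probability-weighted mean of the
#' direction-averaged map over the (eroded) probabilistic ROI restricted
#' to the slices of the configured vertebral-level range. ROI-wise mode:
#' the unweighted mean of the per-slice fit values over the same slices
#' (per-slice values are themselves averaged across directions first).
#'
#' @param maps list of 3D maps (voxel-wise mode), or NULL.
#' @param roi_table per-slice ROI-wise fit table (ROI-wise mode), or NULL.
#' @param prob_mask eroded probabilistic ROI volume.
#' @param levels per-slice level labels.
#' @param level_range levels to include (default: all).
#' @param parameters which parameters to extract.
#' @return Named numeric vector of one scalar per parameter (NA with a
#'   reason attribute when the ROI is empty after erosion).
#' @export
extract_metrics <- function(maps = NULL, roi_table = NULL, prob_mask = NULL,
                            levels = NULL,
                            level_range = NULL,
                            parameters = c("F", "Dstar", "D", "FDstar")) {
  if (is.null(level_range)) level_range <- unique(levels)
  keep_slices <- which(levels %in% level_range)
  if (!is.null(maps)) {
    w <- prob_mask
    sel <- array(FALSE, dim(w))
    sel[, , keep_slices] <- TRUE
    w[!sel] <- 0
    wsum <- sum(w)
    if (wsum == 0) {
      out <- stats::setNames(rep(NA_real_, length(parameters)), parameters)
      attr(out, "reason") <- "empty ROI after erosion"
      return(out)
    }
    vapply(parameters, function(p) {
      vals <- maps[[p]]
      ok <- !is.na(vals) & w > 0
      sum(vals[ok] * w[ok]) / sum(w[ok])
    }, numeric(1))
  } else if (!is.null(roi_table)) {
    sub <- roi_table[roi_table$slice %in% keep_slices, ]
    if (nrow(sub) == 0) {
      out <- stats::setNames(rep(NA_real_, length(parameters)), parameters)
      attr(out, "reason") <- "no ROI-wise slices in level range"
      return(out)
    }
    ## average across directions within slice, then across slices
    per_slice <- stats::aggregate(sub[parameters],
                                  by = list(slice = sub$slice), mean)
    vapply(parameters, function(p) mean(per_slice[[p]]), numeric(1))
  } else stop("provide maps or roi_table", call. = FALSE)
}

#' Run the full phantom test-retest study
#'
#' Orchestrates the end-to-end analysis on simulated data: per subject and
#' session it generates the acquisition
#' (\code{\link{simulate_acquisition}}), computes the b = 0 SNR map inside
#' the eroded cord mask, averages repetitions, fits the IVIM model in the
#' requested modes (voxel-wise maps averaged across directions, ROI-wise
#' per-slice fits) and algorithms (one-step, two-step), extracts
#' per-ROI scalars over the configured vertebral levels, and finally runs
#' the complete reliability battery on the subject x session table.
#' Deterministic under the spec and fit seeds.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param fit a \code{\link{fit_config}} template; its algorithm/mode are
#'   overridden per configuration.
#' @param modes,algorithms which fitting configurations to run.
#' @param erosion_radius radius (voxels) of the spherical kernel applied
#'   to the ROI masks before extraction.
#' @param level_range vertebral levels to average over (default: all).
#' @param out_dir optional directory; when given, the test-retest table,
#'   reliability CSVs and a JSON manifest are written there.
#' @param anova run the 2 x 2 CV ANOVA (needs both modes and both
#'   algorithms).
#' @return list with \code{table} (the test-retest table), \code{report}
#'   (a \code{\link{reliability_report}}), \code{snr} (per subject x
#'   session x direction summaries), \code{truth} and \code{log}.
#' @export
run_study <- function(spec = phantom_spec(),
                      fit = fit_config(),
                      modes = c("voxel_wise", "roi_wise"),
                      algorithms = c("one_step", "two_step"),
                      erosion_radius = 1,
                      level_range = NULL,
                      out_dir = NULL,
                      anova = length(modes) == 2 && length(algorithms) == 2) {
  truth <- sample_ground_truth(spec)
  geom <- truth$geometry
  cord_eroded <- erode_mask(geom$cord, erosion_radius)
  rois <- list(wm = geom$wm_prob, gm = geom$gm_prob)
  rois <- Filter(function(m) sum(m) > 0, rois)
  rois_eroded <- lapply(rois, function(m) m * cord_eroded)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  rows <- list()
  snr_rows <- list()
  for (subj in seq_len(spec$n_subjects)) {
    for (ses in 1:2) {
      raw <- simulate_acquisition(spec, truth, subj, ses)
      if (max(raw$btable$rep) >= 2 && !is.infinite(spec$snr_single_rep)) {
        for (d in names(raw$volumes)) {
          sm <- compute_snr_map(raw, cord_eroded, d)
          snr_rows[[length(snr_rows) + 1L]] <-
            data.frame(subject = subj, session = ses, direction = d,
                       t(sm$summary), n_excluded = sm$n_excluded)
        }
      }
      avg <- average_repetitions(raw)
      say("subject %d session %d: %d cord voxels, %d directions",
          subj, ses, sum(geom$cord), length(avg$volumes))
      for (alg in algorithms) {
        if ("voxel_wise" %in% modes) {
          cfg <- fit; cfg$algorithm <- alg; cfg$mode <- "voxel_wise"
          maps <- fit_voxelwise(avg, geom$cord, cfg)
          avg_maps <- average_maps_across_directions(
            maps, length(spec$directions))
          for (roi in names(rois_eroded)) {
            vals <- extract_metrics(maps = avg_maps,
                                    prob_mask = rois_eroded[[roi]],
                                    levels = avg$levels,
                                    level_range = level_range)
            for (p in names(vals))
              rows[[length(rows) + 1L]] <- data.frame(
                subject = subj, session = ses, roi = roi, parameter = p,
                approach = "voxel_wise", algorithm = alg, value = vals[[p]])
          }
        }
        if ("roi_wise" %in% modes) {
          cfg <- fit; cfg$algorithm <- alg; cfg$mode <- "roi_wise"
          for (roi in names(rois_eroded)) {
            tab <- fit_roiwise(avg, rois_eroded[[roi]], cfg)
            if (length(attr(tab, "skipped")))
              say("roi_wise %s %s sub%d ses%d: %d slice(s) skipped",
                  alg, roi, subj, ses, length(attr(tab, "skipped")))
            vals <- extract_metrics(roi_table = tab,
                                    levels = avg$levels,
                                    level_range = level_range)
            for (p in names(vals))
              rows[[length(rows) + 1L]] <- data.frame(
                subject = subj, session = ses, roi = roi, parameter = p,
                approach = "roi_wise", algorithm = alg, value = vals[[p]])
          }
        }
      }
    }
  }
  long <- do.call(rbind, rows)
  wide <- merge(long[long$session == 1,
                     c("subject", "roi", "parameter", "approach",
                       "algorithm", "value")],
                long[long$session == 2,
                     c("subject", "roi", "parameter", "approach",
                       "algorithm", "value")],
                by = c("subject", "roi", "parameter", "approach", "algorithm"),
                suffixes = c("", "2"))
  names(wide)[names(wide) == "value"] <- "session1"
  names(wide)[names(wide) == "value2"] <- "session2"
  wide <- wide[order(wide$roi, wide$parameter, wide$approach,
                     wide$algorithm, wide$subject), ]
  rownames(wide) <- NULL
  report <- reliability_report(wide, anova = anova)
  snr <- if (length(snr_rows)) do.call(rbind, snr_rows) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(wide, file.path(out_dir, "test_retest_table.csv"),
                     row.names = FALSE)
    if (!is.null(snr))
      utils::write.csv(snr, file.path(out_dir, "snr_summary.csv"),
                       row.names = FALSE)
    write_reliability_report(report, out_dir)
    jsonlite::write_json(
      list(phantom_seed = spec$seed, fit_seed = fit$seed,
           n_subjects = spec$n_subjects, grid = spec$grid,
           bvalues = spec$scheme$bvalues,
           n_repetitions = spec$n_repetitions,
           snr_single_rep = spec$snr_single_rep,
           modes = modes, algorithms = algorithms,
           erosion_radius = erosion_radius,
           bounds = fit$bounds, log = log_lines),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(table = wide, report = report, snr = snr, truth = truth,
       log = log_lines)
}
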