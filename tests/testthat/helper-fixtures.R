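# Shared fixtures: published cervical-cord session-1 voxel-wise one-step
# tissue means, the 14-point acquisition scheme, and independent oracles
# used across test files.

scheme14 <- bvalue_scheme(seq(0, 650, by = 50), cutoff = 400)

wm_truth <- list(S0 = 1, F = 0.0545, Dstar = 24.41e-3, D = 3.74e-4)
gm_truth <- list(S0 = 1, F = 0.0961, Dstar = 17.14e-3, D = 4.17e-4)

make_decay <- function(truth, scheme = scheme14) {
  forward_signal(do.call(ivim_params, truth), scheme)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Independent ICC(A,1) oracle: variance decomposition via stats::aov on the
# long-format table, then the McGraw-Wong absolute-agreement formula.
icc_oracle_aov <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(y = as.vector(mat),
                     subject = factor(rep(seq_len(n), k)),
                     session = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subject + session, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["session", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Independent repeated-measures ANOVA oracle via aov() with Error strata.
rm_anova_oracle_aov <- function(cv_table) {
  cv_table$subject <- factor(cv_table$subject)
  fit <- stats::aov(cv ~ approach * algorithm +
                      Error(subject / (approach * algorithm)),
                    data = cv_table)
  s <- summary(fit)
  grab <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    i <- grep(row, trimws(rownames(tab)), fixed = TRUE)[1]
    c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  rbind(approach = grab("Error: subject:approach", "approach"),
        algorithm = grab("Error: subject:algorithm", "algorithm"),
        interaction = grab("Error: subject:approach:algorithm",
                           "approach:algorithm"))
}

# Brute-force erosion oracle: voxel survives iff every kernel offset stays
# inside the mask.
erode_oracle <- function(mask, radius) {
  dm <- dim(mask)
  out <- array(0, dm)
  r <- floor(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    keep <- TRUE
    for (i in seq_len(nrow(offs))) {
      xx <- x + offs$dx[i]; yy <- y + offs$dy[i]; zz <- z + offs$dz[i]
      if (xx < 1 || xx > dm[1] || yy < 1 || yy > dm[2] ||
          zz < 1 || zz > dm[3] || mask[xx, yy, zz] == 0) { keep <- FALSE; break }
    }
    if (keep) out[x, y, z] <- 1
  }
  out
}

# Small noiseless zero-session-effect phantom spec shared by pipeline tests.
null_phantom_spec <- function(n_subjects = 2L, grid = c(12L, 12L, 3L),
                              seed = 11L, ...) {
  phantom_spec(n_subjects = n_subjects, grid = grid, n_repetitions = 2L,
               snr_single_rep = Inf,
               session_effect_sd = list(wm = c(F = 0, Dstar = 0, D = 0),
                                        gm = c(F = 0, Dstar = 0, D = 0)),
               seed = seed, ...)
}
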