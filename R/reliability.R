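#' Within-subject coefficient of variation of a scan-rescan pair
#'
#' 100 * sd(x1, x2) / mean(x1, x2) with the sample (n - 1) SD, which for
#' two values reduces to 100 * |x1 - x2| / (sqrt(2) * mean). Scale
#' invariant, not shift invariant; always >= 0.
#'
#' @param x1,x2 the two session values (same units).
#' @return The CV in percent.
#' @examples
#' within_subject_cv(9, 11)  # 100 * sqrt(2) / 10
#' @export
within_subject_cv <- function(x1, x2) {
  if (!all(is.finite(c(x1, x2))))
    stop("session values must be finite", call. = FALSE)
  m <- mean(c(x1, x2))
  if (m == 0)
    stop("undefined-CV: zero mean across sessions", call. = FALSE)
  100 * stats::sd(c(x1, x2)) / m
}

## Two-way (rows = subjects, columns = sessions) mean squares, one
## observation per cell.
twoway_mean_squares <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), sst = sst, n = n, k = k)
}

#' Intraclass correlation, two-way model, absolute agreement, single rater
#'
#' ICC(A,1) in the McGraw--Wong taxonomy: the ratio of true
#' between-subject variance to total variance including session
#' (systematic) and residual measurement error,
#' (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)), from the two-way
#' ANOVA mean squares of an n-subject x k-session table. Invariant to a
#' common affine rescaling of the whole table.
#'
#' @param table numeric matrix (or data.frame) with one row per subject
#'   and one column per session (k >= 2), no missing cells.
#' @return list with \code{icc}, the Cicchetti interpretation
#'   \code{label} (poor < 0.4 < fair < 0.6 < good < 0.75 < excellent) and
#'   the mean squares \code{msr}, \code{msc}, \code{mse}.
#' @export
icc_absolute_agreement <- function(table) {
  mat <- as.matrix(table)
  if (any(!is.finite(mat)))
    stop("table must be complete and finite", call. = FALSE)
  if (nrow(mat) < 3)
    stop("insufficient-subjects: need >= 3 subjects for the ICC", call. = FALSE)
  if (ncol(mat) < 2)
    stop("need >= 2 sessions", call. = FALSE)
  ms <- twoway_mean_squares(mat)
  if (ms$sst <= 0)
    stop("degenerate-variance: constant table has no defined ICC", call. = FALSE)
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse))
  list(icc = icc, label = icc_label(icc),
       msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

icc_label <- function(icc) {
  if (!is.finite(icc)) return(NA_character_)
  if (icc < 0.4) "poor" else if (icc < 0.6) "fair"
  else if (icc < 0.75) "good" else "excellent"
}

#' Bland-Altman analysis of a scan-rescan table
#'
#' Differences are oriented session1 - session2 (a convention, stated in
#' all outputs): bias is the mean difference, the 95 percent limits of
#' agreement are bias +/- 1.96 SD of the differences, and the per-subject
#' (mean, difference) pairs are returned for plotting.
#'
#' @param table numeric matrix/data.frame, subjects x 2 sessions.
#' @return list with \code{bias}, \code{loa_low}, \code{loa_high},
#'   \code{sd_diff} and a data.frame \code{points} (\code{mean},
#'   \code{difference} per subject).
#' @export
bland_altman <- function(table) {
  mat <- as.matrix(table)
  if (nrow(mat) < 2 || ncol(mat) != 2)
    stop("need a subjects x 2 sessions table with >= 2 subjects", call. = FALSE)
  d <- mat[, 1] - mat[, 2]
  m <- rowMeans(mat)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * sd_d,
       loa_high = bias + 1.96 * sd_d, sd_diff = sd_d,
       points = data.frame(mean = m, difference = d))
}

#' Pearson correlation between the two sessions
#'
#' @param table numeric matrix/data.frame, subjects x 2 sessions, both
#'   columns non-constant, >= 3 subjects.
#' @return The product-moment correlation coefficient in [-1, 1].
#' @export
pearson_between_sessions <- function(table) {
  mat <- as.matrix(table)
  if (nrow(mat) < 3)
    stop("need >= 3 subjects", call. = FALSE)
  if (stats::sd(mat[, 1]) == 0 || stats::sd(mat[, 2]) == 0)
    stop("degenerate-variance: constant session column", call. = FALSE)
  stats::cor(mat[, 1], mat[, 2])
}

#' Two-factor repeated-measures ANOVA on within-subject CVs
#'
#' Tests the effect of the fitting approach (voxel-wise vs ROI-wise) and
#' fitting algorithm (one-step vs two-step) on the CVs in a complete 2 x 2
#' within-subject design, with subject as the blocking factor: each
#' effect's F statistic uses its own factor-by-subject interaction mean
#' square as the error term (the interaction is tested against the
#' residual). \code{method = "fixed"} instead runs a plain two-way
#' fixed-effects ANOVA (\code{\link[stats]{aov}}) for comparison.
#'
#' @param cv_table data.frame with columns \code{subject},
#'   \code{approach} (2 levels), \code{algorithm} (2 levels), \code{cv};
#'   exactly one observation per subject x cell, >= 3 subjects.
#' @param method \code{"repeated"} (default) or \code{"fixed"}.
#' @return data.frame with one row per effect (\code{approach},
#'   \code{algorithm}, \code{approach:algorithm}) and columns \code{df1},
#'   \code{df2}, \code{ss}, \code{F}, \code{p}.
#' @export
rm_anova_2x2 <- function(cv_table, method = c("repeated", "fixed")) {
  method <- match.arg(method)
  req <- c("subject", "approach", "algorithm", "cv")
  if (!all(req %in% names(cv_table)))
    stop("cv_table needs columns subject, approach, algorithm, cv", call. = FALSE)
  cv_table$subject <- factor(cv_table$subject)
  cv_table$approach <- factor(cv_table$approach)
  cv_table$algorithm <- factor(cv_table$algorithm)
  n <- nlevels(cv_table$subject)
  if (n < 3) stop("need >= 3 subjects", call. = FALSE)
  if (nlevels(cv_table$approach) != 2 || nlevels(cv_table$algorithm) != 2)
    stop("approach and algorithm must each have exactly 2 levels", call. = FALSE)
  tab <- with(cv_table, table(subject, approach, algorithm))
  if (any(tab != 1))
    stop("missing-cell: design must be complete with one value per cell",
         call. = FALSE)

  if (method == "fixed") {
    fit <- stats::aov(cv ~ approach * algorithm, data = cv_table)
    a <- stats::anova(fit)
    return(data.frame(effect = c("approach", "algorithm", "approach:algorithm"),
                      df1 = a$Df[1:3], df2 = a$Df[4],
                      ss = a$`Sum Sq`[1:3], F = a$`F value`[1:3],
                      p = a$`Pr(>F)`[1:3]))
  }

  y <- cv_table$cv
  S <- cv_table$subject; A <- cv_table$approach; B <- cv_table$algorithm
  grand <- mean(y)
  m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_s <- tapply(y, S, mean)
  m_as <- tapply(y, list(A, S), mean); m_bs <- tapply(y, list(B, S), mean)
  m_ab <- tapply(y, list(A, B), mean)

  ss_a <- 2 * n * sum((m_a - grand)^2)
  ss_b <- 2 * n * sum((m_b - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + grand)^2)
  ss_s <- 4 * sum((m_s - grand)^2)
  ss_as <- 2 * sum((sweep(sweep(m_as, 1, m_a), 2, m_s) + grand)^2)
  ss_bs <- 2 * sum((sweep(sweep(m_bs, 1, m_b), 2, m_s) + grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  df_err <- n - 1
  eff <- data.frame(
    effect = c("approach", "algorithm", "approach:algorithm"),
    df1 = 1, df2 = df_err,
    ss = c(ss_a, ss_b, ss_ab),
    ms_err = c(ss_as, ss_bs, ss_abs) / df_err)
  eff$F <- eff$ss / eff$ms_err
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff[c("effect", "df1", "df2", "ss", "F", "p")]
}

#' Full test-retest reliability report
#'
#' For every ROI x parameter x fitting configuration of a scan-rescan
#' table, computes the per-subject within-subject CVs (with their mean and
#' SD across subjects), the ICC (two-way, absolute agreement, with
#' Cicchetti label), the Bland-Altman bias and 95 percent limits of
#' agreement (session1 - session2 convention), and the Pearson
#' between-session correlation; then, per ROI x parameter, the 2 x 2
#' repeated-measures ANOVA of the CVs across fitting approaches and
#' algorithms. Degenerate cases (constant tables) yield NA with a note
#' rather than spurious finite values. No multiple-testing correction is
#' applied across ROIs or parameters; p-values are raw.
#'
#' @param table a test-retest table: data.frame with columns
#'   \code{subject}, \code{roi}, \code{parameter}, \code{approach},
#'   \code{algorithm}, \code{session1}, \code{session2}.
#' @param anova run the CV ANOVA (requires all four configurations).
#' @return An object of class \code{reliability_report}: list with
#'   \code{stats} (one row per ROI x parameter x configuration),
#'   \code{cv_by_subject}, \code{anova} (one row per ROI x parameter x
#'   effect, or NULL) and \code{notes}.
#' @export
reliability_report <- function(table, anova = TRUE) {
  req <- c("subject", "roi", "parameter", "approach", "algorithm",
           "session1", "session2")
  if (!all(req %in% names(table)))
    stop("table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  notes <- character()
  groups <- unique(table[c("roi", "parameter", "approach", "algorithm")])
  stats_rows <- list(); cv_rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    sub <- table[table$roi == g$roi & table$parameter == g$parameter &
                   table$approach == g$approach &
                   table$algorithm == g$algorithm, ]
    sub <- sub[order(sub$subject), ]
    cvs <- mapply(within_subject_cv, sub$session1, sub$session2)
    cv_rows[[i]] <- data.frame(g, subject = sub$subject, cv = cvs,
                               row.names = NULL)
    mat <- cbind(sub$session1, sub$session2)
    icc <- tryCatch(icc_absolute_agreement(mat), error = function(e) {
      notes <<- c(notes, sprintf("ICC %s/%s/%s/%s: %s", g$roi, g$parameter,
                                 g$approach, g$algorithm, conditionMessage(e)))
      list(icc = NA_real_, label = NA_character_)
    })
    r <- tryCatch(pearson_between_sessions(mat), error = function(e) {
      notes <<- c(notes, sprintf("Pearson %s/%s/%s/%s: %s", g$roi, g$parameter,
                                 g$approach, g$algorithm, conditionMessage(e)))
      NA_real_
    })
    ba <- bland_altman(mat)
    stats_rows[[i]] <- data.frame(
      g, n_subjects = nrow(sub),
      wscv_mean = mean(cvs), wscv_sd = stats::sd(cvs),
      icc = icc$icc, icc_label = icc$label,
      bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
      pearson_r = r, row.names = NULL)
  }
  cv_by_subject <- do.call(rbind, cv_rows)
  anova_rows <- NULL
  if (anova) {
    combos <- unique(table[c("roi", "parameter")])
    out <- list()
    for (i in seq_len(nrow(combos))) {
      g <- combos[i, ]
      cvt <- cv_by_subject[cv_by_subject$roi == g$roi &
                             cv_by_subject$parameter == g$parameter, ]
      res <- tryCatch(rm_anova_2x2(cvt), error = function(e) {
        notes <<- c(notes, sprintf("ANOVA %s/%s: %s", g$roi, g$parameter,
                                   conditionMessage(e)))
        NULL
      })
      if (!is.null(res))
        out[[length(out) + 1L]] <- data.frame(roi = g$roi,
                                              parameter = g$parameter, res,
                                              row.names = NULL)
    }
    if (length(out)) anova_rows <- do.call(rbind, out)
  }
  structure(list(stats = do.call(rbind, stats_rows),
                 cv_by_subject = cv_by_subject,
                 anova = anova_rows, notes = notes,
                 conventions = list(
                   difference = "session1 - session2",
                   cv = "sample (n-1) SD over mean, x100",
                   icc = "two-way, absolute agreement, single measures")),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("Test-retest reliability report\n")
  cat(sprintf("  %d configuration rows, %d ANOVA rows, %d notes\n",
              nrow(x$stats),
              if (is.null(x$anova)) 0L else nrow(x$anova),
              length(x$notes)))
  print(utils::head(x$stats, 12))
  invisible(x)
}

#' Write a reliability report as tidy CSV
#'
#' One file per component: the per-configuration statistics, the
#' per-subject CVs, and the ANOVA table (when present).
#'
#' @param report a \code{\link{reliability_report}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reliability_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stats = file.path(dir, "reliability_stats.csv"),
             cv = file.path(dir, "reliability_cv_by_subject.csv"))
  utils::write.csv(report$stats, paths["stats"], row.names = FALSE)
  utils::write.csv(report$cv_by_subject, paths["cv"], row.names = FALSE)
  if (!is.null(report$anova)) {
    paths["anova"] <- file.path(dir, "reliability_anova.csv")
    utils::write.csv(report$anova, paths["anova"], row.names = FALSE)
  }
  invisible(paths)
}
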