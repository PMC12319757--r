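#' IVIM parameter set
#'
#' Bundles the four parameters of the intravoxel incoherent motion (IVIM)
#' biexponential model for one voxel or region: the signal amplitude
#' \code{S0}, the microvascular volume fraction \code{F} (stored as a
#' fraction in [0, 1]; converted to percent only at reporting boundaries),
#' the pseudo-diffusion coefficient \code{Dstar} (mm^2/s) and the diffusion
#' coefficient \code{D} (mm^2/s). The blood-flow-related product
#' \code{FDstar = F * Dstar} is derived, never fitted independently.
#'
#' @param S0 signal amplitude, arbitrary units, > 0.
#' @param F microvascular volume fraction, in [0, 1].
#' @param Dstar pseudo-diffusion coefficient, mm^2/s, >= 0.
#' @param D diffusion coefficient, mm^2/s, >= 0.
#' @return An object of class \code{ivim_params}: a named list with fields
#'   \code{S0}, \code{F}, \code{Dstar}, \code{D} and derived \code{FDstar}.
#' @examples
#' ivim_params(S0 = 1, F = 0.0545, Dstar = 24.41e-3, D = 3.74e-4)
#' @export
ivim_params <- function(S0, F, Dstar, D) {
  vals <- c(S0 = S0, F = F, Dstar = Dstar, D = D)
  if (any(!is.finite(vals)))
    stop("invalid-parameter: all IVIM parameters must be finite", call. = FALSE)
  if (any(vals < 0))
    stop("invalid-parameter: IVIM parameters must be non-negative", call. = FALSE)
  if (S0 <= 0)
    stop("invalid-parameter: S0 must be strictly positive", call. = FALSE)
  if (F > 1)
    stop("invalid-parameter: F is a fraction and must lie in [0, 1]", call. = FALSE)
  structure(list(S0 = S0, F = F, Dstar = Dstar, D = D, FDstar = F * Dstar),
            class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf(
    "IVIM parameters: S0 = %.4g, F = %.2f%%, D* = %.3f e-3 mm2/s, D = %.3f e-4 mm2/s, F.D* = %.3f e-4 mm2/s\n",
    x$S0, 100 * x$F, 1e3 * x$Dstar, 1e4 * x$D, 1e4 * x$FDstar))
  invisible(x)
}

#' Diffusion-weighting scheme
#'
#' An ordered b-value table plus the high-b cut-off that separates the
#' diffusion-only regime used by the mono-exponential prior fit. The default
#' is the 14-point acquisition scheme 0 to 650 s/mm^2 in steps of 50, with
#' the cut-off at 400 s/mm^2 (above which perfusion contributes negligibly
#' to the decay).
#'
#' @param bvalues numeric vector of b-values (s/mm^2), strictly increasing,
#'   starting at 0.
#' @param cutoff high-b threshold (s/mm^2); at least two b-values must lie
#'   strictly above it.
#' @return An object of class \code{bvalue_scheme}.
#' @export
bvalue_scheme <- function(bvalues = seq(0, 650, by = 50), cutoff = 400) {
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) < 3 || any(!is.finite(bvalues)))
    stop("invalid-scheme: need at least 3 finite b-values", call. = FALSE)
  if (bvalues[1] != 0)
    stop("invalid-scheme: first b-value must be 0", call. = FALSE)
  if (any(diff(bvalues) <= 0))
    stop("invalid-scheme: b-values must be strictly increasing", call. = FALSE)
  if (sum(bvalues > cutoff) < 2)
    stop("invalid-scheme: need at least 2 b-values strictly above the cutoff",
         call. = FALSE)
  structure(list(bvalues = bvalues, cutoff = cutoff), class = "bvalue_scheme")
}

#' Signal decay over a b-value scheme
#'
#' A repetition-averaged signal vector indexed by the b-values of a scheme,
#' for one voxel or one region-average and one diffusion-encoding direction.
#'
#' @param values numeric signal per b-value, finite and >= 0.
#' @param scheme a \code{\link{bvalue_scheme}}.
#' @param weight optional scalar weight carried along when the decay is a
#'   probability-weighted ROI average.
#' @return An object of class \code{signal_decay}.
#' @export
signal_decay <- function(values, scheme = bvalue_scheme(), weight = NULL) {
  values <- as.numeric(values)
  if (!inherits(scheme, "bvalue_scheme"))
    stop("scheme must be a bvalue_scheme", call. = FALSE)
  if (length(values) != length(scheme$bvalues))
    stop("invalid-signal: values and scheme b-values differ in length",
         call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("invalid-signal: signal values must be finite and non-negative",
         call. = FALSE)
  structure(list(scheme = scheme, values = values, weight = weight),
            class = "signal_decay")
}

#' Evaluate the IVIM biexponential forward model
#'
#' Computes S(b) = S0 * exp(-b D) * (F * exp(-b D*) + 1 - F) at every
#' b-value of the scheme. The perfusion compartment (fraction F, apparent
#' diffusivity D + D*) decays out of the signal at low b, leaving the
#' mono-exponential tissue tail exp(-b D) at high b.
#'
#' @param params an \code{\link{ivim_params}} object.
#' @param scheme a \code{\link{bvalue_scheme}}, or a bare numeric vector of
#'   b-values (any non-negative grid; simulation may use denser grids than
#'   the acquisition scheme).
#' @return If \code{scheme} is a \code{bvalue_scheme}, a
#'   \code{\link{signal_decay}}; if a bare numeric vector, the numeric
#'   signal values.
#' @examples
#' p <- ivim_params(S0 = 1, F = 0.0545, Dstar = 24.41e-3, D = 3.74e-4)
#' forward_signal(p, bvalue_scheme())
#' @export
forward_signal <- function(params, scheme = bvalue_scheme()) {
  if (!inherits(params, "ivim_params"))
    params <- do.call(ivim_params, as.list(params)[c("S0", "F", "Dstar", "D")])
  bare <- !inherits(scheme, "bvalue_scheme")
  b <- if (bare) as.numeric(scheme) else scheme$bvalues
  if (any(b < 0) || any(!is.finite(b)))
    stop("invalid-scheme: b-values must be finite and non-negative", call. = FALSE)
  s <- ivim_signal(b, params$S0, params$F, params$Dstar, params$D)
  if (bare) s else signal_decay(s, scheme)
}

## bare numeric kernel shared with the optimizer (no class dispatch, no checks)
ivim_signal <- function(b, S0, F, Dstar, D) {
  S0 * exp(-b * D) * (F * exp(-b * Dstar) + 1 - F)
}

#' Coefficient of determination of a fitted decay
#'
#' R^2 = 1 - SS_res / SS_tot, with SS_tot taken about the mean of the
#' observed signal. Values can be negative for fits worse than the mean;
#' a constant observed signal has no defined R^2.
#'
#' @param observed,fitted \code{\link{signal_decay}} objects or bare numeric
#'   vectors of equal length (>= 3 points).
#' @return The coefficient of determination (dimensionless, <= 1).
#' @export
r_squared <- function(observed, fitted) {
  obs <- if (inherits(observed, "signal_decay")) observed$values else as.numeric(observed)
  fit <- if (inherits(fitted, "signal_decay")) fitted$values else as.numeric(fitted)
  if (length(obs) != length(fit))
    stop("observed and fitted must have equal length", call. = FALSE)
  if (length(obs) < 3)
    stop("need at least 3 points for R^2", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    stop("degenerate-signal: constant observed signal has undefined R^2",
         call. = FALSE)
  1 - sum((obs - fit)^2) / ss_tot
}
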