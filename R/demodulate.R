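#' Demodulate one angular intensity series
#'
#' Closed-form inversion of the polarization modulation law for a single
#' pixel. The model `I = 0.5*i0*(1 + sindelta*sin(2*(theta - phi)))` is
#' linear in the harmonic basis `(1, sin 2theta, cos 2theta)`:
#' `I = a + s*sin 2theta + c*cos 2theta` with `a = i0/2`,
#' `s = (i0/2)*sindelta*cos 2phi`, `c = -(i0/2)*sindelta*sin 2phi`.
#' A least-squares fit of the three harmonic coefficients (exact for the
#' equally spaced 18-degree design, ordinary least squares for arbitrary
#' angle sets) therefore recovers
#' `i0 = 2a`, `sindelta = sqrt(s^2 + c^2)/a` and
#' `phi = atan2(-c, s)/2` mapped into `[0, 180)`.
#'
#' Conventions (the two are jointly unidentifiable otherwise):
#' `sindelta >= 0` with the sign folded into `phi`, and `phi` set to 0 and
#' flagged when the modulation amplitude vanishes. Estimates of `sindelta`
#' greater than 1 (possible under noise) are retained and flagged, never
#' clamped, so downstream statistics are not biased.
#'
#' @param intensities Numeric vector of pixel intensities, one per angle.
#' @param angles_deg Numeric vector of incident polarization angles in
#'   degrees; same length as `intensities`, length >= 5, pairwise distinct
#'   modulo 180.
#' @return A list with elements `i0`, `sindelta`, `phi_deg`, `residual_rms`
#'   and integer `flag` (bitwise OR of [flag_codes()]).
#' @seealso [demodulate_stack()] for whole-image stacks.
#' @export
#' @examples
#' th <- pimi_angles()
#' y <- forward_intensity(1, 0.6, 30, th)
#' demodulate_series(y, th)
demodulate_series <- function(intensities, angles_deg) {
  y <- as.numeric(intensities)
  th <- as.numeric(angles_deg)
  if (length(y) != length(th))
    stop("'intensities' and 'angles_deg' must have equal length")
  if (length(y) < 5L)
    stop("at least 5 samples are required")
  if (!all(is.finite(y)))
    stop("intensities must be finite")
  check_angles_distinct(th)
  X <- harmonic_design(th)
  beta <- qr.coef(qr(X), y)
  res <- y - as.vector(X %*% beta)
  out <- harmonic_to_parameters(beta[1L], beta[2L], beta[3L])
  out$residual_rms <- sqrt(mean(res^2))
  out
}

# Design matrix of the second-harmonic regression.
harmonic_design <- function(angles_deg) {
  t2 <- 2 * angles_deg * pi / 180
  cbind(1, sin(t2), cos(t2))
}

#' Per-pixel quality flag codes
#'
#' Flags set by the demodulator, combined by bitwise OR:
#' `nonpositive_mean` (1) the fitted mean level was <= 0 so `sindelta` was
#' set to 0; `overrange_sindelta` (2) the estimate exceeded 1 (noise) and was
#' kept, not clamped; `phi_undefined` (4) the modulation amplitude was
#' numerically zero so `phi` was set to 0 by convention.
#'
#' @return Named integer vector of flag bits.
#' @export
flag_codes <- function() {
  c(nonpositive_mean = 1L, overrange_sindelta = 2L, phi_undefined = 4L)
}

# Vectorized map from harmonic coefficients (a, s, c) to the physical
# parameters, applying the sign/range conventions and quality flags.
harmonic_to_parameters <- function(a, s, co) {
  amp <- sqrt(s^2 + co^2)
  bad_mean <- !(a > 0)
  no_mod <- amp <= 1e-12 * pmax(abs(a), .Machine$double.xmin)
  sindelta <- ifelse(bad_mean, 0, amp / ifelse(bad_mean, 1, a))
  phi <- (atan2(-co, s) * 90 / pi) %% 180
  phi[no_mod] <- 0
  flag <- ifelse(bad_mean, 1L, 0L) +
    ifelse(!bad_mean & sindelta > 1, 2L, 0L) +
    ifelse(no_mod, 4L, 0L)
  list(i0 = 2 * a, sindelta = sindelta, phi_deg = phi,
       flag = as.integer(flag))
}

#' PIMI parameter maps
#'
#' Per-pixel parametric maps recovered from a polarization frame stack:
#' `i0` (mean-level), `sindelta` (modulation depth, >= 0 by convention),
#' `phi` (ellipse orientation, degrees in `[0, 180)`), `residual` (RMS
#' misfit of the harmonic model) and integer `flag` ([flag_codes()]).
#'
#' @param i0,sindelta,phi,residual Numeric matrices of one shared shape.
#' @param flag Integer matrix of the same shape.
#' @param pixel_size_nm Physical pixel pitch in nanometres (carried along
#'   for segmentation).
#' @return An object of class `pimi_maps`.
#' @export
pimi_maps <- function(i0, sindelta, phi, residual, flag,
                      pixel_size_nm = NA_real_) {
  dims <- list(dim(i0), dim(sindelta), dim(phi), dim(residual), dim(flag))
  if (length(unique(dims)) != 1L)
    stop("all maps must share one shape")
  if (any(sindelta < 0))
    stop("'sindelta' must be non-negative (sign folds into phi)")
  if (any(phi < 0 | phi >= 180))
    stop("'phi' must lie in [0, 180)")
  if (any(residual < 0))
    stop("'residual' must be non-negative")
  structure(
    list(i0 = i0, sindelta = sindelta, phi = phi, residual = residual,
         flag = flag, pixel_size_nm = as.numeric(pixel_size_nm)),
    class = "pimi_maps")
}

#' @export
print.pimi_maps <- function(x, ...) {
  d <- dim(x$sindelta)
  cat(sprintf(
    "<pimi_maps> %d x %d px, %d flagged pixel(s)\n  sindelta range [%.4g, %.4g]\n",
    d[1L], d[2L], sum(x$flag != 0L), min(x$sindelta), max(x$sindelta)))
  invisible(x)
}

#' Demodulate a whole polarization stack into parameter maps
#'
#' Applies the closed-form harmonic inversion of [demodulate_series()]
#' independently to every pixel of the stack. Implemented as one dense
#' least-squares solve shared by all pixels, so a 512 x 512 x 10 stack
#' demodulates in well under a second. Degenerate pixels (non-positive mean
#' level, vanishing modulation, over-range `sindelta`) are flagged in the
#' output, never raised as errors.
#'
#' @param stack A [polarization_stack()].
#' @return A [pimi_maps()] object with the stack's frame shape.
#' @export
#' @examples
#' th <- pimi_angles()
#' fr <- lapply(th, function(t) forward_intensity(1, 0.4, 60, t) + matrix(0, 3, 3))
#' maps <- demodulate_stack(polarization_stack(fr, th, 15.625))
#' maps$sindelta[1, 1]
demodulate_stack <- function(stack) {
  stopifnot(inherits(stack, "polarization_stack"))
  d <- dim(stack$frames)
  npx <- d[1L] * d[2L]
  Y <- matrix(stack$frames, nrow = npx, ncol = d[3L])
  X <- harmonic_design(stack$angles_deg)
  # beta = Y X (X'X)^{-1}: one 3x3 solve shared by every pixel
  beta <- Y %*% X %*% solve(crossprod(X))
  res <- Y - beta %*% t(X)
  p <- harmonic_to_parameters(beta[, 1L], beta[, 2L], beta[, 3L])
  shape <- function(v) matrix(v, d[1L], d[2L])
  pimi_maps(
    i0 = shape(p$i0),
    sindelta = shape(p$sindelta),
    phi = shape(p$phi_deg),
    residual = shape(sqrt(rowMeans(res^2))),
    flag = shape(p$flag),
    pixel_size_nm = stack$pixel_size_nm)
}
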