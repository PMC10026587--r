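#' Polarization frame stack
#'
#' Container for a PIMI acquisition: one intensity frame per incident linear
#' polarization angle, together with the acquisition geometry. The modulation
#' of every pixel across the stack follows
#' \deqn{I_i = \tfrac{1}{2} I_0 [1 + \sin\delta \, \sin 2(\theta_i - \phi)],}
#' where \eqn{\theta_i} is the incident polarization angle, \eqn{\sin\delta}
#' the sine of the phase difference between the two orthogonal polarization
#' components of the reflected light, and \eqn{\phi} the polarization ellipse
#' orientation.
#'
#' @param frames A numeric 3-D array (height x width x n) or a list of
#'   equally sized numeric matrices, one per polarization angle. Intensities
#'   must be finite and non-negative (arbitrary camera units).
#' @param angles_deg Numeric vector of incident polarization angles in
#'   degrees, one per frame, pairwise distinct modulo 180. At least 5 frames
#'   are required for the three-parameter demodulation.
#' @param pixel_size_nm Physical pixel pitch in nanometres.
#' @param wavelength_nm Illumination centre wavelength in nanometres.
#' @param bandwidth_nm Illumination bandwidth in nanometres.
#' @return An object of class `polarization_stack`: a list with elements
#'   `frames` (3-D array), `angles_deg`, `pixel_size_nm`, `wavelength_nm`,
#'   `bandwidth_nm`.
#' @seealso [demodulate_stack()], [read_stack()], [write_stack()]
#' @export
#' @examples
#' th <- pimi_angles()
#' fr <- lapply(th, function(t) forward_intensity(1, 0.5, 30, t) + matrix(0, 4, 4))
#' st <- polarization_stack(fr, th, pixel_size_nm = 15.625)
#' dim(st$frames)
polarization_stack <- function(frames, angles_deg, pixel_size_nm,
                               wavelength_nm = 600, bandwidth_nm = 35) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("all frames must share one shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a height x width x n array or a list of matrices")
  n <- dim(frames)[3L]
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) != n)
    stop("length(angles_deg) must equal the number of frames")
  if (n < 5L)
    stop("at least 5 frames are required (3-parameter demodulation)")
  if (!all(is.finite(frames)))
    stop("frame intensities must be finite")
  if (any(frames < 0))
    stop("frame intensities must be non-negative")
  check_angles_distinct(angles_deg)
  structure(
    list(frames = frames, angles_deg = angles_deg,
         pixel_size_nm = as.numeric(pixel_size_nm),
         wavelength_nm = as.numeric(wavelength_nm),
         bandwidth_nm = as.numeric(bandwidth_nm)),
    class = "polarization_stack")
}

#' @export
print.polarization_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(paste0(
    "<polarization_stack> %d x %d px, %d frames\n",
    "  angles [deg]: %s\n",
    "  pixel %g nm, lambda %g nm (bw %g nm)\n"),
    d[1L], d[2L], d[3L],
    paste(format(x$angles_deg, trim = TRUE), collapse = ", "),
    x$pixel_size_nm, x$wavelength_nm, x$bandwidth_nm))
  invisible(x)
}

#' Default PIMI acquisition angles
#'
#' The standard acquisition rotates the incident polarization over half a
#' turn in 18-degree steps, giving ten frames at 0, 18, ..., 162 degrees.
#'
#' @param n Number of frames.
#' @param step_deg Angular step in degrees; default `180 / n`.
#' @return Numeric vector of angles in degrees.
#' @export
pimi_angles <- function(n = 10L, step_deg = 180 / n) {
  seq(0, by = step_deg, length.out = n)
}

# Angles must be pairwise distinct modulo 180 deg or the harmonic design
# matrix is rank-deficient.
check_angles_distinct <- function(angles_deg, tol = 1e-9) {
  a <- sort(angles_deg %% 180)
  gaps <- c(diff(a), 180 - (a[length(a)] - a[1L]))
  if (length(angles_deg) > 1L && min(gaps) <= tol)
    stop("polarization angles must be pairwise distinct modulo 180 degrees")
  invisible(TRUE)
}

#' Forward polarization modulation model
#'
#' Predicted pixel intensity under incident linear polarization at
#' `theta_deg` for a pixel with mean-level parameter `i0`, modulation depth
#' `sindelta` and ellipse orientation `phi_deg`:
#' `0.5 * i0 * (1 + sindelta * sin(2 * (theta - phi)))`.
#' All arguments are vectorized with the usual recycling rules.
#'
#' @param i0 Mean-level parameter (twice the angular mean intensity), >= 0.
#' @param sindelta Modulation depth in `[0, 1]`.
#' @param phi_deg Polarization ellipse orientation in degrees.
#' @param theta_deg Incident polarization angle in degrees.
#' @return Intensity value(s) in `[0, i0]`.
#' @export
#' @examples
#' forward_intensity(2, 0.5, 0, 45)   # 1.5
#' forward_intensity(2, 0.9, 30, 30)  # 1: sin(0) = 0
forward_intensity <- function(i0, sindelta, phi_deg, theta_deg) {
  if (any(i0 < 0))
    stop("'i0' must be non-negative")
  if (any(sindelta < 0 | sindelta > 1))
    stop("'sindelta' must lie in [0, 1]")
  0.5 * i0 * (1 + sindelta * sin(2 * (theta_deg - phi_deg) * pi / 180))
}
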