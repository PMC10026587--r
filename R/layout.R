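#' Array layout of the split-ring lattice on an image
#'
#' Geometry that ties lattice unit indices to image pixels: the sub-pixel
#' centre of unit (1, 1), the lattice pitch (fractional pixels allowed) and
#' the lattice extent. `unit_px` is the side of the square topological unit
#' cropped around each centre (1 um x 1 um at the fabricated 1 um pitch).
#'
#' @param origin_px Numeric length-2 `(row, col)` of the unit (1, 1)
#'   centre, 1-based, sub-pixel allowed.
#' @param pitch_px Lattice pitch in pixels: scalar or length-2
#'   `(row pitch, col pitch)`.
#' @param rows,cols Lattice dimensions.
#' @param unit_px Unit patch side in pixels.
#' @return An object of class `array_layout`.
#' @seealso [estimate_layout()], [segment_units()]
#' @export
array_layout <- function(origin_px, pitch_px, rows, cols, unit_px) {
  pitch_px <- rep(as.numeric(pitch_px), length.out = 2L)
  if (any(pitch_px < unit_px - 0.5))
    stop("pitch_px must be at least unit_px")
  structure(
    list(origin_px = as.numeric(origin_px), pitch_px = pitch_px,
         rows = as.integer(rows), cols = as.integer(cols),
         unit_px = as.integer(unit_px)),
    class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf(
    "<array_layout> origin (%.2f, %.2f) px, pitch (%.3f, %.3f) px, %d x %d units of %d px\n",
    x$origin_px[1L], x$origin_px[2L], x$pitch_px[1L], x$pitch_px[2L],
    x$rows, x$cols, x$unit_px))
  invisible(x)
}

# Autocorrelation of a 1-D profile; peak near the candidate pitch refined
# by parabolic interpolation. Returns NULL when no credible periodicity.
profile_pitch <- function(p, approx, min_peak = 0.3) {
  n <- length(p)
  x <- seq_len(n)
  p <- stats::lm.fit(cbind(1, x), p)$residuals  # remove smooth linear trend
  # autocorrelation (convolve() reverses its second argument itself),
  # overlap-normalised so finite extent does not bias the peak position
  ac <- stats::convolve(p, p, type = "open")[n:(2L * n - 1L)]
  ac <- ac / (n - (seq_len(n) - 1L))
  if (ac[1L] <= 0) return(NULL)
  ac <- ac / ac[1L]
  lo <- max(2L, floor(0.7 * approx))
  hi <- min(n - 2L, ceiling(1.3 * approx))
  if (hi - lo < 2L) return(NULL)
  win <- lo:hi
  k <- win[which.max(ac[win + 1L])]      # ac index 1 is lag 0
  if (ac[k + 1L] < min_peak) return(NULL)
  refine_parabolic(k, ac[k:(k + 2L)])
}

# Sub-pixel peak via the parabola through (x-1, x, x+1) given the three
# ordinates centred on the discrete argmax.
refine_parabolic <- function(x, y3) {
  den <- y3[1L] - 2 * y3[2L] + y3[3L]
  if (den == 0) return(x)
  x + 0.5 * (y3[1L] - y3[3L]) / den
}

# Mean motif over complete periods (integer-pitch folding) and its centre
# of mirror symmetry found by circular correlation with the reversed
# motif: for a motif symmetric about c the correlation peaks at lag 2c.
fold_symmetry_centre <- function(p, pitch) {
  ip <- as.integer(round(pitch))
  nper <- floor(length(p) / ip)
  m <- rowMeans(matrix(p[seq_len(nper * ip)], ip, nper))
  m <- m - mean(m)
  idx <- seq_len(ip) - 1L
  cc <- vapply(idx, function(k)
    sum(m * m[((k - idx) %% ip) + 1L]), numeric(1))
  k <- which.max(cc)
  kk <- refine_parabolic(k, cc[((k - 2L):(k)) %% ip + 1L])
  centre <- ((kk - 1) / 2) %% ip + 1     # lag 2(c-1) -> centre c
  list(motif = m, centres = c(centre, (centre - 1 + ip / 2) %% ip + 1))
}

#' Estimate the lattice layout from a parametric map
#'
#' Refines the lattice pitch from the autocorrelation peak of the row and
#' column mean profiles near `approx_pitch_px` (sub-pixel by parabolic
#' interpolation), then locates unit centres as the mirror-symmetry centre
#' of the mean repeating motif (circular correlation of the folded motif
#' with its reverse). The two half-pitch-ambiguous candidates per axis are
#' disambiguated by picking the origin whose centred window over the mean
#' 2-D motif captures the most pattern mass — unit centres sit on the
#' bright split-ring pattern, half-pitch offsets on the dark inter-ring
#' region.
#'
#' @param map Numeric matrix (typically the sin-delta map); must span at
#'   least three pitches in each direction.
#' @param approx_pitch_px Approximate pitch in pixels (e.g.
#'   `pitch_nm / pixel_size_nm`).
#' @param unit_px Unit side for the returned layout; default
#'   `round(approx_pitch_px)`.
#' @return An [array_layout()] covering every unit centre inside the map.
#' @export
estimate_layout <- function(map, approx_pitch_px,
                            unit_px = round(approx_pitch_px)) {
  stopifnot(is.matrix(map))
  if (nrow(map) < 3 * approx_pitch_px || ncol(map) < 3 * approx_pitch_px)
    stop("map must span at least three lattice pitches in each direction")
  py <- profile_pitch(rowMeans(map), approx_pitch_px)
  px <- profile_pitch(colMeans(map), approx_pitch_px)
  if (is.null(py) || is.null(px))
    stop("no periodic signal detected near the requested pitch")
  sy <- fold_symmetry_centre(rowMeans(map), py)
  sx <- fold_symmetry_centre(colMeans(map), px)
  best <- motif_mass_origin(map, sy$centres, sx$centres, c(py, px))
  origin <- first_centre_inside(best, c(py, px), dim(map))
  rows <- floor((nrow(map) - origin[1L]) / py) + 1L
  cols <- floor((ncol(map) - origin[2L]) / px) + 1L
  array_layout(origin, c(py, px), rows, cols, unit_px)
}

# Rank the 4 candidate origins by pattern mass inside a centred circular
# window of radius pitch/4 over the mean 2-D motif (folded map).
motif_mass_origin <- function(map, cy, cx, pitch) {
  ipy <- as.integer(round(pitch[1L])); ipx <- as.integer(round(pitch[2L]))
  ny <- floor(nrow(map) / ipy); nx <- floor(ncol(map) / ipx)
  sub <- map[seq_len(ny * ipy), seq_len(nx * ipx), drop = FALSE]
  motif <- matrix(0, ipy, ipx)
  for (a in seq_len(ny))
    for (b in seq_len(nx))
      motif <- motif + sub[(a - 1L) * ipy + seq_len(ipy),
                           (b - 1L) * ipx + seq_len(ipx)]
  motif <- motif / (ny * nx)
  motif <- motif - mean(motif)
  rr <- matrix(seq_len(ipy), ipy, ipx)
  cc <- matrix(seq_len(ipx), ipy, ipx, byrow = TRUE)
  score <- function(oy, ox) {
    dy <- pmin(abs(rr - oy), ipy - abs(rr - oy))
    dx <- pmin(abs(cc - ox), ipx - abs(cc - ox))
    sum(motif[dy^2 + dx^2 <= (min(ipy, ipx) / 4)^2])
  }
  cand <- expand.grid(oy = cy, ox = cx, KEEP.OUT.ATTRS = FALSE)
  s <- mapply(score, cand$oy, cand$ox)
  c(cand$oy[which.max(s)], cand$ox[which.max(s)])
}

# Smallest lattice centre with positive pixel coordinates on both axes.
first_centre_inside <- function(origin, pitch, dims) {
  vapply(1:2, function(ax) {
    o <- origin[ax] %% pitch[ax]
    if (o < 0.5) o <- o + pitch[ax]
    o
  }, numeric(1))
}

#' Grid of topological units
#'
#' Equal-size square patches cropped around every lattice centre, plus a
#' validity mask (`FALSE` where the crop would leave the image). Stored as
#' a `unit_px x unit_px x rows x cols` array; invalid units hold `NA`.
#'
#' @param units 4-D numeric array (`unit_px`, `unit_px`, rows, cols).
#' @param valid_mask Logical `rows x cols` matrix.
#' @return An object of class `unit_grid`.
#' @export
unit_grid <- function(units, valid_mask) {
  stopifnot(is.array(units), length(dim(units)) == 4L,
            dim(units)[1L] == dim(units)[2L])
  if (!identical(dim(valid_mask), dim(units)[3:4]))
    stop("valid_mask dimensions must match the lattice dimensions")
  structure(list(units = units, valid_mask = valid_mask),
            class = "unit_grid")
}

#' @export
print.unit_grid <- function(x, ...) {
  d <- dim(x$units)
  cat(sprintf("<unit_grid> %d x %d units of %d px (%d valid)\n",
              d[3L], d[4L], d[1L], sum(x$valid_mask)))
  invisible(x)
}

#' Segment a map into lattice-centred topological units
#'
#' Crops a `unit_px` x `unit_px` patch around every lattice centre with
#' nearest-pixel alignment (no interpolation — the downstream statistics
#' are pixelwise sums and resampling would blur them). Units whose crop
#' extends beyond the image are marked invalid and excluded from all
#' downstream statistics.
#'
#' @param map Numeric matrix.
#' @param layout An [array_layout()].
#' @return A [unit_grid()].
#' @export
segment_units <- function(map, layout) {
  stopifnot(is.matrix(map), inherits(layout, "array_layout"))
  u <- layout$unit_px
  units <- array(NA_real_, c(u, u, layout$rows, layout$cols))
  valid <- matrix(FALSE, layout$rows, layout$cols)
  half <- (u - 1) / 2
  for (i in seq_len(layout$rows)) {
    for (j in seq_len(layout$cols)) {
      ctr <- layout$origin_px + c(i - 1, j - 1) * layout$pitch_px
      r0 <- floor(ctr[1L] - half + 0.5)   # round half up: deterministic
      c0 <- floor(ctr[2L] - half + 0.5)
      if (r0 >= 1 && c0 >= 1 && r0 + u - 1L <= nrow(map) &&
          c0 + u - 1L <= ncol(map)) {
        units[, , i, j] <- map[r0:(r0 + u - 1L), c0:(c0 + u - 1L)]
        valid[i, j] <- TRUE
      }
    }
  }
  if (!any(valid))
    stop("no unit crop fits inside the map")
  unit_grid(units, valid)
}

#' Reassemble a unit grid into a tiled montage image
#'
#' Lays the unit patches back out at the unit pitch (invalid units as
#' `fill`) for visual inspection or TIFF export via [write_map()].
#'
#' @param grid A [unit_grid()] or laplace grid.
#' @param fill Value for invalid units.
#' @return Numeric matrix of size `rows*unit_px` x `cols*unit_px`.
#' @export
unit_montage <- function(grid, fill = 0) {
  d <- dim(grid$units)
  u <- d[1L]
  out <- matrix(fill, d[3L] * u, d[4L] * u)
  for (i in seq_len(d[3L]))
    for (j in seq_len(d[4L]))
      if (grid$valid_mask[i, j])
        out[(i - 1L) * u + seq_len(u), (j - 1L) * u + seq_len(u)] <-
          grid$units[, , i, j]
  out
}
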