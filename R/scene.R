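#' Synthetic split-ring scene specification
#'
#' Parameters of the ground-truthed synthetic scenes used to exercise the
#' full detection pipeline. A scene is a rectangular lattice of identical
#' split-ring "dipole" sin-delta patterns: per unit, a flat baseline plus
#' two Gaussian lobes placed mirror-symmetrically at `+/- lobe_offset_px`
#' along the longitudinal (vertical image) axis — the minimal shape
#' reproducing the symmetric two-dipole far-field pattern of a clean
#' split-ring. A virus-positive unit has the lobe on the attachment side
#' multiplied by `attenuation` and the whole unit lowered by
#' `baseline_drop` (weaker dipole on the virus side, lowered basic
#' intensity). A smooth linear background trend and per-frame Gaussian
#' camera noise complete the forward model.
#'
#' Default geometry follows the fabricated array: 1 um lattice pitch, with
#' the pixel pitch chosen so one topological unit is 64 x 64 px.
#'
#' @param rows,cols Lattice dimensions (units).
#' @param pitch_nm Lattice interval in nanometres (1000 = 1 um array).
#' @param pixel_size_nm Physical pixel pitch; default makes
#'   `pitch_nm / pixel_size_nm = 64` px.
#' @param unit_px Side of one topological unit in pixels
#'   (`round(pitch_nm / pixel_size_nm)`).
#' @param lobe_amplitude Peak sin-delta amplitude of each dipole lobe.
#' @param lobe_sigma_px Gaussian lobe width (pixels).
#' @param lobe_offset_px Longitudinal distance of each lobe centre from the
#'   unit centre (pixels).
#' @param baseline Clean-unit sin-delta floor.
#' @param virus_placements `NULL` or a data frame with columns `i`, `j`
#'   (unit indices, 1-based), `side` (`"top"`/`"bottom"`) and optionally
#'   `attenuation` in `(0, 1]` and `baseline_drop >= 0` (defaults filled
#'   from `virus_attenuation`/`virus_baseline_drop`). Units must be pairwise
#'   distinct: two viruses on one split-ring is assumed negligible.
#' @param virus_attenuation,virus_baseline_drop Default virus effect
#'   parameters used where a placement does not override them.
#' @param background_gradient Peak-to-peak amplitude of a linear sin-delta
#'   trend across the field (smooth background unevenness).
#' @param noise_sigma Additive Gaussian noise s.d. on frame intensities
#'   (camera-unit proxy for read noise; shot noise is not modelled).
#' @param i0_level Mean-level parameter of the scene (camera units).
#' @param phi_deg Base polarization ellipse orientation of the scene.
#' @param angles_deg Acquisition angles used by [render_stack()].
#' @param seed RNG seed for the frame noise.
#' @return An object of class `scene_spec`.
#' @seealso [build_scene()], [render_stack()], [random_placements()]
#' @export
scene_spec <- function(rows = 10L, cols = 10L,
                       pitch_nm = 1000, pixel_size_nm = pitch_nm / 64,
                       unit_px = round(pitch_nm / pixel_size_nm),
                       lobe_amplitude = 0.5, lobe_sigma_px = 6,
                       lobe_offset_px = 12, baseline = 0.15,
                       virus_placements = NULL,
                       virus_attenuation = 0.6, virus_baseline_drop = 0.02,
                       background_gradient = 0.02, noise_sigma = 0.01,
                       i0_level = 1, phi_deg = 45,
                       angles_deg = pimi_angles(), seed = 1L) {
  spec <- structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         pitch_nm = pitch_nm, pixel_size_nm = pixel_size_nm,
         unit_px = as.integer(unit_px),
         lobe_amplitude = lobe_amplitude, lobe_sigma_px = lobe_sigma_px,
         lobe_offset_px = lobe_offset_px, baseline = baseline,
         virus_placements = normalize_placements(virus_placements,
                                                 virus_attenuation,
                                                 virus_baseline_drop),
         virus_attenuation = virus_attenuation,
         virus_baseline_drop = virus_baseline_drop,
         background_gradient = background_gradient,
         noise_sigma = noise_sigma, i0_level = i0_level,
         phi_deg = phi_deg, angles_deg = angles_deg,
         seed = as.integer(seed)),
    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

normalize_placements <- function(vp, attenuation, baseline_drop) {
  if (is.null(vp) || NROW(vp) == 0L)
    return(data.frame(i = integer(), j = integer(), side = character(),
                      attenuation = numeric(), baseline_drop = numeric()))
  vp <- as.data.frame(vp)
  if (!all(c("i", "j", "side") %in% names(vp)))
    stop("virus placements need columns i, j, side")
  if (is.null(vp$attenuation)) vp$attenuation <- attenuation
  if (is.null(vp$baseline_drop)) vp$baseline_drop <- baseline_drop
  vp[c("i", "j", "side", "attenuation", "baseline_drop")]
}

validate_scene_spec <- function(spec) {
  if (spec$rows < 1L || spec$cols < 1L)
    stop("lattice must have at least one unit")
  if (spec$pitch_nm / spec$pixel_size_nm < spec$unit_px - 0.5)
    stop("unit_px must not exceed the lattice pitch in pixels")
  if (spec$unit_px < 8L)
    stop("unit_px must be at least 8")
  vp <- spec$virus_placements
  if (NROW(vp)) {
    if (any(vp$i < 1L | vp$i > spec$rows | vp$j < 1L | vp$j > spec$cols))
      stop("virus placement outside the lattice")
    if (anyDuplicated(vp[c("i", "j")]))
      stop("virus placements must reference pairwise distinct units")
    if (!all(vp$side %in% c("top", "bottom")))
      stop("virus side must be 'top' or 'bottom'")
    if (any(vp$attenuation <= 0 | vp$attenuation > 1))
      stop("attenuation must lie in (0, 1]")
    if (any(vp$baseline_drop < 0))
      stop("baseline_drop must be non-negative")
  }
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<scene_spec> %d x %d units @ %g nm pitch (%d px/unit)\n",
    "  %d virus placement(s), noise sigma %g, seed %d\n"),
    x$rows, x$cols, x$pitch_nm, x$unit_px,
    NROW(x$virus_placements), x$noise_sigma, x$seed))
  invisible(x)
}

# Two-lobe dipole model of one unit; per-side amplitude factors let the
# virus renderer attenuate one lobe.
dipole_patch <- function(spec, top_factor = 1, bottom_factor = 1) {
  u <- spec$unit_px
  if (spec$lobe_offset_px + 3 * spec$lobe_sigma_px > u / 2)
    stop("dipole lobes exceed the unit patch bounds")
  ctr <- (u + 1) / 2
  r <- matrix(seq_len(u), u, u)
  cc <- matrix(seq_len(u), u, u, byrow = TRUE)
  g <- function(cy) exp(-((r - cy)^2 + (cc - ctr)^2) /
                          (2 * spec$lobe_sigma_px^2))
  spec$baseline + spec$lobe_amplitude *
    (top_factor * g(ctr - spec$lobe_offset_px) +
       bottom_factor * g(ctr + spec$lobe_offset_px))
}

#' Render the sin-delta pattern of one clean unit
#'
#' Baseline plus two Gaussian lobes placed mirror-symmetrically about the
#' transverse midline: the far-field signature of an unperturbed
#' split-ring. The patch is exactly mirror-symmetric, so its asymmetry
#' score is 0 by construction.
#'
#' @param spec A [scene_spec()].
#' @return `unit_px` x `unit_px` numeric matrix of sin-delta values.
#' @export
render_clean_unit <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  dipole_patch(spec)
}

#' Render the sin-delta pattern of a virus-bearing unit
#'
#' The lobe on the attachment side is multiplied by `attenuation` and the
#' whole patch is lowered by `baseline_drop` (floored at 0): a weaker
#' dipole on the virus side together with a lowered basic intensity. Any
#' genuine virus effect (`attenuation < 1` or `baseline_drop > 0`) makes
#' the patch total strictly smaller than the clean unit's.
#'
#' @param spec A [scene_spec()].
#' @param side `"top"` or `"bottom"` — which longitudinal lobe is weakened
#'   (image row order: "top" is the lobe nearer row 1).
#' @param attenuation Multiplier in `(0, 1]` applied to the affected lobe.
#' @param baseline_drop Uniform sin-delta decrease, >= 0.
#' @return `unit_px` x `unit_px` numeric matrix.
#' @export
render_virus_unit <- function(spec, side = c("top", "bottom"),
                              attenuation = spec$virus_attenuation,
                              baseline_drop = spec$virus_baseline_drop) {
  stopifnot(inherits(spec, "scene_spec"))
  side <- match.arg(side)
  if (attenuation <= 0 || attenuation > 1)
    stop("attenuation must lie in (0, 1]")
  if (baseline_drop < 0)
    stop("baseline_drop must be non-negative")
  patch <- dipole_patch(spec,
                        top_factor = if (side == "top") attenuation else 1,
                        bottom_factor = if (side == "bottom") attenuation else 1)
  pmax(patch - baseline_drop, 0)
}

#' Build a full synthetic scene: parameter maps plus ground truth
#'
#' Tiles clean units at the lattice pitch, substitutes the virus-bearing
#' units listed in `spec$virus_placements`, adds a smooth linear background
#' trend to the sin-delta map (affine across the field, hence affine in the
#' unit index at unit centres — exactly annihilated by the extended Laplace
#' operator), and attaches smooth plausible `i0` and `phi` maps. The
#' construction is fully deterministic; randomness enters only through the
#' frame noise in [render_stack()].
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `maps` (list of matrices `i0`, `sindelta`,
#'   `phi` of size `rows*unit_px` x `cols*unit_px`) and `truth` (data frame
#'   with one row per lattice unit: `i`, `j`, `virus`, `side`).
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  u <- spec$unit_px
  H <- spec$rows * u
  W <- spec$cols * u
  clean <- render_clean_unit(spec)
  sind <- matrix(0, H, W)
  for (i in seq_len(spec$rows))
    for (j in seq_len(spec$cols))
      sind[(i - 1L) * u + seq_len(u), (j - 1L) * u + seq_len(u)] <- clean
  vp <- spec$virus_placements
  for (k in seq_len(NROW(vp))) {
    patch <- render_virus_unit(spec, vp$side[k], vp$attenuation[k],
                               vp$baseline_drop[k])
    sind[(vp$i[k] - 1L) * u + seq_len(u),
         (vp$j[k] - 1L) * u + seq_len(u)] <- patch
  }
  ry <- if (H > 1L) (seq_len(H) - 1) / (H - 1) else 0
  rx <- if (W > 1L) (seq_len(W) - 1) / (W - 1) else 0
  ramp <- (outer(ry, rx, `+`)) / 2         # linear trend, range [0, 1]
  sind <- sind + spec$background_gradient * ramp
  sind <- pmin(pmax(sind, 0), 1)
  i0 <- spec$i0_level * (1 + 0.05 * ramp)  # gentle illumination falloff
  phi <- (spec$phi_deg + 10 * outer(rep(0, H), rx, `+`)) %% 180
  truth <- expand.grid(i = seq_len(spec$rows), j = seq_len(spec$cols),
                       KEEP.OUT.ATTRS = FALSE)
  truth$virus <- FALSE
  truth$side <- "none"
  if (NROW(vp)) {
    key <- match(paste(vp$i, vp$j), paste(truth$i, truth$j))
    truth$virus[key] <- TRUE
    truth$side[key] <- vp$side
  }
  truth <- truth[order(truth$i, truth$j), ]
  rownames(truth) <- NULL
  list(maps = list(i0 = i0, sindelta = sind, phi = phi), truth = truth)
}

#' Render a polarization frame stack from parameter maps
#'
#' Applies the forward modulation law pixelwise for every acquisition
#' angle and adds seeded Gaussian camera noise of s.d. `spec$noise_sigma`
#' (`noise_sigma = 0` gives the exact noiseless modulation). Negative
#' intensities produced by extreme noise draws are clipped at 0 to respect
#' the physical range.
#'
#' @param maps List with matrices `i0`, `sindelta`, `phi` of one shape
#'   (e.g. `build_scene(spec)$maps`).
#' @param spec A [scene_spec()] providing angles, noise level and seed.
#' @return A [polarization_stack()].
#' @export
render_stack <- function(maps, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  d <- dim(maps$sindelta)
  if (!identical(dim(maps$i0), d) || !identical(dim(maps$phi), d))
    stop("parameter maps must share one shape")
  set.seed(spec$seed)
  frames <- lapply(spec$angles_deg, function(th) {
    f <- forward_intensity(maps$i0, maps$sindelta, maps$phi, th)
    if (spec$noise_sigma > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, spec$noise_sigma),
                      d[1L], d[2L])
    pmax(f, 0)
  })
  polarization_stack(frames, spec$angles_deg, spec$pixel_size_nm)
}

#' Draw random distinct virus placements
#'
#' Samples `n` pairwise distinct lattice units (by default only interior
#' units, whose full 8-neighbourhood exists so they survive the extended
#' Laplace validity mask) and alternates the attachment side.
#'
#' @param spec A [scene_spec()].
#' @param n Number of viruses to plant.
#' @param seed RNG seed for the placement draw.
#' @param interior Restrict placements to interior units.
#' @return Data frame suitable for `scene_spec(virus_placements = ...)`.
#' @export
random_placements <- function(spec, n, seed = spec$seed, interior = TRUE) {
  ri <- if (interior) 2:(spec$rows - 1L) else seq_len(spec$rows)
  rj <- if (interior) 2:(spec$cols - 1L) else seq_len(spec$cols)
  cells <- expand.grid(i = ri, j = rj, KEEP.OUT.ATTRS = FALSE)
  if (n > nrow(cells))
    stop("more placements requested than available units")
  set.seed(seed)
  pick <- cells[sample.int(nrow(cells), n), ]
  data.frame(i = pick$i, j = pick$j,
             side = rep(c("top", "bottom"), length.out = n),
             attenuation = spec$virus_attenuation,
             baseline_drop = spec$virus_baseline_drop)
}

#' Split-curve profile of the ring-splitting gap
#'
#' The gold disk of each nanodot is split into two arms by two
#' omega-shaped curves with profile
#' `y = 0.0000015 * (x^2 - 3600)^2 + 20` (nanometres), whose central
#' opening is slightly smaller than an 80 nm adenovirus. Used only for
#' layout rendering and documentation.
#'
#' @param x_nm Transverse coordinate in nanometres.
#' @return Curve height in nanometres.
#' @export
#' @examples
#' split_curve_y(60)  # 20: quartic term vanishes at x^2 = 3600
#' split_curve_y(0)   # 39.44
split_curve_y <- function(x_nm) {
  stopifnot(all(is.finite(x_nm)))
  0.0000015 * (x_nm^2 - 3600)^2 + 20
}

#' Write scene ground truth as CSV
#'
#' @param truth Ground-truth data frame from [build_scene()].
#' @param path CSV path (columns `i`, `j`, `virus`, `side`).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
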