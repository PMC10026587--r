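#' Read / write polarization stacks as multi-page TIFF + JSON sidecar
#'
#' The on-disk interchange format is a multi-page 32-bit float TIFF, page
#' order equal to angle order, accompanied by a JSON sidecar holding the
#' acquisition metadata (`angles_deg`, `pixel_size_nm`, `wavelength_nm`,
#' `bandwidth_nm`). TIFF pages are stored normalised to `[0, 1]`; the
#' normalisation constant is recorded in the sidecar as `intensity_scale`
#' so physical camera units round-trip (to float32 precision).
#'
#' @param stack A [polarization_stack()].
#' @param tiff_path Path of the multi-page TIFF.
#' @param sidecar_path Path of the JSON sidecar; defaults to
#'   `<tiff_path>.json`.
#' @return `write_stack()` returns `tiff_path` invisibly; `read_stack()`
#'   returns a [polarization_stack()].
#' @export
write_stack <- function(stack, tiff_path,
                        sidecar_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(stack, "polarization_stack"))
  scale <- max(stack$frames)
  if (scale <= 0) scale <- 1
  n <- dim(stack$frames)[3L]
  pages <- lapply(seq_len(n), function(k) stack$frames[, , k] / scale)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(angles_deg = stack$angles_deg,
               pixel_size_nm = stack$pixel_size_nm,
               wavelength_nm = stack$wavelength_nm,
               bandwidth_nm = stack$bandwidth_nm,
               intensity_scale = scale)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_stack
#' @export
read_stack <- function(tiff_path, sidecar_path = paste0(tiff_path, ".json")) {
  if (!file.exists(tiff_path))
    stop(sprintf("stack TIFF not found: %s", tiff_path))
  if (!file.exists(sidecar_path))
    stop(sprintf("sidecar JSON not found: %s", sidecar_path))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("angles_deg", "pixel_size_nm", "intensity_scale"))
    if (is.null(meta[[f]]))
      stop(sprintf("sidecar %s lacks required field '%s'", sidecar_path, f))
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey stored as RGB
    p * meta$intensity_scale
  })
  polarization_stack(frames, meta$angles_deg, meta$pixel_size_nm,
                     wavelength_nm = meta$wavelength_nm %||% 600,
                     bandwidth_nm = meta$bandwidth_nm %||% 35)
}

#' Read / write a single parametric map as 32-bit float TIFF
#'
#' Single-page float TIFF with a JSON sidecar carrying the affine
#' normalisation (`offset`, `scale`) applied for storage, so maps with
#' negative values (extended-Laplace montages) or values above 1 (`i0`,
#' `phi`) round-trip.
#'
#' @param map Numeric matrix.
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path; defaults to `<path>.json`.
#' @return `write_map()` returns `path` invisibly; `read_map()` the matrix.
#' @export
write_map <- function(map, path, sidecar_path = paste0(path, ".json")) {
  stopifnot(is.matrix(map), all(is.finite(map)))
  offset <- min(map, 0)
  scale <- max(map - offset)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF((map - offset) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(offset = offset, scale = scale), sidecar_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, sidecar_path = paste0(path, ".json")) {
  if (!file.exists(path))
    stop(sprintf("map TIFF not found: %s", path))
  if (!file.exists(sidecar_path))
    stop(sprintf("sidecar JSON not found: %s", sidecar_path))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  p * meta$scale + meta$offset
}

`%||%` <- function(a, b) if (is.null(a)) b else a
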