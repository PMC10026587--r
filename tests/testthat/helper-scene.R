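# Compact synthetic scenes for unit tests: 32 px units with lobe geometry
# scaled down in proportion so the dipoles stay inside the patch. The
# asymmetry statistic scales with patch area, so the virus attenuation is
# deepened to keep planted units above the standard call threshold.
small_spec <- function(rows = 5L, cols = 5L, lobe_sigma_px = 3,
                       lobe_offset_px = 6, virus_attenuation = 0.3, ...) {
  scene_spec(rows = rows, cols = cols,
             pixel_size_nm = 1000 / 32, unit_px = 32L,
             lobe_sigma_px = lobe_sigma_px,
             lobe_offset_px = lobe_offset_px,
             virus_attenuation = virus_attenuation,
             ...)
}

# Grid of constant-valued 1x1-pixel units from a matrix of unit values.
value_grid <- function(vals, unit_px = 1L) {
  u <- array(NA_real_, c(unit_px, unit_px, nrow(vals), ncol(vals)))
  for (i in seq_len(nrow(vals)))
    for (j in seq_len(ncol(vals)))
      u[, , i, j] <- vals[i, j]
  unit_grid(u, matrix(TRUE, nrow(vals), ncol(vals)))
}
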