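test_that("clean units are mirror-symmetric two-lobe dipoles", {
  spec <- small_spec()
  patch <- render_clean_unit(spec)
  expect_identical(dim(patch), c(32L, 32L))
  # exact transverse mirror symmetry => asymmetry score 0
  expect_identical(patch, patch[rev(seq_len(32)), ])
  expect_equal(asymmetry_score(patch)$score, 0)
  # maxima sit at the two lobe centres (fractional centre: 4 nearest px)
  ctr <- (32 + 1) / 2
  top <- which(patch == max(patch), arr.ind = TRUE)
  expect_true(all(abs(top[, 1] - c(ctr - 6, ctr + 6)[
    ifelse(top[, 1] < ctr, 1, 2)]) <= 0.5 + 1e-9))
  expect_true(all(abs(top[, 2] - ctr) <= 0.5 + 1e-9))
  # no lobes -> flat baseline
  flat <- render_clean_unit(small_spec(lobe_amplitude = 0))
  expect_true(all(flat == spec$baseline))
})

test_that("lobes that spill out of the patch are rejected", {
  expect_error(render_clean_unit(small_spec(lobe_offset_px = 14)),
               "exceed the unit patch bounds")
})

test_that("virus units lose intensity and gain asymmetry", {
  spec <- small_spec()
  clean <- render_clean_unit(spec)
  # identity case: no attenuation, no drop
  expect_equal(render_virus_unit(spec, "top", 1, 0), clean)
  v <- render_virus_unit(spec, "top", 0.6, 0.02)
  expect_lt(sum(v), sum(clean))
  expect_gt(abs(asymmetry_score(v)$score), 0)
  # top and bottom attachments are mirror images of each other
  vb <- render_virus_unit(spec, "bottom", 0.6, 0.02)
  expect_equal(vb, v[rev(seq_len(32)), ])
  expect_error(render_virus_unit(spec, "top", 0, 0), "\\(0, 1\\]")
  expect_error(render_virus_unit(spec, "top", 1.2, 0), "\\(0, 1\\]")
  expect_error(render_virus_unit(spec, "top", 0.5, -1), "non-negative")
})

test_that("planted asymmetry grows as the lobe attenuation deepens", {
  spec <- small_spec()
  scores <- vapply(c(0.9, 0.7, 0.5, 0.3), function(a)
    abs(asymmetry_score(render_virus_unit(spec, "top", a, 0.02))$score),
    numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("scene assembly honours placements and ground truth exactly", {
  vp <- data.frame(i = c(2, 4), j = c(3, 2),
                   side = c("top", "bottom"))
  spec <- small_spec(virus_placements = vp, background_gradient = 0)
  sc <- build_scene(spec)
  expect_identical(dim(sc$maps$sindelta), c(5L * 32L, 5L * 32L))
  expect_identical(nrow(sc$truth), 25L)
  expect_identical(sum(sc$truth$virus), 2L)
  expect_identical(sc$truth$side[sc$truth$i == 2 & sc$truth$j == 3], "top")
  # planted patch appears verbatim at its lattice slot
  u <- spec$unit_px
  got <- sc$maps$sindelta[(2 - 1) * u + seq_len(u), (3 - 1) * u + seq_len(u)]
  expect_equal(got, render_virus_unit(spec, "top"))
  # placements must be distinct, in range, with legal parameters
  expect_error(small_spec(virus_placements = data.frame(
    i = c(2, 2), j = c(2, 2), side = "top")), "distinct")
  expect_error(small_spec(virus_placements = data.frame(
    i = 9, j = 1, side = "top")), "outside")
  expect_error(small_spec(virus_placements = data.frame(
    i = 2, j = 2, side = "left")), "side")
})

test_that("identical spec and seed give bit-identical scenes and stacks", {
  spec <- small_spec(rows = 3L, cols = 3L,
                     virus_placements = data.frame(i = 2, j = 2,
                                                   side = "top"))
  s1 <- build_scene(spec)
  s2 <- build_scene(spec)
  expect_identical(s1, s2)
  expect_identical(render_stack(s1$maps, spec)$frames,
                   render_stack(s2$maps, spec)$frames)
})

test_that("noiseless stacks obey the modulation law exactly", {
  spec <- small_spec(rows = 3L, cols = 3L, noise_sigma = 0)
  sc <- build_scene(spec)
  st <- render_stack(sc$maps, spec)
  k <- 4L
  expect_equal(st$frames[, , k],
               forward_intensity(sc$maps$i0, sc$maps$sindelta,
                                 sc$maps$phi, spec$angles_deg[k]))
})

test_that("random placements are distinct interior units with both sides", {
  spec <- small_spec(rows = 6L, cols = 6L)
  vp <- random_placements(spec, 6, seed = 3)
  expect_identical(nrow(vp), 6L)
  expect_false(anyDuplicated(vp[c("i", "j")]) > 0)
  expect_true(all(vp$i >= 2 & vp$i <= 5 & vp$j >= 2 & vp$j <= 5))
  expect_setequal(unique(vp$side), c("top", "bottom"))
})

test_that("the ring-splitting curve matches its printed profile", {
  expect_equal(split_curve_y(60), 20)
  expect_equal(split_curve_y(-60), 20)   # even function
  expect_equal(split_curve_y(0), 39.44)
  expect_error(split_curve_y(Inf), "finite")
})
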