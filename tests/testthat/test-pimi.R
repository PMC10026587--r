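test_that("forward model reproduces the modulation law limit cases", {
  expect_equal(forward_intensity(2, 0, 123, 45), 1)          # no modulation
  expect_equal(forward_intensity(2, 0.5, 0, 45), 1.5)        # sin term = 1
  expect_equal(forward_intensity(2, 0.8, 30, 30), 1)         # theta == phi
  # range [0, i0] over a dense angle sweep
  th <- seq(0, 179, by = 1)
  y <- forward_intensity(3, 1, 17, th)
  expect_true(all(y >= 0 & y <= 3))
  expect_error(forward_intensity(-1, 0.5, 0, 0), "non-negative")
  expect_error(forward_intensity(1, 1.2, 0, 0), "\\[0, 1\\]")
})

test_that("constant series demodulates to zero modulation with conventions", {
  r <- demodulate_series(rep(3, 10), pimi_angles())
  expect_equal(r$i0, 6)
  expect_equal(r$sindelta, 0, tolerance = 1e-12)
  expect_equal(r$phi_deg, 0)
  expect_equal(r$residual_rms, 0, tolerance = 1e-12)
  expect_true(bitwAnd(r$flag, flag_codes()[["phi_undefined"]]) > 0)
})

test_that("demodulation inverts the forward model exactly without noise", {
  th <- pimi_angles()
  set.seed(11)
  for (k in 1:100) {
    i0 <- runif(1, 0.1, 10)
    sd <- runif(1, 0.02, 1)
    phi <- runif(1, 0, 180)
    r <- demodulate_series(forward_intensity(i0, sd, phi, th), th)
    expect_equal(r$i0, i0, tolerance = 1e-10)
    expect_equal(r$sindelta, sd, tolerance = 1e-10)
    expect_lt(phi_dist(r$phi_deg, phi), 1e-8)
    expect_lt(r$residual_rms, 1e-12)
    expect_identical(r$flag, 0L)
  }
  # also exact for unequally spaced, distinct angle sets
  th2 <- c(0, 11, 37, 61, 95, 140, 171)
  r2 <- demodulate_series(forward_intensity(2, 0.4, 77, th2), th2)
  expect_equal(r2$sindelta, 0.4, tolerance = 1e-10)
  expect_lt(phi_dist(r2$phi_deg, 77), 1e-8)
})

test_that("demodulation obeys scale equivariance and angle covariance", {
  th <- pimi_angles()
  set.seed(21)
  for (k in 1:20) {
    y <- forward_intensity(runif(1, 0.5, 3), runif(1, 0.1, 0.9),
                           runif(1, 0, 180), th) + rnorm(10, 0, 0.01)
    y <- pmax(y, 0)
    r <- demodulate_series(y, th)
    # intensity scale k multiplies i0, leaves sindelta and phi alone
    rs <- demodulate_series(3.7 * y, th)
    expect_equal(rs$i0, 3.7 * r$i0, tolerance = 1e-12)
    expect_equal(rs$sindelta, r$sindelta, tolerance = 1e-12)
    expect_equal(rs$phi_deg, r$phi_deg, tolerance = 1e-10)
    # global angle shift moves phi only, modulo 180
    delta <- runif(1, 0, 180)
    ra <- demodulate_series(y, th + delta)
    expect_equal(ra$i0, r$i0, tolerance = 1e-10)
    expect_equal(ra$sindelta, r$sindelta, tolerance = 1e-10)
    expect_lt(phi_dist(ra$phi_deg, r$phi_deg + delta), 1e-8)
  }
})

test_that("degenerate series are rejected", {
  th <- pimi_angles()
  expect_error(demodulate_series(1:4, th[1:4]), "at least 5")
  expect_error(demodulate_series(rep(1, 5), c(0, 36, 72, 180, 144)),
               "distinct modulo 180")
  expect_error(demodulate_series(c(1, NA, 1, 1, 1), th[1:5]), "finite")
  expect_error(demodulate_series(1:6, th), "equal length")
})

test_that("noisy demodulation keeps over-range sindelta flagged, unclamped", {
  th <- pimi_angles()
  # clipped over-modulated series: fitted amplitude exceeds the mean level
  y <- pmax(0.3 + 0.8 * sin(2 * th * pi / 180), 0)
  r <- demodulate_series(y, th)
  expect_gt(r$sindelta, 1)
  expect_true(bitwAnd(r$flag, flag_codes()[["overrange_sindelta"]]) > 0)
})

test_that("stack demodulation round-trips rendered parameter maps", {
  spec <- small_spec(rows = 3L, cols = 3L, noise_sigma = 0)
  sc <- build_scene(spec)
  maps <- demodulate_stack(render_stack(sc$maps, spec))
  expect_equal(dim(maps$sindelta), dim(sc$maps$sindelta))
  expect_lt(max(abs(maps$sindelta - sc$maps$sindelta)), 1e-10)
  expect_lt(max(abs(maps$i0 - sc$maps$i0)), 1e-10)
  expect_lt(max(phi_dist(maps$phi, sc$maps$phi)), 1e-8)
  expect_lt(max(maps$residual), 1e-12)
  expect_true(all(maps$flag == 0L))
})

test_that("all-zero stacks flag every pixel instead of aborting", {
  th <- pimi_angles()
  st <- polarization_stack(array(0, c(4, 4, 10)), th, 15.625)
  maps <- demodulate_stack(st)
  expect_true(all(maps$i0 == 0))
  expect_true(all(maps$sindelta == 0))
  expect_true(all(maps$flag != 0L))
})

test_that("shifting every acquisition angle shifts phi only", {
  spec <- small_spec(rows = 3L, cols = 3L, noise_sigma = 0)
  sc <- build_scene(spec)
  st <- render_stack(sc$maps, spec)
  m1 <- demodulate_stack(st)
  st2 <- polarization_stack(
    lapply(seq_along(st$angles_deg), function(k) st$frames[, , k]),
    st$angles_deg + 25, st$pixel_size_nm)
  m2 <- demodulate_stack(st2)
  expect_lt(max(abs(m2$i0 - m1$i0)), 1e-10)
  expect_lt(max(abs(m2$sindelta - m1$sindelta)), 1e-10)
  expect_lt(max(phi_dist(m2$phi, m1$phi + 25)), 1e-8)
})

test_that("stack construction enforces the acquisition invariants", {
  th <- pimi_angles()
  expect_error(polarization_stack(array(1, c(4, 4, 4)), th[1:4], 15),
               "at least 5")
  expect_error(polarization_stack(array(-1, c(4, 4, 10)), th, 15),
               "non-negative")
  expect_error(polarization_stack(array(1, c(4, 4, 10)), rep(0, 10), 15),
               "distinct")
  expect_error(
    polarization_stack(list(matrix(1, 2, 2), matrix(1, 3, 3)), th[1:2], 15),
    "one shape")
})
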