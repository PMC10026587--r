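test_that("extended Laplace cancels identical units exactly", {
  spec <- small_spec()
  patch <- render_clean_unit(spec)
  u <- array(rep(patch, 9), c(32, 32, 3, 3))
  lap <- extended_laplace(unit_grid(u, matrix(TRUE, 3, 3)))
  expect_true(lap$valid_mask[2, 2])
  expect_false(any(lap$valid_mask[-2, ]))
  expect_lt(max(abs(lap$units[, , 2, 2])), 1e-12)
})

test_that("extended Laplace reproduces the hand-computed stencil value", {
  vals <- matrix(c(1, 2, 3, 4, 10, 6, 7, 8, 9), 3, 3, byrow = TRUE)
  lap <- extended_laplace(value_grid(vals))
  expect_equal(lap$units[1, 1, 2, 2], 10 - 40 / 8)  # = 5
})

test_that("extended Laplace annihilates fields affine in the unit index", {
  vals <- outer(1:5, 1:6, function(i, j) 3 + 1.7 * i - 0.4 * j)
  lap <- extended_laplace(value_grid(vals, unit_px = 4L))
  inner <- lap$units[, , 2:4, 2:5]
  expect_lt(max(abs(inner)), 1e-12)
  expect_identical(sum(lap$valid_mask), 12L)
})

test_that("extended Laplace is linear on valid units", {
  set.seed(31)
  mk <- function() array(rnorm(2 * 2 * 4 * 4), c(2, 2, 4, 4))
  X <- mk(); Y <- mk()
  msk <- matrix(TRUE, 4, 4)
  lx <- extended_laplace(unit_grid(X, msk))$units
  ly <- extended_laplace(unit_grid(Y, msk))$units
  lz <- extended_laplace(unit_grid(2.5 * X - 1.3 * Y, msk))$units
  inner <- function(a) a[, , 2:3, 2:3]
  expect_equal(inner(lz), 2.5 * inner(lx) - 1.3 * inner(ly),
               tolerance = 1e-12)
})

test_that("units with incomplete or invalid neighbourhoods are excluded", {
  u <- array(1, c(1, 1, 3, 5))
  msk <- matrix(TRUE, 3, 5)
  msk[1, 2] <- FALSE                   # poisons every unit touching it
  lap <- extended_laplace(unit_grid(u, msk))
  expect_false(lap$valid_mask[2, 2])
  expect_false(lap$valid_mask[2, 3])
  expect_true(lap$valid_mask[2, 4])
  expect_error(extended_laplace(unit_grid(array(1, c(1, 1, 2, 3)),
                                          matrix(TRUE, 2, 3))),
               "3 x 3")
})

test_that("the asymmetry statistic matches its worked values exactly", {
  expect_equal(asymmetry_score(matrix(c(2, 1), 2, 1))$score, 1.5)
  expect_equal(asymmetry_score(matrix(c(1, -1), 2, 1))$score, -4)
  # mirror-symmetric patch scores exactly zero
  p <- matrix(runif(6), 2, 3)
  sym <- rbind(p, p[rev(seq_len(2)), ])
  expect_identical(asymmetry_score(sym)$score, 0)
})

test_that("odd patch heights exclude the middle row from both halves", {
  p <- matrix(c(2, 99, 1), 3, 1)   # middle row must not contribute
  r <- asymmetry_score(p)
  expect_equal(c(r$A, r$B), c(2, 1))
  expect_equal(r$score, 102 * (2 + 0.5 - 2))
})

test_that("mirror-flipping a patch flips the score sign only", {
  set.seed(41)
  for (k in 1:20) {
    p <- matrix(rnorm(64, mean = 0.3), 8, 8)
    r <- asymmetry_score(p)
    rf <- asymmetry_score(p[rev(seq_len(8)), ])
    if (!r$valid) next
    expect_equal(rf$score, -r$score, tolerance = 1e-12)
    expect_equal(c(rf$A, rf$B), c(r$B, r$A))
  }
})

test_that("degenerate patches are flagged, not thrown", {
  # a zero half leaves the ratio undefined -> invalid record
  r <- asymmetry_score(matrix(c(0, 1), 2, 1))
  expect_false(r$valid)
  expect_true(is.na(r$score))
  # no positive pixel: i_sum = 0, score 0, still valid
  r2 <- asymmetry_score(matrix(c(-1, -2), 2, 1))
  expect_identical(r2$i_sum, 0)
  expect_identical(r2$score, 0)
  expect_true(r2$valid)
})

test_that("the call rule applies a strict absolute threshold", {
  recs <- data.frame(i = 1:4, j = 1L, A = 1, B = 1, i_sum = 1,
                     score = c(7.5, -8, 3, 7), valid = TRUE,
                     call = NA, direction = "none")
  out <- call_units(recs, 7)
  expect_identical(out$call, c(TRUE, TRUE, FALSE, FALSE))  # 7 is not > 7
  expect_identical(out$direction, c("bottom", "top", "none", "none"))
  recs$valid[1] <- FALSE
  expect_false(call_units(recs, 7)$call[1])  # call implies valid
  expect_error(call_units(recs, -1), "positive")
})

test_that("summaries compute the count-based misdetection fraction", {
  recs <- data.frame(i = rep(1:3, each = 3), j = rep(1:3, 3),
                     A = 1, B = 1, i_sum = 1, score = 0,
                     valid = TRUE, call = FALSE, direction = "none")
  truth <- expand.grid(i = 1:3, j = 1:3, KEEP.OUT.ATTRS = FALSE)
  truth$virus <- FALSE
  truth$virus[1:6] <- TRUE
  called <- paste(recs$i, recs$j) %in%
    paste(truth$i, truth$j)[truth$virus][1:5]
  recs$call[called] <- TRUE
  s <- summarize_calls(recs, truth)
  expect_identical(c(s$tp, s$fn, s$fp), c(5L, 1L, 0L))
  expect_equal(s$p_mis, 1 / 6)
  expect_equal(s$sensitivity, 5 / 6)
  # clean field, no calls -> specificity 1
  recs$call <- FALSE
  truth$virus <- FALSE
  expect_equal(summarize_calls(recs, truth)$specificity, 1)
  # everything planted and called -> sensitivity 1
  recs$call <- TRUE
  truth$virus <- TRUE
  expect_equal(summarize_calls(recs, truth)$sensitivity, 1)
})

test_that("threshold recalibration scales off the worst clean unit", {
  recs <- data.frame(i = 1:3, j = 1, A = 1, B = 1, i_sum = 1,
                     score = c(0.5, -2, 1), valid = TRUE, call = NA,
                     direction = "none")
  expect_equal(calibrate_threshold(recs, factor = 2), 4)
  recs$valid <- FALSE
  expect_error(calibrate_threshold(recs), "no valid scores")
})

test_that("scoring a segmented field restricts to Laplace-valid units", {
  spec <- small_spec(virus_placements = data.frame(i = 3, j = 3,
                                                   side = "bottom"),
                     noise_sigma = 0)
  sc <- build_scene(spec)
  grid <- segment_units(sc$maps$sindelta,
                        array_layout(c(16.5, 16.5), 32, 5, 5, 32))
  recs <- call_units(score_units(grid))
  expect_identical(nrow(recs), 25L)              # one row per lattice unit
  expect_identical(sum(recs$valid), 9L)          # interior 3 x 3
  hit <- recs[recs$i == 3 & recs$j == 3, ]
  expect_true(hit$call)
  expect_identical(hit$direction, "bottom")
  expect_gt(hit$score, 7)                        # bottom side => positive
  others <- recs[recs$valid & !(recs$i == 3 & recs$j == 3), ]
  expect_true(all(abs(others$score) < 1))
})
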