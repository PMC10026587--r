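#' Extended Laplace operator over the unit lattice
#'
#' Unit-level analogue of the discrete Laplacian stencil: every nine
#' adjacent split-ring units are combined so that each interior unit's
#' output patch is its own patch minus one eighth of the pixelwise sum of
#' its eight neighbouring units' patches,
#' \deqn{I(i,j) = I_0(i,j) - \tfrac{1}{8}\sum_{\mathrm{8\,neighbours}} I_0.}
#' Because the stencil weights sum to zero over symmetric neighbour
#' offsets, the repeating array pattern and any background field that is
#' affine in the unit index are cancelled exactly; what remains is the
#' per-unit deviation — e.g. the intensity decrease caused by a bound
#' virus. A unit is valid in the output only if its complete
#' 8-neighbourhood exists and is valid (border units are excluded, never
#' padded: padding would fabricate background).
#'
#' @param grid A [unit_grid()] of at least 3 x 3 units.
#' @return A `unit_grid` of the same lattice dimensions; output patch
#'   values may be negative; border / incomplete-neighbourhood units are
#'   invalid.
#' @export
#' @examples
#' u <- array(rep(c(1, 2, 3, 4, 10, 6, 7, 8, 9), each = 1), c(1, 1, 3, 3))
#' lap <- extended_laplace(unit_grid(u, matrix(TRUE, 3, 3)))
#' lap$units[1, 1, 2, 2]  # 10 - 40/8 = 5
extended_laplace <- function(grid) {
  stopifnot(inherits(grid, "unit_grid"))
  d <- dim(grid$units)
  if (d[3L] < 3L || d[4L] < 3L)
    stop("extended Laplace needs a grid of at least 3 x 3 units")
  out <- array(NA_real_, d)
  valid <- matrix(FALSE, d[3L], d[4L])
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  for (i in 2:(d[3L] - 1L)) {
    for (j in 2:(d[4L] - 1L)) {
      nb_ok <- all(grid$valid_mask[i + (-1:1), j + (-1:1)])
      if (!nb_ok) next
      acc <- matrix(0, d[1L], d[2L])
      for (k in seq_len(nrow(off)))
        acc <- acc + grid$units[, , i + off$di[k], j + off$dj[k]]
      out[, , i, j] <- grid$units[, , i, j] - acc / 8
      valid[i, j] <- TRUE
    }
  }
  unit_grid(out, valid)
}

#' Asymmetry statistic of one unit patch
#'
#' Longitudinal asymmetry of a topological unit. `A` and `B` are the sums
#' of the rows above and below the transverse midline (for odd patch
#' height the middle row belongs to neither half), and `i_sum` is the sum
#' of all strictly positive pixels in the patch. The statistic is
#' \deqn{As = \mathrm{sign}(A - B)\; I_{sum} (A/B + B/A - 2),}
#' a combined measure of intensity and symmetry: a mirror-symmetric patch
#' scores exactly 0, and mirror-flipping a patch flips only the sign, so
#' the sign indicates the attachment side (negative: upper half weaker,
#' virus on top; positive: lower half weaker).
#'
#' Degenerate cases: `A = 0` or `B = 0` leaves the ratio undefined and the
#' record is marked invalid (no exception); a patch with no positive pixel
#' has `i_sum = 0` and scores 0, recorded valid.
#'
#' @param patch Numeric matrix (values may be negative for
#'   extended-Laplace patches).
#' @param i,j Unit indices carried into the record.
#' @return One-row data frame: `i`, `j`, `A`, `B`, `i_sum`, `score`,
#'   `valid`, `call` (`NA` until [call_units()]), `direction`.
#' @export
#' @examples
#' asymmetry_score(matrix(c(2, 1), 2, 1))   # score 1.5
#' asymmetry_score(matrix(c(1, -1), 2, 1))  # score -4
asymmetry_score <- function(patch, i = NA_integer_, j = NA_integer_) {
  stopifnot(is.matrix(patch))
  h <- floor(nrow(patch) / 2)
  A <- sum(patch[seq_len(h), , drop = FALSE])
  B <- sum(patch[(nrow(patch) - h + 1L):nrow(patch), , drop = FALSE])
  i_sum <- sum(patch[patch > 0])
  if (A == 0 || B == 0) {
    score <- NA_real_
    valid <- FALSE
  } else {
    score <- sign(A - B) * i_sum * (A / B + B / A - 2)
    valid <- TRUE
  }
  data.frame(i = i, j = j, A = A, B = B, i_sum = i_sum, score = score,
             valid = valid, call = NA, direction = "none",
             stringsAsFactors = FALSE)
}

#' Score every unit of a segmented field
#'
#' Computes the asymmetry record for each lattice unit. Validity is taken
#' from the extended-Laplace grid (only units with a complete valid
#' 8-neighbourhood enter the statistics). The patch the statistic is
#' evaluated on is configurable: `source = "sindelta"` (default) scores
#' the raw sin-delta unit patch, whose half-sums are anchored by the
#' pattern baseline and therefore stable; `source = "laplace"` scores the
#' background-subtracted extended-Laplace patch.
#'
#' @param grid The raw [unit_grid()] from [segment_units()].
#' @param lap The matching extended-Laplace grid; computed from `grid`
#'   when omitted.
#' @param source Which patch the A/B split and `i_sum` use.
#' @return Data frame with one record per unit (see [asymmetry_score()]).
#' @export
score_units <- function(grid, lap = extended_laplace(grid),
                        source = c("sindelta", "laplace")) {
  source <- match.arg(source)
  d <- dim(grid$units)
  if (!identical(dim(lap$units), d))
    stop("grid and laplace grid dimensions differ")
  src <- if (source == "sindelta") grid else lap
  recs <- vector("list", d[3L] * d[4L])
  k <- 0L
  for (i in seq_len(d[3L])) {
    for (j in seq_len(d[4L])) {
      k <- k + 1L
      if (lap$valid_mask[i, j]) {
        recs[[k]] <- asymmetry_score(src$units[, , i, j], i, j)
      } else {
        recs[[k]] <- data.frame(i = i, j = j, A = NA_real_, B = NA_real_,
                                i_sum = NA_real_, score = NA_real_,
                                valid = FALSE, call = NA,
                                direction = "none",
                                stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
}

#' Apply the virus call threshold
#'
#' A unit is called virus-positive when it is valid and `|score|`
#' strictly exceeds the threshold (default 7, the judgment standard
#' established on the experimental arrays). The attachment direction is
#' read off the sign of the score: negative = upper ("top") half weaker.
#'
#' @param records Data frame from [score_units()].
#' @param threshold Positive call threshold on `|score|`.
#' @return `records` with `call` and `direction` filled in.
#' @export
call_units <- function(records, threshold = 7) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  ok <- records$valid & is.finite(records$score)
  records$call <- ok & abs(records$score) > threshold
  records$direction <- ifelse(records$call,
                              ifelse(records$score < 0, "top", "bottom"),
                              "none")
  records
}

#' Summarize calls, optionally against ground truth
#'
#' Counts calls over the valid units; when ground truth is supplied also
#' tabulates the confusion matrix, sensitivity, specificity and the
#' empirical misdetection fraction (missed / attached among valid units)
#' — the count-based estimator of the misdetection probability used by
#' the detection-limit model.
#'
#' @param records Data frame from [call_units()].
#' @param truth Optional ground-truth data frame (`i`, `j`, `virus`) from
#'   [build_scene()].
#' @return Named list of counts and rates.
#' @export
summarize_calls <- function(records, truth = NULL) {
  val <- records[records$valid & !is.na(records$call), ]
  out <- list(n_units = nrow(records), n_valid = nrow(val),
              n_called = sum(val$call))
  if (!is.null(truth)) {
    key <- match(paste(val$i, val$j), paste(truth$i, truth$j))
    if (anyNA(key))
      stop("ground truth lacks rows for some valid units")
    tv <- truth$virus[key]
    out$tp <- sum(val$call & tv)
    out$fp <- sum(val$call & !tv)
    out$fn <- sum(!val$call & tv)
    out$tn <- sum(!val$call & !tv)
    out$sensitivity <- if (out$tp + out$fn > 0)
      out$tp / (out$tp + out$fn) else NA_real_
    out$specificity <- if (out$tn + out$fp > 0)
      out$tn / (out$tn + out$fp) else NA_real_
    out$p_mis <- if (out$tp + out$fn > 0)
      out$fn / (out$tp + out$fn) else NA_real_
  }
  out
}

#' Recalibrate the call threshold on clean units
#'
#' Utility for arrays whose clean-unit score spread differs from the
#' reference structures: sets the threshold a safety factor above the
#' largest clean-unit |score|.
#'
#' @param records Records from [score_units()] on a virus-free field.
#' @param factor Safety factor (> 1).
#' @return Suggested threshold.
#' @export
calibrate_threshold <- function(records, factor = 2) {
  s <- abs(records$score[records$valid & is.finite(records$score)])
  if (!length(s))
    stop("no valid scores to calibrate on")
  factor * max(s)
}

#' Write asymmetry records as CSV
#'
#' @param records Data frame from [call_units()].
#' @param path CSV path (columns `i`, `j`, `A`, `B`, `i_sum`, `score`,
#'   `valid`, `call`, `direction`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(format(records, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
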