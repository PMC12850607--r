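# Motion quantification from images, breathing-rate estimation from the
# cushion log, and the MAE validation statistic.

# 3x3 median filter with replicated edges
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- function(i) pmin(pmax(i, 1), nr)
  ci <- function(j) pmin(pmax(j, 1), nc)
  stackv <- array(NA_real_, c(nr, nc, 9))
  k <- 0
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1
    stackv[, , k] <- img[ri(seq_len(nr) + dr), ci(seq_len(nc) + dc)]
  }
  apply(stackv, c(1, 2), stats::median)
}

# second-order-accurate central differences along rows (one-sided at the
# ends), the numpy.gradient convention
row_gradient <- function(img) {
  nr <- nrow(img)
  g <- img
  if (nr >= 3) {
    g[2:(nr - 1), ] <- (img[3:nr, , drop = FALSE] -
                          img[1:(nr - 2), , drop = FALSE]) / 2
  }
  g[1, ] <- img[2, ] - img[1, ]
  g[nr, ] <- img[nr, ] - img[nr - 1, ]
  g
}

#' Detect a horizontal boundary row within an ROI
#'
#' The edge-detection algorithm used to track the lung-liver interface or
#' the phantom edge: (1) crop to the rectangular ROI, (2) 3x3 median filter,
#' (3) column-wise derivatives along rows by second-order-accurate central
#' differences, (4) row-wise sums of derivative magnitudes, (5) the row with
#' the maximum sum is the boundary (ties broken toward the smaller row
#' index). Scoring gradient magnitude makes the detector polarity-agnostic.
#'
#' @param image Numeric matrix (rows = superior-inferior axis).
#' @param roi List with integer index vectors `rows` (>= 5) and `cols`
#'   (>= 3) defining the rectangular region over the moving boundary.
#' @return Detected boundary row index in full-image coordinates.
#' @export
detect_edge <- function(image, roi) {
  stopifnot(is.list(roi), length(roi$rows) >= 5, length(roi$cols) >= 3)
  crop <- image[roi$rows, roi$cols, drop = FALSE]
  med <- median_filter3(crop)
  g <- row_gradient(med)
  score <- rowSums(abs(g))
  if (max(score) <= 1e-12) {
    stop("no detectable edge: ROI gradient is zero everywhere")
  }
  roi$rows[which.max(score)]
}

#' Per-frame displacement series from a frame stack
#'
#' Applies [detect_edge()] to the Dixon water image of every frame and
#' reports the boundary position relative to the first (exhaled) frame, the
#' frame-to-frame differences, and the mean absolute respiratory motion
#' (mean over frames of the absolute frame-to-frame difference).
#'
#' @param stack A `frame_stack` (see [simulate_series()]).
#' @param roi Edge-detection ROI, see [detect_edge()].
#' @return List with `edge_rows`, `displacement_mm` (relative to the first
#'   frame), `frame_diff_mm`, `mean_abs_motion_mm`.
#' @export
displacement_series <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- dim(stack$echo1)[3]
  edges <- integer(n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    w <- dixon_water(stack$echo1[, , i], stack$echo2[, , i])
    e <- tryCatch(detect_edge(w, roi), error = function(err) NA_integer_)
    if (is.na(e)) failed <- c(failed, i)
    edges[i] <- e
  }
  if (length(failed)) {
    stop("edge detection failed on frame(s): ", paste(failed, collapse = ", "))
  }
  disp <- (edges - edges[1]) * stack$pixel_mm
  dd <- diff(disp)
  list(edge_rows = edges,
       displacement_mm = disp,
       frame_diff_mm = dd,
       mean_abs_motion_mm = if (length(dd)) mean(abs(dd)) else 0)
}

#' Breathing rate from a cushion log
#'
#' (1) min-max normalizes the signal, (2) thresholds it at `threshold_frac`
#' of the normalized range, (3) identifies threshold crossings, (4) keeps one
#' reference index per excursion by a continuity condition (crossings closer
#' than a refractory interval collapse to the first), (5) computes breathing
#' periods between every second reference index, and (6) returns
#' `60 / mean(period)`.
#'
#' @param log A [cushion_log()].
#' @param threshold_frac Threshold as a fraction of the normalized range
#'   (default 0.5).
#' @param rate_hint_bpm Optional expected rate; sets the refractory interval
#'   to 0.2 x the expected period (default interval: 0.3 s). The interval
#'   must stay below the shortest gap between genuine crossings -- 1/3 of
#'   the period for the default inhale-dwell fraction -- while absorbing
#'   noise chatter around the threshold.
#' @return Estimated rate in breaths per minute.
#' @export
breathing_rate <- function(log, threshold_frac = 0.5, rate_hint_bpm = NULL) {
  stopifnot(inherits(log, "cushion_log"))
  v <- log$value
  rng <- range(v)
  if (diff(rng) <= 1e-12) stop("cushion signal is constant: no cycles recoverable")
  vn <- (v - rng[1]) / diff(rng)
  s <- sign(vn - threshold_frac)
  s[s == 0] <- 1
  cross <- which(s[-1] != s[-length(s)])
  if (length(cross) < 2) stop("insufficient cycles: fewer than 2 threshold crossings")
  tc <- log$time[cross]
  refractory <- if (!is.null(rate_hint_bpm)) 0.2 * 60 / rate_hint_bpm else 0.3
  refs <- tc[1]
  for (t in tc[-1]) {
    if (t - refs[length(refs)] >= refractory) refs <- c(refs, t)
  }
  anchors <- refs[seq(1, length(refs), by = 2)]
  periods <- diff(anchors)
  if (length(periods) < 2) {
    stop("insufficient cycles: fewer than 2 breathing periods recoverable")
  }
  60 / mean(periods)
}

#' Mean absolute error between ROI-averaged asymmetry vectors
#'
#' The deviation between a motion experiment and the static ground truth:
#' the mean of the absolute differences of the 9 ROI-averaged MTR-asymmetry
#' terms (3 target offsets x cortex/medulla/pelvis), with a 95% interval.
#' The interval is either a normal-theory t interval on the 9 absolute
#' deviations (default) or a percentile bootstrap over the 9 terms.
#'
#' @param x,y Numeric vectors of the 9 matched ROI-offset means (percent),
#'   or `roi_aggregate()` data frames which are matched on (roi, offset).
#' @param interval `"normal"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return List with `mae_pct`, `ci_lower`, `ci_upper`, `deviations`,
#'   `interval`.
#' @export
mae <- function(x, y, interval = c("normal", "bootstrap"), level = 0.95,
                n_boot = 2000L, seed = 1L) {
  interval <- match.arg(interval)
  if (is.data.frame(x) || is.data.frame(y)) {
    return(mae_from_stats(x, y, interval = interval, level = level,
                          n_boot = n_boot, seed = seed))
  }
  if (length(x) != 9L || length(y) != 9L) {
    stop("x and y must each contain exactly the 9 (offset, ROI) means")
  }
  if (anyNA(x) || anyNA(y)) {
    miss <- which(is.na(x) | is.na(y))
    stop("missing terms at position(s): ", paste(miss, collapse = ", "))
  }
  d <- abs(x - y)
  m <- mean(d)
  n <- length(d)
  if (interval == "normal") {
    half <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(d) / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    bs <- replicate(n_boot, mean(d[sample.int(n, n, replace = TRUE)]))
    ci <- stats::quantile(bs, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
  }
  list(mae_pct = m, ci_lower = ci[1], ci_upper = ci[2], deviations = d,
       interval = interval)
}

#' @rdname mae
#' @param stats_x,stats_y `roi_aggregate()` data frames for the experiment
#'   and the static ground truth.
#' @export
mae_from_stats <- function(stats_x, stats_y, interval = c("normal", "bootstrap"),
                           level = 0.95, n_boot = 2000L, seed = 1L) {
  key <- function(df) paste(df$roi, df$offset_ppm, sep = "@")
  kx <- key(stats_x); ky <- key(stats_y)
  common <- intersect(kx, ky)
  bad_x <- stats_x$empty[match(common, kx)]
  bad_y <- stats_y$empty[match(common, ky)]
  if (any(bad_x | bad_y)) {
    stop("empty ROI term(s): ", paste(common[bad_x | bad_y], collapse = ", "))
  }
  if (length(common) != 9L || length(union(kx, ky)) != 9L) {
    stop("x and y must contain exactly the same 9 (offset, ROI) terms; ",
         "unmatched: ",
         paste(setdiff(union(kx, ky), common), collapse = ", "))
  }
  x <- stats_x$mean_pct[match(common, kx)]
  y <- stats_y$mean_pct[match(common, ky)]
  names(x) <- names(y) <- common
  mae(x, y, interval = match.arg(interval), level = level,
      n_boot = n_boot, seed = seed)
}
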