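#' Default radius grid for variance-scale curves
#'
#' Thirty logarithmically spaced radii from twice the median step length to
#' half the bounding-box diagonal of the path. Log spacing resolves nested
#' scales; the lower bound keeps the smallest circles above the sampling
#' resolution, while the upper bound must comfortably exceed the largest
#' scale domain of interest — a peak can only be resolved if the curve
#' descends again beyond it, so the grid extends well past the radius at
#' which peaks are expected.
#'
#' @param traj a [trajectory()].
#' @param n number of radii.
#' @return Numeric vector of `n` strictly increasing radii.
#' @export
default_radius_grid <- function(traj, n = 30) {
  stopifnot(inherits(traj, "trajectory"))
  lo <- 2 * median_step(traj)
  hi <- sqrt(diff(range(traj$x))^2 + diff(range(traj$y))^2) / 2
  if (!is.finite(lo) || lo <= 0) lo <- hi / 100
  if (hi <= lo) stop("path extent too small for a radius grid", call. = FALSE)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Variance-scale curve of a trajectory
#'
#' Computes the residence time of every fix for each radius in a grid, then
#' the variation of those residence times per radius, in one of two modes:
#' `"var_log_rt"`, the unbiased sample variance of natural-log residence
#' times (the log transformation makes the variance independent of the
#' mean), or `"cv_rt"`, the coefficient of variation (sample SD divided by
#' mean). A peak in the resulting curve appears at the radius matching the
#' spatial scale of area-restricted search; several distinct peaks indicate
#' a multiscale (e.g. hierarchical) response.
#'
#' Censored residence times (the path starts or ends inside the circle, so
#' the full residence is not observed) are included by default: at radii
#' approaching the path extent censored residence times converge on the
#' total path duration, which reproduces the canonical large-radius decline
#' of the curve (larger circles contain ever more heterogeneous path
#' segments, so residence times grow more similar). Setting
#' `include_censored = FALSE` instead drops censored values, leaving
#' `n_valid` to shrink at large radii. Zero residence times are excluded
#' from the log mode, with the exclusion count recorded in attribute
#' `n_zero_excluded`.
#'
#' @param traj a [trajectory()].
#' @param radii radius grid; default [default_radius_grid()].
#' @param mode `"var_log_rt"` (default) or `"cv_rt"`.
#' @param max_time_outside if `> 0`, residence times are the merged focal
#'   visit durations from [revisit_stats()] rather than the plain
#'   first-entry-to-first-exit definition. Default 0 (no merging).
#' @param include_censored include censored residence times?
#' @param method crossing method, see [first_passage_time()].
#' @return An object of class `"vsc"`: data frame with columns `r`,
#'   `statistic`, `n_valid` (radii with fewer than 2 valid residence times
#'   carry `NA`), plus attributes `mode`, `n_fixes`, `n_zero_excluded`.
#' @examples
#' tr <- trajectory(0:200, 0:200, rep(0, 201))
#' variance_scale_curve(tr, radii = c(2, 5, 10))$statistic  # ~0: constant RT
#' @export
variance_scale_curve <- function(traj, radii = NULL,
                                 mode = c("var_log_rt", "cv_rt"),
                                 max_time_outside = 0,
                                 include_censored = TRUE,
                                 method = c("interpolate", "discrete")) {
  stopifnot(inherits(traj, "trajectory"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (is.null(radii)) radii <- default_radius_grid(traj)
  check_radius(radii)
  if (is.unsorted(radii, strictly = TRUE))
    stop("radii must be strictly increasing", call. = FALSE)
  n_zero <- 0L
  stat <- numeric(length(radii)); n_valid <- integer(length(radii))
  if (max_time_outside > 0) {
    for (j in seq_along(radii)) {
      rs <- revisit_stats(traj, radii[j], max_time_outside)
      res <- vsc_statistic(rs$focal_duration, rs$focal_censored,
                           mode, include_censored)
      stat[j] <- res$stat; n_valid[j] <- res$n; n_zero <- n_zero + res$zeros
    }
  } else {
    rtm <- cpp_rt_matrix(traj$t, traj$x, traj$y, as.numeric(radii),
                         method == "interpolate")
    for (j in seq_along(radii)) {
      res <- vsc_statistic(rtm$rt[, j], rtm$censored[, j],
                           mode, include_censored)
      stat[j] <- res$stat; n_valid[j] <- res$n; n_zero <- n_zero + res$zeros
    }
  }
  if (n_zero > 0)
    message("excluded ", n_zero, " zero residence time(s) from log variance")
  out <- data.frame(r = as.numeric(radii), statistic = stat,
                    n_valid = n_valid)
  class(out) <- c("vsc", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "n_fixes") <- nrow(traj)
  attr(out, "n_zero_excluded") <- n_zero
  out
}

vsc_statistic <- function(rt, censored, mode, include_censored) {
  keep <- is.finite(rt) & (include_censored | !censored)
  zeros <- 0L
  v <- rt[keep]
  if (mode == "var_log_rt") {
    zeros <- sum(v <= 0)
    v <- v[v > 0]
    s <- if (length(v) >= 2) var(log(v)) else NA_real_
  } else {
    s <- if (length(v) >= 2 && mean(v) > 0) sd(v) / mean(v) else NA_real_
  }
  list(stat = s, n = length(v), zeros = zeros)
}

#' Detect peaks in a variance-scale curve
#'
#' After moving-average smoothing, interior local maxima whose prominence
#' (height above the higher of the two flanking minima) is at least
#' `min_prominence_frac` of the curve's total range are reported, ordered by
#' radius. A maximum at the smallest grid radius is the signature of resting
#' stops (the curve "peaking at r = 0") and is reported separately via the
#' `r0_peak` attribute, not counted among ARS scales.
#'
#' @param curve a `"vsc"` object from [variance_scale_curve()].
#' @param min_prominence_frac minimum prominence as a fraction of the
#'   smoothed curve's range (max minus min). Relative, so peak detection is
#'   invariant to uniform scaling of the statistic.
#' @param smooth_window odd moving-average window width (`1` = no
#'   smoothing). Windows shrink symmetrically at the curve ends.
#' @return An object of class `"vsc_peaks"`: data frame with columns
#'   `r_peak`, `height`, `prominence`, plus attributes `r0_peak` (logical)
#'   and `r0_height`.
#' @export
detect_peaks <- function(curve, min_prominence_frac = 0.05,
                         smooth_window = 3) {
  stopifnot(inherits(curve, "vsc"))
  if (!is.numeric(smooth_window) || length(smooth_window) != 1 ||
      smooth_window < 1 || smooth_window %% 2 != 1)
    stop("smooth_window must be a positive odd integer", call. = FALSE)
  ok <- is.finite(curve$statistic)
  r <- curve$r[ok]; yraw <- curve$statistic[ok]
  m <- length(yraw)
  empty <- data.frame(r_peak = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (m < 3) {
    out <- empty
    class(out) <- c("vsc_peaks", "data.frame")
    attr(out, "r0_peak") <- FALSE
    return(out)
  }
  y <- moving_average(yraw, smooth_window)
  rng <- max(y) - min(y)
  idx <- local_maxima(y)
  idx <- idx[idx > 1 & idx < m]  # interior only
  if (rng <= 0 || !length(idx)) {
    peaks <- empty
  } else {
    prom <- vapply(seq_along(idx), function(k) {
      i <- idx[k]
      left_lo <- if (k == 1) 1L else idx[k - 1]
      right_hi <- if (k == length(idx)) m else idx[k + 1]
      lmin <- min(y[left_lo:i])
      rmin <- min(y[i:right_hi])
      y[i] - max(lmin, rmin)
    }, numeric(1))
    keep <- prom >= min_prominence_frac * rng
    peaks <- data.frame(r_peak = r[idx[keep]], height = y[idx[keep]],
                        prominence = prom[keep])
  }
  class(peaks) <- c("vsc_peaks", "data.frame")
  attr(peaks, "r0_peak") <- y[1] > y[2]
  attr(peaks, "r0_height") <- if (y[1] > y[2]) y[1] else NA_real_
  attr(peaks, "mode") <- attr(curve, "mode")
  peaks
}

# centred moving average with symmetric window shrinkage at the ends
moving_average <- function(y, w) {
  if (w <= 1) return(y)
  h <- (w - 1) / 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(y[(i - k):(i + k)])
  }, numeric(1))
}

# indices of interior local maxima, plateau-aware (first index of a maximal
# plateau); plateaus touching either end of the series are not maxima
local_maxima <- function(y) {
  rl <- rle(y)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  k <- length(rl$values)
  out <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1 || j == k) next
    if (rl$values[j - 1] < rl$values[j] && rl$values[j + 1] < rl$values[j])
      out <- c(out, starts[j])
  }
  out
}

#' Characteristic ARS radius from detected peaks
#'
#' `policy = "per_peak"` returns each peak's radius. `policy =
#' "upper_limit"` groups peaks into scale domains (peaks whose radii differ
#' by less than a factor of `domain_factor` belong to the same domain) and
#' returns the largest radius in each domain — when a curve, or a set of
#' curves, indicates a range of radii for one scale, the upper limit of that
#' range is the safer choice for place identification, because
#' under-estimating the radius splits single visits into spurious revisits.
#'
#' @param peaks a `"vsc_peaks"` object (or data frame with `r_peak`).
#' @param policy `"upper_limit"` (default) or `"per_peak"`.
#' @param domain_factor radii within this multiplicative factor of each
#'   other are treated as one scale domain.
#' @return Numeric vector of characteristic radii (one per domain for
#'   `"upper_limit"`). Errors if no peaks were detected.
#' @export
characteristic_radius <- function(peaks, policy = c("upper_limit", "per_peak"),
                                  domain_factor = 2) {
  policy <- match.arg(policy)
  if (!nrow(peaks)) stop("no ARS scale detected (empty peak list)",
                         call. = FALSE)
  r <- sort(peaks$r_peak)
  if (policy == "per_peak") return(r)
  dom <- cumsum(c(1, as.numeric(diff(log(r)) >= log(domain_factor))))
  as.numeric(tapply(r, dom, max))
}

#' @export
print.vsc <- function(x, ...) {
  cat(sprintf("Variance-scale curve (%s): %d radii in [%.4g, %.4g], %d fixes\n",
              attr(x, "mode"), nrow(x), min(x$r), max(x$r),
              attr(x, "n_fixes")))
  invisible(x)
}

#' @export
plot.vsc <- function(x, log = "x", type = "b", peaks = NULL, ...) {
  ylab <- if (attr(x, "mode") == "var_log_rt") "var(log RT)" else "CV(RT)"
  plot(x$r, x$statistic, log = log, type = type, xlab = "radius",
       ylab = ylab, ...)
  if (!is.null(peaks) && nrow(peaks))
    abline(v = peaks$r_peak, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
print.vsc_peaks <- function(x, ...) {
  cat(sprintf("%d ARS-scale peak(s)%s\n", nrow(x),
              if (isTRUE(attr(x, "r0_peak")))
                " + maximum at smallest radius (resting-stop signature)"
              else ""))
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}
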