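#' First-passage time from a focal fix
#'
#' Time from the focal fix's timestamp until the path first reaches the
#' perimeter of the circle of radius `r` centred on that fix, scanning
#' forward or backward along the path. The crossing is located by linear
#' interpolation between fixes (`method = "interpolate"`); the discrete
#' alternative counts time to the first recorded fix at distance `>= r`,
#' which reproduces grid-stepped analyses exactly.
#'
#' If the path ends (or starts, scanning backward) before leaving the circle
#' the passage is censored and the returned duration is the time to the path
#' end (start).
#'
#' @param traj a [trajectory()].
#' @param i focal fix index (1-based).
#' @param r circle radius, `> 0`.
#' @param direction `"forward"` or `"backward"`.
#' @param method `"interpolate"` (default) or `"discrete"`.
#' @return A list with `duration` and logical `censored`.
#' @export
first_passage_time <- function(traj, i, r,
                               direction = c("forward", "backward"),
                               method = c("interpolate", "discrete")) {
  stopifnot(inherits(traj, "trajectory"))
  direction <- match.arg(direction)
  method <- match.arg(method)
  check_radius(r)
  check_index(i, nrow(traj))
  res <- cpp_fpt(traj$t, traj$x, traj$y, as.integer(i) - 1L, r,
                 if (direction == "forward") 1L else -1L,
                 method == "interpolate")
  list(duration = res$duration, censored = res$censored)
}

#' Residence time around a focal fix
#'
#' The total time spent inside the circle of radius `r` centred on fix `i`,
#' from first entry to first exit: the sum of the backward and forward
#' first-passage times. Censored if the path starts or ends inside the
#' circle. High residence times mark locations where the animal performed
#' area-restricted search (tortuous or slow movement within a confined
#' area).
#'
#' @inheritParams first_passage_time
#' @return A list with `duration` and logical `censored`.
#' @examples
#' tr <- trajectory(0:20, 0:20, rep(0, 21))  # unit speed, straight
#' residence_time(tr, 11, r = 3)$duration    # 2 * r / speed = 6
#' @export
residence_time <- function(traj, i, r, method = c("interpolate", "discrete")) {
  method <- match.arg(method)
  fb <- first_passage_time(traj, i, r, "backward", method)
  ff <- first_passage_time(traj, i, r, "forward", method)
  list(duration = fb$duration + ff$duration,
       censored = fb$censored || ff$censored)
}

#' Residence times of every fix over a radius grid
#'
#' Long-format table of residence times: one row per focal fix per radius.
#'
#' @inheritParams first_passage_time
#' @param radii numeric vector of radii, all `> 0`.
#' @return A data frame with columns `fix`, `t`, `x`, `y`, `r`, `rt`,
#'   `censored`.
#' @export
residence_times <- function(traj, radii, method = c("interpolate", "discrete")) {
  stopifnot(inherits(traj, "trajectory"))
  method <- match.arg(method)
  check_radius(radii)
  res <- cpp_rt_matrix(traj$t, traj$x, traj$y, as.numeric(radii),
                       method == "interpolate")
  n <- nrow(traj); m <- length(radii)
  data.frame(fix = rep(seq_len(n), m),
             t = rep(traj$t, m), x = rep(traj$x, m), y = rep(traj$y, m),
             r = rep(as.numeric(radii), each = n),
             rt = as.vector(res$rt),
             censored = as.vector(res$censored))
}

#' Revisit history of a circle around a focal fix
#'
#' Traces all backward and forward segments of the path that pass inside the
#' circle of radius `r` centred on fix `i`, i.e. every maximal interpolated
#' sub-interval of the path spent inside the circle. Consecutive segments
#' separated by a time outside the circle strictly shorter than
#' `max_time_outside` are merged into a single visit whose duration is the
#' sum of the inside durations only (excursion time is not counted).
#'
#' `max_time_outside = 0` performs no merging; `Inf` collapses all time
#' inside the circle into one visit.
#'
#' @inheritParams first_passage_time
#' @param max_time_outside merging threshold (same time unit as `traj$t`),
#'   `>= 0`. There is no meaningful universal default above zero: choosing a
#'   threshold requires a priori knowledge of the relevant temporal scales,
#'   so it is always an explicit argument.
#' @return An object of class `"revisit_history"`: a data frame of visit
#'   segments with columns `t_in`, `t_out`, `duration`, `kind` (`"backward"`,
#'   `"focal"` or `"forward"`), `censored_start`, `censored_end`, and
#'   attributes `focal_index`, `r`, `max_time_outside`, `n_visits`,
#'   `mean_visit_duration`, `total_time`.
#' @export
revisit_history <- function(traj, i, r, max_time_outside = 0) {
  stopifnot(inherits(traj, "trajectory"))
  check_radius(r)
  check_index(i, nrow(traj))
  if (!is.numeric(max_time_outside) || length(max_time_outside) != 1 ||
      is.na(max_time_outside) || max_time_outside < 0)
    stop("max_time_outside must be a single number >= 0", call. = FALSE)
  seg <- cpp_visit_segments(traj$t, traj$x, traj$y,
                            traj$x[i], traj$y[i], r)
  seg <- as.data.frame(seg)
  seg <- merge_segments(seg, max_time_outside)
  tf <- traj$t[i]
  kind <- ifelse(seg$t_out < tf, "backward",
                 ifelse(seg$t_in > tf, "forward", "focal"))
  out <- data.frame(t_in = seg$t_in, t_out = seg$t_out,
                    duration = seg$duration, kind = kind,
                    censored_start = seg$censored_start > 0,
                    censored_end = seg$censored_end > 0)
  class(out) <- c("revisit_history", "data.frame")
  attr(out, "focal_index") <- i
  attr(out, "r") <- r
  attr(out, "max_time_outside") <- max_time_outside
  attr(out, "n_visits") <- nrow(out)
  attr(out, "mean_visit_duration") <- mean(out$duration)
  attr(out, "total_time") <- sum(out$duration)
  out
}

# merge raw inside intervals whose outside gap is strictly < max_time_outside;
# merged duration sums inside time only
merge_segments <- function(seg, max_time_outside) {
  seg$duration <- seg$t_out - seg$t_in
  if (nrow(seg) <= 1 || max_time_outside <= 0) return(seg)
  grp <- cumsum(c(1, as.numeric(
    seg$t_in[-1] - seg$t_out[-nrow(seg)] >= max_time_outside)))
  out <- do.call(rbind, lapply(split(seg, grp), function(g) {
    data.frame(t_in = g$t_in[1], t_out = g$t_out[nrow(g)],
               duration = sum(g$duration),
               censored_start = g$censored_start[1],
               censored_end = g$censored_end[nrow(g)])
  }))
  rownames(out) <- NULL
  out
}

#' Per-fix revisit statistics at one radius
#'
#' For each requested focal fix, the number of (merged) visits its circle
#' received, their mean duration, their total duration, and the duration of
#' the visit containing the focal fix itself. This is the bulk engine behind
#' ARS-place identification and the merged-RT option of the variance-scale
#' curve.
#'
#' @inheritParams revisit_history
#' @param indices focal fix indices; default all fixes.
#' @return A data frame with one row per focal fix: `fix`, `n_visits`,
#'   `mean_visit_duration`, `total_time`, `focal_duration`, `focal_censored`.
#' @export
revisit_stats <- function(traj, r, max_time_outside = 0, indices = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  check_radius(r)
  if (is.null(indices)) indices <- seq_len(nrow(traj))
  check_index(indices, nrow(traj))
  m <- cpp_revisit_stats(traj$t, traj$x, traj$y,
                         as.integer(indices) - 1L, r, max_time_outside)
  data.frame(fix = as.integer(indices),
             n_visits = as.integer(m[, "n_visits"]),
             mean_visit_duration = m[, "mean_visit_duration"],
             total_time = m[, "total_time"],
             focal_duration = m[, "focal_duration"],
             focal_censored = m[, "focal_censored"] > 0)
}

#' @export
print.revisit_history <- function(x, ...) {
  cat(sprintf(
    "Revisit history of fix %d (r = %g, max_time_outside = %g):\n",
    attr(x, "focal_index"), attr(x, "r"), attr(x, "max_time_outside")))
  cat(sprintf("  %d visit(s), mean duration %.4g, total time inside %.4g\n",
              attr(x, "n_visits"), attr(x, "mean_visit_duration"),
              attr(x, "total_time")))
  print(as.data.frame(x))
  invisible(x)
}

check_radius <- function(r) {
  if (!is.numeric(r) || !length(r) || anyNA(r) || any(r <= 0))
    stop("radius must be positive", call. = FALSE)
  invisible(r)
}

check_index <- function(i, n) {
  if (!is.numeric(i) || !length(i) || anyNA(i) || any(i < 1) || any(i > n) ||
      any(i != round(i)))
    stop("fix index out of range 1..", n, call. = FALSE)
  invisible(i)
}
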