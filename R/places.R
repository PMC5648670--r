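#' Filter out non-ARS locations
#'
#' Step two of the ARS-place algorithm. Given a per-fix revisit criterion
#' (mean visit duration or total time inside the circle), the threshold is
#' the larger of the mean and the median of the criterion's distribution,
#' and fixes whose value is strictly greater than the threshold survive.
#' Recorded locations that the animal merely crossed en route fall below
#' the threshold; with all values identical nothing exceeds it and the
#' survivor set is empty ("no ARS detected").
#'
#' @param stats per-fix revisit statistics from [revisit_stats()] (or any
#'   data frame with a `fix` column and the criterion column).
#' @param criterion `"mean_visit_duration"` or `"total_time"`.
#' @return A list with `indices` (surviving fix indices), `threshold`, and
#'   `values` (criterion value per input row).
#' @examples
#' s <- data.frame(fix = 1:5, mean_visit_duration = c(1, 1, 1, 1, 100))
#' filter_locations(s, "mean_visit_duration")$indices  # only fix 5
#' @export
filter_locations <- function(stats,
                             criterion = c("mean_visit_duration",
                                           "total_time")) {
  criterion <- match.arg(criterion)
  v <- stats[[criterion]]
  if (is.null(v) || !length(v)) stop("no revisit statistics supplied",
                                     call. = FALSE)
  thr <- max(mean(v), median(v))
  keep <- which(v > thr)
  list(indices = stats$fix[keep], threshold = thr, values = v)
}

#' Proximity graph of surviving locations
#'
#' Step three, part one. Surviving locations are graph nodes; an undirected
#' edge joins two locations when each lies inside the other's circle — with
#' a single shared radius this is simply Euclidean distance strictly less
#' than `r` (the same strict inside-ness convention used everywhere).
#'
#' @param traj a [trajectory()].
#' @param survivors fix indices (nodes).
#' @param r circle radius, `> 0`.
#' @return An undirected `igraph` graph with vertex attribute `fix` holding
#'   the trajectory fix index.
#' @export
build_proximity_graph <- function(traj, survivors, r) {
  stopifnot(inherits(traj, "trajectory"))
  check_radius(r)
  survivors <- as.integer(survivors)
  check_index(survivors, nrow(traj))
  edges <- cpp_proximity_edges(traj$x[survivors], traj$y[survivors], r)
  g <- igraph::make_empty_graph(n = length(survivors), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::set_vertex_attr(g, "fix", value = survivors)
}

#' Connected components of a proximity graph
#'
#' Step three, part two. ARS places are the maximal connected components of
#' the proximity graph: subgroups in which any two locations are directly
#' or indirectly connected. Traversal is iterative (no recursion), so
#' arbitrarily long chains of locations are handled.
#'
#' @param graph a graph from [build_proximity_graph()].
#' @return A list of integer vectors of trajectory fix indices, one per
#'   component, ordered by first fix.
#' @export
connected_components <- function(graph) {
  comp <- igraph::components(graph)
  fix <- igraph::vertex_attr(graph, "fix")
  if (is.null(fix)) fix <- seq_len(igraph::vcount(graph))
  out <- split(fix, comp$membership)
  out <- lapply(out, sort)
  names(out) <- NULL
  out[order(vapply(out, min, numeric(1)))]
}

#' Representative location of an ARS place
#'
#' Step four. The component member with the largest criterion value
#' represents the central location of the place; its own revisit history
#' stands for the history of the place (pooling members' histories would in
#' part be pseudoreplication). Ties go to the earliest fix index.
#'
#' @param component integer vector of fix indices.
#' @param stats per-fix statistics from [revisit_stats()] covering the
#'   component members.
#' @param criterion `"mean_visit_duration"` or `"total_time"`.
#' @return The representative fix index.
#' @export
choose_representative <- function(component, stats,
                                  criterion = c("mean_visit_duration",
                                                "total_time")) {
  criterion <- match.arg(criterion)
  component <- sort(as.integer(component))
  v <- stats[[criterion]][match(component, stats$fix)]
  if (anyNA(v)) stop("statistics missing for some component members",
                     call. = FALSE)
  component[which.max(v)]  # which.max takes the first (earliest) maximum
}

#' Identify spatially distinct revisited ARS places
#'
#' The full four-step algorithm: (1) trace the revisit history of every fix
#' at radius `r`; (2) filter out fixes whose criterion value does not
#' strictly exceed the max(mean, median) threshold; (3) connect surviving
#' fixes lying within distance `r` of each other and take connected
#' components as candidate places; (4) represent each place by its
#' highest-criterion member, whose revisit history supplies the place's
#' mean visit duration and number of revisits.
#'
#' Diagnostics: `single_visit` flags places whose representative circle was
#' entered only once — typically a long stationary stop rather than ARS;
#' `drop_single_visit = TRUE` removes them. `oversized` flags components
#' whose spatial extent exceeds twice the analysis radius; such components
#' may merge adjacent distinct places and should be inspected (they are
#' flagged, never split automatically).
#'
#' @param traj a [trajectory()].
#' @param r analysis radius, typically a [characteristic_radius()] from the
#'   variance-scale step.
#' @param criterion filtering/representative criterion,
#'   `"mean_visit_duration"` (recommended for ARS detection) or
#'   `"total_time"`.
#' @param max_time_outside visit-merging threshold, see [revisit_history()].
#' @param drop_single_visit drop places with a single visit?
#' @return An object of class `"ars_places"`: a list with `places` (data
#'   frame: `place`, `representative_index`, `x`, `y`, `n_revisits`,
#'   `mean_visit_duration`, `total_time`, `extent_radius`, `single_visit`,
#'   `oversized`), `members` (list of fix-index vectors), `histories`
#'   (list of [revisit_history()] objects of the representatives), plus
#'   `r`, `criterion`, `threshold`, `n_survivors`.
#' @export
identify_ars_places <- function(traj, r,
                                criterion = c("mean_visit_duration",
                                              "total_time"),
                                max_time_outside = 0,
                                drop_single_visit = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  criterion <- match.arg(criterion)
  check_radius(r)
  stats <- revisit_stats(traj, r, max_time_outside)
  filt <- filter_locations(stats, criterion)
  empty <- list(places = data.frame(
    place = integer(0), representative_index = integer(0),
    x = numeric(0), y = numeric(0), n_revisits = integer(0),
    mean_visit_duration = numeric(0), total_time = numeric(0),
    extent_radius = numeric(0), single_visit = logical(0),
    oversized = logical(0)),
    members = list(), histories = list(), r = r, criterion = criterion,
    threshold = filt$threshold, n_survivors = length(filt$indices))
  if (!length(filt$indices)) {
    message("no locations exceed the filtering threshold; no ARS detected")
    class(empty) <- "ars_places"
    return(empty)
  }
  g <- build_proximity_graph(traj, filt$indices, r)
  comps <- connected_components(g)
  reps <- vapply(comps, choose_representative, integer(1),
                 stats = stats, criterion = criterion)
  histories <- lapply(reps, function(i)
    revisit_history(traj, i, r, max_time_outside))
  places <- data.frame(
    place = seq_along(comps),
    representative_index = reps,
    x = traj$x[reps],
    y = traj$y[reps],
    n_revisits = vapply(histories, function(h) attr(h, "n_visits"),
                        integer(1)),
    mean_visit_duration = vapply(histories, function(h)
      attr(h, "mean_visit_duration"), numeric(1)),
    total_time = vapply(histories, function(h) attr(h, "total_time"),
                        numeric(1)),
    extent_radius = vapply(seq_along(comps), function(k) {
      m <- comps[[k]]
      max(sqrt((traj$x[m] - traj$x[reps[k]])^2 +
               (traj$y[m] - traj$y[reps[k]])^2))
    }, numeric(1)))
  places$single_visit <- places$n_revisits == 1L
  places$oversized <- places$extent_radius > 2 * r
  keep <- if (drop_single_visit) !places$single_visit else
    rep(TRUE, nrow(places))
  places <- places[keep, , drop = FALSE]
  places$place <- seq_len(nrow(places))
  rownames(places) <- NULL
  out <- list(places = places, members = comps[keep],
              histories = histories[keep], r = r, criterion = criterion,
              threshold = filt$threshold, n_survivors = length(filt$indices))
  class(out) <- "ars_places"
  out
}

#' Between-visit intervals of an ARS place
#'
#' Durations between consecutive visits (exit of one to entry of the next)
#' of a revisit history or of a place's representative history. The shape
#' of this distribution hints at the knowledge the animal has of profitable
#' places: systematic (trap-lining) revisitation produces tightly clustered
#' intervals.
#'
#' @param x a `"revisit_history"` or `"ars_places"` object.
#' @param place place id (row of `x$places`) when `x` is `"ars_places"`.
#' @param ... unused.
#' @return Numeric vector of `n_visits - 1` intervals (empty for a single
#'   visit).
#' @export
between_visit_intervals <- function(x, ...) UseMethod("between_visit_intervals")

#' @rdname between_visit_intervals
#' @export
between_visit_intervals.revisit_history <- function(x, ...) {
  n <- nrow(x)
  if (n < 2) return(numeric(0))
  x$t_in[-1] - x$t_out[-n]
}

#' @rdname between_visit_intervals
#' @export
between_visit_intervals.ars_places <- function(x, place, ...) {
  stopifnot(place %in% x$places$place)
  between_visit_intervals(x$histories[[which(x$places$place == place)]])
}

#' @export
print.ars_places <- function(x, ...) {
  cat(sprintf(
    "ARS places at r = %g (criterion: %s, threshold %.4g, %d survivors)\n",
    x$r, x$criterion, x$threshold, x$n_survivors))
  cat(sprintf("  %d place(s)", nrow(x$places)))
  if (any(x$places$single_visit)) cat(";", sum(x$places$single_visit),
                                      "single-visit")
  if (any(x$places$oversized)) cat(";", sum(x$places$oversized),
                                   "flagged oversized")
  cat("\n")
  if (nrow(x$places)) print(x$places)
  invisible(x)
}

#' @export
summary.ars_places <- function(object, ...) {
  p <- object$places
  cat(sprintf("%d ARS place(s) at radius %g\n", nrow(p), object$r))
  if (nrow(p)) {
    cat(sprintf("  revisits: median %g (range %g-%g)\n",
                median(p$n_revisits), min(p$n_revisits), max(p$n_revisits)))
    cat(sprintf("  mean visit duration: median %.4g (range %.4g-%.4g)\n",
                median(p$mean_visit_duration), min(p$mean_visit_duration),
                max(p$mean_visit_duration)))
  }
  invisible(p)
}

#' @export
plot.ars_places <- function(x, traj = NULL, ...) {
  if (!is.null(traj)) {
    plot(traj$x, traj$y, type = "l", col = "grey70", asp = 1,
         xlab = "x", ylab = "y", ...)
  } else {
    plot(x$places$x, x$places$y, type = "n", asp = 1, xlab = "x",
         ylab = "y", ...)
  }
  for (m in x$members)
    if (!is.null(traj)) points(traj$x[m], traj$y[m], pch = 16, cex = 0.4,
                               col = "grey40")
  points(x$places$x, x$places$y, pch = 5, col = "blue", lwd = 2)
  invisible(x)
}

#' Export places and their visit segments as data frames
#'
#' @param x an `"ars_places"` object.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @return The `places` data frame; the per-place visit segments are
#'   attached as attribute `"segments"` (columns `place`, `t_in`, `t_out`,
#'   `duration`).
#' @export
as.data.frame.ars_places <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  segs <- do.call(rbind, lapply(seq_along(x$histories), function(k) {
    h <- as.data.frame(x$histories[[k]])
    if (!nrow(h)) return(NULL)
    data.frame(place = x$places$place[k], t_in = h$t_in, t_out = h$t_out,
               duration = h$duration)
  }))
  out <- x$places
  attr(out, "segments") <- segs
  out
}
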