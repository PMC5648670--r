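#' Build a trajectory from time-stamped planar coordinates
#'
#' A trajectory is an ordered sequence of fixes, each a `(t, x, y)` triple in
#' planar coordinates. Time is numeric and unit-agnostic (simulation steps,
#' seconds, ...); durations are always computed from timestamps, never from
#' fix counts, so irregular sampling intervals are handled throughout.
#'
#' @param t numeric vector of timestamps. Must be finite with no duplicates;
#'   fixes are sorted by `t`.
#' @param x,y numeric vectors of planar coordinates, same length as `t`.
#' @param crs_note optional free-text note on the provenance/unit of the
#'   coordinates (e.g. "grid cells", "UTM 36N metres").
#' @return An object of class `"trajectory"`: a data frame with columns
#'   `t`, `x`, `y` and attribute `crs_note`.
#' @examples
#' tr <- trajectory(t = 0:9, x = 0:9, y = rep(0, 10))
#' tr
#' @export
trajectory <- function(t, x, y, crs_note = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y))
    stop("t, x, y must have the same length", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("trajectory fixes must be finite (t, x, y)", call. = FALSE)
  ord <- order(t)
  t <- t[ord]; x <- x[ord]; y <- y[ord]
  dup <- which(diff(t) == 0)
  if (length(dup))
    stop("duplicate timestamps at sorted row(s) ", paste(dup + 1L, collapse = ", "),
         " (t = ", t[dup[1] + 1L], ")", call. = FALSE)
  out <- data.frame(t = t, x = x, y = y)
  class(out) <- c("trajectory", "data.frame")
  attr(out, "crs_note") <- crs_note
  out
}

#' Read a trajectory from a delimited text file
#'
#' Reads CSV/TSV relocation data with a header. Columns are selected through
#' a column mapping; Movebank-style names (`timestamp`, `location-long`,
#' `location-lat`) are auto-detected with a warning that coordinates are
#' treated as planar. Timestamps may be numeric or ISO-8601 date-times; the
#' latter are converted to seconds since the first fix.
#'
#' @param path path to a delimited text file with a header row.
#' @param t_col,x_col,y_col names of the time and coordinate columns.
#' @param sep field separator; `NULL` (default) picks `","` or `"\t"` from
#'   the file extension (`.tsv`/`.txt` gives tab).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, t_col = "t", x_col = "x", y_col = "y",
                            sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  cols <- c(t = t_col, x = x_col, y = y_col)
  if (!all(cols %in% names(df))) {
    mb <- c(t = "timestamp", x = "location-long", y = "location-lat")
    if (all(mb %in% names(df))) {
      warning("Movebank-style columns detected; longitude/latitude are ",
              "used as planar x/y coordinates", call. = FALSE)
      cols <- mb
    } else {
      missing_cols <- cols[!cols %in% names(df)]
      stop("column(s) not found in ", path, ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  tv <- df[[cols["t"]]]
  if (!is.numeric(tv)) {
    tt <- as.POSIXct(tv, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    if (anyNA(tt))
      stop("unparseable timestamp at row ", which(is.na(tt))[1], call. = FALSE)
    tv <- as.numeric(tt) - as.numeric(min(tt))
  }
  trajectory(tv, df[[cols["x"]]], df[[cols["y"]]],
             crs_note = paste0("read from ", basename(path)))
}

#' Write a trajectory to CSV with a JSON provenance sidecar
#'
#' @param traj a [trajectory()].
#' @param path output CSV path. A sidecar `<path>.json` recording the source
#'   note and resample factor is written alongside unless `sidecar = FALSE`.
#' @param sidecar write the JSON sidecar?
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (sidecar) {
    meta <- list(crs_note = attr(traj, "crs_note"),
                 resample_factor = attr(traj, "resample_factor"),
                 n_fixes = nrow(traj))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Thin a trajectory by keeping every k-th fix
#'
#' Keeps fixes at indices 1, 1+k, 1+2k, ... Original timestamps are retained,
#' so the typical inter-fix duration becomes k times the original; this mimics
#' the coarser sampling of a GPS device relative to the underlying path.
#'
#' @param traj a [trajectory()].
#' @param k positive integer thinning factor; `k = 1` returns the trajectory
#'   unchanged.
#' @return A [trajectory()] with `ceiling(nrow(traj) / k)` fixes.
#' @examples
#' tr <- trajectory(0:99, 0:99, rep(0, 100))
#' nrow(resample_trajectory(tr, 10))
#' @export
resample_trajectory <- function(traj, k) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a single integer >= 1", call. = FALSE)
  keep <- seq(1L, nrow(traj), by = as.integer(k))
  out <- trajectory(traj$t[keep], traj$x[keep], traj$y[keep],
                    crs_note = attr(traj, "crs_note"))
  prev <- attr(traj, "resample_factor")
  attr(out, "resample_factor") <- if (is.null(prev)) k else prev * k
  out
}

#' Earliest crossing of a circle by an interpolated path segment
#'
#' Positions (and hence times) are interpolated linearly between the two
#' fixes. Inside-ness is strict: a point at distance exactly `r` from the
#' center is outside the circle. Returns the earliest time in `(a["t"],
#' b["t"]]` at which the segment meets the circle boundary, or `NA` if it
#' never does.
#'
#' @param a,b named numeric vectors `c(t=, x=, y=)` with `a["t"] < b["t"]`.
#' @param center numeric length-2 circle center `(x, y)`.
#' @param r circle radius, `> 0`.
#' @return Crossing time (numeric scalar) or `NA_real_`.
#' @examples
#' circle_crossing_time(c(t = 0, x = 0, y = 0), c(t = 2, x = 4, y = 0),
#'                      center = c(0, 0), r = 2)  # 1
#' @export
circle_crossing_time <- function(a, b, center, r) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0)
    stop("r must be a single positive number", call. = FALSE)
  if (a[["t"]] >= b[["t"]]) stop("a must precede b in time", call. = FALSE)
  ux <- a[["x"]] - center[1]; uy <- a[["y"]] - center[2]
  dx <- b[["x"]] - a[["x"]]; dy <- b[["y"]] - a[["y"]]
  A <- dx * dx + dy * dy
  B <- ux * dx + uy * dy
  C <- ux * ux + uy * uy - r * r
  if (A == 0) return(NA_real_)  # no spatial motion
  disc <- B * B - A * C
  if (disc < 0) return(NA_real_)
  sq <- sqrt(disc)
  roots <- sort(c((-B - sq) / A, (-B + sq) / A))
  s <- roots[roots > 1e-12 & roots <= 1]
  if (!length(s)) return(NA_real_)
  a[["t"]] + s[1] * (b[["t"]] - a[["t"]])
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d fixes, t in [%g, %g]\n", nrow(x),
              x$t[1], x$t[nrow(x)]))
  note <- attr(x, "crs_note")
  if (!is.null(note)) cat("  coordinates:", note, "\n")
  k <- attr(x, "resample_factor")
  if (!is.null(k)) cat("  resampled 1-in-", k, "\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., asp = 1, type = "l") {
  plot(x$x, x$y, type = type, asp = asp, xlab = "x", ylab = "y", ...)
  invisible(x)
}

# median step length; used for default radius grids
median_step <- function(traj) {
  stats::median(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}
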