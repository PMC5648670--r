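# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form crossing solution: state changes are located on a
# dense re-discretization of the path and refined by bisection on the
# linearly interpolated position function.

# linear interpolation of position at arbitrary times
interp_xy <- function(traj, tt) {
  list(x = stats::approx(traj$t, traj$x, xout = tt)$y,
       y = stats::approx(traj$t, traj$y, xout = tt)$y)
}

dist_at <- function(traj, tt, center) {
  p <- interp_xy(traj, tt)
  sqrt((p$x - center[1])^2 + (p$y - center[2])^2)
}

# bisection for dist(t) == r on [lo, hi], where the sign of (dist - r)
# differs at the ends
bisect_crossing <- function(traj, center, r, lo, hi, tol = 1e-9) {
  a <- min(lo, hi); b <- max(lo, hi)
  fa <- dist_at(traj, a, center) - r
  for (i in 1:200) {
    mid <- (a + b) / 2
    if (b - a < tol) break
    fm <- dist_at(traj, mid, center) - r
    if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
  }
  (a + b) / 2
}

# dense times over the fix intervals spanned by indices i1..i2 (k points per
# inter-fix segment, endpoints included)
dense_times <- function(traj, i1, i2, k = 1000) {
  unlist(lapply(seq(i1, i2 - 1), function(j)
    seq(traj$t[j], traj$t[j + 1], length.out = k + 1)[-(k + 1)]),
    use.names = FALSE)
}

# oracle first-passage time: scan densely from fix i until the first sample
# at distance >= r, then refine the crossing by bisection
oracle_fpt <- function(traj, i, r, direction = "forward", k = 1000) {
  n <- nrow(traj)
  center <- c(traj$x[i], traj$y[i])
  if (direction == "forward") {
    if (i == n) return(list(duration = 0, censored = TRUE))
    tt <- c(dense_times(traj, i, n, k), traj$t[n])
  } else {
    if (i == 1) return(list(duration = 0, censored = TRUE))
    tt <- rev(c(dense_times(traj, 1, i, k), traj$t[i]))
  }
  d <- dist_at(traj, tt, center)
  out <- which(d >= r)
  if (!length(out))
    return(list(duration = abs(tt[length(tt)] - traj$t[i]), censored = TRUE))
  j <- out[1]
  tc <- bisect_crossing(traj, center, r, tt[j - 1], tt[j])
  list(duration = abs(tc - traj$t[i]), censored = FALSE)
}

# oracle visit segments: maximal inside intervals of the whole path for one
# circle, located on the dense grid and refined by bisection
oracle_segments <- function(traj, center, r, k = 1000) {
  n <- nrow(traj)
  tt <- c(dense_times(traj, 1, n, k), traj$t[n])
  inside <- dist_at(traj, tt, center) < r
  rl <- rle(inside)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  segs <- data.frame(t_in = numeric(0), t_out = numeric(0))
  for (j in seq_along(rl$values)) {
    if (!rl$values[j]) next
    t_in <- if (starts[j] == 1) tt[1] else
      bisect_crossing(traj, center, r, tt[starts[j] - 1], tt[starts[j]])
    t_out <- if (ends[j] == length(tt)) tt[length(tt)] else
      bisect_crossing(traj, center, r, tt[ends[j]], tt[ends[j] + 1])
    segs <- rbind(segs, data.frame(t_in = t_in, t_out = t_out))
  }
  segs
}

# union-find partition oracle for connected components
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find_root(as.integer(edges[e, 1]))
      b <- find_root(as.integer(edges[e, 2]))
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), function(i) as.integer(find_root(i)),
                  integer(1))
  unname(split(seq_len(n), match(roots, unique(roots))))
}

# random meandering test path: correlated walk with variable speed, so
# circles are entered and left repeatedly
random_path <- function(n = 200, seed = 1, v = 0.4) {
  set.seed(seed)
  ang <- cumsum(rnorm(n - 1, 0, sqrt(v)))
  step <- runif(n - 1, 0.2, 1.8)
  trajectory(t = seq_len(n) - 1,
             x = c(0, cumsum(step * cos(ang))),
             y = c(0, cumsum(step * sin(ang))))
}

# scripted path commuting between patch centres: `visits` dwell bouts at
# each centre in alternation, fast straight travel in between, with an
# excursion far from the next centre before every approach so that
# consecutive visits to the same centre leave its circle in between
make_commute_path <- function(centers, visits = 3, dwell = 30,
                              travel_step = 15, jitter_r = 1.5,
                              excursion = 120, seed = 99) {
  set.seed(seed)
  pos <- matrix(c(-200, -200), ncol = 2)  # start far away
  leg_to <- function(from, to) {
    gap <- sqrt(sum((to - from)^2))
    nsteps <- max(2, ceiling(gap / travel_step))
    cbind(seq(from[1], to[1], length.out = nsteps + 1),
          seq(from[2], to[2], length.out = nsteps + 1))[-1, , drop = FALSE]
  }
  for (v in seq_len(visits)) {
    for (ci in seq_along(centers)) {
      cc <- centers[[ci]]
      phi <- runif(1, -pi, pi)
      waypoint <- cc + excursion * c(cos(phi), sin(phi))
      pos <- rbind(pos, leg_to(pos[nrow(pos), ], waypoint))
      pos <- rbind(pos, leg_to(pos[nrow(pos), ], cc))
      a <- runif(dwell, -pi, pi)
      rad <- runif(dwell, 0, jitter_r)
      pos <- rbind(pos, cbind(cc[1] + rad * cos(a), cc[2] + rad * sin(a)))
    }
  }
  pos <- rbind(pos, c(500, 500))  # leave for good
  trajectory(t = seq_len(nrow(pos)) - 1, x = pos[, 1], y = pos[, 2])
}
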