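#' Generate a resource map
#'
#' Builds the food landscape a simulated forager moves over: a square grid
#' of `grid_size` x `grid_size` cells holding point food items in one of
#' three spatial structures.
#'
#' * `"scattered"` — `n_items` items placed uniformly at random.
#' * `"patchy"` — `n_patches` patch centers placed uniformly; each patch
#'   receives `round(N(items_per_patch_mean, items_per_patch_sd))` items
#'   (minimum 1), each at a distance `|N(item_distance_mean,
#'   item_distance_sd)|` from the patch center in a uniformly random
#'   direction.
#' * `"hierarchical"` — `n_clumps` clump centers placed uniformly; patches
#'   are placed around clump centers exactly as items are placed around
#'   patch centers (counts `patches_per_clump_*`, distances
#'   `patch_distance_*`), then items fill each patch as in `"patchy"`.
#'
#' Items falling outside the grid are clipped to its edge. Consumed items
#' re-emerge `regeneration_delay` steps after being exploited. Patch and
#' clump centers are retained as ground truth for validation studies.
#'
#' @param kind `"scattered"`, `"patchy"` or `"hierarchical"`.
#' @param grid_size cells per side.
#' @param n_items number of items (scattered maps).
#' @param n_patches number of patches (patchy maps).
#' @param items_per_patch_mean,items_per_patch_sd normal parameters for the
#'   per-patch item count.
#' @param item_distance_mean,item_distance_sd normal parameters for the
#'   item-to-patch-center distance (cells).
#' @param n_clumps number of clumps (hierarchical maps).
#' @param patches_per_clump_mean,patches_per_clump_sd normal parameters for
#'   the per-clump patch count.
#' @param patch_distance_mean,patch_distance_sd normal parameters for the
#'   patch-to-clump-center distance (cells).
#' @param regeneration_delay steps until an exploited item re-emerges.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return An object of class `"resource_map"`: a list with `items` (data
#'   frame `x`, `y`, `patch_id`), `patch_centers`, `clump_centers` (data
#'   frames or `NULL`), `kind`, `grid_size`, `regeneration_delay`.
#' @export
generate_resource_map <- function(kind = c("patchy", "scattered",
                                           "hierarchical"),
                                  grid_size = 1000,
                                  n_items = 500,
                                  n_patches = 30,
                                  items_per_patch_mean = 20,
                                  items_per_patch_sd = 5,
                                  item_distance_mean = 10,
                                  item_distance_sd = 3,
                                  n_clumps = 5,
                                  patches_per_clump_mean = 5,
                                  patches_per_clump_sd = 1,
                                  patch_distance_mean = 160,
                                  patch_distance_sd = 40,
                                  regeneration_delay = 10000,
                                  seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(grid_size >= 1, regeneration_delay >= 0)
  if (!is.null(seed)) set.seed(seed)
  clump_centers <- NULL
  patch_centers <- NULL
  if (kind == "scattered") {
    stopifnot(n_items >= 1)
    items <- data.frame(x = runif(n_items, 0, grid_size),
                        y = runif(n_items, 0, grid_size),
                        patch_id = NA_integer_)
  } else {
    if (kind == "patchy") {
      stopifnot(n_patches >= 1)
      patch_centers <- data.frame(patch_id = seq_len(n_patches),
                                  x = runif(n_patches, 0, grid_size),
                                  y = runif(n_patches, 0, grid_size),
                                  clump_id = NA_integer_)
    } else {
      stopifnot(n_clumps >= 1)
      clump_centers <- data.frame(clump_id = seq_len(n_clumps),
                                  x = runif(n_clumps, 0, grid_size),
                                  y = runif(n_clumps, 0, grid_size))
      pc <- lapply(seq_len(n_clumps), function(ci) {
        k <- clamped_count(rnorm(1, patches_per_clump_mean,
                                 patches_per_clump_sd))
        d <- abs(rnorm(k, patch_distance_mean, patch_distance_sd))
        a <- runif(k, -pi, pi)
        data.frame(x = clump_centers$x[ci] + d * cos(a),
                   y = clump_centers$y[ci] + d * sin(a),
                   clump_id = ci)
      })
      pc <- do.call(rbind, pc)
      patch_centers <- data.frame(patch_id = seq_len(nrow(pc)),
                                  x = pmin(pmax(pc$x, 0), grid_size),
                                  y = pmin(pmax(pc$y, 0), grid_size),
                                  clump_id = pc$clump_id)
    }
    items <- do.call(rbind, lapply(seq_len(nrow(patch_centers)),
                                   function(pi_) {
      k <- clamped_count(rnorm(1, items_per_patch_mean, items_per_patch_sd))
      d <- abs(rnorm(k, item_distance_mean, item_distance_sd))
      a <- runif(k, -pi, pi)
      data.frame(x = patch_centers$x[pi_] + d * cos(a),
                 y = patch_centers$y[pi_] + d * sin(a),
                 patch_id = patch_centers$patch_id[pi_])
    }))
  }
  items$x <- pmin(pmax(items$x, 0), grid_size)
  items$y <- pmin(pmax(items$y, 0), grid_size)
  rownames(items) <- NULL
  out <- list(items = items, patch_centers = patch_centers,
              clump_centers = clump_centers, kind = kind,
              grid_size = grid_size,
              regeneration_delay = regeneration_delay)
  class(out) <- "resource_map"
  out
}

clamped_count <- function(x) {
  k <- round(x)
  if (k < 1) {
    warning("drawn count below 1 clamped to 1", call. = FALSE)
    k <- 1
  }
  as.integer(k)
}

#' Forager behavioural configuration
#'
#' Parameters of the biased correlated random walk and of the three
#' foraging strategies. The walk draws each heading from a normal
#' distribution centred on the previous heading with variance
#' `v = v_b * (1 - p * cos(heading - omega))` under attraction to the
#' bearing `omega` of a target (plus sign for repulsion); see
#' [turning_variance()]. Step length is one cell per step.
#'
#' Strategies:
#' * `"simple_search"` — always exploring (`p = 0`), consuming items that
#'   come within `perceptual_range`.
#' * `"simple_ars"` — explores until an item is consumed, then performs
#'   area-restricted search: an attraction walk (variance base `v_b_ars`,
#'   attraction `p`) anchored on the running centroid of the bout's
#'   consumption locations (the forager's patch-centre estimate, updated on
#'   every find), so successive search loops sweep the whole patch. Reverts
#'   to exploration once `giving_up_time_patch` steps pass without a find.
#' * `"hierarchical_ars"` — as `"simple_ars"` within a patch; on giving up
#'   it searches the patch's neighbourhood with repeated forays radiating
#'   away from the departed patch (centroid of that bout's consumption
#'   locations) and back toward it, each outbound leg `foray_growth` times
#'   longer than the last, until a new item is found or
#'   `giving_up_time_clump` steps pass without one.
#'
#' @param strategy one of `"simple_search"`, `"simple_ars"`,
#'   `"hierarchical_ars"`.
#' @param v_b basic turning variance (radians^2) while exploring and during
#'   forays.
#' @param v_b_ars basic turning variance during ARS; larger than `v_b`, so
#'   search within a patch is tortuous while exploration is nearly straight.
#' @param p attraction level in `[0, 1]` used during ARS.
#' @param p_foray attraction/repulsion level during foray legs.
#' @param perceptual_range distance (cells) within which items are detected
#'   and consumed.
#' @param giving_up_time_patch steps without a find before abandoning a
#'   patch.
#' @param giving_up_time_clump steps without a find before abandoning the
#'   foray search around a departed patch (hierarchical strategy only).
#' @param foray_leg0 initial outbound foray leg length (cells).
#' @param foray_growth multiplicative growth of successive foray legs.
#' @param rest_prob per-step probability of starting a rest bout while
#'   exploring (`0` disables resting). Rest bouts leave the forager
#'   stationary; they produce the elevated residence-time variance at the
#'   smallest radii that stationary stops cause in real paths.
#' @param rest_mean mean rest-bout length (steps, geometric).
#' @param n_steps number of simulation steps.
#' @return A list of class `"forager_config"`.
#' @export
forager_config <- function(strategy = c("simple_ars", "simple_search",
                                        "hierarchical_ars"),
                           v_b = 0.03, v_b_ars = 0.5, p = 0.8,
                           p_foray = 0.8, perceptual_range = 2,
                           giving_up_time_patch = 250,
                           giving_up_time_clump = 1500,
                           foray_leg0 = 60, foray_growth = 1.3,
                           rest_prob = 0.004, rest_mean = 30,
                           n_steps = 60000) {
  strategy <- match.arg(strategy)
  stopifnot(v_b > 0, v_b_ars > 0, p >= 0, p <= 1, p_foray >= 0,
            p_foray <= 1, perceptual_range >= 0, giving_up_time_patch >= 0,
            giving_up_time_clump >= 0, foray_leg0 > 0, foray_growth >= 1,
            rest_prob >= 0, rest_prob <= 1, rest_mean >= 1, n_steps >= 1)
  out <- list(strategy = strategy, v_b = v_b, v_b_ars = v_b_ars, p = p,
              p_foray = p_foray, perceptual_range = perceptual_range,
              giving_up_time_patch = giving_up_time_patch,
              giving_up_time_clump = giving_up_time_clump,
              foray_leg0 = foray_leg0, foray_growth = foray_growth,
              rest_prob = rest_prob, rest_mean = rest_mean,
              n_steps = as.integer(n_steps))
  class(out) <- "forager_config"
  out
}

#' Turning variance of the biased correlated random walk
#'
#' `v = v_b * (1 - p * cos(theta_prev - omega))` under attraction;
#' `v = v_b * (1 + p * cos(theta_prev - omega))` under repulsion. With
#' `p = 0` the walk is an unbiased correlated random walk of constant
#' variance `v_b`; with `p = 1` and the heading aligned with the target the
#' variance vanishes (complete attraction locks the heading on the target),
#' and heading directly away gives the maximal reorientation variance
#' `2 * v_b`.
#'
#' @param theta_prev previous heading (radians).
#' @param omega bearing of the target location (radians).
#' @param v_b basic variance (radians^2), `> 0`.
#' @param p attraction level in `[0, 1]`.
#' @param bias_sign `"attraction"` or `"repulsion"`.
#' @return The turning variance (never negative).
#' @examples
#' turning_variance(0.3, 1.2, v_b = 0.1, p = 0)        # 0.1
#' turning_variance(0.7, 0.7, v_b = 0.1, p = 1)        # 0: locked on target
#' @export
turning_variance <- function(theta_prev, omega, v_b, p,
                             bias_sign = c("attraction", "repulsion")) {
  bias_sign <- match.arg(bias_sign)
  if (!is.numeric(p) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  stopifnot(v_b > 0)
  s <- if (bias_sign == "attraction") -1 else 1
  pmax(v_b * (1 + s * p * cos(theta_prev - omega)), 0)
}

#' Simulate a foraging walk on a resource map
#'
#' Runs `config$n_steps` steps of the biased correlated random walk with
#' the chosen strategy's mode switching (see [forager_config()]),
#' consuming items within perceptual range and letting them re-emerge
#' after the map's regeneration delay. Walls reflect. All randomness flows
#' through R's RNG, so results are fully reproducible from `set.seed()` or
#' the `seed` argument.
#'
#' @param map a [generate_resource_map()] object.
#' @param config a [forager_config()].
#' @param seed optional integer seed.
#' @return An object of class `"forager_sim"`: a list with
#'   * `trajectory` — a [trajectory()] of the positions at t = 1..n_steps;
#'   * `modes` — factor (`explore`, `ars`, `foray_out`, `foray_back`) per
#'     step;
#'   * `resting` — logical per step, `TRUE` during rest bouts (the mode
#'     stays `explore` while resting);
#'   * `events` — data frame of consumption events (`t`, `item`,
#'     `patch_id`, `x`, `y`);
#'   * `episodes` — data frame of ARS episodes (`patch_id`, `t_start`,
#'     `t_end`), a patch's id being the one most consumed from during the
#'     episode; episodes are maximal runs of the `ars` mode;
#'   * `map_final` — the map with end-state item availability.
#' @export
simulate_forager <- function(map, config, seed = NULL) {
  stopifnot(inherits(map, "resource_map"), inherits(config, "forager_config"))
  if (!is.null(seed)) set.seed(seed)
  strat <- match(config$strategy,
                 c("simple_search", "simple_ars", "hierarchical_ars")) - 1L
  res <- cpp_simulate(as.matrix(map$items[, c("x", "y")]),
                      as.integer(map$items$patch_id),
                      map$grid_size, config$n_steps, strat,
                      config$v_b, config$v_b_ars, config$p, config$p_foray,
                      config$perceptual_range, config$giving_up_time_patch,
                      config$giving_up_time_clump, map$regeneration_delay,
                      config$foray_leg0, config$foray_growth,
                      config$rest_prob, config$rest_mean)
  traj <- trajectory(seq_len(config$n_steps), res$x, res$y,
                     crs_note = "simulated grid cells")
  mode_levels <- c("explore", "ars", "foray_out", "foray_back")
  modes <- factor(mode_levels[res$mode + 1L], levels = mode_levels)
  events <- data.frame(t = res$event_t, item = res$event_item,
                       patch_id = map$items$patch_id[res$event_item],
                       x = map$items$x[res$event_item],
                       y = map$items$y[res$event_item])
  map_final <- map
  map_final$items$available <- res$available
  map_final$items$regrow_at <- res$regrow_at
  out <- list(trajectory = traj, modes = modes, resting = res$resting,
              events = events, episodes = ars_episodes(modes, events),
              map_final = map_final, config = config)
  class(out) <- "forager_sim"
  out
}

# maximal runs of the ars mode, labelled with the modal consumed patch
ars_episodes <- function(modes, events) {
  is_ars <- modes == "ars"
  if (!any(is_ars))
    return(data.frame(patch_id = integer(0), t_start = numeric(0),
                      t_end = numeric(0)))
  rl <- rle(as.vector(is_ars))
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  keep <- which(rl$values)
  ep <- data.frame(t_start = starts[keep], t_end = ends[keep])
  ep$patch_id <- vapply(seq_len(nrow(ep)), function(k) {
    pid <- events$patch_id[events$t >= ep$t_start[k] &
                           events$t <= ep$t_end[k]]
    pid <- pid[!is.na(pid)]
    if (!length(pid)) return(NA_integer_)
    as.integer(names(sort(table(pid), decreasing = TRUE))[1])
  }, integer(1))
  ep[, c("patch_id", "t_start", "t_end")]
}

#' @export
print.resource_map <- function(x, ...) {
  cat(sprintf("Resource map (%s): %d items on a %g x %g grid\n", x$kind,
              nrow(x$items), x$grid_size, x$grid_size))
  if (!is.null(x$patch_centers))
    cat(" ", nrow(x$patch_centers), "patches")
  if (!is.null(x$clump_centers))
    cat(",", nrow(x$clump_centers), "clumps")
  if (!is.null(x$patch_centers)) cat("\n")
  invisible(x)
}

#' @export
plot.resource_map <- function(x, ...) {
  plot(x$items$x, x$items$y, pch = 16, cex = 0.4, col = "grey50", asp = 1,
       xlim = c(0, x$grid_size), ylim = c(0, x$grid_size),
       xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' @export
print.forager_sim <- function(x, ...) {
  cat(sprintf("Forager simulation: %s, %d steps\n", x$config$strategy,
              x$config$n_steps))
  cat(sprintf("  %d consumption events, %d ARS episodes\n",
              nrow(x$events), nrow(x$episodes)))
  tab <- table(x$modes)
  cat("  steps by mode:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.forager_sim <- function(x, ...) {
  plot(x$map_final$items$x, x$map_final$items$y, pch = 16, cex = 0.3,
       col = "grey60", asp = 1, xlab = "x", ylab = "y", ...)
  lines(x$trajectory$x, x$trajectory$y, col = "red", lwd = 0.5)
  invisible(x)
}
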