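test_that("resource maps realise their configured structure", {
  m <- generate_resource_map("scattered", n_items = 100, seed = 1)
  expect_equal(nrow(m$items), 100)
  expect_true(all(m$items$x >= 0 & m$items$x <= 1000))
  # degenerate distance sd places every item exactly at the mean distance
  m2 <- generate_resource_map("patchy", n_patches = 5, item_distance_sd = 0,
                              grid_size = 10000, seed = 2)
  d <- sqrt((m2$items$x - m2$patch_centers$x[m2$items$patch_id])^2 +
            (m2$items$y - m2$patch_centers$y[m2$items$patch_id])^2)
  expect_equal(d, rep(10, length(d)), tolerance = 1e-9)
  # hierarchical maps cluster patches around their own clump centres
  m3 <- generate_resource_map("hierarchical", seed = 3)
  pc <- m3$patch_centers; cl <- m3$clump_centers
  own <- sqrt((pc$x - cl$x[pc$clump_id])^2 + (pc$y - cl$y[pc$clump_id])^2)
  other <- vapply(seq_len(nrow(pc)), function(i) {
    d <- sqrt((pc$x[i] - cl$x)^2 + (pc$y[i] - cl$y)^2)
    min(d[-pc$clump_id[i]])
  }, numeric(1))
  expect_lt(mean(own), mean(other))
})

test_that("scattered item placement is spatially uniform", {
  # chi-square on a 4 x 4 binning across seeds; uniformity should rarely be
  # rejected at the 1% level
  rejections <- 0
  for (seed in 1:40) {
    m <- generate_resource_map("scattered", n_items = 160, seed = seed)
    bins <- table(factor(findInterval(m$items$x, seq(0, 1000, 250),
                                      rightmost.closed = TRUE), levels = 1:4),
                  factor(findInterval(m$items$y, seq(0, 1000, 250),
                                      rightmost.closed = TRUE), levels = 1:4))
    p <- suppressWarnings(chisq.test(as.vector(bins),
                                     p = rep(1 / 16, 16))$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)  # >= 95% of runs unrejected
})

test_that("the turning-variance law reproduces its limiting cases", {
  # no attraction: basic variance regardless of headings
  expect_equal(turning_variance(0.3, 1.2, v_b = 0.1, p = 0), 0.1)
  expect_equal(turning_variance(-2, 3, v_b = 0.5, p = 0), 0.5)
  # complete attraction, aligned: variance vanishes (locked on target)
  expect_equal(turning_variance(0.7, 0.7, v_b = 0.1, p = 1), 0)
  # complete attraction, heading directly away: maximal reorientation 2 v_b
  expect_equal(turning_variance(pi, 0, v_b = 0.1, p = 1), 0.2)
  # repulsion flips the sign
  expect_equal(turning_variance(0, 0, v_b = 0.1, p = 1,
                                bias_sign = "repulsion"), 0.2)
  expect_error(turning_variance(0, 0, v_b = 0.1, p = 1.5), "p")
})

test_that("simulations are reproducible and conserve items and step length", {
  m <- generate_resource_map("patchy", seed = 7)
  cfg <- forager_config("simple_ars", n_steps = 3000)
  s1 <- simulate_forager(m, cfg, seed = 42)
  s2 <- simulate_forager(m, cfg, seed = 42)
  expect_identical(s1$trajectory$x, s2$trajectory$x)
  expect_identical(s1$trajectory$y, s2$trajectory$y)
  expect_identical(s1$events, s2$events)
  # conservation: every unavailable item is pending regrowth, none other
  fin <- s1$map_final$items
  expect_true(all(is.na(fin$regrow_at[fin$available])))
  expect_true(all(!is.na(fin$regrow_at[!fin$available])))
  # displacement is one cell per moving step (away from reflecting walls),
  # zero during rest bouts
  dx <- diff(s1$trajectory$x); dy <- diff(s1$trajectory$y)
  step_len <- sqrt(dx^2 + dy^2)
  moving <- !s1$resting[-1]
  inside <- s1$trajectory$x[-1] > 1 & s1$trajectory$x[-1] < 999 &
            s1$trajectory$y[-1] > 1 & s1$trajectory$y[-1] < 999
  expect_true(all(abs(step_len[moving & inside] - 1) < 1e-9))
  expect_true(all(step_len[!moving] < 1e-12))
})

test_that("p = 0 walks reproduce the basic turning variance empirically", {
  m <- generate_resource_map("scattered", n_items = 1, seed = 1)
  for (vb in c(0.1, 0.3)) {
    cfg <- forager_config("simple_search", v_b = vb, rest_prob = 0,
                          n_steps = 1e5, perceptual_range = 0)
    sim <- simulate_forager(m, cfg, seed = 9)
    dx <- diff(sim$trajectory$x); dy <- diff(sim$trajectory$y)
    heading <- atan2(dy, dx)
    turn <- diff(heading)
    turn <- ((turn + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]
    # drop steps affected by wall reflection
    ok <- sim$trajectory$x[-c(1, 2)] > 2 & sim$trajectory$x[-c(1, 2)] < 998 &
          sim$trajectory$y[-c(1, 2)] > 2 & sim$trajectory$y[-c(1, 2)] < 998
    expect_equal(var(turn[ok]), vb, tolerance = 0.05 * vb + 0.002)
  }
})

test_that("items inside perceptual range are consumed on arrival", {
  m <- generate_resource_map("scattered", n_items = 400, seed = 5)
  cfg <- forager_config("simple_search", perceptual_range = 2, n_steps = 20000)
  sim <- simulate_forager(m, cfg, seed = 11)
  expect_gt(nrow(sim$events), 0)
  # every event's item was within perceptual range of that step's position
  d <- sqrt((sim$events$x - sim$trajectory$x[sim$events$t])^2 +
            (sim$events$y - sim$trajectory$y[sim$events$t])^2)
  expect_true(all(d <= cfg$perceptual_range + 1e-9))
})

test_that("strategy mode logic matches its triggers", {
  m <- generate_resource_map("patchy", seed = 13)
  # simple search never enters ARS
  s0 <- simulate_forager(m, forager_config("simple_search", n_steps = 20000),
                         seed = 3)
  expect_equal(nrow(s0$episodes), 0)
  expect_true(all(s0$modes == "explore"))
  # simple ARS: every episode starts with a consumption on its first step
  s1 <- simulate_forager(m, forager_config("simple_ars"), seed = 3)
  expect_gt(nrow(s1$episodes), 0)
  starts <- s1$episodes$t_start
  expect_true(all(starts %in% s1$events$t))
  # giving-up: the gap from an episode's last find to its end equals the
  # giving-up time
  gaps <- vapply(seq_len(nrow(s1$episodes)), function(k) {
    ev <- s1$events$t[s1$events$t >= s1$episodes$t_start[k] &
                      s1$events$t <= s1$episodes$t_end[k]]
    s1$episodes$t_end[k] - max(ev)
  }, numeric(1))
  done <- s1$episodes$t_end < max(s1$trajectory$t)  # unfinished final bout
  expect_true(all(gaps[done] == forager_config("simple_ars")$giving_up_time_patch))
})

test_that("forays let hierarchical foragers find neighbouring patches", {
  # over several seeds, clump-level bouts should usually reach more than one
  # patch, which plain patch-ARS cannot do
  multi <- 0; total <- 0
  for (seed in 1:6) {
    m <- generate_resource_map("hierarchical", seed = seed)
    sim <- simulate_forager(m, forager_config("hierarchical_ars"),
                            seed = seed + 100)
    nonexp <- sim$modes != "explore"
    rl <- rle(as.vector(nonexp))
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    for (k in which(rl$values)) {
      pid <- sim$events$patch_id[sim$events$t >= starts[k] &
                                 sim$events$t <= ends[k]]
      pid <- unique(pid[!is.na(pid)])
      total <- total + 1
      if (length(pid) > 1) multi <- multi + 1
    }
    expect_true(any(sim$modes %in% c("foray_out", "foray_back")))
  }
  expect_gt(multi / total, 0.3)
})
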