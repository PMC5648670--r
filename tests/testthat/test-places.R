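test_that("filtering uses the max(mean, median) threshold, strictly greater", {
  s <- data.frame(fix = 1:5, mean_visit_duration = c(1, 1, 1, 1, 100))
  f <- filter_locations(s, "mean_visit_duration")
  expect_equal(f$threshold, 20.8)
  expect_equal(f$indices, 5L)
  # all-equal values leave nothing above the threshold
  s2 <- data.frame(fix = 1:4, total_time = rep(7, 4))
  expect_length(filter_locations(s2, "total_time")$indices, 0)
})

test_that("proximity edges follow the strict distance convention", {
  r <- 10
  tr <- trajectory(0:2, c(0, 0.9 * r, 0.9 * r + r), rep(0, 3))
  g <- build_proximity_graph(tr, 1:3, r)
  em <- igraph::as_edgelist(g)
  expect_equal(nrow(em), 1)  # only the pair at 0.9 r
  # a pair at exactly r gets no edge
  tr2 <- trajectory(0:1, c(0, r), c(0, 0))
  expect_equal(igraph::ecount(build_proximity_graph(tr2, 1:2, r)), 0)
})

test_that("random proximity graphs match a brute-force edge comparison", {
  set.seed(77)
  tr <- trajectory(0:49, runif(50, 0, 30), runif(50, 0, 30))
  r <- 6
  g <- build_proximity_graph(tr, 1:50, r)
  em <- igraph::as_edgelist(g)
  got <- sort(paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2])))
  want <- c()
  for (i in 1:49) for (j in (i + 1):50) {
    if (sqrt((tr$x[i] - tr$x[j])^2 + (tr$y[i] - tr$y[j])^2) < r)
      want <- c(want, paste(i, j))
  }
  expect_equal(got, sort(want))
})

test_that("connected components partition the survivors correctly", {
  # edgeless graph: all singletons
  tr <- trajectory(0:9, seq(0, 900, 100), rep(0, 10))
  g <- build_proximity_graph(tr, 1:10, 5)
  comps <- connected_components(g)
  expect_length(comps, 10)
  # chain a-b-c: one component through indirect connection
  tr2 <- trajectory(0:2, c(0, 4, 8), rep(0, 3))
  comps2 <- connected_components(build_proximity_graph(tr2, 1:3, 5))
  expect_equal(comps2, list(1:3))
})

test_that("components of random graphs match the union-find oracle", {
  for (seed in c(5, 6, 7)) {
    set.seed(seed)
    n <- 200
    tr <- trajectory(seq_len(n) - 1, runif(n, 0, 60), runif(n, 0, 60))
    r <- 5
    g <- build_proximity_graph(tr, seq_len(n), r)
    got <- connected_components(g)
    edges <- igraph::as_edgelist(g)
    want <- uf_components(n, edges)
    canon <- function(l) unname(l[order(vapply(l, min, numeric(1)))])
    expect_equal(canon(lapply(got, sort)), canon(lapply(want, sort)))
  }
})

test_that("long chains do not hit recursion limits", {
  n <- 10000
  tr <- trajectory(seq_len(n) - 1, seq_len(n), rep(0, n))
  g <- build_proximity_graph(tr, seq_len(n), 1.5)  # path graph
  comps <- connected_components(g)
  expect_length(comps, 1)
  expect_length(comps[[1]], n)
})

test_that("representatives maximise the criterion with earliest-index ties", {
  s <- data.frame(fix = c(3, 7, 12), mean_visit_duration = c(5, 9, 9))
  expect_equal(choose_representative(c(3, 7, 12), s), 7)
  expect_equal(choose_representative(12, s), 12)  # singleton forced
})

test_that("a commuting path yields one place per patch with the scripted visit count", {
  tr <- make_commute_path(list(c(0, 0), c(150, 0)), visits = 3, dwell = 40)
  res <- identify_ars_places(tr, r = 8)
  expect_equal(nrow(res$places), 2)
  expect_equal(sort(res$places$n_revisits), c(3, 3))
  expect_false(any(res$places$oversized))
  # centres recovered near the planted patch centres
  d1 <- min(sqrt(res$places$x^2 + res$places$y^2))
  d2 <- min(sqrt((res$places$x - 150)^2 + res$places$y^2))
  expect_lt(d1, 8)
  expect_lt(d2, 8)
})

test_that("a single long stationary stop is flagged as a single-visit place", {
  set.seed(12)
  stop_pos <- cbind(60 + runif(80, -0.5, 0.5), runif(80, -0.5, 0.5))
  pos <- rbind(cbind(seq(-100, 55, 5), 0), stop_pos, cbind(seq(65, 220, 5), 0))
  tr <- trajectory(seq_len(nrow(pos)) - 1, pos[, 1], pos[, 2])
  res <- identify_ars_places(tr, r = 6, criterion = "mean_visit_duration")
  expect_equal(nrow(res$places), 1)
  expect_true(res$places$single_visit[1])
  expect_equal(res$places$n_revisits[1], 1L)
  # drop_single_visit removes the stopping-site artifact
  res2 <- identify_ars_places(tr, r = 6, drop_single_visit = TRUE)
  expect_equal(nrow(res2$places), 0)
})

test_that("total-time filtering overlooks places with few long visits", {
  # two ARS patches visited once or twice for long bouts, plus one site
  # revisited many times briefly: the mean-duration criterion keeps the ARS
  # patches and filters the busy site, while the total-time criterion is
  # dominated by the busy site and misses the few-visit patches
  trA1 <- make_commute_path(list(c(0, 0)), visits = 2, dwell = 60, seed = 5)
  trA2 <- make_commute_path(list(c(300, 0)), visits = 1, dwell = 100, seed = 6)
  trB <- make_commute_path(list(c(600, 0)), visits = 30, dwell = 15, seed = 7)
  pos <- rbind(as.matrix(as.data.frame(trA1)[, c("x", "y")]),
               as.matrix(as.data.frame(trA2)[, c("x", "y")]),
               as.matrix(as.data.frame(trB)[, c("x", "y")]))
  tr <- trajectory(seq_len(nrow(pos)) - 1, pos[, 1], pos[, 2])
  by_mean <- identify_ars_places(tr, r = 8, criterion = "mean_visit_duration")
  by_total <- identify_ars_places(tr, r = 8, criterion = "total_time")
  expect_lt(nrow(by_total$places), nrow(by_mean$places))
  # the long-bout patches survive under the mean criterion
  expect_true(any(sqrt(by_mean$places$x^2 + by_mean$places$y^2) < 8))
  expect_true(any(sqrt((by_mean$places$x - 300)^2 + by_mean$places$y^2) < 8))
})

test_that("adjacent patches merge into one oversized-flagged component", {
  # two patches closer together than 2 r + their radii: the proximity graph
  # unites their surviving locations and the component extent exceeds 2 r
  r <- 5
  tr <- make_commute_path(list(c(0, 0), c(7, 0), c(14, 0), c(21, 0)),
                          visits = 3, dwell = 40, jitter_r = 5, seed = 8)
  res <- identify_ars_places(tr, r = r)
  expect_equal(nrow(res$places), 1)
  expect_true(res$places$oversized[1])
  # well-separated patches at the same radius stay distinct and unflagged
  tr2 <- make_commute_path(list(c(0, 0), c(200, 0)), visits = 3, dwell = 40,
                           jitter_r = 5, seed = 8)
  res2 <- identify_ars_places(tr2, r = r)
  expect_equal(nrow(res2$places), 2)
  expect_false(any(res2$places$oversized))
})

test_that("every survivor belongs to exactly one place", {
  tr <- make_commute_path(list(c(0, 0), c(120, 60), c(-80, 90)), visits = 2,
                          dwell = 30)
  res <- identify_ars_places(tr, r = 8)
  members <- unlist(res$members)
  expect_equal(length(members), length(unique(members)))
  expect_equal(length(members), res$n_survivors)
})

test_that("place statistics ignore far-away additions to the trajectory", {
  tr <- make_commute_path(list(c(0, 0), c(150, 0)), visits = 3, dwell = 40)
  res <- identify_ars_places(tr, r = 8)
  # append a distant excursion outside every circle of interest
  ext <- rbind(as.matrix(as.data.frame(tr)[, c("x", "y")]),
               cbind(seq(600, 900, 10), seq(600, 900, 10)))
  tr2 <- trajectory(seq_len(nrow(ext)) - 1, ext[, 1], ext[, 2])
  res2 <- identify_ars_places(tr2, r = 8)
  m1 <- res$places[order(res$places$x), "mean_visit_duration"]
  m2 <- res2$places[order(res2$places$x), "mean_visit_duration"]
  expect_equal(m1, m2, tolerance = 1e-9)
})

test_that("between-visit intervals report gaps between consecutive visits", {
  h <- data.frame(t_in = c(0, 50, 100), t_out = c(10, 70, 105),
                  duration = c(10, 20, 5), kind = c("focal", "forward", "forward"),
                  censored_start = FALSE, censored_end = FALSE)
  class(h) <- c("revisit_history", "data.frame")
  expect_equal(between_visit_intervals(h), c(40, 30))
  expect_length(between_visit_intervals(h[1, ]), 0)
})

test_that("a periodic return path yields near-constant between-visit intervals", {
  # trap-lining style: a fixed-length excursion away from the patch makes
  # the between-visit interval the same on every cycle
  set.seed(3)
  away_len <- 80
  pos <- matrix(numeric(0), ncol = 2)
  for (v in 1:5) {
    away <- cbind(seq(10, 10 * away_len, length.out = away_len), 50)
    dwell <- cbind(runif(20, -1, 1), runif(20, -1, 1))
    pos <- rbind(pos, dwell, away)
  }
  tr <- trajectory(seq_len(nrow(pos)) - 1, pos[, 1], pos[, 2])
  h <- revisit_history(tr, which.min(tr$x^2 + tr$y^2), r = 5)
  iv <- between_visit_intervals(h)
  expect_gte(length(iv), 3)
  expect_true(all(abs(iv - away_len) <= 3))  # constant period up to crossings
  expect_lt(max(iv) - min(iv), 3)
})
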