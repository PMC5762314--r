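test_that("parent outcome sampling honors death and survival semantics", {
  dist <- make_point_dist(c(0, 2), c(0, 1))
  # certain death: always the zero vector
  set.seed(1)
  out <- sample_parent_outcome(dist, make_death(1), "ALDHpos", n = 50)
  expect_true(all(out == 0))
  # no death, point mass (0,2): retention adds the parent's own unit
  kept <- sample_parent_outcome(dist, make_death(0), "ALDHpos", n = 10)
  expect_true(all(kept[, "ALDHpos"] == 1 & kept[, "ALDHneg"] == 2))
  literal <- sample_parent_outcome(dist, make_death(0), "ALDHpos", n = 10,
                                   literal_equation = TRUE)
  expect_true(all(literal[, "ALDHpos"] == 0 & literal[, "ALDHneg"] == 2))
  expect_error(sample_parent_outcome(dist, make_death(0), "nope"), "unknown cell type")
})

test_that("survival frequencies match the binomial law", {
  # all-zero histogram, g = 0.3: literal draws are always zero; with
  # retention the parent-only vector appears with survival probability 0.7
  dist <- make_point_dist(c(0, 0))
  death <- make_death(0.3)
  n <- 100000
  set.seed(99)
  lit <- sample_parent_outcome(dist, death, "ALDHpos", n = n,
                               literal_equation = TRUE)
  expect_true(all(lit == 0))
  ret <- sample_parent_outcome(dist, death, "ALDHpos", n = n)
  frac <- mean(ret[, "ALDHpos"] == 1)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(frac - 0.7), 3 * se)
})

test_that("a step preserves the column-sum identity and basic edge cases", {
  dist <- make_test_dist()
  empty <- population_state(c(ALDHpos = 0, ALDHneg = 0), two_types)
  res <- step_population(empty, dist, make_death(0))
  expect_equal(unname(res$state$counts), c(0, 0))
  expect_equal(unname(res$realization), matrix(0, 2, 2))

  # certain death: extinction in one step from any counts
  alive <- population_state(c(ALDHpos = 40, ALDHneg = 60), two_types)
  set.seed(2)
  dead <- step_population(alive, dist, make_death(1))
  expect_equal(unname(dead$state$counts), c(0, 0))

  # column sums of V(t+1) are the new counts, at every step of a run
  set.seed(3)
  state <- alive
  for (s in 1:4) {
    res <- step_population(state, dist, make_death(0.1))
    expect_equal(colSums(res$realization), res$state$counts)
    expect_true(all(res$state$counts >= 0))
    expect_true(all(res$state$counts == round(res$state$counts)))
    state <- res$state
  }
  expect_equal(state$time_index, 4L)
})

test_that("stepped ensemble means match the mean-field oracle", {
  dist <- make_test_dist()
  death <- make_death(0.15, 0.05)
  M <- mean_offspring_matrix(dist, death, parent_retained = TRUE)
  c0 <- c(ALDHpos = 100, ALDHneg = 100)
  expected <- as.numeric(c0 %*% M)
  n_rep <- 10000
  set.seed(404)
  draws <- matrix(0, n_rep, 2)
  st <- population_state(c0, two_types)
  for (r in seq_len(n_rep)) {
    draws[r, ] <- step_population(st, dist, death)$state$counts
  }
  for (j in 1:2) {
    se <- stats::sd(draws[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(draws[, j]) - expected[j]), 3 * se)
  }
})

test_that("replicate trajectories are seed-deterministic and anchored at t0", {
  cfg <- make_config(horizon = 4L, seed = 7L)
  t1 <- run_replicate(cfg, 1)
  t2 <- run_replicate(cfg, 1)
  expect_identical(t1, t2)
  expect_equal(unname(unlist(t1[1, c("ALDHpos", "ALDHneg")])), c(50, 50))
  expect_equal(t1$time_hours, t1$time_index * 72)
  # a different replicate index gives a different draw
  t3 <- run_replicate(cfg, 2)
  expect_false(identical(t1$total, t3$total))

  # horizon 0: the trajectory is the initial state alone
  t0 <- run_replicate(make_config(horizon = 0L), 1)
  expect_equal(nrow(t0), 1)
  expect_equal(t0$total, 100)
})

test_that("pure survival gives a constant trajectory and extinction absorbs", {
  still <- make_point_dist(c(0, 0))
  cfg <- make_config(dist = still, death = make_death(0), horizon = 5L)
  traj <- run_replicate(cfg, 1)
  expect_true(all(traj$ALDHpos == 50))
  expect_true(all(traj$ALDHneg == 50))

  # once extinct, always extinct
  gone <- make_config(dist = make_test_dist(), death = make_death(1), horizon = 4L)
  tg <- run_replicate(gone, 1)
  expect_equal(tg$total[-1], rep(0, 4))
})

test_that("ensemble medians follow the documented conventions", {
  cfg <- make_config(horizon = 2L, replicates = 1L)
  ens <- run_ensemble(cfg, keep_replicates = TRUE)
  med <- median_trajectory(ens)
  one <- ens$replicates[[1]]
  expect_equal(med$total, one$total)

  # deterministic dynamics: median equals the closed-form iterate
  det <- make_config(dist = make_point_dist(c(1, 0), c(0, 1)),
                     death = make_death(0), horizon = 3L, replicates = 6L)
  # point mass (1,0) with retention doubles ALDH+ each step; ALDH- grows by
  # its own doubling too
  m <- median_trajectory(run_ensemble(det))
  expect_equal(m$ALDHpos, 50 * 2^(0:3))
  expect_equal(m$ALDHneg, 50 * 2^(0:3))
})

test_that("ALDH+ dynamics decouple from ALDH- under the one-way hierarchy", {
  dist <- make_test_dist()  # ALDH- vectors have no ALDH+ entries
  base <- scenario_config(two_types, c(ALDHpos = 80, ALDHneg = 100),
                          dist, make_death(0.1), horizon = 5L,
                          replicates = 20L, seed = 11L)
  alt <- scenario_config(two_types, c(ALDHpos = 80, ALDHneg = 7000),
                         dist, make_death(0.1), horizon = 5L,
                         replicates = 20L, seed = 11L)
  m1 <- median_trajectory(run_ensemble(base))
  m2 <- median_trajectory(run_ensemble(alt))
  expect_identical(m1$ALDHpos, m2$ALDHpos)
  expect_false(identical(m1$ALDHneg, m2$ALDHneg))
})

test_that("mean-field trajectories iterate the matrix exactly", {
  expect_equal(mean_field_trajectory(c(3, 4), diag(2), 3),
               matrix(rep(c(3, 4), each = 4), 4, 2), ignore_attr = TRUE)
  expect_equal(as.numeric(mean_field_trajectory(1, matrix(2), 3)),
               c(1, 2, 4, 8))
  expect_error(mean_field_trajectory(c(1, 1), matrix(-1, 2, 2), 1), "non-negative")

  # Monte-Carlo agreement over a short horizon
  dist <- make_test_dist()
  death <- make_death(0.1)
  M <- mean_offspring_matrix(dist, death)
  mf <- mean_field_trajectory(c(30, 30), M, 3)
  cfg <- scenario_config(two_types, c(ALDHpos = 30, ALDHneg = 30), dist, death,
                         horizon = 3L, replicates = 1L, seed = 0L)
  n_rep <- 10000
  sums <- array(0, dim = c(4, 2, n_rep))
  for (r in seq_len(n_rep)) {
    tr <- run_replicate(cfg, r)
    sums[, , r] <- as.matrix(tr[, c("ALDHpos", "ALDHneg")])
  }
  for (s in 2:4) {
    for (j in 1:2) {
      x <- sums[s, j, ]
      se <- stats::sd(x) / sqrt(n_rep)
      expect_lt(abs(mean(x) - mf[s, j]), 3 * se)
    }
  }
})

test_that("raising a death probability never raises the expected population", {
  dist <- make_test_dist()
  c0 <- c(100, 200)
  set.seed(8)
  for (k in 1:10) {
    g1 <- runif(2, 0, 0.8)
    bump <- runif(1, 0, 0.2)
    g2 <- pmin(g1 + c(bump, 0), 1)
    M1 <- mean_offspring_matrix(dist, death_model(setNames(g1, type_labels(two_types))))
    M2 <- mean_offspring_matrix(dist, death_model(setNames(g2, type_labels(two_types))))
    expect_lte(sum(c0 %*% M2), sum(c0 %*% M1))
  }
})

test_that("counts beyond the exact sampling range raise an overflow error", {
  dist <- make_point_dist(c(2, 0), c(0, 2))
  st <- population_state(c(ALDHpos = 2^31, ALDHneg = 0), two_types)
  expect_error(step_population(st, dist, make_death(0)), "exceeds")
})

test_that("volume conversion uses the 1e8 cells/cm^3 constant both ways", {
  expect_equal(cells_from_volume(1), 1e8)
  expect_equal(cells_from_volume(0), 0)
  expect_equal(cells_from_volume(0.25), 2.5e7)
  expect_equal(volume_from_cells(1e8), 1)
  expect_equal(volume_from_cells(cells_from_volume(0.73)), 0.73)
  expect_error(cells_from_volume(-1), "non-negative")
})

test_that("interpolation is exponential between steps and exact at nodes", {
  traj <- data.frame(replicate = 1L, time_index = 0:2, time_hours = c(0, 72, 144),
                     ALDHpos = c(100, 200, 400), ALDHneg = c(100, 300, 900),
                     total = c(200, 500, 1300))
  out <- interpolate_trajectory(traj, c(0, 36, 72))
  expect_equal(out$ALDHpos, c(100, 100 * 2^0.5, 200))
  expect_equal(out$ALDHneg[2], 100 * 3^0.5)
  expect_equal(out$interpolated, c(FALSE, TRUE, FALSE))
  expect_error(interpolate_trajectory(traj, 200), "outside")
})
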