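test_that("cell type sets validate labels and fix ordering", {
  types <- cell_type_set(c("A", "B", "C"))
  expect_length(types, 3)
  expect_identical(type_labels(types), c("A", "B", "C"))
  expect_error(cell_type_set(character()), "at least one")
  expect_error(cell_type_set(c("A", "A")), "unique")
  expect_error(cell_type_set(c("A", "")), "non-empty")
})

test_that("offspring histograms tally viable single-parent records exactly", {
  obs <- chamber_observations(
    parent_type = c("ALDHpos", "ALDHpos", "ALDHpos", "ALDHneg"),
    progeny = rbind(c(1, 0), c(1, 0), c(0, 2), c(0, 1)),
    types = two_types
  )
  dist <- build_offspring_distribution(obs)
  hp <- dist$histograms$ALDHpos
  key <- apply(hp$vectors, 1, paste, collapse = ",")
  expect_setequal(key, c("1,0", "0,2"))
  expect_equal(hp$frequency[key == "1,0"], 2)
  expect_equal(hp$frequency[key == "0,2"], 1)
  # conservation: total usable records in = total frequency out, per type
  expect_equal(sum(hp$frequency), 3)
  expect_equal(sum(dist$histograms$ALDHneg$frequency), 1)
})

test_that("non-viable and multi-cell records are excluded and counted", {
  obs <- chamber_observations(
    parent_type = rep(c("ALDHpos", "ALDHneg"), each = 3),
    progeny = rbind(c(2, 0), c(1, 0), c(5, 5), c(0, 1), c(0, 1), c(0, 3)),
    types = two_types,
    parent_viable = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    initial_cell_count = c(1, 1, 2, 1, 1, 1)
  )
  dist <- build_offspring_distribution(obs)
  expect_equal(dist$exclusions$nonviable, 1)
  expect_equal(dist$exclusions$multicell, 1)
  expect_equal(sum(dist$histograms$ALDHpos$frequency), 1)
  # the dead parent's (1,0) vector must not appear
  expect_false(any(apply(dist$histograms$ALDHpos$vectors, 1,
                         paste, collapse = ",") == "1,0"))
})

test_that("estimation errors on mixed periods and on missing types", {
  obs <- chamber_observations(
    parent_type = c("ALDHpos", "ALDHneg"),
    progeny = rbind(c(1, 0), c(0, 1)),
    types = two_types,
    period_hours = c(72, 120)
  )
  expect_error(build_offspring_distribution(obs), "period_hours")

  only_pos <- chamber_observations(
    parent_type = c("ALDHpos", "ALDHneg"),
    progeny = rbind(c(1, 0), c(0, 1)),
    types = two_types,
    parent_viable = c(TRUE, FALSE)
  )
  expect_error(build_offspring_distribution(only_pos), "ALDHneg")
})

test_that("quiescent fraction counts all-zero progeny among viable singles", {
  obs <- chamber_observations(
    parent_type = rep("ALDHpos", 5),
    progeny = rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 1), c(0, 3)),
    types = two_types
  )
  expect_equal(quiescent_fraction(obs, "ALDHpos"), 0.4)
  expect_error(quiescent_fraction(obs, "ALDHneg"), "no usable")

  dividing <- chamber_observations(
    parent_type = rep("ALDHpos", 3),
    progeny = rbind(c(1, 0), c(2, 1), c(0, 3)),
    types = two_types
  )
  expect_equal(quiescent_fraction(dividing, "ALDHpos"), 0)
})

test_that("summary statistics are invariant to record order", {
  set.seed(5)
  obs <- generate_chambers(chamber_preset("skov3_control", n_per_type = 300, seed = 9))
  shuffled <- obs[sample(nrow(obs)), , drop = FALSE]
  expect_equal(quiescent_fraction(shuffled, "ALDHpos"),
               quiescent_fraction(obs, "ALDHpos"))
  expect_equal(mean_cells_per_dividing_parent(shuffled, "ALDHneg"),
               mean_cells_per_dividing_parent(obs, "ALDHneg"))
})

test_that("mean cells per dividing parent supports both counting conventions", {
  obs <- chamber_observations(
    parent_type = rep("ALDHpos", 3),
    progeny = rbind(c(1, 0), c(3, 2), c(0, 0)),
    types = two_types
  )
  excl <- mean_cells_per_dividing_parent(obs, "ALDHpos")
  expect_equal(excl$mean, 3)  # mean progeny over the two dividing records
  expect_equal(excl$n_dividing, 2)
  incl <- mean_cells_per_dividing_parent(obs, "ALDHpos", include_parent = TRUE)
  expect_equal(incl$mean, 4)  # (2 + 6) / 2 counting the surviving parent

  one <- chamber_observations("ALDHpos", rbind(c(3, 0)), two_types)
  expect_equal(mean_cells_per_dividing_parent(one, "ALDHpos",
                                              include_parent = TRUE)$mean, 4)
  quiescent_only <- chamber_observations("ALDHpos", rbind(c(0, 0)), two_types)
  expect_error(mean_cells_per_dividing_parent(quiescent_only, "ALDHpos"),
               "no dividing")
})

test_that("transition support reflects positive entries only", {
  # one-way hierarchy: ALDH- vectors carry no ALDH+ counts
  dist <- make_test_dist()
  ts <- transition_support(dist)
  pairs <- paste(ts$parent, ts$offspring, sep = "->")
  expect_setequal(pairs, c("ALDHpos->ALDHpos", "ALDHpos->ALDHneg",
                           "ALDHneg->ALDHneg"))
  expect_false("ALDHneg->ALDHpos" %in% pairs)

  # a single mixed ALDH+ vector supports both outgoing transitions
  mixed <- make_point_dist(c(1, 2), c(0, 1))
  tm <- transition_support(mixed)
  expect_true(all(c("ALDHpos->ALDHpos", "ALDHpos->ALDHneg") %in%
                    paste(tm$parent, tm$offspring, sep = "->")))

  # all-quiescent histograms support nothing
  silent <- make_point_dist(c(0, 0))
  expect_equal(nrow(transition_support(silent)), 0)
})

test_that("mean offspring matrix matches hand expectations", {
  dist <- make_point_dist(c(2, 1), c(0, 1))
  # certain death zeroes the matrix
  M0 <- mean_offspring_matrix(dist, make_death(1), parent_retained = TRUE)
  expect_equal(unname(M0), matrix(0, 2, 2))
  # no death, point mass (2,1), parent retained: ALDH+ row is (3,1)
  M <- mean_offspring_matrix(dist, make_death(0), parent_retained = TRUE)
  expect_equal(unname(M["ALDHpos", ]), c(3, 1))
  expect_equal(unname(M["ALDHneg", ]), c(0, 2))
  # without retention the parent unit disappears
  Mn <- mean_offspring_matrix(dist, make_death(0), parent_retained = FALSE)
  expect_equal(unname(Mn["ALDHpos", ]), c(2, 1))
})

test_that("mean offspring matrix agrees with Monte-Carlo sampling", {
  dist <- make_test_dist()
  death <- make_death(0.2, 0.1)
  M <- mean_offspring_matrix(dist, death, parent_retained = TRUE)
  n <- 200000
  set.seed(301)
  for (lab in type_labels(two_types)) {
    draws <- sample_parent_outcome(dist, death, lab, n = n)
    for (j in seq_len(ncol(draws))) {
      se <- stats::sd(draws[, j]) / sqrt(n)
      expect_lt(abs(mean(draws[, j]) - M[lab, j]), 3 * se + 1e-12)
    }
  }
})

test_that("histogram estimation is consistent as sample size grows", {
  spec_for <- function(n, seed) chamber_preset("skov3_control", n_per_type = n, seed = seed)
  ref <- cscsim:::implied_distribution(spec_for(1, 1))
  tv_at <- function(n) {
    est <- build_offspring_distribution(generate_chambers(spec_for(n, 77)))
    tv_distance(est, ref, "ALDHpos")
  }
  tvs <- vapply(c(100, 1000, 10000), tv_at, numeric(1))
  expect_true(all(diff(tvs) < 0))
  expect_lt(tvs[3], 0.05)
})

test_that("offspring distributions survive a JSON round trip", {
  dist <- make_test_dist()
  path <- withr::local_tempfile(fileext = ".json")
  write_offspring_distribution(dist, path)
  back <- read_offspring_distribution(path)
  expect_equal(type_labels(back$types), type_labels(dist$types))
  expect_equal(back$period_hours, dist$period_hours)
  for (lab in type_labels(dist$types)) {
    expect_equal(back$histograms[[lab]]$vectors,
                 unname(dist$histograms[[lab]]$vectors),
                 ignore_attr = TRUE)
    expect_equal(back$histograms[[lab]]$frequency,
                 dist$histograms[[lab]]$frequency)
  }
  expect_equal(tv_distance(back, dist, "ALDHpos"), 0)
})

test_that("chamber tables survive a CSV round trip", {
  obs <- generate_chambers(chamber_preset("primary_control", n_per_type = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_chambers(obs, path)
  back <- read_chambers(path, two_types)
  expect_equal(back$parent_viable, obs$parent_viable)
  expect_equal(back$progeny_ALDHpos, obs$progeny_ALDHpos)
  expect_equal(back$period_hours, obs$period_hours)
})
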