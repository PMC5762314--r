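# ---------------------------------------------------------------------------
# RNG sub-streams
#
# One root seed drives everything. Each (replicate, type) pair gets its own
# Mersenne-Twister stream, seeded by a fixed arithmetic rule on the root seed.
# Because a given type's draws come only from its own stream, the marginal law
# of a type that receives no immigration from other types is unchanged when
# the other types' initial counts change — the hierarchy-decoupling property
# holds exactly, not just in distribution.
# ---------------------------------------------------------------------------

# documented splitting rule: sub-seed for (replicate r >= 1, type index k >= 1)
derive_stream_seed <- function(root_seed, replicate, type_index) {
  root <- as.numeric(root_seed) %% 2147483647
  (root + 1000003 * as.numeric(replicate) + 7919 * as.numeric(type_index)) %% 2147483647
}

# create one saved RNG state per type for a replicate
make_type_streams <- function(root_seed, replicate, l) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  lapply(seq_len(l), function(k) {
    set.seed(derive_stream_seed(root_seed, replicate, k))
    get0(".Random.seed", envir = globalenv())
  })
}

get_rng_state <- function() {
  get0(".Random.seed", envir = globalenv(), inherits = FALSE)
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# largest parent count the exact multinomial sampler accepts
.max_parent_count <- 2147483647

#' Population state at one time index
#'
#' Counts per cell type at discrete time `t`, measured in multiples of the
#' chamber observation period `h`.
#'
#' @param counts Named (or ordered) vector of non-negative integer counts,
#'   one per type.
#' @param types A `cell_type_set`.
#' @param time_index Non-negative integer time index `t`.
#' @param period_hours Observation period `h` in hours.
#' @return An object of class `population_state`.
#' @export
population_state <- function(counts, types, time_index = 0L, period_hours = 72) {
  types <- as_cell_type_set(types)
  labels <- type_labels(types)
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), labels)) {
      stop("count names must match the cell type labels", call. = FALSE)
    }
    counts <- counts[labels]
  }
  counts <- as.numeric(counts)
  if (length(counts) != length(labels)) {
    stop("one count per cell type required", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  names(counts) <- labels
  structure(list(counts = counts, types = types,
                 time_index = as.integer(time_index),
                 period_hours = as.numeric(period_hours)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state at t = %d (%.0f h):\n",
              x$time_index, x$time_index * x$period_hours))
  print(x$counts)
  invisible(x)
}

#' Sample per-parent offspring outcomes
#'
#' Draws the realized offspring vector `q*` for `n` independent parents of
#' one type: with probability `g(t+1)` the parent dies and contributes the
#' zero vector; otherwise a progeny vector is resampled from the type's
#' empirical histogram. With `parent_retained = TRUE` (the default) a
#' surviving parent additionally contributes one cell to its own compartment,
#' so a surviving quiescent parent persists. `literal_equation = TRUE`
#' drops that extra unit: a survivor contributes only its sampled progeny
#' vector.
#'
#' Draws come from R's global random number generator; seed it (or use the
#' stream machinery inside [run_replicate()]) for reproducibility.
#'
#' @param dist An `offspring_distribution`.
#' @param death A `death_model`.
#' @param parent_type Parent cell type label.
#' @param t Time index at which the step starts.
#' @param n Number of independent parents to sample.
#' @param parent_retained Add a surviving parent to its own slot.
#' @param literal_equation Survivor contributes only the sampled progeny
#'   vector (overrides `parent_retained`).
#' @return An `n` x `l` integer matrix, one sampled outcome vector per row.
#' @export
sample_parent_outcome <- function(dist, death, parent_type, t = 0, n = 1,
                                  parent_retained = TRUE,
                                  literal_equation = FALSE) {
  stopifnot(inherits(dist, "offspring_distribution"))
  labels <- type_labels(dist$types)
  k <- type_index(dist$types, parent_type)
  hgm <- dist$histograms[[k]]
  g <- death_prob(death, parent_type, t)

  dead <- stats::runif(n) < g
  idx <- sample.int(nrow(hgm$vectors), n, replace = TRUE,
                    prob = hgm$frequency)
  out <- hgm$vectors[idx, , drop = FALSE]
  if (parent_retained && !literal_equation) {
    out[, k] <- out[, k] + 1L
  }
  out[dead, ] <- 0L
  colnames(out) <- labels
  out
}

#' Advance the population by one observation period
#'
#' For each type `lambda`, the `c_lambda(t)` parents draw independent
#' outcomes `q*`; their sum is row `lambda` of the realization matrix
#' `V(t+1)`, and the new counts are the column sums
#' `c_lambda(t+1) = sum_m V[m, lambda]`. Internally the independent
#' per-parent draws of one type are aggregated through a single multinomial
#' draw over the type's distinct outcomes (death plus each histogram vector),
#' which is distributionally identical to summing per-parent samples and
#' keeps large populations tractable.
#'
#' @param state A `population_state`.
#' @param dist An `offspring_distribution`.
#' @param death A `death_model`.
#' @param parent_retained Surviving parents persist into their own slot
#'   (default `TRUE`).
#' @param literal_equation Survivors contribute only the sampled progeny
#'   vector.
#' @param streams Optional list of per-type saved RNG states (internal; used
#'   by [run_replicate()] to give each type its own stream). Modified in
#'   place via the returned value.
#' @return A list with `state` (the `population_state` at `t + 1`),
#'   `realization` (the l x l integer matrix `V(t+1)`), and `streams`
#'   (updated per-type RNG states, or `NULL`).
#' @export
step_population <- function(state, dist, death,
                            parent_retained = TRUE,
                            literal_equation = FALSE,
                            streams = NULL) {
  stopifnot(inherits(state, "population_state"),
            inherits(dist, "offspring_distribution"))
  labels <- type_labels(state$types)
  if (!identical(labels, type_labels(dist$types))) {
    stop("state and offspring distribution use different type sets", call. = FALSE)
  }
  l <- length(labels)
  V <- matrix(0, l, l, dimnames = list(labels, labels))
  counts <- state$counts

  for (k in seq_len(l)) {
    c_k <- counts[k]
    if (c_k == 0) next
    if (c_k > .max_parent_count) {
      stop(sprintf(
        "count of type '%s' (%.3g) exceeds the exact-integer sampling range (%d)",
        labels[k], c_k, .max_parent_count), call. = FALSE)
    }
    hgm <- dist$histograms[[k]]
    g <- death_prob(death, labels[k], state$time_index)
    w <- hgm$frequency / sum(hgm$frequency)
    probs <- c(g, (1 - g) * w)

    if (!is.null(streams)) set_rng_state(streams[[k]])
    draws <- stats::rmultinom(1L, size = as.integer(c_k), prob = probs)[, 1L]
    if (!is.null(streams)) streams[[k]] <- get_rng_state()

    n_dead <- draws[1L]
    vec_counts <- draws[-1L]
    row <- as.numeric(t(hgm$vectors) %*% vec_counts)
    if (parent_retained && !literal_equation) {
      row[k] <- row[k] + (c_k - n_dead)
    }
    V[k, ] <- row
  }

  new_counts <- colSums(V)
  if (any(new_counts > 2^53)) {
    stop("population count exceeds the exact-integer range of a double", call. = FALSE)
  }
  list(
    state = population_state(new_counts, state$types,
                             time_index = state$time_index + 1L,
                             period_hours = state$period_hours),
    realization = V,
    streams = streams
  )
}

#' Simulate one replicate trajectory
#'
#' Iterates [step_population()] from the configured initial counts for
#' `horizon` steps. Deterministic given the configuration's seed: replicate
#' `r` of type `k` draws from a stream seeded by a fixed rule on
#' (seed, r, k).
#'
#' @param config A `scenario_config` (see [scenario_config()]).
#' @param replicate Replicate index (seeds the per-type streams).
#' @return A `data.frame` with columns `replicate`, `time_index`,
#'   `time_hours`, one column per type, and `total`; attribute
#'   `"realizations"` holds the list of per-step realization matrices.
#' @export
run_replicate <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  labels <- type_labels(config$types)
  l <- length(labels)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  streams <- make_type_streams(config$seed, replicate, l)

  state <- population_state(config$initial_counts, config$types,
                            time_index = 0L,
                            period_hours = config$offspring$period_hours)
  states <- vector("list", config$horizon + 1L)
  realizations <- vector("list", config$horizon)
  states[[1L]] <- state
  if (config$horizon > 0) {
    for (s in seq_len(config$horizon)) {
      res <- step_population(state, config$offspring, config$death,
                             parent_retained = config$parent_retained,
                             literal_equation = config$literal_equation,
                             streams = streams)
      state <- res$state
      streams <- res$streams
      states[[s + 1L]] <- state
      realizations[[s]] <- res$realization
    }
  }

  counts <- do.call(rbind, lapply(states, function(s) s$counts))
  out <- data.frame(
    replicate = rep(as.integer(replicate), nrow(counts)),
    time_index = seq_len(nrow(counts)) - 1L,
    time_hours = (seq_len(nrow(counts)) - 1L) * config$offspring$period_hours
  )
  for (j in seq_len(l)) out[[labels[j]]] <- counts[, j]
  out$total <- rowSums(counts)
  attr(out, "realizations") <- realizations
  out
}

#' Run an ensemble of replicates and summarize per time and type
#'
#' Runs `R` independent replicates of a scenario and reports, per time index
#' and cell type, the median and the 2.5% / 97.5% quantiles across
#' replicates. Medians use the inclusive midpoint convention for even `R`
#' (the mean of the two central order statistics); outer quantiles use the
#' standard interpolating definition (R's type 7). The default `R = 50`
#' matches the practice of recording medians over 50 iterations.
#'
#' @param config A `scenario_config`.
#' @param keep_replicates Keep all replicate trajectories in the result
#'   (default `FALSE`).
#' @return An object of class `ensemble_summary`: a list with `summary` (a
#'   `data.frame` in trajectory layout whose `replicate` column holds
#'   `"median"`, `"q025"`, `"q975"`), `config`, and optionally `replicates`.
#' @export
run_ensemble <- function(config, keep_replicates = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  labels <- type_labels(config$types)
  reps <- lapply(seq_len(config$replicates), function(r) run_replicate(config, r))

  times <- reps[[1L]][, c("time_index", "time_hours")]
  summarize <- function(fn, tag) {
    out <- data.frame(replicate = rep(tag, nrow(times)),
                      time_index = times$time_index,
                      time_hours = times$time_hours,
                      stringsAsFactors = FALSE)
    for (lab in c(labels, "total")) {
      m <- vapply(reps, function(df) df[[lab]], numeric(nrow(times)))
      m <- matrix(m, nrow = nrow(times))
      out[[lab]] <- apply(m, 1L, fn)
    }
    out
  }
  summary <- rbind(
    summarize(stats::median, "median"),
    summarize(function(x) stats::quantile(x, 0.025, names = FALSE, type = 7), "q025"),
    summarize(function(x) stats::quantile(x, 0.975, names = FALSE, type = 7), "q975")
  )
  structure(
    list(summary = summary, config = config,
         replicates = if (keep_replicates) reps else NULL),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: %d replicates, horizon %d steps of %g h\n",
              x$config$replicates, x$config$horizon, x$config$offspring$period_hours))
  print(x$summary[x$summary$replicate == "median", , drop = FALSE], row.names = FALSE)
  invisible(x)
}

#' Median trajectory of an ensemble
#'
#' @param ensemble An `ensemble_summary`.
#' @return The `data.frame` rows of the ensemble summary with
#'   `replicate == "median"`.
#' @export
median_trajectory <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_summary"))
  out <- ensemble$summary[ensemble$summary$replicate == "median", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deterministic mean-field trajectory
#'
#' Repeated application of the expected offspring matrix:
#' `c(t+1) = c(t) %*% M`. Real-valued; used as a fast preview and as the
#' expectation oracle against which the stochastic simulator is tested.
#'
#' @param initial_counts Numeric vector of initial counts (length l).
#' @param M Non-negative l x l matrix, e.g. from [mean_offspring_matrix()].
#' @param steps Number of steps.
#' @return A `(steps + 1)` x l numeric matrix of expected counts, one row
#'   per time index.
#' @export
mean_field_trajectory <- function(initial_counts, M, steps) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("M must be non-negative", call. = FALSE)
  l <- nrow(M)
  stopifnot(ncol(M) == l, length(initial_counts) == l, steps >= 0)
  out <- matrix(0, steps + 1L, l)
  colnames(out) <- colnames(M)
  out[1L, ] <- as.numeric(initial_counts)
  if (steps > 0) {
    for (s in seq_len(steps)) out[s + 1L, ] <- out[s, , drop = FALSE] %*% M
  }
  out
}

#' Interpolate a trajectory at arbitrary hour marks
#'
#' The simulator advances in whole multiples of the chamber observation
#' period (72 h for the cell line, 120 h for primary cells). Validation
#' measurements, however, may fall between steps (e.g. every 24 h). This
#' helper interpolates each type's counts exponentially (log-linearly)
#' between the two adjacent simulated steps; where a count is zero at either
#' end it falls back to linear interpolation. Interpolated rows are labeled
#' as such — they are a reporting convention, not sub-step dynamics.
#'
#' @param trajectory A trajectory `data.frame` (one `replicate` level) as
#'   produced by [run_replicate()] or [median_trajectory()].
#' @param times_hours Numeric vector of hour marks within the simulated
#'   range.
#' @return A `data.frame` with `time_hours`, one column per type, `total`,
#'   and a logical `interpolated` column.
#' @export
interpolate_trajectory <- function(trajectory, times_hours) {
  h_cols <- setdiff(names(trajectory),
                    c("replicate", "time_index", "time_hours", "total"))
  t_sim <- trajectory$time_hours
  if (any(times_hours < min(t_sim) | times_hours > max(t_sim))) {
    stop("requested times fall outside the simulated range", call. = FALSE)
  }
  out <- data.frame(time_hours = times_hours)
  for (lab in h_cols) {
    y <- trajectory[[lab]]
    vals <- vapply(times_hours, function(tt) {
      i <- findInterval(tt, t_sim, rightmost.closed = TRUE)
      if (t_sim[i] == tt) return(y[i])
      frac <- (tt - t_sim[i]) / (t_sim[i + 1L] - t_sim[i])
      y0 <- y[i]; y1 <- y[i + 1L]
      if (y0 > 0 && y1 > 0) y0 * (y1 / y0)^frac else y0 + frac * (y1 - y0)
    }, numeric(1))
    out[[lab]] <- vals
  }
  out$total <- rowSums(out[, h_cols, drop = FALSE])
  out$interpolated <- !(times_hours %in% t_sim)
  out
}
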