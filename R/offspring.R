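#' Estimate per-type empirical offspring distributions from chamber data
#'
#' For each parent cell type, tallies the progeny-count vectors of viable,
#' single-cell chambers into a frequency histogram. Forward simulation later
#' resamples these vectors with probability proportional to their observed
#' frequency, so the histogram is the model: no parametric family is fitted.
#' Chambers whose parent died before the endpoint, or that were loaded with
#' more than one cell, are excluded and their exclusion counts reported.
#'
#' @param observations Chamber observation `data.frame`
#'   (see [chamber_observations()]).
#' @param types Optional `cell_type_set`; inferred from the progeny columns
#'   when `NULL`. Every type must have at least one usable record.
#' @return An object of class `offspring_distribution` with elements
#'   `types`, `period_hours`, `histograms` (per type, a list with an integer
#'   `vectors` matrix of distinct offspring vectors and a `frequency` vector),
#'   and `exclusions` (counts of dropped non-viable and multi-cell records).
#' @examples
#' types <- cell_type_set(c("ALDHpos", "ALDHneg"))
#' obs <- chamber_observations(
#'   parent_type = c("ALDHpos", "ALDHpos", "ALDHneg"),
#'   progeny = rbind(c(1, 0), c(1, 0), c(0, 2)),
#'   types = types
#' )
#' dist <- build_offspring_distribution(obs)
#' dist$histograms$ALDHpos$frequency
#' @export
build_offspring_distribution <- function(observations, types = NULL) {
  types <- if (is.null(types)) chamber_types(observations) else as_cell_type_set(types)
  validate_chambers(observations, types)
  labels <- type_labels(types)

  h <- unique(observations$period_hours)
  if (length(h) > 1L) {
    stop(sprintf("all observations must share one period_hours; found: %s",
                 paste(sort(h), collapse = ", ")), call. = FALSE)
  }

  usable <- observations$parent_viable & observations$initial_cell_count == 1L
  exclusions <- list(
    nonviable = sum(!observations$parent_viable),
    multicell = sum(observations$parent_viable & observations$initial_cell_count != 1L)
  )
  obs <- observations[usable, , drop = FALSE]

  missing <- setdiff(labels, unique(obs$parent_type))
  if (length(missing)) {
    stop(sprintf("no usable (viable, single-cell) records for type(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  pm <- progeny_matrix(obs, types)
  histograms <- lapply(labels, function(lab) {
    rows <- pm[obs$parent_type == lab, , drop = FALSE]
    key <- apply(rows, 1L, paste, collapse = ",")
    tab <- table(key)
    vecs <- do.call(rbind, lapply(strsplit(names(tab), ",", fixed = TRUE), as.integer))
    colnames(vecs) <- labels
    list(vectors = vecs, frequency = as.integer(tab))
  })
  names(histograms) <- labels

  structure(
    list(types = types, period_hours = as.numeric(h),
         histograms = histograms, exclusions = exclusions),
    class = "offspring_distribution"
  )
}

# construct an offspring_distribution directly from vectors + frequencies;
# used by presets, deserialization and tests
offspring_distribution <- function(types, histograms, period_hours) {
  types <- as_cell_type_set(types)
  labels <- type_labels(types)
  if (!setequal(names(histograms), labels)) {
    stop("histograms must be named by the cell type labels", call. = FALSE)
  }
  histograms <- histograms[labels]
  for (lab in labels) {
    hgm <- histograms[[lab]]
    v <- as.matrix(hgm$vectors)
    if (ncol(v) != length(labels)) {
      stop(sprintf("offspring vectors for '%s' must have length %d", lab, length(labels)),
           call. = FALSE)
    }
    if (any(v < 0) || any(v != round(v))) {
      stop("offspring vectors must be non-negative integers", call. = FALSE)
    }
    f <- as.numeric(hgm$frequency)
    if (length(f) != nrow(v) || any(f <= 0) || sum(f) < 1) {
      stop(sprintf("histogram for '%s' must have positive frequencies (total >= 1)", lab),
           call. = FALSE)
    }
    colnames(v) <- labels
    histograms[[lab]] <- list(vectors = v, frequency = f)
  }
  structure(
    list(types = types, period_hours = as.numeric(period_hours),
         histograms = histograms,
         exclusions = list(nonviable = 0L, multicell = 0L)),
    class = "offspring_distribution"
  )
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat(sprintf("offspring_distribution over %d h, types: %s\n",
              x$period_hours, paste(type_labels(x$types), collapse = ", ")))
  for (lab in type_labels(x$types)) {
    hgm <- x$histograms[[lab]]
    cat(sprintf("  %s: %d distinct vectors, total frequency %d\n",
                lab, nrow(hgm$vectors), as.integer(sum(hgm$frequency))))
  }
  if (x$exclusions$nonviable + x$exclusions$multicell > 0) {
    cat(sprintf("  excluded records: %d non-viable, %d multi-cell\n",
                x$exclusions$nonviable, x$exclusions$multicell))
  }
  invisible(x)
}

#' Fraction of viable single parents that produced no progeny
#'
#' A quiescent cell is viable at the endpoint but produced zero offspring
#' over the observation period (an all-zero progeny vector).
#'
#' @param observations Chamber observation `data.frame`.
#' @param type Parent cell type label.
#' @return Proportion in \[0, 1\].
#' @export
quiescent_fraction <- function(observations, type) {
  types <- validate_chambers(observations)
  type_index(types, type)
  keep <- observations$parent_viable &
    observations$initial_cell_count == 1L &
    observations$parent_type == type
  if (!any(keep)) {
    stop(sprintf("no usable records of type '%s'", type), call. = FALSE)
  }
  pm <- progeny_matrix(observations[keep, , drop = FALSE], types)
  mean(rowSums(pm) == 0)
}

#' Mean cells produced per dividing single parent
#'
#' Averages the chamber endpoint count over the viable single parents that
#' divided (progeny total of at least one). By default the parent cell itself
#' is not counted, matching the progeny axis of the chamber histograms; set
#' `include_parent = TRUE` to count the surviving parent as one additional
#' cell.
#'
#' @param observations Chamber observation `data.frame`.
#' @param type Parent cell type label.
#' @param include_parent Count the surviving parent as one cell
#'   (default `FALSE`).
#' @return A list with `mean` (the statistic) and `n_dividing` (number of
#'   dividing records used).
#' @export
mean_cells_per_dividing_parent <- function(observations, type, include_parent = FALSE) {
  types <- validate_chambers(observations)
  type_index(types, type)
  keep <- observations$parent_viable &
    observations$initial_cell_count == 1L &
    observations$parent_type == type
  pm <- progeny_matrix(observations[keep, , drop = FALSE], types)
  totals <- rowSums(pm)
  totals <- totals[totals >= 1]
  if (!length(totals)) {
    stop(sprintf("no dividing records of type '%s'", type), call. = FALSE)
  }
  list(mean = mean(totals) + as.numeric(include_parent),
       n_dividing = length(totals))
}

#' Observed parent-to-offspring state transitions
#'
#' Returns the ordered pairs (parent type, offspring type) for which at least
#' one observed offspring vector carries a positive count. In the source data
#' ALDH- parents were only ever seen to produce ALDH- progeny, so their row
#' carries no ALDH+ pair; the structure nevertheless permits such transitions
#' whenever data contain them.
#'
#' @param dist An `offspring_distribution`.
#' @return A `data.frame` with character columns `parent` and `offspring`,
#'   one row per supported transition (possibly zero rows).
#' @export
transition_support <- function(dist) {
  stopifnot(inherits(dist, "offspring_distribution"))
  labels <- type_labels(dist$types)
  pairs <- list()
  for (i in labels) {
    v <- dist$histograms[[i]]$vectors
    seen <- colSums(v > 0) > 0
    for (j in labels[seen]) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (!length(pairs)) {
    return(data.frame(parent = character(), offspring = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, pairs)
  data.frame(parent = m[, 1], offspring = m[, 2], stringsAsFactors = FALSE)
}

#' Expected offspring matrix of one simulation step
#'
#' Analytic expectation of the per-parent sampling scheme: entry (lambda, j)
#' is the expected number of type-j cells contributed at t+1 by one type-
#' lambda parent alive at t, i.e.
#' `(1 - g_lambda(t+1)) * (E[u_lambda_j] + [lambda == j] * parent_retained)`.
#' The deterministic iteration `c(t+1) = c(t) %*% M` built from this matrix
#' serves as a mean-field oracle for the stochastic simulator.
#'
#' @param dist An `offspring_distribution`.
#' @param death A `death_model`.
#' @param t Time index at which the step starts (default 0).
#' @param parent_retained Does a surviving parent persist into its own
#'   compartment (default `TRUE`).
#' @return An l x l numeric matrix with rows = parent type, columns =
#'   offspring type.
#' @export
mean_offspring_matrix <- function(dist, death, t = 0, parent_retained = TRUE) {
  stopifnot(inherits(dist, "offspring_distribution"))
  labels <- type_labels(dist$types)
  l <- length(labels)
  M <- matrix(0, l, l, dimnames = list(labels, labels))
  for (i in seq_len(l)) {
    hgm <- dist$histograms[[i]]
    w <- hgm$frequency / sum(hgm$frequency)
    eu <- as.numeric(t(hgm$vectors) %*% w)
    if (parent_retained) eu[i] <- eu[i] + 1
    M[i, ] <- (1 - death_prob(death, labels[i], t)) * eu
  }
  M
}

#' Serialize an offspring distribution to JSON
#'
#' The JSON lists the type labels, the observation period, and per type an
#' array of `{vector, frequency}` pairs. Frequencies are kept as raw counts
#' (not normalized probabilities) so exact resampling weights survive a
#' round trip.
#'
#' @param dist An `offspring_distribution`.
#' @param path File path.
#' @return `write_offspring_distribution()` returns `path` invisibly;
#'   `read_offspring_distribution()` returns the `offspring_distribution`.
#' @export
write_offspring_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "offspring_distribution"))
  labels <- type_labels(dist$types)
  obj <- list(
    types = labels,
    period_hours = dist$period_hours,
    histograms = lapply(dist$histograms, function(hgm) {
      lapply(seq_along(hgm$frequency), function(k) {
        list(vector = as.integer(hgm$vectors[k, ]),
             frequency = as.integer(hgm$frequency[k]))
      })
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_offspring_distribution
#' @export
read_offspring_distribution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels <- vapply(obj$types, as.character, character(1))
  histograms <- lapply(labels, function(lab) {
    entries <- obj$histograms[[lab]]
    vecs <- do.call(rbind, lapply(entries, function(e) as.integer(unlist(e$vector))))
    freq <- vapply(entries, function(e) as.numeric(e$frequency), numeric(1))
    list(vectors = vecs, frequency = freq)
  })
  names(histograms) <- labels
  offspring_distribution(cell_type_set(labels), histograms,
                         period_hours = as.numeric(obj$period_hours))
}

#' Total variation distance between two offspring histograms
#'
#' Compares the normalized offspring histograms of one parent type across two
#' `offspring_distribution` objects: half the L1 distance over the union of
#' their supports. Used to quantify how well an estimated histogram recovers
#' a generating one.
#'
#' @param dist_a,dist_b `offspring_distribution` objects sharing type labels.
#' @param type Parent cell type label.
#' @return A number in \[0, 1\].
#' @export
tv_distance <- function(dist_a, dist_b, type) {
  stopifnot(inherits(dist_a, "offspring_distribution"),
            inherits(dist_b, "offspring_distribution"))
  key <- function(d) {
    hgm <- d$histograms[[type]]
    p <- hgm$frequency / sum(hgm$frequency)
    names(p) <- apply(hgm$vectors, 1L, paste, collapse = ",")
    p
  }
  pa <- key(dist_a)
  pb <- key(dist_b)
  keys <- union(names(pa), names(pb))
  qa <- ifelse(keys %in% names(pa), pa[keys], 0)
  qb <- ifelse(keys %in% names(pb), pb[keys], 0)
  0.5 * sum(abs(qa - qb))
}
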