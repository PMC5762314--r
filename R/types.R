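#' Define an ordered set of cell states
#'
#' The model tracks a population split into `l` distinguishable cell states
#' (by default the ALDH+ stem-like and ALDH- bulk compartments of an ovarian
#' cancer cell population). The ordering of the labels is fixed and defines
#' the index positions of every count vector and realization matrix produced
#' downstream.
#'
#' @param labels Character vector of distinct, non-empty state names.
#'   Defaults to `c("ALDHpos", "ALDHneg")`.
#' @return An object of class `cell_type_set`: a character vector of labels
#'   with fixed ordering.
#' @examples
#' types <- cell_type_set()
#' length(types)
#' @export
cell_type_set <- function(labels = c("ALDHpos", "ALDHneg")) {
  labels <- as.character(labels)
  if (length(labels) < 1L) {
    stop("a cell_type_set needs at least one state label", call. = FALSE)
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("cell state labels must be non-empty and non-missing", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("cell state labels must be unique", call. = FALSE)
  }
  structure(labels, class = "cell_type_set")
}

#' @export
print.cell_type_set <- function(x, ...) {
  cat("cell_type_set with", length(x), "states:", paste(unclass(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cell_type_set
#' @param x A `cell_type_set` (or plain character vector of labels).
#' @export
type_labels <- function(x) {
  if (inherits(x, "cell_type_set")) as.character(unclass(x)) else as.character(x)
}

# coerce and validate a types argument; accepts cell_type_set or character
as_cell_type_set <- function(types) {
  if (inherits(types, "cell_type_set")) types else cell_type_set(types)
}

# index of a label within a type set, with a clear error for unknown labels
type_index <- function(types, label) {
  idx <- match(label, type_labels(types))
  if (is.na(idx)) {
    stop(sprintf("unknown cell type '%s'; known types: %s",
                 label, paste(type_labels(types), collapse = ", ")),
         call. = FALSE)
  }
  idx
}

#' Per-type death model
#'
#' Each cell type carries a probability that a parent of that type dies during
#' the next time interval and contributes the zero offspring vector. In the
#' source experiments these probabilities come from Annexin-V flow cytometry,
#' not from the chamber histograms, so they are a separate model object. The
#' default form is a constant per type; a function of the time index is also
#' accepted for time-varying death.
#'
#' @param rates Either a named numeric vector of constant death probabilities
#'   (one per type, each in \[0, 1\]) or a named list mixing constants and
#'   functions `g(t)` returning a probability for time index `t`.
#' @param types A `cell_type_set`; defaults to the names of `rates`.
#' @return An object of class `death_model`.
#' @examples
#' dm <- death_model(c(ALDHpos = 0.05, ALDHneg = 0.05))
#' death_prob(dm, "ALDHpos", t = 1)
#' @export
death_model <- function(rates, types = NULL) {
  if (is.null(types)) {
    if (is.null(names(rates))) {
      stop("`rates` must be named by cell type when `types` is not given", call. = FALSE)
    }
    types <- cell_type_set(names(rates))
  }
  types <- as_cell_type_set(types)
  labels <- type_labels(types)
  if (is.numeric(rates)) rates <- as.list(rates)
  if (is.null(names(rates)) && length(rates) == length(labels)) {
    names(rates) <- labels
  }
  if (!setequal(names(rates), labels)) {
    stop("`rates` must supply exactly one entry per cell type", call. = FALSE)
  }
  fns <- lapply(labels, function(lab) {
    r <- rates[[lab]]
    if (is.function(r)) {
      r
    } else {
      r <- as.numeric(r)
      if (length(r) != 1L || is.na(r) || r < 0 || r > 1) {
        stop(sprintf("death probability for '%s' must be a single value in [0, 1]", lab),
             call. = FALSE)
      }
      local({
        val <- r
        function(t) val
      })
    }
  })
  names(fns) <- labels
  structure(list(types = types, g = fns), class = "death_model")
}

#' @rdname death_model
#' @param model A `death_model`.
#' @param type A cell type label.
#' @param t Time index (the probability applies to the interval ending at
#'   `t + 1`).
#' @export
death_prob <- function(model, type, t = 0) {
  stopifnot(inherits(model, "death_model"))
  idx <- type_index(model$types, type)
  p <- model$g[[idx]](t + 1)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("death model for '%s' returned an invalid probability at t = %s",
                 type, format(t)), call. = FALSE)
  }
  as.numeric(p)
}

#' @export
print.death_model <- function(x, ...) {
  cat("death_model over types:", paste(type_labels(x$types), collapse = ", "), "\n")
  for (lab in type_labels(x$types)) {
    cat(sprintf("  g(%s) at t=1: %.4f\n", lab, death_prob(x, lab, 0)))
  }
  invisible(x)
}
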