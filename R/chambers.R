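#' Construct a table of single-cell chamber observations
#'
#' One row per microfluidic chamber: the captured parent cell's type, whether
#' the parent was viable at the endpoint, the number of cells initially loaded
#' into the chamber, the progeny counted per type at the endpoint (excluding
#' the parent cell itself, so a live quiescent parent scores all zeros), and
#' the observation period in hours.
#'
#' @param parent_type Character vector of parent cell type labels.
#' @param progeny Matrix (or data.frame) of non-negative integer progeny
#'   counts, one column per cell type in the order of `types`.
#' @param types A `cell_type_set` naming the progeny columns.
#' @param parent_viable Logical vector; was the parent alive at the endpoint.
#' @param initial_cell_count Integer vector of cells loaded per chamber
#'   (estimation only uses chambers with a single captured cell).
#' @param period_hours Observation period `h` in hours (single value or
#'   per-row vector).
#' @param chamber_id Optional identifiers; generated when missing.
#' @return A `data.frame` with columns `chamber_id`, `parent_type`,
#'   `initial_cell_count`, `parent_viable`, one `progeny_<label>` column per
#'   type, and `period_hours`.
#' @export
chamber_observations <- function(parent_type, progeny, types,
                                 parent_viable = TRUE,
                                 initial_cell_count = 1L,
                                 period_hours = 72,
                                 chamber_id = NULL) {
  types <- as_cell_type_set(types)
  labels <- type_labels(types)
  progeny <- as.matrix(progeny)
  n <- length(parent_type)
  if (nrow(progeny) != n) {
    stop("`progeny` must have one row per parent", call. = FALSE)
  }
  if (ncol(progeny) != length(labels)) {
    stop("`progeny` must have one column per cell type", call. = FALSE)
  }
  if (any(progeny < 0) || any(progeny != round(progeny))) {
    stop("progeny counts must be non-negative integers", call. = FALSE)
  }
  bad <- setdiff(unique(parent_type), labels)
  if (length(bad)) {
    stop(sprintf("unknown parent type(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(chamber_id)) chamber_id <- sprintf("ch%05d", seq_len(n))
  out <- data.frame(
    chamber_id = as.character(chamber_id),
    parent_type = as.character(parent_type),
    initial_cell_count = as.integer(rep_len(initial_cell_count, n)),
    parent_viable = as.logical(rep_len(parent_viable, n)),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(labels)) {
    out[[paste0("progeny_", labels[j])]] <- as.integer(progeny[, j])
  }
  out$period_hours <- as.numeric(rep_len(period_hours, n))
  out
}

# required fixed columns of the chamber table
.chamber_fixed_cols <- c("chamber_id", "parent_type", "initial_cell_count",
                         "parent_viable", "period_hours")

# infer the cell_type_set from the progeny_<label> columns of a chamber table
chamber_types <- function(obs) {
  pc <- grep("^progeny_", names(obs), value = TRUE)
  if (!length(pc)) stop("no progeny_<label> columns found", call. = FALSE)
  cell_type_set(sub("^progeny_", "", pc))
}

# validate a chamber table against an (optional) expected type set
validate_chambers <- function(obs, types = NULL) {
  missing_cols <- setdiff(.chamber_fixed_cols, names(obs))
  if (length(missing_cols)) {
    stop(sprintf("chamber table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  found <- chamber_types(obs)
  if (!is.null(types)) {
    types <- as_cell_type_set(types)
    if (!identical(type_labels(found), type_labels(types))) {
      stop(sprintf("chamber table types (%s) do not match expected types (%s)",
                   paste(type_labels(found), collapse = ", "),
                   paste(type_labels(types), collapse = ", ")), call. = FALSE)
    }
  }
  pm <- progeny_matrix(obs, found)
  if (any(pm < 0) || any(pm != round(pm))) {
    stop("progeny counts must be non-negative integers", call. = FALSE)
  }
  invisible(found)
}

# extract the n x l progeny count matrix in type order
progeny_matrix <- function(obs, types) {
  labels <- type_labels(types)
  m <- as.matrix(obs[, paste0("progeny_", labels), drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- labels
  m
}

#' Read and write chamber observation tables
#'
#' The on-disk format is plain CSV with a header row and columns
#' `chamber_id`, `parent_type`, `initial_cell_count`, `parent_viable`
#' (true/false), one `progeny_<label>` column per cell type, and
#' `period_hours`.
#'
#' @param path File path.
#' @param types Optional `cell_type_set` to validate against; inferred from
#'   the progeny columns when `NULL`.
#' @return `read_chambers()` returns the chamber `data.frame`;
#'   `write_chambers()` returns `path` invisibly.
#' @export
read_chambers <- function(path, types = NULL) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  obs$parent_viable <- .parse_logical(obs$parent_viable)
  validate_chambers(obs, types)
  obs
}

#' @rdname read_chambers
#' @param obs A chamber observation `data.frame`.
#' @export
write_chambers <- function(obs, path) {
  validate_chambers(obs)
  out <- obs
  out$parent_viable <- ifelse(out$parent_viable, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop("parent_viable must be true/false", call. = FALSE)
  out
}
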