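#' Compare predicted and observed values by Pearson correlation
#'
#' Product-moment correlation with the conventional t-test p-value, via
#' [stats::cor.test()]. The paired values are echoed in the result so a
#' reported correlation can be audited. A p-value is only reported for
#' three or more pairs; zero variance in either argument is an error rather
#' than a silent `NA`.
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 2) of
#'   finite values.
#' @return An object of class `comparison_result`: a list with `r`,
#'   `p_value` (`NA` when `n < 3`), `n`, `predicted`, `observed`.
#' @examples
#' compare_predictions(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
#' @export
compare_predictions <- function(predicted, observed) {
  predicted <- as.numeric(predicted)
  observed <- as.numeric(observed)
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  n <- length(predicted)
  if (n < 2L) stop("at least two pairs are required", call. = FALSE)
  if (!all(is.finite(predicted)) || !all(is.finite(observed))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("correlation is undefined for zero-variance input", call. = FALSE)
  }
  if (n >= 3L) {
    ct <- stats::cor.test(predicted, observed, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    r <- stats::cor(predicted, observed)
    p <- NA_real_
  }
  structure(
    list(r = r,
         p_value = p,
         n = n, predicted = predicted, observed = observed),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (n = %d", x$r, x$n))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat(")\n")
  invisible(x)
}

#' Descriptive comparison of two chamber datasets
#'
#' Thin pass-through to standard tests for the report's descriptive block:
#' progeny totals of viable single dividing parents are compared with the
#' Mann-Whitney U test ([stats::wilcox.test()]) and quiescent proportions
#' with a chi-squared test ([stats::prop.test()]). Nothing bespoke — these
#' are conventional summaries, not part of the sampling model.
#'
#' @param obs_a,obs_b Chamber observation `data.frame`s.
#' @param type Parent cell type label present in both.
#' @return A list with `mann_whitney_p`, `chi_squared_p`, and the group
#'   summary statistics used.
#' @export
chamber_group_tests <- function(obs_a, obs_b, type) {
  totals <- function(obs) {
    types <- validate_chambers(obs)
    keep <- obs$parent_viable & obs$initial_cell_count == 1L & obs$parent_type == type
    rowSums(progeny_matrix(obs[keep, , drop = FALSE], types))
  }
  ta <- totals(obs_a)
  tb <- totals(obs_b)
  if (!length(ta) || !length(tb)) {
    stop(sprintf("both datasets need usable records of type '%s'", type), call. = FALSE)
  }
  mw <- suppressWarnings(stats::wilcox.test(ta[ta >= 1], tb[tb >= 1]))
  quies <- c(sum(ta == 0), sum(tb == 0))
  totn <- c(length(ta), length(tb))
  cs <- suppressWarnings(stats::prop.test(quies, totn))
  list(
    mann_whitney_p = mw$p.value,
    chi_squared_p = cs$p.value,
    quiescent = stats::setNames(quies / totn, c("a", "b")),
    mean_dividing = c(a = mean(ta[ta >= 1]), b = mean(tb[tb >= 1])),
    n = stats::setNames(totn, c("a", "b"))
  )
}
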