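#' Ranked series of non-negative values
#'
#' A `rank_series` holds ordered (rank, value) pairs, the common currency of
#' the rank-law tools: Zipf and meta-law curves, the inscribed-polygon
#' peripheral-area series, and empirical hollow curves all travel in this
#' container.
#'
#' @param ranks Strictly increasing positive integers.
#' @param values Non-negative finite values, one per rank.
#' @param label Short label used in printing and curve-comparison reports.
#'
#' @return An object of class `rank_series` with fields `label`, `ranks`
#'   and `values`.
#' @examples
#' rank_series(1:5, 1 / (1:5), label = "zipf")
#' @export
rank_series <- function(ranks, values, label = "series") {
  check_whole(ranks, "ranks")
  if (length(ranks) < 1L) stop_domain("a rank series needs at least one rank")
  if (any(ranks < 1L)) stop_domain("ranks must be >= 1")
  if (any(diff(ranks) <= 0)) stop_domain("ranks must be strictly increasing")
  if (!is.numeric(values) || length(values) != length(ranks)) {
    stop_domain("`values` must be numeric and the same length as `ranks`")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_domain("values must be finite and >= 0")
  }
  structure(
    list(label = as.character(label)[1L],
         ranks = as.integer(ranks),
         values = as.numeric(values)),
    class = "rank_series"
  )
}

#' @export
print.rank_series <- function(x, ...) {
  cat(sprintf("rank_series '%s' (%d ranks, %d..%d)\n", x$label,
              length(x$ranks), min(x$ranks), max(x$ranks)))
  print(utils::head(data.frame(rank = x$ranks, value = x$values), 12L))
  if (length(x$ranks) > 12L) cat("...\n")
  invisible(x)
}

#' @export
format.rank_series <- function(x, ...) {
  sprintf("rank_series '%s' [%d]", x$label, length(x$ranks))
}

as_rank_series <- function(x, label = "series") {
  if (inherits(x, "rank_series")) return(x)
  if (is.data.frame(x) && all(c("rank", "value") %in% names(x))) {
    return(rank_series(x$rank, x$value, label))
  }
  stop_domain("cannot interpret object of class %s as a rank series",
              paste(class(x), collapse = "/"))
}

#' Fit a spreadsheet-style trendline to a ranked series
#'
#' Least-squares fit on linearised axes, mirroring the power and exponential
#' trendlines of spreadsheet software: the power family regresses
#' `log(value)` on `log(rank)` (model `value = amplitude * rank^exponent`),
#' the exponential family regresses `log(value)` on `rank`
#' (model `value = amplitude * exp(rate * rank)`). `r_squared` is reported on
#' the transformed scale, as spreadsheet trendlines do.
#'
#' @param series A [rank_series()] (or a data frame with `rank`/`value`
#'   columns) with at least three strictly positive values.
#' @param family `"power"` or `"exponential"`.
#'
#' @return A `trendline_fit` with fields `family`, `amplitude`,
#'   `rate_or_exponent` and `r_squared`.
#' @examples
#' s <- rank_series(1:12, exp(-(1:12) / 3), "metalaw")
#' fit_trendline(s, "exponential")
#' @export
fit_trendline <- function(series, family = c("power", "exponential")) {
  family <- match.arg(family)
  series <- as_rank_series(series)
  if (length(series$values) < 3L) {
    stop_domain("trendline fitting needs at least 3 points, got %d",
                length(series$values))
  }
  if (any(series$values <= 0)) {
    stop_domain("trendline fitting needs strictly positive values (log transform)")
  }
  y <- log(series$values)
  x <- if (family == "power") log(series$ranks) else series$ranks
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(family = family,
         amplitude = unname(exp(stats::coef(fit)[1L])),
         rate_or_exponent = unname(stats::coef(fit)[2L]),
         r_squared = r2),
    class = "trendline_fit"
  )
}

#' Evaluate a fitted trendline at given ranks
#'
#' @param object A `trendline_fit` from [fit_trendline()].
#' @param ranks Ranks (>= 1) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.trendline_fit <- function(object, ranks, ...) {
  check_whole(ranks, "ranks")
  if (any(ranks < 1)) stop_domain("ranks must be >= 1")
  if (object$family == "power") {
    object$amplitude * ranks^object$rate_or_exponent
  } else {
    object$amplitude * exp(object$rate_or_exponent * ranks)
  }
}

#' @export
print.trendline_fit <- function(x, ...) {
  form <- if (x$family == "power") {
    sprintf("value = %.6g * rank^%.6g", x$amplitude, x$rate_or_exponent)
  } else {
    sprintf("value = %.6g * exp(%.6g * rank)", x$amplitude, x$rate_or_exponent)
  }
  cat(sprintf("trendline_fit (%s): %s  [r^2 = %.4f]\n", x$family, form, x$r_squared))
  invisible(x)
}

#' Compare a ranked series against the Zipf and meta-law curves
#'
#' Computes the root-mean-square error of the series against Zipf's law
#' (`1/r`) and against the exponential meta-law (`exp(-r/3)`) over the ranks
#' present in the series, and names the better-matching law.
#'
#' @param series A [rank_series()] whose ranks start at 1.
#' @return A `curve_comparison` with fields `reference_label`,
#'   `per_law_rmse` (named numeric vector) and `best_label`.
#' @examples
#' geo <- rank_series(1:12, c(0.67, 0.50, 0.37, 0.27, 0.20, 0.15,
#'                            0.11, 0.09, 0.07, 0.06, 0.05, 0.04), "geometric")
#' compare_to_laws(geo)
#' @export
compare_to_laws <- function(series) {
  series <- as_rank_series(series)
  if (length(series$ranks) == 0L) stop_domain("empty series")
  if (series$ranks[1L] != 1L) {
    stop_domain("curve comparison expects the series to start at rank 1, got %d",
                series$ranks[1L])
  }
  rmse <- function(pred) sqrt(mean((series$values - pred)^2))
  per_law <- c(zipf = rmse(zipf_value(series$ranks)),
               metalaw = rmse(metalaw_value(series$ranks)))
  structure(
    list(reference_label = series$label,
         per_law_rmse = per_law,
         best_label = names(per_law)[which.min(per_law)]),
    class = "curve_comparison"
  )
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf("curve_comparison for '%s'\n", x$reference_label))
  for (law in names(x$per_law_rmse)) {
    marker <- if (law == x$best_label) " <- best" else ""
    cat(sprintf("  RMSE vs %-8s %.6f%s\n", law, x$per_law_rmse[[law]], marker))
  }
  invisible(x)
}
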