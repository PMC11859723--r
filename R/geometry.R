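#' Area fractions of a regular polygon inscribed in a circle
#'
#' In the geometric model of balanced peripatric speciation, a circle is the
#' range of an ancestral species and the `n` equal segments between an
#' inscribed regular `n`-gon and the circle are the peripheral survival areas
#' available to `n` coexisting descendant species. `polygon_inside_fraction()`
#' is the polygon's area divided by the circle's,
#' `n * sin(2*pi/n) / (2*pi)`; `polygon_outside_fraction()` is its complement,
#' the total peripheral fraction left for descendants.
#'
#' The monogon (`n = 1`) and digon (`n = 2`) are degenerate (zero area);
#' values for those ranks can only be extrapolated, see
#' [outside_fraction_series()].
#'
#' @param n Number of polygon sides; whole numbers `>= 3` (vectorised).
#'
#' @return Fractions in (0, 1). The inside fraction increases strictly with
#'   `n` and tends to 1; the outside fraction decreases strictly to 0.
#' @examples
#' polygon_inside_fraction(4) # square: 2/pi
#' polygon_outside_fraction(3:8)
#' @export
polygon_inside_fraction <- function(n) {
  check_whole(n, "n")
  if (any(n < 3)) {
    stop_domain(paste0(
      "n must be >= 3: the monogon (n = 1) and digon (n = 2) are degenerate ",
      "polygons of zero area (singular ranks); use outside_fraction_series() ",
      "to extrapolate them"))
  }
  n * sin(2 * pi / n) / (2 * pi)
}

#' @rdname polygon_inside_fraction
#' @export
polygon_outside_fraction <- function(n) {
  1 - polygon_inside_fraction(n)
}

#' Monte-Carlo estimate of the peripheral area fraction
#'
#' Independent check on [polygon_outside_fraction()]: points are sampled
#' uniformly in the circumscribing circle and tested against the inscribed
#' regular `n`-gon; the outside fraction is estimated as the rejection rate.
#'
#' @param n Number of polygon sides (single whole number `>= 3`).
#' @param samples Number of uniform samples (`>= 1`).
#' @param seed RNG seed; the estimate is reproducible given (`n`, `samples`,
#'   `seed`).
#'
#' @return A single estimate of the outside fraction; unbiased, with binomial
#'   standard error `sqrt(p * (1 - p) / samples)`.
#' @examples
#' monte_carlo_outside_fraction(4, samples = 1e5, seed = 1)
#' @export
monte_carlo_outside_fraction <- function(n, samples, seed = 1L) {
  check_scalar_number(n, "n")
  check_whole(n, "n")
  check_scalar_number(samples, "samples")
  check_whole(samples, "samples")
  if (samples < 1) stop_domain("`samples` must be >= 1")
  polygon_outside_fraction(n) # domain check on n (>= 3)
  with_seed(seed, {
    theta <- stats::runif(samples, 0, 2 * pi)
    r <- sqrt(stats::runif(samples)) # uniform over the unit disk
    # A regular n-gon with vertices on the unit circle at angles 2*pi*k/n has
    # edge midlines at distance cos(pi/n); a point is inside iff its radius is
    # at most cos(pi/n) / cos(phi) where phi is the angular offset from the
    # nearest edge normal.
    phi <- (theta %% (2 * pi / n)) - pi / n
    inside <- r <= cos(pi / n) / cos(phi)
    mean(!inside)
  })
}

#' Ranked series of peripheral area fractions
#'
#' Builds the outside-area fraction series over polygon ranks. Ranks
#' `3..max_rank` carry the exact closed-form values; ranks 1 and 2 are
#' geometric singularities (monogon, digon) and are either omitted or filled
#' by extrapolating an exponential trendline fitted to the exact ranks --
#' the same spreadsheet-trendline device used to complete the published
#' rank table.
#'
#' @param max_rank Largest rank (number of polygon sides), `>= 3`.
#' @param low_rank_mode `"extrapolate"` to fill ranks 1-2 from the fitted
#'   exponential trendline, `"omit"` to start the series at rank 3.
#'
#' @return A [rank_series()]; strictly decreasing in rank.
#' @examples
#' outside_fraction_series(8, "omit")
#' outside_fraction_series(12)
#' @export
outside_fraction_series <- function(max_rank = 12L,
                                    low_rank_mode = c("extrapolate", "omit")) {
  low_rank_mode <- match.arg(low_rank_mode)
  check_scalar_number(max_rank, "max_rank")
  check_whole(max_rank, "max_rank")
  if (max_rank < 3) stop_domain("`max_rank` must be >= 3, got %g", max_rank)
  exact_ranks <- 3:max_rank
  exact <- polygon_outside_fraction(exact_ranks)
  if (low_rank_mode == "omit") {
    return(rank_series(exact_ranks, exact, "outside_fraction"))
  }
  if (max_rank < 5) {
    stop_domain("extrapolating ranks 1-2 needs at least 3 exact ranks (max_rank >= 5)")
  }
  fit <- fit_trendline(rank_series(exact_ranks, exact, "outside_fraction"),
                       family = "exponential")
  low <- predict(fit, 1:2)
  rank_series(1:max_rank, c(low, exact), "outside_fraction")
}

#' Rank-law value functions
#'
#' `zipf_value()` is Zipf's law `1 / r^a` (harmonic series for `a = 1`);
#' `zipf_mandelbrot_value()` is the Zipf-Mandelbrot variant
#' `1 / (r + shift)^exponent`, more flexible at small ranks and reducing to
#' Zipf at `shift = 0`; `metalaw_value()` is the exponential "meta-law"
#' `exp(-r/3)` reported for symbol frequencies across physics formulae and
#' used here as a comparison curve for the geometric speciation model.
#'
#' @param r Rank(s), `>= 1` (vectorised).
#' @param a Zipf exponent, default 1.
#' @param shift Zipf-Mandelbrot rank shift, `>= 0`.
#' @param exponent Zipf-Mandelbrot exponent, `> 0`.
#'
#' @return Numeric values; strictly decreasing in `r`.
#' @examples
#' zipf_value(5)           # 0.20
#' metalaw_value(3)        # exp(-1)
#' zipf_mandelbrot_value(1, shift = 1, exponent = 1) # 0.5
#' @export
zipf_value <- function(r, a = 1) {
  check_whole(r, "r")
  if (any(r < 1)) stop_domain("rank `r` must be >= 1")
  1 / r^a
}

#' @rdname zipf_value
#' @export
zipf_mandelbrot_value <- function(r, shift = 0, exponent = 1) {
  check_whole(r, "r")
  if (any(r < 1)) stop_domain("rank `r` must be >= 1")
  check_scalar_number(shift, "shift")
  check_scalar_number(exponent, "exponent")
  if (shift < 0) stop_domain("`shift` must be >= 0")
  if (exponent <= 0) stop_domain("`exponent` must be > 0")
  if (any(r + shift <= 0)) stop_domain("`r + shift` must be > 0")
  1 / (r + shift)^exponent
}

#' @rdname zipf_value
#' @export
metalaw_value <- function(r) {
  check_whole(r, "r")
  if (any(r < 1)) stop_domain("rank `r` must be >= 1")
  exp(-r / 3)
}

#' Rank comparison table of the geometric model and the rank laws
#'
#' Tabulates, for ranks `1..max_rank`, the peripheral (outside) area fraction
#' of the inscribed-polygon model in both its exact (`NA` below rank 3) and
#' trendline-extrapolated variants, Zipf's law `1/r`, and the meta-law
#' `exp(-r/3)`, each rounded half-up to two decimals as in the published
#' table.
#'
#' @param max_rank Largest rank, `>= 3`; default 12.
#' @return A data frame with columns `rank`, `outside_exact`,
#'   `outside_extrapolated`, `zipf`, `metalaw`.
#' @examples
#' build_table1()
#' @export
build_table1 <- function(max_rank = 12L) {
  check_scalar_number(max_rank, "max_rank")
  check_whole(max_rank, "max_rank")
  if (max_rank < 3) stop_domain("`max_rank` must be >= 3, got %g", max_rank)
  ranks <- seq_len(max_rank)
  extrap_values <- if (max_rank >= 5) {
    outside_fraction_series(max_rank, "extrapolate")$values
  } else {
    rep(NA_real_, max_rank) # too few exact ranks to fit the trendline
  }
  exact <- c(NA_real_, NA_real_, polygon_outside_fraction(3:max_rank))
  data.frame(
    rank = ranks,
    outside_exact = round_half_up(exact, 2L),
    outside_extrapolated = round_half_up(extrap_values, 2L),
    zipf = round_half_up(zipf_value(ranks), 2L),
    metalaw = round_half_up(metalaw_value(ranks), 2L)
  )
}
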