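#' Species-per-genus size distribution
#'
#' `size_histogram()` tallies genus sizes into a dense histogram over
#' `1..max(sizes)`; `fraction_at_most()` returns the fraction of genera
#' with at most `k` species (the mass below the classic five-species line
#' of hollow species-per-genus curves).
#'
#' @param sizes Positive integers, species per genus (may be empty).
#' @param dist A `genus_size_distribution` from `size_histogram()`.
#' @param k Size cutoff, `>= 1`; default 5.
#'
#' @return `size_histogram()`: an object of class
#'   `genus_size_distribution` with fields `sizes` and `histogram` (named
#'   integer vector, dense over `1..max`). `fraction_at_most()`: a fraction
#'   in `[0, 1]` (`NaN` for an empty distribution).
#' @examples
#' d <- size_histogram(c(1, 1, 2, 5))
#' d$histogram
#' fraction_at_most(d, 5)
#' @export
size_histogram <- function(sizes) {
  if (length(sizes) == 0L) {
    return(structure(list(sizes = integer(0L),
                          histogram = stats::setNames(integer(0L), character(0L))),
                     class = "genus_size_distribution"))
  }
  check_whole(sizes, "sizes")
  if (any(sizes < 1)) stop_domain("genus sizes must be >= 1")
  sizes <- as.integer(sizes)
  counts <- tabulate(sizes, nbins = max(sizes))
  structure(
    list(sizes = sizes,
         histogram = stats::setNames(as.integer(counts), seq_len(max(sizes)))),
    class = "genus_size_distribution"
  )
}

#' @rdname size_histogram
#' @export
fraction_at_most <- function(dist, k = 5L) {
  stopifnot(inherits(dist, "genus_size_distribution"))
  check_scalar_number(k, "k")
  check_whole(k, "k")
  if (k < 1) stop_domain("`k` must be >= 1")
  if (length(dist$sizes) == 0L) return(NaN)
  mean(dist$sizes <= k)
}

#' @export
print.genus_size_distribution <- function(x, ...) {
  cat(sprintf("genus_size_distribution: %d genera, sizes 1..%d\n",
              length(x$sizes), if (length(x$sizes)) max(x$sizes) else 0L))
  if (length(x$histogram)) print(x$histogram)
  invisible(x)
}

#' Classify a genus-size distribution as a hollow curve
#'
#' A hollow curve has its mass at small sizes and a long thin tail. The
#' operational test: the modal size is at most 2 and the counts never
#' increase from the mode outward (over sizes actually observed). Both the
#' power and the exponential trendline are fitted to count-versus-size
#' ([fit_trendline()]; zero-count sizes are excluded from the log
#' transform, or smoothed by adding 0.5 to every count when
#' `smoothing = TRUE`), and the family with the higher transformed-scale
#' r-squared is reported as `best_family`.
#'
#' @param dist A `genus_size_distribution` with at least 3 distinct
#'   observed sizes.
#' @param smoothing Add 0.5 to all counts (including zeros) before fitting
#'   instead of dropping zero-count sizes.
#'
#' @return A list with fields `is_hollow`, `modal_size`, `best_family`, and
#'   `fits` (named list of `trendline_fit`s).
#' @examples
#' classify_hollow(size_histogram(rep(1:6, times = c(60, 30, 15, 8, 4, 2))))
#' @export
classify_hollow <- function(dist, smoothing = FALSE) {
  stopifnot(inherits(dist, "genus_size_distribution"))
  counts <- dist$histogram
  support <- which(counts > 0L)
  if (length(support) < 3L) {
    stop_domain("hollow-curve classification needs >= 3 distinct sizes with non-zero counts, got %d",
                length(support))
  }
  modal_size <- support[which.max(counts[support])]
  after_mode <- support[support >= modal_size]
  is_hollow <- modal_size <= 2L && all(diff(counts[after_mode]) <= 0)

  fit_data <- if (smoothing) {
    rank_series(seq_along(counts), as.numeric(counts) + 0.5, "genus sizes")
  } else {
    rank_series(support, as.numeric(counts[support]), "genus sizes")
  }
  fits <- list(power = fit_trendline(fit_data, "power"),
               exponential = fit_trendline(fit_data, "exponential"))
  best_family <- names(fits)[which.max(vapply(fits, function(f) f$r_squared, numeric(1L)))]
  list(is_hollow = is_hollow, modal_size = as.integer(modal_size),
       best_family = best_family, fits = fits)
}

#' Fractal dimension of a speciation burst
#'
#' `log(total_species) / log(generators)`: with four descendant species
#' added to one generating ancestor the 5:4 ratio gives
#' `log(5)/log(4) = 1.16`, the Mandelbrot fractal dimension matching the
#' Pareto 80:20 distribution (80% of the species generated by 20% of the
#' source).
#'
#' @param total_species Total species after the burst (`> generators`).
#' @param generators Number of generating species (`>= 2`).
#' @return The fractal dimension (a real `> 1`).
#' @examples
#' fractal_dimension(5, 4)
#' @export
fractal_dimension <- function(total_species, generators) {
  check_scalar_number(total_species, "total_species")
  check_scalar_number(generators, "generators")
  check_whole(total_species, "total_species")
  check_whole(generators, "generators")
  if (generators < 2) stop_domain("`generators` must be >= 2")
  if (total_species < generators) {
    stop_domain("`total_species` (%g) must be >= `generators` (%g)",
                total_species, generators)
  }
  log(total_species) / log(generators)
}

#' Rule-of-five bracketing probability
#'
#' The probability that the population median of a continuous distribution
#' lies strictly between the minimum and maximum of `n` independent draws:
#' `1 - 2 * (1/2)^n`. For `n = 5` this is the classic 0.9375 -- five random
#' samples bracket the median better than 15 times out of 16.
#'
#' @param n Sample size, `>= 1`.
#' @return A probability in `[0, 1)`.
#' @examples
#' rule_of_five_probability(5) # 0.9375
#' @export
rule_of_five_probability <- function(n = 5L) {
  check_scalar_number(n, "n")
  check_whole(n, "n")
  if (n < 1) stop_domain("`n` must be >= 1")
  1 - 2 * (1 / 2)^n
}

#' Paraphyly records and their summary arithmetic
#'
#' `paraphyly_records()` validates a table of per-species molecular
#' paraphyly annotations: for each molecularly multiracial species, its
#' number of molecular races, whether it is paraphyletic on the cladogram
#' (exemplars nesting other named taxa -- read as an extant ancestor),
#' how many apophyletic species (descendants distal to the paraphyly) it
#' subtends, and the maximal node distance between its paraphyletic
#' exemplars. `paraphyly_summary()` computes the marginal arithmetic:
#' mean races per species, the paraphyletic fraction, apophyletic species
#' per paraphyletic species, and the mean node distance over paraphyletic
#' records. Means are stored at full precision; rounding happens only in
#' printing.
#'
#' @param records A data frame with columns `species_id`, `race_count`
#'   (`>= 1`), `paraphyletic` (logical), `apophyletic_count` (`>= 0`, must
#'   be 0 for non-paraphyletic records), `max_node_distance` (`>= 0`).
#'
#' @return `paraphyly_records()`: the validated data frame (class
#'   `paraphyly_records`). `paraphyly_summary()`: an object of class
#'   `paraphyly_summary` with fields `n_species`, `total_races`,
#'   `mean_races`, `n_paraphyletic_species`, `paraphyletic_fraction`,
#'   `n_apophyletic`, `apophyletic_per_paraphyletic`, `mean_node_distance`.
#' @examples
#' paraphyly_summary(moss_paraphyly_records())
#' @export
paraphyly_records <- function(records) {
  required <- c("species_id", "race_count", "paraphyletic",
                "apophyletic_count", "max_node_distance")
  if (!is.data.frame(records) || !all(required %in% names(records))) {
    stop_domain("`records` must be a data frame with columns: %s",
                paste(required, collapse = ", "))
  }
  if (nrow(records) == 0L) stop_domain("`records` must be non-empty")
  records$species_id <- as.character(records$species_id)
  records$paraphyletic <- as.logical(records$paraphyletic)
  check_whole(records$race_count, "race_count")
  check_whole(records$apophyletic_count, "apophyletic_count")
  check_whole(records$max_node_distance, "max_node_distance")
  if (any(records$race_count < 1)) stop_domain("`race_count` must be >= 1")
  if (any(records$apophyletic_count < 0)) stop_domain("`apophyletic_count` must be >= 0")
  if (any(records$max_node_distance < 0)) stop_domain("`max_node_distance` must be >= 0")
  bad <- !records$paraphyletic & records$apophyletic_count > 0
  if (any(bad)) {
    stop_domain("non-paraphyletic record(s) with apophyletic species: %s",
                paste(records$species_id[bad], collapse = ", "))
  }
  class(records) <- c("paraphyly_records", "data.frame")
  records
}

#' @rdname paraphyly_records
#' @export
paraphyly_summary <- function(records) {
  records <- paraphyly_records(as.data.frame(records))
  n_par <- sum(records$paraphyletic)
  n_apo <- sum(records$apophyletic_count)
  if (n_par == 0L && n_apo > 0L) {
    stop_domain("inconsistent records: %d apophyletic species but no paraphyletic species", n_apo)
  }
  structure(
    list(n_species = nrow(records),
         total_races = sum(records$race_count),
         mean_races = sum(records$race_count) / nrow(records),
         n_paraphyletic_species = n_par,
         paraphyletic_fraction = n_par / nrow(records),
         n_apophyletic = n_apo,
         apophyletic_per_paraphyletic = if (n_par > 0L) n_apo / n_par else NA_real_,
         mean_node_distance = if (n_par > 0L) {
           mean(records$max_node_distance[records$paraphyletic])
         } else {
           NA_real_
         }),
    class = "paraphyly_summary"
  )
}

#' @export
print.paraphyly_summary <- function(x, ...) {
  cat(sprintf("paraphyly summary: %d species, %d molecular races (mean %.1f)\n",
              x$n_species, x$total_races, x$mean_races))
  cat(sprintf("  paraphyletic species: %d (fraction %.2f)\n",
              x$n_paraphyletic_species, x$paraphyletic_fraction))
  if (!is.na(x$apophyletic_per_paraphyletic)) {
    cat(sprintf("  apophyletic species: %d (%.1f per paraphyletic species)\n",
                x$n_apophyletic, x$apophyletic_per_paraphyletic))
    cat(sprintf("  mean max node distance among paraphyletic exemplars: %.2f\n",
                x$mean_node_distance))
  }
  invisible(x)
}

#' Synthetic record set reproducing published moss paraphyly counts
#'
#' A deterministic, synthetic set of 46 molecularly multiracial moss
#' species records whose marginal totals match a published compilation for
#' the family Pottiaceae: 208 molecular races over 46 species (mean 4.52),
#' 22 paraphyletic species, 79 apophyletic species (3.59 per paraphyletic
#' species), and 133 total maximal node distances. The per-species values
#' are an even synthetic split of those totals, not the original
#' per-species data (which are not published).
#'
#' @return A `paraphyly_records` data frame of 46 rows.
#' @examples
#' paraphyly_summary(moss_paraphyly_records())
#' @export
moss_paraphyly_records <- function() {
  n <- 46L
  # race counts summing to 208: 24 species with 5 races, 22 with 4
  races <- c(rep(5L, 24L), rep(4L, 22L))
  paraphyletic <- c(rep(FALSE, 24L), rep(TRUE, 22L))
  # 79 apophyletic species over the 22 paraphyletic ones: 13 x 4 + 9 x 3
  apophyletic <- c(rep(0L, 24L), rep(4L, 13L), rep(3L, 9L))
  # 133 total nodes distributed over the 22 paraphyletic species: 1 x 7 + 21 x 6
  nodes <- c(rep(0L, 24L), 7L, rep(6L, 21L))
  paraphyly_records(data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    race_count = races,
    paraphyletic = paraphyletic,
    apophyletic_count = apophyletic,
    max_node_distance = nodes
  ))
}
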