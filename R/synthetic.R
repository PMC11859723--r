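#' Configuration for the peripatric-radiation simulator
#'
#' Collects and validates the parameters of [simulate_peripatric()]. The
#' defaults encode the study conditions of the geometric speciation model:
#' at most four immediate descendants per ancestor (rule of four), novon
#' sizes averaging about four traits with a two-trait floor, meta-law
#' survival odds for successive descendants, mild extinction thinning, and
#' a radiation of 200 founder genera followed for 20 epochs.
#'
#' @param n_founders Number of founding ancestral species (`>= 1`).
#' @param max_descendants Hard cap on coexisting immediate descendants per
#'   ancestor; default 4.
#' @param novon_size_mean Mean novon size in traits; default 4.
#' @param novon_size_min Minimum novon size; `>= 2` (the smallest trait set
#'   that distinguishes a species).
#' @param survival_mode How the acceptance probability of the k-th
#'   coexisting descendant decays: `"metalaw"` uses `exp(-k/3)`;
#'   `"geometric_area"` uses the per-descendant peripheral polygon area
#'   `polygon_outside_fraction(k + 2) / k`, normalised so the first
#'   descendant's probability is the full triangle value; `"uniform"` is a
#'   constant 0.5.
#' @param extinction_rate Per-species, per-epoch extinction probability.
#' @param n_epochs Number of epochs to simulate.
#' @param secondary_prob Probability that a planted matrix descendant
#'   carries a secondary descendant (used when emitting matrices).
#' @param founding_prob Per-epoch probability that an established
#'   descendant disperses and founds a new genus of its own.
#' @param seed RNG seed; every simulator output is reproducible under it.
#'
#' @return A validated list of class `simulation_config`.
#' @examples
#' simulation_config(n_founders = 10, n_epochs = 5, seed = 42)
#' @export
simulation_config <- function(n_founders = 200L,
                              max_descendants = 4L,
                              novon_size_mean = 4,
                              novon_size_min = 2L,
                              survival_mode = c("metalaw", "geometric_area", "uniform"),
                              extinction_rate = 0.05,
                              n_epochs = 20L,
                              secondary_prob = 0.05,
                              founding_prob = 0.1,
                              seed = 1L) {
  survival_mode <- match.arg(survival_mode)
  for (nm in c("n_founders", "max_descendants", "novon_size_min", "n_epochs", "seed")) {
    check_scalar_number(get(nm), nm)
    check_whole(get(nm), nm)
  }
  check_scalar_number(novon_size_mean, "novon_size_mean")
  if (n_founders < 1) stop_domain("`n_founders` must be >= 1")
  if (max_descendants < 1) stop_domain("`max_descendants` must be >= 1")
  if (novon_size_min < 2) stop_domain("`novon_size_min` must be >= 2")
  if (novon_size_mean < novon_size_min) {
    stop_domain("`novon_size_mean` must be >= `novon_size_min`")
  }
  if (n_epochs < 0) stop_domain("`n_epochs` must be >= 0")
  for (nm in c("extinction_rate", "secondary_prob", "founding_prob")) {
    p <- get(nm)
    check_scalar_number(p, nm)
    if (p < 0 || p > 1) stop_domain("`%s` must be a probability in [0, 1]", nm)
  }
  structure(
    list(n_founders = as.integer(n_founders),
         max_descendants = as.integer(max_descendants),
         novon_size_mean = as.numeric(novon_size_mean),
         novon_size_min = as.integer(novon_size_min),
         survival_mode = survival_mode,
         extinction_rate = extinction_rate,
         n_epochs = as.integer(n_epochs),
         secondary_prob = secondary_prob,
         founding_prob = founding_prob,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Acceptance probability for establishing the k-th coexisting descendant.
descendant_acceptance <- function(k, mode) {
  switch(mode,
         metalaw = exp(-k / 3),
         geometric_area = (polygon_outside_fraction(k + 2L) / k) /
           polygon_outside_fraction(3L),
         uniform = rep(0.5, length(k)))
}

#' Generate a planted trait matrix with known ground truth
#'
#' Builds the idealised microgenus data structure the ancestor-descendant
#' protocol assumes: an all-plesiomorphic outgroup (`OG`), an ancestor
#' (`ANC`) carrying its own novon, immediate descendants (`D1`, `D2`, ...)
#' each carrying the ancestor's full states plus a disjoint novon of their
#' own, and optional secondary descendants (`S1`, ...) that carry their
#' parent descendant's novon plus their own but revert at least one
#' ancestor-novon trait to the plesiomorphic state (so they do not carry
#' the ancestor's novon entire). Independent per-cell state flips at
#' `noise_rate` are then applied to the ingroup rows (the outgroup row
#' defines polarity and stays clean).
#'
#' @param n_descendants Number of immediate descendants (`>= 0`).
#' @param novon_size Traits per novon (`>= 2`).
#' @param noise_rate Per-cell flip probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param n_secondary Number of secondary descendants (`<= n_descendants`
#'   unless 0; parents are assigned round-robin `D1, D2, ...`).
#' @param n_traits Total trait budget; default exactly fits the disjoint
#'   novons. An explicit budget too small for them is an error.
#'
#' @return A list with `matrix` (a [trait_matrix()]) and `truth` (class
#'   `planted_truth`: `ancestor_id`, `descendant_ids`, `secondary_map`,
#'   `novons` -- the planted trait-id sets).
#' @examples
#' pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4, seed = 1)
#' pm$truth$ancestor_id
#' @export
generate_planted_matrix <- function(n_descendants, novon_size = 4L,
                                    noise_rate = 0, seed = 1L,
                                    n_secondary = 0L, n_traits = NULL) {
  check_scalar_number(n_descendants, "n_descendants")
  check_whole(n_descendants, "n_descendants")
  if (n_descendants < 0) stop_domain("`n_descendants` must be >= 0")
  check_scalar_number(novon_size, "novon_size")
  check_whole(novon_size, "novon_size")
  if (novon_size < 2) stop_domain("`novon_size` must be >= 2 (species minimum)")
  check_scalar_number(noise_rate, "noise_rate")
  if (noise_rate < 0 || noise_rate > 1) stop_domain("`noise_rate` must be in [0, 1]")
  check_scalar_number(n_secondary, "n_secondary")
  check_whole(n_secondary, "n_secondary")
  if (n_secondary < 0) stop_domain("`n_secondary` must be >= 0")
  if (n_secondary > 0 && n_descendants == 0) {
    stop_domain("secondary descendants need at least one immediate descendant")
  }

  n_novons <- 1L + n_descendants + n_secondary
  needed <- novon_size * n_novons
  if (is.null(n_traits)) n_traits <- needed
  check_scalar_number(n_traits, "n_traits")
  check_whole(n_traits, "n_traits")
  if (n_traits < needed) {
    stop_domain("trait budget too small for disjoint novons: need %d traits, got %d",
                needed, n_traits)
  }

  trait_ids <- sprintf("t%03d", seq_len(n_traits))
  desc_ids <- if (n_descendants) sprintf("D%d", seq_len(n_descendants)) else character(0L)
  sec_ids <- if (n_secondary) sprintf("S%d", seq_len(n_secondary)) else character(0L)
  species <- c("OG", "ANC", desc_ids, sec_ids)

  # carve disjoint novon blocks off the front of the trait list
  blocks <- split(trait_ids[seq_len(needed)],
                  rep(seq_len(n_novons), each = novon_size))
  novons <- stats::setNames(blocks, c("ANC", desc_ids, sec_ids))

  states <- matrix(0L, nrow = length(species), ncol = n_traits,
                   dimnames = list(species, trait_ids))
  states["ANC", novons[["ANC"]]] <- 1L
  for (d in desc_ids) {
    states[d, ] <- states["ANC", ]
    states[d, novons[[d]]] <- 1L
  }
  secondary_map <- character(0L)
  with_seed(seed, {
    for (i in seq_len(n_secondary)) {
      s <- sec_ids[i]
      parent <- desc_ids[((i - 1L) %% n_descendants) + 1L]
      secondary_map[s] <- parent
      states[s, ] <- states[parent, ]
      states[s, novons[[s]]] <- 1L
      # revert part of the ancestor novon: the secondary does not carry it entire
      revert <- sample(novons[["ANC"]], size = max(1L, novon_size %/% 2L))
      states[s, revert] <- 0L
    }
    if (noise_rate > 0 && length(species) > 1L) {
      ingroup <- setdiff(species, "OG")
      flips <- matrix(stats::runif(length(ingroup) * n_traits) < noise_rate,
                      nrow = length(ingroup))
      block <- states[ingroup, , drop = FALSE]
      block[flips] <- 1L - block[flips]
      states[ingroup, ] <- block
    }
  })

  truth <- structure(
    list(ancestor_id = "ANC",
         descendant_ids = desc_ids,
         secondary_map = secondary_map,
         novons = novons),
    class = "planted_truth"
  )
  list(matrix = trait_matrix(states, "OG"), truth = truth)
}

#' Simulate a peripatric radiation
#'
#' A discrete-epoch formalisation of balanced peripatric radiation. Each
#' epoch: (1) every living species goes extinct independently with
#' probability `extinction_rate`; (2) every genus with a living ancestor
#' attempts one new descendant, accepted with a probability that decays
#' with the number already coexisting (see
#' [simulation_config()]`$survival_mode`) and refused outright beyond
#' `max_descendants` (overflow extinction of the propagule); (3) each
#' established descendant disperses with probability `founding_prob`,
#' leaving its genus to found a new one as its ancestor. Genus sizes are
#' counted as living species per genus (ancestor plus surviving immediate
#' descendants), so sizes never exceed `max_descendants + 1` and the size
#' sample is hollow: many young small genera, few saturated ones.
#'
#' @param config A [simulation_config()].
#' @param emit_matrices Also generate one planted trait matrix per
#'   surviving genus (novon sizes drawn as `novon_size_min` plus a Poisson
#'   excess with mean `novon_size_mean - novon_size_min`).
#'
#' @return A list with `genera` (data frame: `genus_id`, `founded_epoch`,
#'   `ancestor_alive`, `n_descendants`, `size`), `sizes` (integer vector of
#'   living-genus sizes), and `matrices` (list of planted matrices, or
#'   `NULL`). Fully reproducible under `config$seed`.
#' @examples
#' sim <- simulate_peripatric(simulation_config(n_founders = 20, n_epochs = 5,
#'                                              seed = 7))
#' size_histogram(sim$sizes)
#' @export
simulate_peripatric <- function(config, emit_matrices = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    genera <- data.frame(genus_id = seq_len(config$n_founders),
                         founded_epoch = 0L,
                         ancestor_alive = TRUE,
                         n_descendants = 0L)
    # descendants tracked individually: genus id and age in epochs
    desc <- data.frame(genus = integer(0L), age = integer(0L))

    for (epoch in seq_len(config$n_epochs)) {
      # extinction sweep
      if (config$extinction_rate > 0) {
        anc_dies <- stats::runif(nrow(genera)) < config$extinction_rate
        genera$ancestor_alive <- genera$ancestor_alive & !anc_dies
        if (nrow(desc)) {
          keep <- stats::runif(nrow(desc)) >= config$extinction_rate
          desc <- desc[keep, , drop = FALSE]
        }
      }
      counts <- tabulate(desc$genus, nbins = nrow(genera))
      # one speciation attempt per genus with a living ancestor
      attempting <- which(genera$ancestor_alive)
      for (g in attempting) {
        k <- counts[g] + 1L
        if (k > config$max_descendants) next # overflow extinction
        if (stats::runif(1L) < descendant_acceptance(k, config$survival_mode)) {
          desc <- rbind(desc, data.frame(genus = g, age = 0L))
          counts[g] <- k
        }
      }
      # established descendants may disperse and found new genera
      if (nrow(desc)) {
        established <- desc$age >= 1L
        founds <- established & stats::runif(nrow(desc)) < config$founding_prob
        if (any(founds)) {
          n_new <- sum(founds)
          genera <- rbind(genera, data.frame(
            genus_id = seq.int(nrow(genera) + 1L, length.out = n_new),
            founded_epoch = epoch,
            ancestor_alive = TRUE,
            n_descendants = 0L))
          desc <- desc[!founds, , drop = FALSE]
        }
        desc$age <- desc$age + 1L
      }
    }

    genera$n_descendants <- tabulate(desc$genus, nbins = nrow(genera))
    genera$size <- genera$n_descendants + as.integer(genera$ancestor_alive)
    sizes <- genera$size[genera$size > 0L]

    matrices <- NULL
    if (emit_matrices) {
      living <- which(genera$size > 0L)
      matrices <- lapply(living, function(g) {
        nv <- config$novon_size_min +
          stats::rpois(1L, max(0, config$novon_size_mean - config$novon_size_min))
        n_sec <- stats::rbinom(1L, size = genera$n_descendants[g],
                               prob = config$secondary_prob)
        generate_planted_matrix(
          n_descendants = genera$n_descendants[g],
          novon_size = nv,
          noise_rate = 0,
          seed = stats::runif(1L, 1, .Machine$integer.max - 1),
          n_secondary = n_sec)
      })
      names(matrices) <- sprintf("genus%04d", genera$genus_id[living])
    }

    list(genera = genera, sizes = as.integer(sizes), matrices = matrices)
  })
}

#' Genus-size sample from a peripatric simulation
#'
#' Convenience adapter: runs [simulate_peripatric()] and returns only the
#' genus sizes (living species per genus), ready for [size_histogram()].
#'
#' @param config A [simulation_config()].
#' @return Integer vector of genus sizes, each `>= 1`.
#' @examples
#' genus_size_sample(simulation_config(n_founders = 20, n_epochs = 5, seed = 7))
#' @export
genus_size_sample <- function(config) {
  simulate_peripatric(config)$sizes
}
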