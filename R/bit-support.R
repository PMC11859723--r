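#' Shannon information in bits
#'
#' `shannon_bits()` converts a probability into self-information,
#' `-log2(p)`: deciding between two equally likely trait-change directions
#' (`p = 1/2`) yields exactly one bit. Under the one-bit-per-new-trait
#' convention each trait in a novon contributes one bit of support for an
#' ancestor-descendant transition, and `accumulate_bits()` adds bits along a
#' chain of speciation events (bits are additive, and the sum is
#' order-invariant).
#'
#' @param p Probability in (0, 1] (vectorised).
#' @param novon_sizes Non-negative bit counts (typically novon sizes), any
#'   length including zero.
#'
#' @return `shannon_bits()`: bits `>= 0`; `accumulate_bits()`: their sum.
#' @examples
#' shannon_bits(1 / 2)      # 1 bit
#' accumulate_bits(c(4, 3, 4))
#' @export
shannon_bits <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p))) stop_domain("`p` must be numeric and finite")
  if (any(p <= 0) || any(p > 1)) {
    stop_domain("`p` must lie in (0, 1]; got values outside the domain")
  }
  -log2(p)
}

#' @rdname shannon_bits
#' @export
accumulate_bits <- function(novon_sizes) {
  if (length(novon_sizes) == 0L) return(0)
  if (!is.numeric(novon_sizes) || any(!is.finite(novon_sizes))) {
    stop_domain("`novon_sizes` must be numeric and finite")
  }
  if (any(novon_sizes < 0)) stop_domain("novon sizes must be >= 0")
  sum(novon_sizes)
}

#' Convert accumulated bits to a Bayesian posterior probability
#'
#' Bits map to odds of `2^b : 1` for the supported ancestor-descendant
#' arrangement against its alternative, hence a posterior of
#' `2^b / (2^b + 1)`. Zero bits is even odds (0.5); each additional bit
#' doubles the odds; the posterior and the probability against sum to 1.
#'
#' @param b Bits, `>= 0` (vectorised; fractional bits allowed).
#' @return Posterior probabilities in `[0.5, 1)`, strictly increasing in `b`.
#' @examples
#' bits_to_posterior(c(0, 1, 4)) # 0.5, 2/3, 16/17
#' @export
bits_to_posterior <- function(b) {
  if (!is.numeric(b) || any(!is.finite(b))) stop_domain("`b` must be numeric and finite")
  if (any(b < 0)) stop_domain("bits must be >= 0")
  1 / (1 + 2^(-b)) # stable for large b
}

#' Sequential-Bayes support along an ancestor chain
#'
#' Sums the novon-size bit annotations along the unique directed chain
#' connecting two species in a caulogram (in whichever orientation the chain
#' runs: support reads both backwards and forwards along the chain) and
#' converts the total to a posterior via [bits_to_posterior()].
#'
#' @param caulogram A [caulogram()].
#' @param from_species,to_species Species ids present in the caulogram.
#'
#' @return A list with fields `from`, `to`, `bits` and `posterior`. The
#'   result is symmetric under swapping the endpoints; `from == to` gives 0
#'   bits (posterior 0.5).
#' @examples
#' pm <- generate_planted_matrix(n_descendants = 2, novon_size = 4, seed = 1)
#' cg <- assemble_caulogram(pm$matrix, groups = list(g1 = setdiff(
#'   pm$matrix$species_ids, pm$matrix$outgroup_id)))
#' path_support(cg, "D1", "D2")
#' @export
path_support <- function(caulogram, from_species, to_species) {
  if (!inherits(caulogram, "caulogram")) stop_domain("`caulogram` must be a caulogram object")
  nodes <- caulogram$nodes
  for (sp in c(from_species, to_species)) {
    if (!sp %in% nodes) stop_domain("species '%s' is not in the caulogram", sp)
  }
  res <- chain_bits(caulogram, from_species, to_species)
  if (is.null(res)) res <- chain_bits(caulogram, to_species, from_species)
  if (is.null(res)) {
    stop_domain("no directed ancestor chain connects '%s' and '%s'",
                from_species, to_species)
  }
  list(from = from_species, to = to_species,
       bits = res, posterior = bits_to_posterior(res))
}

# Walk parent links from `descendant` up towards `ancestor`; NULL if the
# chain never reaches it. A walk longer than the node count means a cycle.
chain_bits <- function(caulogram, ancestor, descendant) {
  parent <- stats::setNames(caulogram$edges$ancestor, caulogram$edges$descendant)
  bits <- stats::setNames(caulogram$edges$bits, caulogram$edges$descendant)
  total <- 0
  cur <- descendant
  steps <- 0L
  while (cur != ancestor) {
    steps <- steps + 1L
    if (steps > length(caulogram$nodes)) {
      stop_domain("invalid caulogram: cycle detected while tracing ancestry")
    }
    if (!cur %in% names(parent)) return(NULL) # reached a root
    total <- total + bits[[cur]]
    cur <- parent[[cur]]
  }
  total
}

#' Flag an extinction gap on a caulogram edge
#'
#' Under the rule of four a speciation event carries about four new traits
#' (four bits). A much larger bit distance between two contiguous ancestral
#' species implies one or more extinct intermediates: a missing ancestor
#' accounts for its own novon plus the novon of the next step, about
#' `2 * typical_novon` bits each. An edge is flagged once its bits reach
#' `threshold`, and the number of missing intermediates is estimated as
#' `round(edge_bits / (2 * typical_novon))`. The published worked instance is
#' an 11-trait spate flagging one missing species (probably the ancestor of
#' an extinct genus).
#'
#' @param edge_bits Bit annotation of the edge, `>= 0`.
#' @param typical_novon Typical novon size in traits, `>= 2`; default 4.
#' @param threshold Bits at which an edge is flagged; default 9
#'   (just above two typical novons).
#'
#' @return A list with fields `flagged` (logical) and
#'   `estimated_missing_intermediates` (integer, 0 when not flagged).
#' @examples
#' detect_extinction_gap(11) # flagged, 1 missing intermediate
#' detect_extinction_gap(4)  # a normal speciation step
#' @export
detect_extinction_gap <- function(edge_bits, typical_novon = 4L, threshold = 9) {
  check_scalar_number(edge_bits, "edge_bits")
  if (edge_bits < 0) stop_domain("`edge_bits` must be >= 0")
  check_scalar_number(typical_novon, "typical_novon")
  check_whole(typical_novon, "typical_novon")
  if (typical_novon < 2) stop_domain("`typical_novon` must be >= 2")
  check_scalar_number(threshold, "threshold")
  flagged <- edge_bits >= threshold
  missing <- if (flagged) {
    as.integer(round(edge_bits / (2 * typical_novon)))
  } else {
    0L
  }
  list(flagged = flagged, estimated_missing_intermediates = missing)
}
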