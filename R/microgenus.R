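#' Identify the ancestral species of a minimally monophyletic group
#'
#' The ancestral species of a microgenus is scored by two criteria read off
#' the polarised matrix: (i) outgroup similarity, the fraction of matching
#' non-missing states against the outgroup, and (ii) generality, the
#' negated apomorphy count (fewer derived states = more generalist). Each
#' candidate is ranked under both criteria and the winner minimises the rank
#' sum; ties break by fewer autapomorphies (derived states unique to the
#' candidate within the group), then by species id. The result is
#' deterministic and invariant to species row order.
#'
#' @param matrix A [trait_matrix()].
#' @param group Character vector of candidate species ids (non-empty,
#'   excluding the outgroup).
#'
#' @return A list with fields `ancestor_id`, `criteria_agree` (did both
#'   criteria pick the same species?) and `diagnostics`, a data frame of
#'   per-candidate scores and ranks.
#' @examples
#' pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4, seed = 1)
#' identify_ancestor(pm$matrix, setdiff(pm$matrix$species_ids, "OG"))$ancestor_id
#' @export
identify_ancestor <- function(matrix, group) {
  stopifnot(inherits(matrix, "trait_matrix"))
  group <- validate_group(matrix, group)
  og <- matrix$states[matrix$outgroup_id, ]
  apo <- polarize(matrix)[group, , drop = FALSE]

  similarity <- vapply(group, function(sp) {
    s <- matrix$states[sp, ]
    usable <- !is.na(s)
    if (!any(usable)) return(NA_real_)
    mean(s[usable] == og[usable])
  }, numeric(1L))
  apomorphies <- rowSums(apo, na.rm = TRUE)
  # autapomorphies: derived states held by this candidate and no other member
  derived_counts <- colSums(apo == 1L, na.rm = TRUE)
  autapomorphies <- vapply(group, function(sp) {
    mine <- which(apo[sp, ] == 1L)
    sum(derived_counts[mine] == 1L)
  }, numeric(1L))

  rank_similarity <- rank(-similarity, ties.method = "min")
  rank_generality <- rank(apomorphies, ties.method = "min")
  rank_sum <- rank_similarity + rank_generality
  ord <- order(rank_sum, autapomorphies, group)
  diagnostics <- data.frame(
    species_id = group,
    outgroup_similarity = similarity,
    apomorphies = as.integer(apomorphies),
    autapomorphies = as.integer(autapomorphies),
    rank_similarity = as.integer(rank_similarity),
    rank_generality = as.integer(rank_generality),
    rank_sum = as.integer(rank_sum),
    row.names = NULL
  )[ord, ]
  rownames(diagnostics) <- NULL
  list(
    ancestor_id = group[ord[1L]],
    criteria_agree = group[which.min(rank_similarity)] == group[which.min(rank_generality)],
    diagnostics = diagnostics
  )
}

validate_group <- function(matrix, group) {
  if (length(group) == 0L) stop_domain("`group` must contain at least one species")
  group <- as.character(group)
  unknown <- setdiff(group, matrix$species_ids)
  if (length(unknown)) {
    stop_domain("group members not in the matrix: %s", paste(unknown, collapse = ", "))
  }
  if (matrix$outgroup_id %in% group) {
    stop_domain("the outgroup ('%s') cannot be a group member", matrix$outgroup_id)
  }
  sort(group)
}

#' Extract a species' novon relative to its ancestor
#'
#' The novon is the set of newly evolved traits a species acquired at its
#' origin: traits where the species holds a derived (non-outgroup) state
#' that also differs from the ancestor's state. A valid species' novon has
#' at least two traits; sizes below that are returned with a warning from
#' the assembly functions.
#'
#' @param matrix A [trait_matrix()].
#' @param species_id,ancestor_id Distinct species ids in the matrix.
#'
#' @return An object of class `novon`: list with `species_id` and `traits`,
#'   a data frame of (`trait_id`, `state`) pairs. `novon_size()` returns the
#'   number of traits in it.
#' @examples
#' pm <- generate_planted_matrix(n_descendants = 2, novon_size = 4, seed = 1)
#' extract_novon(pm$matrix, "D1", "ANC")
#' @export
extract_novon <- function(matrix, species_id, ancestor_id) {
  stopifnot(inherits(matrix, "trait_matrix"))
  for (sp in c(species_id, ancestor_id)) {
    if (!sp %in% matrix$species_ids) stop_domain("species '%s' not in the matrix", sp)
  }
  if (identical(species_id, ancestor_id)) {
    stop_domain("a species has no novon relative to itself ('%s')", species_id)
  }
  s <- matrix$states[species_id, ]
  a <- matrix$states[ancestor_id, ]
  og <- matrix$states[matrix$outgroup_id, ]
  derived <- !is.na(s) & !is.na(og) & s != og
  new_vs_ancestor <- derived & (is.na(a) | s != a)
  idx <- which(new_vs_ancestor)
  structure(
    list(species_id = species_id,
         traits = data.frame(trait_id = matrix$trait_ids[idx],
                             state = unname(s[idx]),
                             row.names = NULL)),
    class = "novon"
  )
}

#' @rdname extract_novon
#' @param novon A `novon` object.
#' @export
novon_size <- function(novon) {
  stopifnot(inherits(novon, "novon"))
  nrow(novon$traits)
}

#' @export
print.novon <- function(x, ...) {
  cat(sprintf("novon of '%s': %d trait(s)\n", x$species_id, nrow(x$traits)))
  if (nrow(x$traits)) {
    cat(" ", paste(sprintf("%s=%d", x$traits$trait_id, x$traits$state), collapse = ", "), "\n")
  }
  invisible(x)
}

# (trait_id, state) pairs of all derived states of a species, as "id=state"
# keys for set comparisons.
derived_keys <- function(matrix, species_id) {
  s <- matrix$states[species_id, ]
  og <- matrix$states[matrix$outgroup_id, ]
  idx <- which(!is.na(s) & !is.na(og) & s != og)
  sprintf("%s=%d", matrix$trait_ids[idx], s[idx])
}

novon_keys <- function(novon) {
  sprintf("%s=%d", novon$traits$trait_id, novon$traits$state)
}

#' Assemble a minimally monophyletic group (microgenus)
#'
#' Runs the ancestor-descendant protocol within one group: the ancestral
#' species is chosen by [identify_ancestor()]; every other member that
#' carries the ancestor's full derived trait set (the ancestor's novon is
#' inherited entire by each immediate descendant) becomes an immediate
#' descendant; a member that instead carries some immediate descendant's
#' own novon entire is classified as a secondary descendant attributed to
#' that descendant. A member carrying neither is an orphan and raises an
#' error. Traits missing in more than half the group are flagged in the
#' validation report, and novons below the two-trait species minimum draw a
#' warning.
#'
#' @param matrix A [trait_matrix()].
#' @param group Character vector of member species ids (>= 1, excluding the
#'   outgroup).
#'
#' @return An object of class `microgenus`: fields `ancestor_id`,
#'   `descendant_ids`, `secondary_descendant_ids` (named by their parent
#'   descendant), `ancestor_novon`, `descendant_novons`, `secondary_novons`
#'   and `validation`.
#' @examples
#' pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4, seed = 1)
#' assemble_microgenus(pm$matrix, setdiff(pm$matrix$species_ids, "OG"))
#' @export
assemble_microgenus <- function(matrix, group) {
  stopifnot(inherits(matrix, "trait_matrix"))
  group <- validate_group(matrix, group)
  anc <- identify_ancestor(matrix, group)
  ancestor_id <- anc$ancestor_id
  others <- setdiff(group, ancestor_id)

  ancestor_novon <- extract_novon(matrix, ancestor_id, matrix$outgroup_id)
  anc_keys <- novon_keys(ancestor_novon)

  derived <- lapply(stats::setNames(others, others),
                    function(sp) derived_keys(matrix, sp))
  immediate <- others[vapply(others, function(sp) all(anc_keys %in% derived[[sp]]),
                             logical(1L))]
  descendant_novons <- lapply(stats::setNames(immediate, immediate),
                              function(sp) extract_novon(matrix, sp, ancestor_id))

  leftovers <- setdiff(others, immediate)
  secondary <- character(0L)
  secondary_novons <- list()
  for (sp in leftovers) {
    carrier <- NULL
    best_overlap <- -1L
    for (d in immediate) {
      dn <- novon_keys(descendant_novons[[d]])
      if (length(dn) && all(dn %in% derived[[sp]])) {
        overlap <- length(dn)
        if (overlap > best_overlap) {
          best_overlap <- overlap
          carrier <- d
        }
      }
    }
    if (is.null(carrier)) {
      stop_domain(paste0(
        "orphan species in group: '%s' carries neither the ancestor's ('%s') ",
        "full novon nor any immediate descendant's novon"), sp, ancestor_id)
    }
    secondary <- c(secondary, stats::setNames(sp, carrier))
    secondary_novons[[sp]] <- extract_novon(matrix, sp, carrier)
  }

  all_novons <- c(list(ancestor_novon), descendant_novons, secondary_novons)
  small <- vapply(all_novons, novon_size, integer(1L)) < 2L
  if (any(small)) {
    ids <- vapply(all_novons[small], function(nv) nv$species_id, character(1L))
    warning(sprintf(
      "novon below the 2-trait species minimum for: %s (2 is the smallest set that distinguishes a species)",
      paste(ids, collapse = ", ")), call. = FALSE)
  }

  member_rows <- matrix$states[group, , drop = FALSE]
  missing_frac <- colMeans(is.na(member_rows))
  structure(
    list(ancestor_id = ancestor_id,
         descendant_ids = immediate,
         secondary_descendant_ids = secondary,
         ancestor_novon = ancestor_novon,
         descendant_novons = descendant_novons,
         secondary_novons = secondary_novons,
         validation = list(
           criteria_agree = anc$criteria_agree,
           diagnostics = anc$diagnostics,
           small_novon_ids = if (any(small)) {
             vapply(all_novons[small], function(nv) nv$species_id, character(1L))
           } else {
             character(0L)
           },
           high_missing_traits = matrix$trait_ids[missing_frac > 0.5],
           oversized = length(immediate) > 4L
         )),
    class = "microgenus"
  )
}

#' @export
print.microgenus <- function(x, ...) {
  cat(sprintf("microgenus: ancestor '%s', %d immediate descendant(s)%s\n",
              x$ancestor_id, length(x$descendant_ids),
              if (length(x$secondary_descendant_ids)) {
                sprintf(", %d secondary", length(x$secondary_descendant_ids))
              } else ""))
  if (length(x$descendant_ids)) {
    cat("  immediate:", paste(x$descendant_ids, collapse = ", "), "\n")
  }
  if (length(x$secondary_descendant_ids)) {
    cat("  secondary:",
        paste(sprintf("%s (via %s)", x$secondary_descendant_ids,
                      names(x$secondary_descendant_ids)), collapse = ", "), "\n")
  }
  if (x$validation$oversized) {
    cat("  note: more than 4 immediate descendants (beyond the rule-of-four optimum)\n")
  }
  invisible(x)
}
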