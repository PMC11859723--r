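#' Morphological trait matrix with a designated outgroup
#'
#' The input container for ancestor-descendant analysis: an integer state
#' matrix (species by traits; "morphology" means all expressed traits), a
#' designated outgroup species against which character polarity is read, and
#' optional group (genus) assignments. Missing states are `NA`.
#'
#' @param states Integer matrix, species in rows, traits in columns, with
#'   unique row (species) and column (trait) names; `NA` marks missing data.
#'   Non-missing states must be small non-negative integers.
#' @param outgroup_id Row name of the outgroup species.
#' @param group_assignments Optional named character vector mapping species
#'   ids (all but the outgroup) to group labels.
#'
#' @return An object of class `trait_matrix` with fields `states`,
#'   `species_ids`, `trait_ids`, `outgroup_id`, `group_assignments`.
#' @examples
#' m <- rbind(OG = c(0, 0, 0, 0), A = c(1, 1, 0, 0), B = c(1, 1, 1, 1))
#' colnames(m) <- paste0("t", 1:4)
#' trait_matrix(m, "OG")
#' @export
trait_matrix <- function(states, outgroup_id, group_assignments = NULL) {
  if (!is.matrix(states)) stop_domain("`states` must be a matrix")
  if (is.null(rownames(states)) || is.null(colnames(states))) {
    stop_domain("`states` needs species row names and trait column names")
  }
  species <- rownames(states)
  traits <- colnames(states)
  dup <- species[duplicated(species)]
  if (length(dup)) stop_domain("duplicate species id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- traits[duplicated(traits)]
  if (length(dup)) stop_domain("duplicate trait id(s): %s", paste(unique(dup), collapse = ", "))
  storage.mode(states) <- "integer"
  ok <- is.na(states) | states >= 0L
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_domain("negative state at species '%s', trait '%s'",
                species[bad[1L]], traits[bad[2L]])
  }
  if (length(outgroup_id) != 1L || !outgroup_id %in% species) {
    stop_domain("`outgroup_id` must name one of the species")
  }
  if (!is.null(group_assignments)) {
    if (is.null(names(group_assignments))) {
      stop_domain("`group_assignments` must be named by species id")
    }
    unknown <- setdiff(names(group_assignments), species)
    if (length(unknown)) {
      stop_domain("group assignment for unknown species: %s",
                  paste(unknown, collapse = ", "))
    }
    group_assignments <- vapply(group_assignments, as.character, character(1L))
  }
  structure(
    list(states = states,
         species_ids = species,
         trait_ids = traits,
         outgroup_id = outgroup_id,
         group_assignments = group_assignments),
    class = "trait_matrix"
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d species x %d traits (outgroup '%s', %d missing cells)\n",
              length(x$species_ids), length(x$trait_ids), x$outgroup_id,
              sum(is.na(x$states))))
  if (!is.null(x$group_assignments)) {
    cat(sprintf("  groups: %s\n",
                paste(unique(x$group_assignments), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$states)

#' Read a trait matrix from CSV/TSV or a NEXUS characters block
#'
#' The delimited dialect is: first column species id, header row of trait
#' ids, integer states, `?` for missing. NEXUS files are parsed with
#' [ape::read.nexus.data()] (standard characters block, digit symbols).
#'
#' @param path Path to the file.
#' @param format `"csv"`, `"tsv"` or `"nexus"`; default guessed from the
#'   file extension.
#' @param outgroup_id Outgroup species id; defaults to the first species in
#'   the file (with a message).
#' @param group_assignments Optional named character vector (species ->
#'   group), or path to a two-column `species,group` CSV.
#'
#' @return A [trait_matrix()].
#' @export
read_trait_matrix <- function(path, format = c("guess", "csv", "tsv", "nexus"),
                              outgroup_id = NULL, group_assignments = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv", tsv = "tsv",
                     nex = "nexus", nexus = "nexus", nxs = "nexus",
                     stop_domain("cannot guess format from extension '.%s'; pass `format`", ext))
  }
  states <- if (format == "nexus") read_states_nexus(path) else read_states_delim(path, format)
  if (is.character(group_assignments) && length(group_assignments) == 1L &&
      is.null(names(group_assignments)) && file.exists(group_assignments)) {
    group_assignments <- read_group_assignments(group_assignments)
  }
  if (is.null(outgroup_id)) {
    outgroup_id <- rownames(states)[1L]
    message(sprintf("no outgroup given; using the first species, '%s'", outgroup_id))
  }
  trait_matrix(states, outgroup_id, group_assignments)
}

read_states_delim <- function(path, format) {
  sep <- if (format == "csv") "," else "\t"
  fields <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop_domain("ragged row in %s: line %d has %d fields, expected %d",
                path, bad, fields[bad], fields[1L])
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L) stop_domain("%s: need a species-id column plus at least one trait", path)
  species <- raw[[1L]]
  dup <- unique(species[duplicated(species)])
  if (length(dup)) stop_domain("%s: duplicated species id(s): %s", path, paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  parsed <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells)))
  bad <- which(is.na(parsed) & !(cells %in% c("?", "", "NA")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_domain("%s: unknown state symbol '%s' at row %d (species '%s'), column '%s'",
                path, cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L] + 1L,
                species[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]])
  }
  dimnames(parsed) <- list(species, colnames(cells))
  parsed
}

read_states_nexus <- function(path) {
  chars <- ape::read.nexus.data(path)
  lens <- lengths(chars)
  if (length(unique(lens)) > 1L) {
    stop_domain("%s: unequal character counts across taxa", path)
  }
  cells <- do.call(rbind, chars)
  parsed <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells)))
  bad <- which(is.na(parsed) & !(cells %in% c("?", "-")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_domain("%s: unknown state symbol '%s' for taxon '%s', character %d",
                path, cells[bad[1L, 1L], bad[1L, 2L]],
                names(chars)[bad[1L, 1L]], bad[1L, 2L])
  }
  dimnames(parsed) <- list(names(chars), sprintf("char%02d", seq_len(ncol(parsed))))
  parsed
}

read_group_assignments <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop_domain("%s: expected columns species,group", path)
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a trait matrix to CSV/TSV
#'
#' Inverse of [read_trait_matrix()] for the delimited dialect (`?` marks
#' missing states). Group assignments, if any, are written alongside when
#' `groups_path` is given.
#'
#' @param matrix A [trait_matrix()].
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @param groups_path Optional path for a `species,group` CSV.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(matrix, path, format = c("csv", "tsv"),
                               groups_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "trait_matrix"))
  sep <- if (format == "csv") "," else "\t"
  cells <- matrix$states
  out <- apply(cells, 2L, function(col) ifelse(is.na(col), "?", as.character(col)))
  df <- data.frame(species = matrix$species_ids, out, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path) && !is.null(matrix$group_assignments)) {
    utils::write.csv(data.frame(species = names(matrix$group_assignments),
                                group = unname(matrix$group_assignments)),
                     groups_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Polarise a trait matrix against its outgroup
#'
#' Reads character polarity by outgroup comparison: a cell of the returned
#' binary apomorphy matrix is 1 when the species' state differs from the
#' outgroup's state at that trait (a derived state, whatever its value), 0
#' when it matches, `NA` when missing. The outgroup row must be complete,
#' since it defines polarity.
#'
#' @param matrix A [trait_matrix()].
#' @return Integer matrix (species by traits) of 0/1/`NA`; the outgroup row
#'   is all zeros.
#' @examples
#' pm <- generate_planted_matrix(n_descendants = 2, novon_size = 4, seed = 1)
#' polarize(pm$matrix)
#' @export
polarize <- function(matrix) {
  stopifnot(inherits(matrix, "trait_matrix"))
  og <- matrix$states[matrix$outgroup_id, ]
  if (anyNA(og)) {
    stop_domain("outgroup '%s' has missing states at: %s; polarity is undefined",
                matrix$outgroup_id,
                paste(matrix$trait_ids[is.na(og)], collapse = ", "))
  }
  apo <- sweep(matrix$states, 2L, og, FUN = "!=")
  storage.mode(apo) <- "integer"
  apo
}

# Count of derived (non-outgroup) states per species; NA cells ignored.
apomorphy_counts <- function(matrix, species = matrix$species_ids) {
  apo <- polarize(matrix)
  rowSums(apo[species, , drop = FALSE], na.rm = TRUE)
}
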