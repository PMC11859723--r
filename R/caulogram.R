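#' Directed ancestor-descendant tree (caulogram)
#'
#' A caulogram is a multichotomous stem-taxon tree whose nodes are species
#' (extant or inferred ancestors included, unlike a cladogram's unnamed
#' nodes) and whose directed edges run ancestor to descendant, annotated
#' with the descendant's novon size in bits. Each node has at most one
#' ancestor; multichotomies are allowed and out-degrees above four are
#' flagged (beyond the rule-of-four optimum).
#'
#' @param nodes Character vector of species ids.
#' @param edges Data frame with columns `ancestor`, `descendant`, `bits`.
#' @param novons Optional named list of novon trait data frames
#'   (`trait_id`, `state`), one per node where known.
#' @param secondary Optional named character vector mapping secondary
#'   descendants to the immediate descendant carrying them.
#' @param groups Optional named character vector mapping species to group
#'   (genus) labels.
#'
#' @return An object of class `caulogram` with fields `nodes`, `edges`,
#'   `roots`, `novons`, `secondary`, `groups`.
#' @export
caulogram <- function(nodes, edges, novons = NULL, secondary = NULL,
                      groups = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_domain("duplicate node ids in caulogram")
  if (!is.data.frame(edges) || !all(c("ancestor", "descendant", "bits") %in% names(edges))) {
    stop_domain("`edges` must be a data frame with ancestor, descendant, bits")
  }
  edges <- data.frame(ancestor = as.character(edges$ancestor),
                      descendant = as.character(edges$descendant),
                      bits = as.numeric(edges$bits),
                      row.names = NULL)
  unknown <- setdiff(c(edges$ancestor, edges$descendant), nodes)
  if (length(unknown)) {
    stop_domain("edge endpoints not in `nodes`: %s", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(edges$descendant)) {
    dup <- unique(edges$descendant[duplicated(edges$descendant)])
    stop_domain("invalid caulogram: node(s) with more than one ancestor: %s",
                paste(dup, collapse = ", "))
  }
  if (any(edges$bits < 0)) stop_domain("edge bits must be >= 0")
  assert_acyclic(nodes, edges)
  roots <- setdiff(nodes, edges$descendant)
  if (!is.null(novons)) {
    unknown <- setdiff(names(novons), nodes)
    if (length(unknown)) {
      stop_domain("novon entries for unknown node(s): %s", paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(nodes = nodes, edges = edges, roots = roots,
         novons = novons, secondary = secondary, groups = groups),
    class = "caulogram"
  )
}

assert_acyclic <- function(nodes, edges) {
  parent <- stats::setNames(edges$ancestor, edges$descendant)
  for (start in nodes) {
    cur <- start
    steps <- 0L
    while (cur %in% names(parent)) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > length(nodes)) {
        stop_domain("invalid caulogram: cycle detected through '%s'", start)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.caulogram <- function(x, ...) {
  outdeg <- table(x$edges$ancestor)
  cat(sprintf("caulogram: %d species, %d edges, %d root(s) [%s]\n",
              length(x$nodes), nrow(x$edges), length(x$roots),
              paste(x$roots, collapse = ", ")))
  cat(sprintf("  total support: %g bits over the edges\n", sum(x$edges$bits)))
  if (length(outdeg) && max(outdeg) > 4L) {
    cat("  note: multichotomy wider than 4 at:",
        paste(names(outdeg)[outdeg > 4L], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble a caulogram from a grouped trait matrix
#'
#' Runs the full protocol: each group is assembled into a microgenus
#' ([assemble_microgenus()]); within a genus, edges run ancestor to each
#' immediate descendant (bits = the descendant's own novon size) and
#' immediate descendant to each secondary descendant; genus ancestors are
#' then linked into a backbone. In `auto` linking the genus ancestor with
#' the fewest apomorphies roots the tree and every other genus ancestor
#' attaches, in increasing apomorphy order, to the already-placed ancestor
#' at minimal apomorphy (Hamming) distance, which cannot create a cycle. In
#' `explicit` linking the caller supplies the backbone as a named vector
#' (child ancestor -> parent ancestor); cycles raise an error. Backbone
#' edges carry the child ancestor's novon size relative to its parent.
#'
#' @param matrix A [trait_matrix()].
#' @param groups Named list of character vectors partitioning the
#'   non-outgroup species into groups, or `NULL` to use the matrix's
#'   `group_assignments`.
#' @param linking `"auto"` or `"explicit"`.
#' @param links Named character vector (child genus ancestor -> parent genus
#'   ancestor) when `linking = "explicit"`.
#'
#' @return A [caulogram()].
#' @examples
#' pm <- generate_planted_matrix(n_descendants = 3, novon_size = 4, seed = 1)
#' assemble_caulogram(pm$matrix,
#'                    groups = list(g1 = setdiff(pm$matrix$species_ids, "OG")))
#' @export
assemble_caulogram <- function(matrix, groups = NULL,
                               linking = c("auto", "explicit"), links = NULL) {
  linking <- match.arg(linking)
  stopifnot(inherits(matrix, "trait_matrix"))
  if (is.null(groups)) {
    if (is.null(matrix$group_assignments)) {
      stop_domain("no `groups` given and the matrix carries no group assignments")
    }
    ga <- matrix$group_assignments
    groups <- split(names(ga), unname(ga))
  }
  ingroup <- setdiff(matrix$species_ids, matrix$outgroup_id)
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop_domain("groups overlap at: %s",
                paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  if (!setequal(members, ingroup)) {
    missing_sp <- setdiff(ingroup, members)
    extra <- setdiff(members, ingroup)
    stop_domain("groups must partition the non-outgroup species%s%s",
                if (length(missing_sp)) paste0("; unassigned: ", paste(missing_sp, collapse = ", ")) else "",
                if (length(extra)) paste0("; not in matrix/outgroup: ", paste(extra, collapse = ", ")) else "")
  }

  genera <- lapply(groups, function(g) assemble_microgenus(matrix, g))
  ancestors <- vapply(genera, function(mg) mg$ancestor_id, character(1L))

  edges <- list()
  novons <- list()
  secondary <- character(0L)
  group_of <- character(0L)
  for (gi in seq_along(genera)) {
    mg <- genera[[gi]]
    glabel <- names(genera)[gi]
    ids <- c(mg$ancestor_id, mg$descendant_ids, unname(mg$secondary_descendant_ids))
    group_of[ids] <- glabel
    novons[[mg$ancestor_id]] <- mg$ancestor_novon$traits
    for (d in mg$descendant_ids) {
      nv <- mg$descendant_novons[[d]]
      novons[[d]] <- nv$traits
      edges[[length(edges) + 1L]] <- data.frame(
        ancestor = mg$ancestor_id, descendant = d, bits = nrow(nv$traits))
    }
    for (s in unname(mg$secondary_descendant_ids)) {
      parent_d <- names(mg$secondary_descendant_ids)[mg$secondary_descendant_ids == s]
      nv <- mg$secondary_novons[[s]]
      novons[[s]] <- nv$traits
      secondary <- c(secondary, stats::setNames(s, parent_d))
      edges[[length(edges) + 1L]] <- data.frame(
        ancestor = parent_d, descendant = s, bits = nrow(nv$traits))
    }
  }

  backbone <- link_genus_ancestors(matrix, unname(ancestors), linking, links)
  for (i in seq_len(nrow(backbone))) {
    nv <- extract_novon(matrix, backbone$descendant[i], backbone$ancestor[i])
    edges[[length(edges) + 1L]] <- data.frame(
      ancestor = backbone$ancestor[i], descendant = backbone$descendant[i],
      bits = novon_size(nv))
  }

  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(ancestor = character(0L), descendant = character(0L), bits = numeric(0L))
  }
  caulogram(nodes = ingroup, edges = edges, novons = novons,
            secondary = if (length(secondary)) secondary else NULL,
            groups = group_of[ingroup])
}

# Order genus ancestors by apomorphy count; the most outgroup-similar roots
# the backbone and the rest greedily attach to the nearest placed ancestor.
link_genus_ancestors <- function(matrix, ancestors, linking, links) {
  empty <- data.frame(ancestor = character(0L), descendant = character(0L))
  if (length(ancestors) <= 1L) return(empty)
  if (linking == "explicit") {
    if (is.null(links) || is.null(names(links))) {
      stop_domain("explicit linking needs `links` as a named vector (child -> parent)")
    }
    unknown <- setdiff(c(names(links), unname(links)), ancestors)
    if (length(unknown)) {
      stop_domain("explicit links name non-ancestor species: %s",
                  paste(unknown, collapse = ", "))
    }
    bb <- data.frame(ancestor = unname(links), descendant = names(links))
    assert_acyclic(ancestors, data.frame(ancestor = bb$ancestor,
                                         descendant = bb$descendant,
                                         bits = 0))
    return(bb)
  }
  apo <- apomorphy_counts(matrix, ancestors)
  ord <- ancestors[order(apo, ancestors)]
  dist_fun <- function(a, b) {
    sa <- matrix$states[a, ]
    sb <- matrix$states[b, ]
    usable <- !is.na(sa) & !is.na(sb)
    sum(sa[usable] != sb[usable])
  }
  placed <- ord[1L]
  bb <- empty
  for (child in ord[-1L]) {
    d <- vapply(placed, function(p) dist_fun(child, p), numeric(1L))
    best <- placed[order(d, apo[placed], placed)][1L]
    bb <- rbind(bb, data.frame(ancestor = best, descendant = child))
    placed <- c(placed, child)
  }
  bb
}

#' Serialize / deserialize a caulogram
#'
#' `write_caulogram()` writes two files: a JSON document (the authoritative
#' serialization: schema-versioned, holding nodes, edges with bits and
#' posteriors, roots, novons and secondary-descendant attributions) and a
#' Newick rendering with ancestors as labelled internal nodes and edge bits
#' as branch lengths (one tree per root). `read_caulogram()` reads the JSON
#' back into an identical object.
#'
#' @param caulogram A [caulogram()].
#' @param path Path of the JSON file.
#' @param newick_path Path of the Newick file; default replaces the
#'   extension of `path` with `.nwk`.
#' @return `write_caulogram()`: `path`, invisibly. `read_caulogram()`: the
#'   [caulogram()].
#' @export
write_caulogram <- function(caulogram, path, newick_path = NULL) {
  stopifnot(inherits(caulogram, "caulogram"))
  if (is.null(newick_path)) {
    newick_path <- paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".nwk")
  }
  doc <- list(
    schema = "caulokit-caulogram-1",
    nodes = caulogram$nodes,
    roots = caulogram$roots,
    edges = data.frame(ancestor = caulogram$edges$ancestor,
                       descendant = caulogram$edges$descendant,
                       bits = caulogram$edges$bits,
                       posterior = bits_to_posterior(caulogram$edges$bits)),
    novons = caulogram$novons,
    secondary = if (is.null(caulogram$secondary)) NULL else
      as.list(stats::setNames(unname(caulogram$secondary), names(caulogram$secondary))),
    groups = if (is.null(caulogram$groups)) NULL else as.list(caulogram$groups)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  writeLines(caulogram_newick(caulogram), newick_path)
  invisible(path)
}

#' @rdname write_caulogram
#' @export
read_caulogram <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: %s", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_domain("malformed caulogram file %s: %s",
                                                  path, conditionMessage(e)))
  if (!identical(doc$schema, "caulokit-caulogram-1")) {
    stop_domain("%s: not a caulokit caulogram document (schema '%s')",
                path, if (is.null(doc$schema)) "<none>" else doc$schema)
  }
  edges <- if (length(doc$edges) && length(doc$edges$ancestor)) {
    data.frame(ancestor = doc$edges$ancestor,
               descendant = doc$edges$descendant,
               bits = as.numeric(doc$edges$bits))
  } else {
    data.frame(ancestor = character(0L), descendant = character(0L), bits = numeric(0L))
  }
  novons <- if (is.null(doc$novons)) NULL else {
    lapply(doc$novons, function(df) {
      data.frame(trait_id = as.character(df$trait_id),
                 state = as.integer(df$state), row.names = NULL)
    })
  }
  secondary <- if (is.null(doc$secondary) || !length(doc$secondary)) NULL else {
    stats::setNames(vapply(doc$secondary, as.character, character(1L)),
                    names(doc$secondary))
  }
  groups <- if (is.null(doc$groups) || !length(doc$groups)) NULL else {
    stats::setNames(vapply(doc$groups, as.character, character(1L)),
                    names(doc$groups))
  }
  caulogram(nodes = doc$nodes, edges = edges, novons = novons,
            secondary = secondary, groups = groups)
}

#' Newick rendering of a caulogram
#'
#' Ancestors appear as labelled internal nodes, edge bits as branch lengths;
#' one Newick line per root. The output parses with [ape::read.tree()].
#'
#' @param caulogram A [caulogram()].
#' @return Character vector of Newick strings.
#' @export
caulogram_newick <- function(caulogram) {
  stopifnot(inherits(caulogram, "caulogram"))
  kids <- split(seq_len(nrow(caulogram$edges)), caulogram$edges$ancestor)
  render <- function(node) {
    rows <- kids[[node]]
    if (is.null(rows)) return(quote_newick(node))
    parts <- vapply(rows, function(i) {
      sprintf("%s:%g", render(caulogram$edges$descendant[i]), caulogram$edges$bits[i])
    }, character(1L))
    sprintf("(%s)%s", paste(parts, collapse = ","), quote_newick(node))
  }
  vapply(caulogram$roots, function(r) paste0(render(r), ";"), character(1L))
}

quote_newick <- function(x) {
  if (grepl("[\\s(),:;'\\[\\]]", x, perl = TRUE)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}
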