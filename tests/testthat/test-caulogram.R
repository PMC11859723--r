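test_that("caulogram construction enforces tree invariants", {
  edges <- data.frame(ancestor = c("a", "a"), descendant = c("b", "c"), bits = c(4, 3))
  cg <- caulogram(c("a", "b", "c"), edges)
  expect_identical(cg$roots, "a")

  two_parents <- data.frame(ancestor = c("a", "b"), descendant = c("c", "c"),
                            bits = c(1, 1))
  expect_error(caulogram(c("a", "b", "c"), two_parents), "more than one ancestor")

  cyc <- data.frame(ancestor = c("a", "b"), descendant = c("b", "a"), bits = c(1, 1))
  expect_error(caulogram(c("a", "b"), cyc), "cycle")
})

test_that("a single planted genus assembles into a one-root caulogram", {
  pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4, seed = 6)
  cg <- assemble_caulogram(pm$matrix, groups = list(
    g1 = setdiff(pm$matrix$species_ids, "OG")))
  expect_identical(cg$roots, "ANC")
  expect_equal(nrow(cg$edges), 4)
  expect_true(all(cg$edges$bits == 4))
})

test_that("auto linking reproduces the explicit two-genus wiring", {
  tm <- two_genus_matrix()
  auto <- assemble_caulogram(tm)
  explicit <- assemble_caulogram(tm, linking = "explicit", links = c(A2 = "A1"))

  key <- function(cg) {
    e <- cg$edges[order(cg$edges$ancestor, cg$edges$descendant), ]
    paste(e$ancestor, e$descendant, e$bits)
  }
  expect_setequal(key(auto), key(explicit))
  expect_identical(auto$roots, "A1")
  backbone <- auto$edges[auto$edges$descendant == "A2", ]
  expect_identical(backbone$ancestor, "A1")
  expect_equal(backbone$bits, 4)

  cyc <- c(A2 = "A1", A1 = "A2")
  expect_error(assemble_caulogram(tm, linking = "explicit", links = cyc), "cycle")
})

test_that("caulogram edge bits equal the extracted novon sizes", {
  tm <- two_genus_matrix()
  cg <- assemble_caulogram(tm)
  for (i in seq_len(nrow(cg$edges))) {
    expect_equal(cg$edges$bits[i],
                 novon_size(extract_novon(tm, cg$edges$descendant[i],
                                          cg$edges$ancestor[i])))
  }
})

test_that("groups must partition the non-outgroup species", {
  tm <- two_genus_matrix()
  expect_error(assemble_caulogram(tm, groups = list(g1 = c("A1", "X1"))),
               "unassigned")
  expect_error(assemble_caulogram(tm, groups = list(
    g1 = c("A1", "X1", "X2"), g2 = c("A2", "Y1", "Y2", "X1"))), "overlap")
})

test_that("JSON round trip restores the caulogram exactly", {
  cg <- two_genus_caulogram()
  path <- test_tempfile(".json")
  write_caulogram(cg, path)
  back <- read_caulogram(path)
  expect_equal(back, cg)

  # sidecar bits are conserved: their sum equals the total novon sizes on edges
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sum(doc$edges$bits), sum(cg$edges$bits))
  expect_equal(doc$edges$posterior, bits_to_posterior(cg$edges$bits))

  expect_error(read_caulogram(test_tempfile(".json")), "not found")
  junk <- test_tempfile(".json")
  writeLines("{\"schema\": \"something-else\"}", junk)
  expect_error(read_caulogram(junk), "schema")
})

test_that("Newick output has labelled ancestors and parses with ape", {
  pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4, seed = 6)
  cg1 <- assemble_caulogram(pm$matrix, groups = list(
    g1 = setdiff(pm$matrix$species_ids, "OG")))
  json <- test_tempfile(".json")
  nwk <- test_tempfile(".nwk")
  write_caulogram(cg1, json, newick_path = nwk)
  tree <- ape::read.tree(nwk)
  expect_equal(length(tree$tip.label), 4)
  expect_identical(tree$node.label, "ANC")

  tree2 <- ape::read.tree(text = caulogram_newick(two_genus_caulogram()))
  expect_setequal(tree2$tip.label, c("X1", "X2", "Y1", "Y2"))
  expect_setequal(tree2$node.label, c("A1", "A2"))
  # branch lengths carry the bit annotations
  expect_setequal(tree2$edge.length, c(4, 4, 4, 4, 4))
})
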