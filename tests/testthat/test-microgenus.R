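test_that("the planted ancestor wins both criteria on clean data", {
  pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4, seed = 1)
  group <- setdiff(pm$matrix$species_ids, "OG")
  res <- identify_ancestor(pm$matrix, group)
  expect_identical(res$ancestor_id, "ANC")
  expect_true(res$criteria_agree)
  expect_identical(res$diagnostics$species_id[1], "ANC")
  expect_equal(res$diagnostics$apomorphies[res$diagnostics$species_id == "ANC"], 4L)

  expect_identical(identify_ancestor(pm$matrix, "D2")$ancestor_id, "D2")
  expect_error(identify_ancestor(pm$matrix, character(0)), "at least one")
  expect_error(identify_ancestor(pm$matrix, c("ANC", "OG")), "outgroup")
})

test_that("ancestor identification is invariant to species row order", {
  pm <- generate_planted_matrix(n_descendants = 4, novon_size = 3, seed = 5,
                                noise_rate = 0.05)
  group <- setdiff(pm$matrix$species_ids, "OG")
  base <- identify_ancestor(pm$matrix, group)
  perm <- sample(pm$matrix$species_ids)
  shuffled <- trait_matrix(pm$matrix$states[perm, ], "OG")
  res <- identify_ancestor(shuffled, sample(group))
  expect_identical(res$ancestor_id, base$ancestor_id)
  expect_equal(res$diagnostics, base$diagnostics)
})

test_that("novon extraction returns the newly derived trait set", {
  tm <- two_genus_matrix()
  nv <- extract_novon(tm, "X1", "A1")
  expect_equal(novon_size(nv), 4)
  expect_identical(nv$traits$trait_id, sprintf("t%03d", 5:8))

  # identical species: an empty novon (invalid as a species)
  dup <- tm$states
  dup <- rbind(dup, A1copy = dup["A1", ])
  nv0 <- extract_novon(trait_matrix(dup, "OG"), "A1copy", "A1")
  expect_equal(novon_size(nv0), 0)

  # on noise-free planted data the novon size equals the apomorphy difference
  pm <- generate_planted_matrix(n_descendants = 3, novon_size = 5, seed = 2)
  apo <- rowSums(polarize(pm$matrix))
  for (d in pm$truth$descendant_ids) {
    expect_equal(novon_size(extract_novon(pm$matrix, d, "ANC")),
                 unname(apo[d] - apo["ANC"]))
  }
  expect_error(extract_novon(tm, "A1", "A1"), "itself")
})

test_that("microgenus assembly recovers planted wiring exactly at zero noise", {
  pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4, seed = 3)
  mg <- assemble_microgenus(pm$matrix, setdiff(pm$matrix$species_ids, "OG"))
  expect_identical(mg$ancestor_id, "ANC")
  expect_setequal(mg$descendant_ids, pm$truth$descendant_ids)
  expect_length(mg$secondary_descendant_ids, 0)
  for (d in mg$descendant_ids) {
    expect_setequal(mg$descendant_novons[[d]]$traits$trait_id, pm$truth$novons[[d]])
  }
  expect_setequal(mg$ancestor_novon$traits$trait_id, pm$truth$novons[["ANC"]])

  # every immediate descendant carries the ancestor's novon entire
  anc_traits <- mg$ancestor_novon$traits$trait_id
  for (d in mg$descendant_ids) {
    expect_true(all(pm$matrix$states[d, anc_traits] == 1L))
  }
})

test_that("secondary descendants are attributed to the carrier of their novon", {
  pm <- generate_planted_matrix(n_descendants = 3, novon_size = 4, seed = 4,
                                n_secondary = 1)
  mg <- assemble_microgenus(pm$matrix, setdiff(pm$matrix$species_ids, "OG"))
  expect_setequal(mg$descendant_ids, c("D1", "D2", "D3"))
  expect_identical(unname(mg$secondary_descendant_ids), "S1")
  expect_identical(names(mg$secondary_descendant_ids),
                   unname(pm$truth$secondary_map["S1"]))
  expect_setequal(mg$secondary_novons[["S1"]]$traits$trait_id, pm$truth$novons[["S1"]])
})

test_that("assembly raises orphans and warns on sub-minimal novons", {
  tm <- two_genus_matrix()
  # a species with a private novon only: carries neither ancestor nor
  # descendant novon -> orphan
  st <- rbind(tm$states, ORPH = 0L)
  st["ORPH", 21:24] <- 2L
  expect_error(assemble_microgenus(trait_matrix(st, "OG"), c("A1", "X1", "X2", "ORPH")),
               "orphan.*ORPH")

  # a one-trait species triggers the two-trait minimum warning
  st2 <- rbind(tm$states, TINY = tm$states["A1", ])
  st2["TINY", 24] <- 1L
  expect_warning(assemble_microgenus(trait_matrix(st2, "OG"), c("A1", "X1", "X2", "TINY")),
                 "2-trait")
})

test_that("ancestor recovery holds at 5% cell noise across replicates", {
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    pm <- generate_planted_matrix(n_descendants = 4, novon_size = 4,
                                  noise_rate = 0.05, seed = 1000L + i)
    got <- identify_ancestor(pm$matrix, setdiff(pm$matrix$species_ids, "OG"))
    hits <- hits + (got$ancestor_id == "ANC")
  }
  expect_gte(hits / n_rep, 0.9)
})
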