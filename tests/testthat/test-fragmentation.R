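test_that("reduced graph units follow ring > group > linker precedence", {
  nn <- parse_structure("O=[N+]([O-])c1cccc2ccccc12")
  rg <- build_reduced_graph(nn)
  kinds <- vapply(rg$units, `[[`, "", "kind")
  expect_identical(sort(kinds), c("functional_group", "ring", "ring"))
  expect_equal(nrow(rg$edges), 2)   # nitro-ring and ring-ring: a path

  b <- build_reduced_graph(parse_structure("c1ccccc1"))
  expect_length(b$units, 1)
  expect_identical(b$units[[1]]$kind, "ring")
  expect_equal(nrow(b$edges), 0)

  bu <- build_reduced_graph(parse_structure("CCCC"))
  expect_length(bu$units, 4)
  expect_true(all(vapply(bu$units, `[[`, "", "kind") == "linker"))
  expect_equal(nrow(bu$edges), 3)

  # every atom belongs to at least one unit
  covered <- sort(unique(unlist(lapply(rg$units, `[[`, "atom_ids"))))
  expect_identical(covered, nn$atoms$atom_id)
})

test_that("1-nitronaphthalene fragments into 6 connected fragments", {
  nn <- parse_structure("O=[N+]([O-])c1cccc2ccccc12")
  frags <- enumerate_fragments(build_reduced_graph(nn))
  expect_length(frags, 6)
  # the root fragment is the query itself
  root <- frags[[6]]
  expect_setequal(root$atom_ids, nn$atoms$atom_id)
  # the naphthalene ring-pair fragment is present
  keys <- vapply(frags, `[[`, "", "key")
  expect_true(canonical_smiles(parse_structure("c1ccc2ccccc2c1")) %in% keys)
  # the single-unit nitro fragment is present
  expect_true(any(vapply(frags, function(f) setequal(f$atom_ids, 0:2), TRUE)))
})

test_that("expand_fragment honours its contract", {
  nn <- parse_structure("O=[N+]([O-])c1cccc2ccccc12")
  rg <- build_reduced_graph(nn)
  # single nitro unit
  fg_unit <- which(vapply(rg$units, `[[`, "", "kind") == "functional_group") - 1L
  f <- expand_fragment(rg, fg_unit)
  expect_setequal(f$atom_ids, c(0, 1, 2))
  # the two rings expand to naphthalene
  ring_units <- which(vapply(rg$units, `[[`, "", "kind") == "ring") - 1L
  f2 <- expand_fragment(rg, ring_units)
  expect_identical(f2$key, canonical_smiles(parse_structure("c1ccc2ccccc2c1")))
  # all units give back the whole structure
  f3 <- expand_fragment(rg, 0:(length(rg$units) - 1))
  expect_setequal(f3$atom_ids, nn$atoms$atom_id)
  # disconnected subset refused (nitro + far ring are non-adjacent)
  expect_error(expand_fragment(rg, c(fg_unit, ring_units[2])), "not connected")
})

test_that("fragment counts match the exhaustive connected-subset oracle", {
  # path reduced graphs from n-alkanes: m(m+1)/2 fragments
  for (m in c(2, 4, 6)) {
    alkane <- parse_structure(paste(rep("C", m), collapse = ""))
    frags <- enumerate_fragments(build_reduced_graph(alkane))
    expect_length(frags, m * (m + 1) / 2)
    edges <- cbind(0:(m - 2), 1:(m - 1))
    expect_length(frags, oracle_connected_subset_count(m, edges))
  }
  # star reduced graph: neopentane (centre + 4 leaves)
  star <- parse_structure("CC(C)(C)C")
  rg <- build_reduced_graph(star)
  centre <- which(vapply(rg$units, function(u) 1 %in% u$atom_ids, TRUE)) - 1L
  star_edges <- cbind(centre, setdiff(0:4, centre))
  n_oracle <- oracle_connected_subset_count(5, star_edges)
  expect_equal(n_oracle, 2^4 + 4)   # subsets containing the centre + leaf singletons
  expect_length(enumerate_fragments(rg), n_oracle)
})

test_that("fragments are connected, unique, and hierarchy-closed", {
  lib20 <- make_toy_library(20, seed = 5)
  for (s in lib20$structures) {
    frags <- enumerate_fragments(build_reduced_graph(s))
    sets <- lapply(frags, `[[`, "atom_ids")
    keys <- vapply(sets, paste, "", collapse = ",")
    expect_identical(anyDuplicated(keys), 0L)
    nmax <- max(lengths(sets))
    for (k in seq_along(frags)) {
      # connectivity via the fragment's own structure
      fs <- fragment_as_structure(s, frags[[k]])
      expect_equal(max(fragnet:::structure_components(fs)), 1)
      # hierarchy closure: every non-root has a strict superset fragment
      if (length(sets[[k]]) < nmax) {
        expect_true(any(vapply(sets, function(o)
          length(o) > length(sets[[k]]) && all(sets[[k]] %in% o), TRUE)))
      }
    }
  }
})

test_that("depth limiting and the unit cap behave", {
  hexane <- parse_structure("CCCCCC")
  rg <- build_reduced_graph(hexane)
  fr2 <- enumerate_fragments(rg, max_depth = 2)
  # 6 singletons + 5 pairs + always the root
  expect_length(fr2, 12)
  expect_error(enumerate_fragments(rg, unit_cap = 3), "unit_cap|max_depth")
})
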