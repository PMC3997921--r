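test_that("bitset network of {1,3,7,8} has the expected shape", {
  combos <- enumerate_bitsets(c(1L, 3L, 7L, 8L), prune_level = Inf)
  net <- build_bitset_network(combos)
  expect_length(net$nodes, 15)
  root <- net$nodes[[net$root_index + 1]]
  expect_identical(root$payload, c(1L, 3L, 7L, 8L))
  expect_length(root$parents, 0)
  # every k=3 node has 3 children and one parent (the root)
  k3 <- Filter(function(nd) length(nd$payload) == 3, net$nodes)
  expect_length(k3, 4)
  for (nd in k3) {
    expect_length(nd$children, 3)
    expect_identical(nd$parents, root$index)
  }
  # every non-root node has at least one parent
  for (nd in net$nodes) {
    if (nd$index != net$root_index) expect_gte(length(nd$parents), 1)
  }
})

test_that("single-node and degenerate networks build", {
  net <- build_bitset_network(list(fragnet:::new_bit_combination(c(0L, 2L))))
  expect_length(net$nodes, 1)
  expect_identical(net$root_index, 0L)
  expect_error(build_bitset_network(list(fragnet:::new_bit_combination(0L),
                                         fragnet:::new_bit_combination(1L))),
               "root|maximal")
})

test_that("parenthood equals brute-force minimal supersets on random prunings", {
  for (seed in 1:8) {
    set.seed(seed)
    n_bits <- sample(4:7, 1)
    all_combos <- enumerate_bitsets(seq_len(n_bits) - 1L, prune_level = Inf)
    keep <- sort(sample(seq_along(all_combos),
                        sample(3:min(12, length(all_combos) - 1), 1)))
    payloads <- lapply(all_combos[keep], function(x) as.integer(unclass(x)))
    # always include the root
    payloads <- unique(c(payloads, list(seq_len(n_bits) - 1L)))
    net <- build_bitset_network(lapply(payloads, fragnet:::new_bit_combination))
    got <- lapply(net$nodes, `[[`, "parents")
    ordered_payloads <- lapply(net$nodes, `[[`, "payload")
    want <- oracle_minimal_supersets(ordered_payloads)
    for (i in seq_along(net$nodes)) {
      expect_identical(sort(got[[i]]), sort(which(want[i, ]) - 1L),
                       info = paste("seed", seed, "node", i))
    }
  }
})

test_that("fragment networks organise by atom-set inclusion", {
  nn <- parse_structure("O=[N+]([O-])c1cccc2ccccc12")
  frags <- enumerate_fragments(build_reduced_graph(nn))
  net <- build_fragment_network(frags)
  expect_length(net$nodes, 6)
  root <- net$nodes[[net$root_index + 1]]
  expect_setequal(root$payload, nn$atoms$atom_id)
  # nitro fragment and the far lone ring are leaves
  leaves <- Filter(function(nd) length(nd$children) == 0, net$nodes)
  leaf_sets <- lapply(leaves, `[[`, "payload")
  expect_true(any(vapply(leaf_sets, function(x) setequal(x, 0:2), TRUE)))
  # parenthood equals oracle
  want <- oracle_minimal_supersets(lapply(net$nodes, `[[`, "payload"))
  for (i in seq_along(net$nodes)) {
    expect_identical(sort(net$nodes[[i]]$parents), sort(which(want[i, ]) - 1L))
  }
})

test_that("network invariants hold: DAG, strict inclusion, closures", {
  for (seed in 1:10) {
    net <- make_random_network(sample(2:30, 1), seed = seed)
    sizes <- vapply(net$nodes, function(nd) length(nd$payload), 0L)
    for (nd in net$nodes) {
      for (p in nd$parents) {
        pp <- net$nodes[[p + 1]]$payload
        expect_true(all(nd$payload %in% pp) && length(pp) > length(nd$payload))
      }
      expect_false(nd$index %in% nd$ascendants)
      # closure consistency: asc(x) = union over parents of {p} + asc(p)
      expected_asc <- integer(0)
      for (p in nd$parents)
        expected_asc <- union(expected_asc, c(p, net$nodes[[p + 1]]$ascendants))
      expect_setequal(nd$ascendants, expected_asc)
    }
    # acyclicity via topological order by payload size
    for (nd in net$nodes) {
      for (p in nd$parents) expect_gt(sizes[p + 1], length(nd$payload))
    }
  }
})

test_that("network export round-trips and colours follow the legend", {
  net <- classify_nodes(demo_assessment_network())
  js <- jsonlite::fromJSON(export_network(net, "json"), simplifyVector = FALSE)
  expect_equal(js$root_index, 0)
  expect_length(js$nodes, 11)
  for (k in seq_along(js$nodes)) {
    nd <- net$nodes[[k]]
    expect_equal(js$nodes[[k]]$index, nd$index)
    expect_equal(as.numeric(unlist(js$nodes[[k]]$parents)), as.numeric(nd$parents))
    expect_identical(js$nodes[[k]]$assessment, nd$assessment)
  }
  dot <- export_network(net, "dot")
  counts <- vapply(c(red = "fillcolor=red", green = "fillcolor=green",
                     orange = "fillcolor=orange", purple = "fillcolor=purple",
                     pink = "fillcolor=pink", blue = "fillcolor=blue"),
                   function(p) sum(grepl(p, strsplit(dot, "\n")[[1]], fixed = TRUE)), 0L)
  expect_identical(unname(counts), c(1L, 2L, 2L, 1L, 3L, 2L))
  # unassessed network renders neutral
  dot2 <- export_network(demo_assessment_network(), "dot")
  expect_true(any(grepl("fillcolor=grey", strsplit(dot2, "\n")[[1]], fixed = TRUE)))
  expect_error(export_network(net, "xml"), "arg")
})
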