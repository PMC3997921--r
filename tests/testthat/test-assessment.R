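test_that("predict_nodes fills predictions and keeps the root's model output", {
  oracle <- default_rule_oracle()
  nn <- parse_structure("O=[N+]([O-])c1cccc2ccccc12")
  frags <- enumerate_fragments(build_reduced_graph(nn))
  fvs <- lapply(frags, function(f) fp_for_fragment(nn, f))
  net <- build_fragment_network(frags, feature_vectors = fvs)
  net <- predict_nodes(net, oracle)
  preds <- net_predictions(net)
  expect_false(anyNA(preds))
  # rule evaluated per node: active iff the fragment contains the nitro unit
  has_nitro <- vapply(net$nodes, function(nd) all(0:2 %in% nd$payload), TRUE)
  expect_identical(preds == "active", has_nitro)
  # root prediction equals the plain model prediction of the query
  expect_identical(preds[net$root_index + 1],
                   predict_fv(oracle, structural_key_fp(nn))$label)

  # constant predictor: everything inactive
  net2 <- predict_nodes(net, constant_predictor("inactive"))
  expect_true(all(net_predictions(net2) == "inactive"))

  # a predictor failure names the node
  broken <- structure(list(), class = c("no_such", "fragnet_predictor"))
  expect_error(predict_nodes(net, broken), "node")
})

test_that("the demonstration network reproduces the reference assessments", {
  net <- classify_nodes(demo_assessment_network())
  ass <- net_assessments(net)
  expect_identical(unname(ass[as.character(6)]), "ACTIVATING")
  expect_identical(unname(ass[as.character(c(7, 2))]), rep("IGNORE", 2))
  expect_identical(unname(ass[as.character(c(8, 9))]), rep("DEACTIVATED", 2))
  expect_identical(unname(ass[as.character(c(4, 5))]), rep("DEACTIVATING", 2))
  expect_identical(unname(ass[as.character(10)]), "NEGATED")
  expect_identical(unname(ass[as.character(c(0, 1, 3))]), rep("ACTIVITY_IDENTIFIED", 3))

  s <- summarize_network(net)
  expect_identical(s$activation_nodes, 6L)
  pairs <- t(vapply(s$deactivations, function(d) d$nodes, c(deactivated = 0L, deactivating = 0L)))
  expect_setequal(paste(pairs[, "deactivating"], pairs[, "deactivated"], sep = "-"),
                  c("4-8", "5-8", "5-9"))
  # condensation leaves this chain-free summary untouched
  s2 <- condense_deactivations(s, net)
  expect_length(s2$deactivations, 3)
})

test_that("structural constraints of the demonstration fixture hold", {
  net <- demo_assessment_network()
  node <- function(i) net$nodes[[i + 1]]
  expect_setequal(node(6)$ascendants, c(3, 1, 0))
  expect_setequal(node(10)$ascendants, c(8, 4, 5, 2, 0))
  inactive_asc <- Filter(function(a) node(a)$prediction == "inactive",
                         node(10)$ascendants)
  expect_setequal(inactive_asc, c(2, 4, 5))
})

test_that("an all-inactive network is all IGNORE", {
  net <- make_random_network(12, seed = 2)
  for (i in seq_along(net$nodes)) net$nodes[[i]]$prediction <- "inactive"
  ass <- net_assessments(classify_nodes(net))
  expect_true(all(ass == "IGNORE"))
})

test_that("classification matches the fixpoint oracle on random networks", {
  for (seed in 1:60) {
    n <- 2 + (seed %% 9) * 3
    net <- make_random_network(n, seed = seed)
    got <- unname(net_assessments(classify_nodes(net)))
    expect_identical(got, oracle_classify_fixpoint(net),
                     info = paste("seed", seed))
  }
})

test_that("assessment invariants hold across random fixtures", {
  for (seed in 101:130) {
    net <- classify_nodes(make_random_network(2 + (seed %% 7) * 4, seed = seed))
    ass <- unname(net_assessments(net))
    preds <- net_predictions(net)
    # partition into exactly one of six types
    expect_true(all(ass %in% c("ACTIVATING", "DEACTIVATED", "DEACTIVATING",
                               "NEGATED", "ACTIVITY_IDENTIFIED", "IGNORE")))
    # root-activity equivalence
    expect_identical(any(ass == "ACTIVATING"),
                     preds[net$root_index + 1] == "active")
    for (i in seq_along(net$nodes)) {
      nd <- net$nodes[[i]]
      if (ass[i] == "DEACTIVATED")
        expect_true(any(ass[nd$parents + 1] == "DEACTIVATING"))
      if (ass[i] == "DEACTIVATING")
        expect_true(any(preds[nd$children + 1] == "active"))
      # activity sits at the lowest feature of a path
      if (ass[i] == "ACTIVATING")
        expect_false(any(ass[nd$descendants + 1] == "ACTIVATING" &
                           vapply(net$nodes[nd$descendants + 1], function(d)
                             all(d$payload %in% nd$payload), TRUE)))
    }
  }
})

test_that("summaries map assessments to query highlights", {
  oracle <- default_rule_oracle()
  # nitrobenzene: one activation localised to the nitro group
  res <- interpret(parse_structure("O=[N+]([O-])c1ccccc1"), oracle)
  expect_identical(res$summary$final_prediction, "active")
  expect_length(res$summary$activations, 1)
  expect_setequal(res$summary$activations[[1]]$atom_ids, c(0, 1, 2))

  # benzene: inactive, empty summary
  res2 <- interpret(parse_structure("c1ccccc1"), oracle)
  expect_identical(res2$summary$final_prediction, "inactive")
  expect_length(res2$summary$activations, 0)
  expect_length(res2$summary$deactivations, 0)

  # ortho carboxylic acid deactivates the aromatic amine
  res3 <- interpret(parse_structure("Nc1ccccc1C(=O)O"), oracle)
  expect_identical(res3$summary$final_prediction, "inactive")
  expect_length(res3$summary$activations, 0)
  expect_length(res3$summary$deactivations, 1)
  d <- res3$summary$deactivations[[1]]
  expect_setequal(d$deactivated$atom_ids, 0:6)        # amine + ring
  expect_setequal(d$deactivating$atom_ids, 7:9)       # the added acid context

  # 2-amino-6-nitrobenzoic acid: nitro activation plus amine deactivation
  res4 <- interpret(parse_structure("Nc1cccc([N+](=O)[O-])c1C(=O)O"), oracle)
  expect_identical(res4$summary$final_prediction, "active")
  act_sets <- lapply(res4$summary$activations, `[[`, "atom_ids")
  expect_true(any(vapply(act_sets, function(x) setequal(x, 6:8), TRUE)))
  expect_gte(length(res4$summary$deactivations), 1)

  # interpretation never changes the prediction
  lib10 <- make_toy_library(12, seed = 9)
  for (i in seq_along(lib10$structures)) {
    s <- lib10$structures[[i]]
    plain <- predict_fv(oracle, structural_key_fp(s))$label
    expect_identical(interpret(s, oracle)$summary$final_prediction, plain)
  }
})

test_that("condense_deactivations keeps the largest deactivation context", {
  # 4-level chain: leaf active -> mid1 inactive -> mid2 active -> root inactive
  payloads <- list(0L, c(0L, 1L), c(0L, 1L, 2L), c(0L, 1L, 2L, 3L))
  net <- build_bitset_network(lapply(payloads, fragnet:::new_bit_combination))
  labs <- c("active", "inactive", "active", "inactive")
  for (i in seq_along(net$nodes)) net$nodes[[i]]$prediction <- labs[i]
  net <- classify_nodes(net)
  s <- summarize_network(net)
  expect_length(s$deactivations, 2)
  s2 <- condense_deactivations(s, net)
  expect_length(s2$deactivations, 1)
  expect_identical(unname(s2$deactivations[[1]]$nodes),
                   c(2L, 3L))   # (deactivated mid2, deactivating root)
  # idempotent / fixpoint on chain-free summaries
  expect_identical(condense_deactivations(s2, net)$deactivations, s2$deactivations)
})

test_that("the bitset route mirrors the fragment route on simple alerts", {
  oracle <- default_rule_oracle()
  res <- interpret(parse_structure("O=[N+]([O-])c1ccccc1"), oracle,
                   approach = "bitset", prune_level = Inf)
  expect_identical(res$summary$final_prediction, "active")
  # the minimal activating combination carries the nitro witness atoms
  act <- res$summary$activations
  expect_gte(length(act), 1)
  expect_true(any(vapply(act, function(a) all(c(0, 1, 2) %in% a$atom_ids), TRUE)))
  # all-zero vector degenerates to a single-node network
  res2 <- interpret(parse_structure("CCCC"), oracle, approach = "bitset")
  expect_length(res2$network$nodes, 1)
  expect_identical(res2$summary$final_prediction, "inactive")
})
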