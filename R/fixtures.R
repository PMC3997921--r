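# Deterministic toy-data generators: everything here is a pure function of
# its seed, so every pipeline stage is testable without external data.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# scaffold templates (slots filled with attachment-first substituent SMILES)
.toy_scaffolds <- list(
  benzene_mono = list(tpl = "c1ccc(%s)cc1", slots = 1L),
  benzene_ortho = list(tpl = "c1ccc(%s)c(%s)c1", slots = 2L),
  benzene_para = list(tpl = "c1cc(%s)ccc1%s", slots = 2L),
  naphthalene_mono = list(tpl = "c1ccc2cc(%s)ccc2c1", slots = 1L),
  cyclohexane_mono = list(tpl = "C1CCC(%s)CC1", slots = 1L),
  butane_mono = list(tpl = "CCC(%s)C", slots = 1L)
)

# substituents; %d is the ring-closure digit when the group itself is cyclic.
# Sampling weights shape the library towards the stated fixture world: about
# a dozen nitro-containing structures per 40 and a mid-range class balance.
.toy_substituents <- list(
  nitro = list(smi = "[N+](=O)[O-]", alert = TRUE, w = 0.25),
  amine = list(smi = "N", alert = TRUE, w = 0.15),   # alert only on aromatic rings
  epoxide = list(smi = "CC%dCO%d", alert = TRUE, w = 0.08),
  aziridine = list(smi = "CC%dCN%d", alert = TRUE, w = 0.07),
  carboxylic_acid = list(smi = "C(=O)O", alert = FALSE, w = 0.10),
  methyl = list(smi = "C", alert = FALSE, w = 0.10),
  ethyl = list(smi = "CC", alert = FALSE, w = 0.05),
  chloro = list(smi = "Cl", alert = FALSE, w = 0.08),
  hydroxy = list(smi = "O", alert = FALSE, w = 0.07),
  methoxy = list(smi = "OC", alert = FALSE, w = 0.05)
)

.toy_exemplars <- c(
  benzene = "c1ccccc1",
  toluene = "Cc1ccccc1",
  nitrobenzene = "O=[N+]([O-])c1ccccc1",
  aniline = "Nc1ccccc1",
  anthranilic_acid = "Nc1ccccc1C(=O)O",
  naphthalene = "c1ccc2ccccc2c1",
  nitronaphthalene = "O=[N+]([O-])c1cccc2ccccc12",
  phenyl_oxirane = "c1ccc(cc1)C2CO2",
  methyl_aziridine = "CC1CN1",
  chlorobutane = "CCCCCl"
)

#' Deterministic toy molecule library with planted alerts
#'
#' Molecules are assembled from a scaffold + substituent grammar. Planted
#' alerts (nitro, epoxide, aziridine, aromatic amine) and the planted
#' deactivating context (ortho carboxylic acid on an aromatic amine) follow
#' the motifs the default rule oracle recognises; labels are assigned by that
#' oracle, so label logic and ground truth coincide by construction. The
#' first ten structures are fixed exemplars covering every motif class.
#'
#' @param n number of structures (>= 10).
#' @param seed RNG seed; the output is a pure function of it.
#' @param lib key library used for labelling and ground truth.
#' @return list with `structures`, `labels` (`"active"`/`"inactive"`),
#'   `smiles`, `names` and `ground_truth` (per structure: list of planted
#'   non-deactivated alert witnesses, each with `alert` and `atom_ids`).
#' @export
make_toy_library <- function(n = 40L, seed = 1L, lib = default_key_library()) {
  if (n < 10) stop("n must be at least 10 to cover all motif classes", call. = FALSE)
  smiles <- unname(.toy_exemplars)
  names_out <- names(.toy_exemplars)
  extra <- with_local_seed(seed, {
    out <- character(0)
    nm <- character(0)
    while (length(out) < n - length(.toy_exemplars)) {
      sc <- .toy_scaffolds[[sample.int(length(.toy_scaffolds), 1)]]
      digit <- 8L
      subs <- character(sc$slots)
      labels <- character(sc$slots)
      for (k in seq_len(sc$slots)) {
        pool <- .toy_substituents
        w <- vapply(pool, `[[`, 0, "w")
        idx <- sample.int(length(pool), 1, prob = w)
        pick <- pool[[idx]]
        labels[k] <- names(pool)[idx]
        smi <- pick$smi
        if (grepl("%d", smi)) {
          smi <- gsub("%d", as.character(digit), smi)
          digit <- digit + 1L
        }
        subs[k] <- smi
      }
      cand <- do.call(sprintf, c(list(sc$tpl), as.list(subs)))
      out <- c(out, cand)
      nm <- c(nm, paste0("toy_", length(out), "_", paste(labels, collapse = "_")))
    }
    list(smiles = out, names = nm)
  })
  smiles <- c(smiles, extra$smiles)
  names_out <- c(names_out, extra$names)
  structures <- mapply(parse_structure, smiles, names_out, SIMPLIFY = FALSE)
  names(structures) <- NULL
  oracle <- default_rule_oracle(lib)
  labels <- vapply(structures, function(s)
    predict_fv(oracle, structural_key_fp(s, lib))$label, "")
  ground_truth <- lapply(structures, function(s) planted_alerts(s, oracle, lib))
  list(structures = structures, labels = labels, smiles = smiles,
       names = names_out, ground_truth = ground_truth)
}

# ground truth: witnesses of each non-deactivated alert in the structure
planted_alerts <- function(s, oracle, lib) {
  out <- list()
  fvbits <- set_bits(structural_key_fp(s, lib))
  for (i in seq_along(oracle$alerts)) {
    if (!(oracle$alert_bits[i] %in% fvbits)) next
    ctx <- oracle$deact_bits[[oracle$alerts[i]]]
    if (!is.null(ctx) && any(ctx %in% fvbits)) next
    for (w in match_pattern(oracle$alerts[i], s)) {
      out[[length(out) + 1]] <- list(alert = oracle$alerts[i],
                                     atom_ids = sort(w$atom_ids))
    }
  }
  out
}

#' Random feature network with predictions
#'
#' Samples distinct random subsets of a small bit universe (always including
#' the full set as root), builds the subset-lattice network through the
#' regular constructor and attaches random predictions. Used to fuzz the
#' assessment rules against an independent oracle.
#'
#' @param n_nodes number of nodes (1..50).
#' @param seed RNG seed.
#' @param n_bits size of the bit universe (default 8).
#' @return a predicted, unassessed `FeatureNetwork`.
#' @export
make_random_network <- function(n_nodes, seed = 1L, n_bits = 8L) {
  stopifnot(n_nodes >= 1, n_nodes <= 50)
  with_local_seed(seed, {
    payloads <- list(0:(n_bits - 1L))
    keys <- paste(payloads[[1]], collapse = ",")
    guard <- 0L
    while (length(payloads) < n_nodes) {
      guard <- guard + 1L
      if (guard > 10000L) stop("cannot sample enough distinct subsets", call. = FALSE)
      bits <- which(stats::runif(n_bits) < 0.4) - 1L
      if (!length(bits) || length(bits) == n_bits) next
      key <- paste(bits, collapse = ",")
      if (key %in% keys) next
      keys <- c(keys, key)
      payloads[[length(payloads) + 1]] <- bits
    }
    net <- build_bitset_network(lapply(payloads, new_bit_combination))
    for (i in seq_along(net$nodes)) {
      net$nodes[[i]]$prediction <- if (stats::runif(1) < 0.5) "active" else "inactive"
      net$nodes[[i]]$confidence <- stats::runif(1, 0.5, 1)
    }
    net
  })
}

#' Eleven-node demonstration network exercising every assessment type
#'
#' A reconstruction of the worked assessment example: node 6 is the sole
#' activating feature (all its ascendants 3, 1, 0 are active), nodes 8 and 9
#' are active but deactivated by inactive parents 4 and 5, node 10's activity
#' is negated further up, node 7 and 2 are ignored, and the active ascendants
#' 0, 1, 3 carry activity identified lower down. The exact edge list is a
#' reconstruction consistent with every stated constraint; payloads are
#' synthetic index sets that realise the required subset relations.
#'
#' @return a predicted, unassessed `FeatureNetwork` with node indices 0-10.
#' @export
demo_assessment_network <- function() {
  edges <- rbind(   # child, parent (0-based indices)
    c(6L, 3L), c(7L, 3L), c(3L, 1L), c(1L, 0L), c(2L, 0L),
    c(4L, 2L), c(5L, 2L), c(8L, 4L), c(8L, 5L), c(9L, 5L), c(10L, 8L)
  )
  active <- c(0L, 1L, 3L, 6L, 8L, 9L, 10L)
  n <- 11L
  children <- rep(list(integer(0)), n)
  parents <- rep(list(integer(0)), n)
  for (e in seq_len(nrow(edges))) {
    ch <- edges[e, 1]; pa <- edges[e, 2]
    children[[pa + 1]] <- sort(c(children[[pa + 1]], ch))
    parents[[ch + 1]] <- sort(c(parents[[ch + 1]], pa))
  }
  # payload of a node: itself plus all its descendants (realises strict
  # subset inclusion along every edge)
  desc <- function(i) {
    out <- integer(0)
    for (ch in children[[i + 1]]) out <- union(out, c(ch, desc(ch)))
    out
  }
  nodes <- vector("list", n)
  for (i in 0:(n - 1)) {
    nd <- new_network_node(i, sort(c(i, desc(i))), "bitset")
    nd$parents <- parents[[i + 1]]
    nd$children <- children[[i + 1]]
    nd$prediction <- if (i %in% active) "active" else "inactive"
    nd$confidence <- 1
    nodes[[i + 1]] <- nd
  }
  net <- structure(list(nodes = nodes, root_index = 0L), class = "FeatureNetwork")
  compute_closures(net)
}
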