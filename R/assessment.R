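# Node assessment and interpretation summary.
#
# Every node of the feature network is predicted by the black-box model and
# then classified into exactly one of six assessment types, bottom-up:
#
#   inactive node:  DEACTIVATING  if at least one child is predicted active,
#                   IGNORE        otherwise;
#   active node:    DEACTIVATED   if at least one parent is predicted inactive,
#                   ACTIVITY_IDENTIFIED if a descendant is assessed ACTIVATING,
#                   NEGATED       if all parents are active but some ascendant
#                                 is predicted inactive,
#                   ACTIVATING    otherwise (the lowest non-deactivated active
#                                 feature on its path).
#
# The precedence DEACTIVATED > ACTIVITY_IDENTIFIED > NEGATED > ACTIVATING
# ensures a node above an established activation is never mislabelled.
# The interpretation never changes the prediction itself: the root keeps the
# plain model output.

#' Predictor contract
#'
#' A predictor is any object with a `predict_fv` method returning
#' `list(label = "active"|"inactive", confidence = numeric or NA)` for a
#' `FeatureVector`. Predictions must be deterministic per vector.
#'
#' @param model a predictor object.
#' @param fv a `FeatureVector`.
#' @return list with `label` and `confidence`.
#' @export
predict_fv <- function(model, fv) UseMethod("predict_fv")

#' @export
predict_fv.default <- function(model, fv) {
  stop("object of class '", paste(class(model), collapse = "/"),
       "' does not implement the predictor contract (predict_fv)", call. = FALSE)
}

#' Run the model over every network node
#'
#' @param net a `FeatureNetwork` whose nodes carry feature vectors.
#' @param model a predictor (see [predict_fv()]).
#' @return the network with `prediction` / `confidence` filled on every node.
#' @export
predict_nodes <- function(net, model) {
  for (i in seq_along(net$nodes)) {
    fv <- net$nodes[[i]]$feature_vector
    if (is.null(fv)) stop("node ", net$nodes[[i]]$index,
                          " has no feature vector", call. = FALSE)
    res <- tryCatch(predict_fv(model, fv), error = function(e)
      stop("predictor failed on node ", net$nodes[[i]]$index, ": ",
           conditionMessage(e), call. = FALSE))
    if (!res$label %in% c("active", "inactive"))
      stop("predictor returned invalid label on node ",
           net$nodes[[i]]$index, call. = FALSE)
    net$nodes[[i]]$prediction <- res$label
    net$nodes[[i]]$confidence <- if (is.null(res$confidence)) NA_real_ else res$confidence
  }
  net
}

#' Classify every node into one of the six assessment types
#'
#' Single bottom-up pass in ascending payload size. ACTIVATING decisions
#' depend only on already-visited descendants and on raw predictions of
#' parents and ascendants, so one pass suffices.
#'
#' @param net a predicted `FeatureNetwork`.
#' @return the network with `assessment` set on every node.
#' @export
classify_nodes <- function(net) {
  n <- length(net$nodes)
  preds <- vapply(net$nodes, `[[`, "", "prediction")
  if (anyNA(preds)) stop("all nodes must be predicted before classification",
                         call. = FALSE)
  active <- preds == "active"
  sizes <- vapply(net$nodes, function(nd) length(nd$payload), 0L)
  idx1 <- vapply(net$nodes, `[[`, 0L, "index") + 1L
  ord <- order(sizes, idx1)
  assessment <- rep(NA_character_, n)
  for (i in ord) {
    nd <- net$nodes[[i]]
    if (!active[i]) {
      child_active <- any(active[nd$children + 1])
      assessment[i] <- if (child_active) "DEACTIVATING" else "IGNORE"
    } else {
      parent_inactive <- any(!active[nd$parents + 1])
      if (parent_inactive) {
        assessment[i] <- "DEACTIVATED"
      } else if (any(assessment[nd$descendants + 1] == "ACTIVATING", na.rm = TRUE)) {
        assessment[i] <- "ACTIVITY_IDENTIFIED"
      } else if (any(!active[nd$ascendants + 1])) {
        assessment[i] <- "NEGATED"
      } else {
        assessment[i] <- "ACTIVATING"
      }
    }
  }
  for (i in seq_len(n)) net$nodes[[i]]$assessment <- assessment[i]
  net
}

node_highlight <- function(net, i, role) {   # i: 1-based node position
  nd <- net$nodes[[i]]
  if (nd$payload_kind == "fragment") {
    atoms <- nd$fragment$atom_ids
    bonds <- nd$fragment$bond_ids
  } else {
    # bitset payload: union of provenance witnesses for member bits of the
    # root feature vector
    root_fv <- net$nodes[[net$root_index + 1]]$feature_vector
    atoms <- integer(0); bonds <- integer(0)
    if (!is.null(root_fv$provenance)) {
      for (b in nd$payload) {
        for (w in root_fv$provenance[[b + 1]]) {
          atoms <- union(atoms, w$atoms)
          bonds <- union(bonds, w$bonds)
        }
      }
    }
  }
  list(atom_ids = sort(atoms), bond_ids = sort(bonds), role = role)
}

#' Summarise an assessed network
#'
#' Activations are the atom/bond highlights of every ACTIVATING node;
#' deactivations are (deactivated child, deactivating parent) edge pairs,
#' with the deactivating highlight reduced to the context the parent adds
#' beyond the child. NEGATED and ACTIVITY_IDENTIFIED nodes do not appear:
#' the former are subsets of a larger deactivation context, the latter
#' restate an activation already reported lower down.
#'
#' @param net a classified `FeatureNetwork`.
#' @return an `InterpretationSummary`.
#' @export
summarize_network <- function(net) {
  ass <- vapply(net$nodes, `[[`, "", "assessment")
  if (anyNA(ass)) stop("network must be classified before summary", call. = FALSE)
  activations <- list()
  act_nodes <- integer(0)
  for (i in which(ass == "ACTIVATING")) {
    activations[[length(activations) + 1]] <- node_highlight(net, i, "ACTIVATING")
    act_nodes <- c(act_nodes, net$nodes[[i]]$index)
  }
  deactivations <- list()
  for (i in which(ass == "DEACTIVATED")) {
    nd <- net$nodes[[i]]
    for (p in nd$parents) {
      if (ass[p + 1] != "DEACTIVATING") next
      child_h <- node_highlight(net, i, "DEACTIVATED")
      parent_h <- node_highlight(net, p + 1, "DEACTIVATING")
      ctx_atoms <- setdiff(parent_h$atom_ids, child_h$atom_ids)
      ctx_bonds <- setdiff(parent_h$bond_ids, child_h$bond_ids)
      if (length(ctx_atoms) || length(ctx_bonds)) {
        parent_h$atom_ids <- ctx_atoms
        parent_h$bond_ids <- ctx_bonds
      }
      deactivations[[length(deactivations) + 1]] <- list(
        deactivated = child_h, deactivating = parent_h,
        nodes = c(deactivated = nd$index, deactivating = as.integer(p)))
    }
  }
  root <- net$nodes[[net$root_index + 1]]
  structure(
    list(final_prediction = root$prediction,
         confidence = root$confidence,
         activations = activations,
         activation_nodes = sort(act_nodes),
         deactivations = deactivations),
    class = "InterpretationSummary"
  )
}

#' @exportS3Method base::print
print.InterpretationSummary <- function(x, ...) {
  cat(sprintf("<InterpretationSummary: %s; %d activation(s), %d deactivation pair(s)>\n",
              x$final_prediction, length(x$activations), length(x$deactivations)))
  for (a in x$activations)
    cat(sprintf("  ACTIVATING atoms {%s} bonds {%s}\n",
                paste(a$atom_ids, collapse = ","), paste(a$bond_ids, collapse = ",")))
  for (d in x$deactivations)
    cat(sprintf("  DEACTIVATED atoms {%s} by atoms {%s} (nodes %d-%d)\n",
                paste(d$deactivated$atom_ids, collapse = ","),
                paste(d$deactivating$atom_ids, collapse = ","),
                d$nodes[["deactivated"]], d$nodes[["deactivating"]]))
  invisible(x)
}

#' Keep only the largest context of chained deactivations
#'
#' When activity is deactivated, re-established higher in the network and
#' deactivated again, the summary lists several pairs along one path. This
#' retains, for each such chain, only the pair whose deactivation happened
#' in the largest context: a pair is dropped when another pair's deactivated
#' node is an ascendant of its deactivating node.
#'
#' @param summary an `InterpretationSummary` from [summarize_network()].
#' @param net the classified network the summary came from.
#' @return the summary with a (possibly) reduced set of deactivation pairs.
#' @export
condense_deactivations <- function(summary, net) {
  if (length(summary$deactivations) < 2) return(summary)
  idx_of <- function(index) which(vapply(net$nodes, `[[`, 0L, "index") == index)
  deact_nodes <- vapply(summary$deactivations, function(d) d$nodes[["deactivated"]], 0L)
  keep <- rep(TRUE, length(summary$deactivations))
  for (i in seq_along(summary$deactivations)) {
    deactivating <- summary$deactivations[[i]]$nodes[["deactivating"]]
    asc <- net$nodes[[idx_of(deactivating)]]$ascendants
    if (any(deact_nodes[-i] %in% asc)) keep[i] <- FALSE
  }
  summary$deactivations <- summary$deactivations[keep]
  summary
}

#' End-to-end interpretation of a query structure
#'
#' Composes the full pipeline: sub-feature generation (reduced-graph
#' fragmentation or bit-combination enumeration), network construction,
#' per-node prediction, six-way assessment and summary. The summary's final
#' prediction is exactly the plain model prediction of the query.
#'
#' @param query a standardized `Structure`.
#' @param model a predictor (see [predict_fv()]).
#' @param approach `"fragment"` (structure enumeration) or `"bitset"`
#'   (feature-vector enumeration).
#' @param lib key library for fingerprints and units.
#' @param scheme fingerprint scheme for fragment nodes.
#' @param prune_level bitset-route pruning (see [enumerate_bitsets()]).
#' @param max_depth fragment-route unit-subset size limit.
#' @param condense apply [condense_deactivations()] to the summary.
#' @param hash_depth,n_bits hashed-path parameters when
#'   `scheme = "hashed_path"`.
#' @return list with `summary` (an `InterpretationSummary`) and `network`
#'   (the assessed `FeatureNetwork`).
#' @examples
#' \donttest{
#' oracle <- default_rule_oracle()
#' res <- interpret(parse_structure("O=[N+]([O-])c1ccccc1"), oracle)
#' res$summary
#' }
#' @export
interpret <- function(query, model, approach = c("fragment", "bitset"),
                      lib = default_key_library(),
                      scheme = c("structural_keys", "hashed_path"),
                      prune_level = 4L, max_depth = Inf, condense = FALSE,
                      hash_depth = 6L, n_bits = 1024L) {
  approach <- match.arg(approach)
  scheme <- match.arg(scheme)
  stopifnot(inherits(query, "Structure"))
  if (approach == "fragment") {
    rg <- build_reduced_graph(query, lib)
    frags <- enumerate_fragments(rg, max_depth = max_depth)
    fvs <- lapply(frags, function(f)
      fp_for_fragment(query, f, scheme = scheme, lib = lib,
                      max_depth = hash_depth, n_bits = n_bits))
    net <- build_fragment_network(frags, feature_vectors = fvs)
  } else {
    fv <- structural_key_fp(query, lib)
    if (sum(fv$bits) == 0) {
      # no set bits: the query is its own single-node network carrying the
      # all-zero vector (nothing to enumerate)
      node <- new_network_node(0L, integer(0), "bitset", feature_vector = fv)
      net <- structure(list(nodes = list(node), root_index = 0L),
                       class = "FeatureNetwork")
    } else {
      combos <- enumerate_bitsets(fv, prune_level = prune_level)
      net <- build_bitset_network(combos)
      for (i in seq_along(net$nodes)) {
        bits <- integer(length(fv$bits))
        bits[net$nodes[[i]]$payload + 1] <- 1L
        sub_fv <- new_feature_vector(bits, fv$scheme, provenance = fv$provenance,
                                     params = fv$params)
        net$nodes[[i]]$feature_vector <- sub_fv
      }
      net$nodes[[net$root_index + 1]]$feature_vector <- fv
    }
  }
  net <- predict_nodes(net, model)
  net <- classify_nodes(net)
  summary <- summarize_network(net)
  if (condense) summary <- condense_deactivations(summary, net)
  list(summary = summary, network = net)
}
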