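# Feature networks: DAGs of enumerated sub-features ordered by strict subset
# inclusion of their payloads (bit sets for the feature-vector route, atom-id
# sets for the fragment route). Parenthood is the minimal-enumerated-superset
# relation, which also bridges the level gap introduced by pruning.

new_network_node <- function(index, payload, payload_kind,
                             fragment = NULL, feature_vector = NULL) {
  structure(
    list(index = index, payload = sort(as.integer(payload)),
         payload_kind = payload_kind, fragment = fragment,
         feature_vector = feature_vector,
         prediction = NA_character_, confidence = NA_real_,
         assessment = NA_character_,
         parents = integer(0), children = integer(0),
         ascendants = integer(0), descendants = integer(0)),
    class = "NetworkNode"
  )
}

# Core constructor shared by both routes: payloads is a list of sorted
# integer vectors, already deduplicated; node order / 0-based indices follow
# (payload size, lexicographic payload).
build_network <- function(payloads, payload_kind, fragments = NULL,
                          feature_vectors = NULL) {
  n <- length(payloads)
  keys <- vapply(payloads, function(p) paste(p, collapse = ","), "")
  if (anyDuplicated(keys)) stop("duplicate payload sets in network input", call. = FALSE)
  sizes <- lengths(payloads)
  lex <- vapply(payloads, function(p) paste(sprintf("%09d", p), collapse = ","), "")
  ord <- order(sizes, lex)
  payloads <- payloads[ord]
  if (!is.null(fragments)) fragments <- fragments[ord]
  if (!is.null(feature_vectors)) feature_vectors <- feature_vectors[ord]
  sizes <- sizes[ord]

  root_payload <- payloads[[n]]
  for (p in payloads) {
    if (!all(p %in% root_payload))
      stop("root payload is not a superset of every node", call. = FALSE)
  }
  if (n > 1 && sizes[n] == sizes[n - 1])
    stop("no unique maximal payload (root)", call. = FALSE)

  # subset matrix via set-membership counts
  maxid <- max(unlist(payloads)) + 1L
  M <- matrix(FALSE, nrow = n, ncol = maxid)
  for (i in seq_len(n)) M[i, payloads[[i]] + 1] <- TRUE
  common <- M %*% t(M)                        # |payload_i intersect payload_j|
  # sub[i, j] iff |i ∩ j| == |i| and |j| > |i|  (i strict subset of j)
  sub <- (common == matrix(sizes, n, n)) & outer(sizes, sizes, `<`)
  reach2 <- (sub %*% sub) > 0                 # i ⊂ l ⊂ j for some enumerated l
  parent_of <- sub & !reach2                  # minimal enumerated supersets

  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    nodes[[i]] <- new_network_node(i - 1L, payloads[[i]], payload_kind,
                                   fragment = if (!is.null(fragments)) fragments[[i]],
                                   feature_vector = if (!is.null(feature_vectors)) feature_vectors[[i]])
    nodes[[i]]$parents <- which(parent_of[i, ]) - 1L
    nodes[[i]]$children <- which(parent_of[, i]) - 1L
  }
  net <- structure(list(nodes = nodes, root_index = n - 1L), class = "FeatureNetwork")
  compute_closures(net)
}

# ascendant/descendant transitive closures, processed along payload size
compute_closures <- function(net) {
  n <- length(net$nodes)
  sizes <- vapply(net$nodes, function(nd) length(nd$payload), 0L)
  for (i in order(-sizes)) {     # root first: parents already done
    asc <- integer(0)
    for (p in net$nodes[[i]]$parents)
      asc <- union(asc, c(p, net$nodes[[p + 1]]$ascendants))
    net$nodes[[i]]$ascendants <- sort(asc)
  }
  for (i in order(sizes)) {      # leaves first
    dsc <- integer(0)
    for (cc in net$nodes[[i]]$children)
      dsc <- union(dsc, c(cc, net$nodes[[cc + 1]]$descendants))
    net$nodes[[i]]$descendants <- sort(dsc)
  }
  net
}

#' Build a feature network from bit combinations
#'
#' Node B is a parent of node A iff A's bits are a strict subset of B's and
#' no enumerated combination lies strictly between them; with pruning the
#' root therefore adopts all top-level pruned combinations directly.
#'
#' @param combos list of `BitCombination`s (unique).
#' @param root the full-query combination; must be among / a superset of all.
#' @return a `FeatureNetwork` with 0-based node indices, root = full set.
#' @export
build_bitset_network <- function(combos, root = NULL) {
  payloads <- lapply(combos, function(x) sort(as.integer(unclass(x))))
  if (!is.null(root)) {
    root <- sort(as.integer(unclass(root)))
    keys <- vapply(payloads, paste, "", collapse = ",")
    if (!paste(root, collapse = ",") %in% keys)
      payloads <- c(payloads, list(root))
  }
  build_network(payloads, "bitset")
}

#' Build a feature network from fragments
#'
#' Parenthood by minimal strict superset of atom-id sets; the unique fragment
#' with maximal atom set (the full query) becomes the root.
#'
#' @param frags list of `Fragment`s with unique atom sets.
#' @param feature_vectors optional list of per-fragment `FeatureVector`s
#'   (same order as `frags`).
#' @return a `FeatureNetwork`.
#' @export
build_fragment_network <- function(frags, feature_vectors = NULL) {
  payloads <- lapply(frags, `[[`, "atom_ids")
  build_network(payloads, "fragment", fragments = frags,
                feature_vectors = feature_vectors)
}

#' @exportS3Method base::print
print.FeatureNetwork <- function(x, ...) {
  preds <- vapply(x$nodes, `[[`, "", "prediction")
  ass <- vapply(x$nodes, `[[`, "", "assessment")
  cat(sprintf("<FeatureNetwork: %d nodes, root=%d%s%s>\n", length(x$nodes),
              x$root_index,
              if (all(is.na(preds))) "" else ", predicted",
              if (all(is.na(ass))) "" else ", assessed"))
  invisible(x)
}

.assessment_colours <- c(
  ACTIVATING = "red", DEACTIVATING = "green", DEACTIVATED = "orange",
  NEGATED = "purple", ACTIVITY_IDENTIFIED = "pink", IGNORE = "blue"
)

#' Export a feature network
#'
#' JSON export round-trips all node fields and indices; DOT export colours
#' nodes by assessment (activating red, deactivating green, deactivated
#' orange, negated purple, activity-identified pink, ignore blue, unassessed
#' grey).
#'
#' @param net a `FeatureNetwork`.
#' @param format `"json"` or `"dot"`.
#' @return a character scalar with the serialised network.
#' @export
export_network <- function(net, format = c("json", "dot")) {
  format <- match.arg(format)
  if (format == "json") {
    nodes <- lapply(net$nodes, function(nd) {
      list(index = nd$index, payload = nd$payload,
           payload_kind = nd$payload_kind,
           key = if (!is.null(nd$fragment)) nd$fragment$key else NULL,
           prediction = if (is.na(nd$prediction)) NULL else nd$prediction,
           confidence = if (is.na(nd$confidence)) NULL else nd$confidence,
           assessment = if (is.na(nd$assessment)) NULL else nd$assessment,
           parents = nd$parents, children = nd$children,
           ascendants = nd$ascendants, descendants = nd$descendants)
    })
    return(as.character(jsonlite::toJSON(
      list(root_index = net$root_index, nodes = nodes),
      auto_unbox = TRUE, null = "null", digits = NA)))
  }
  lines <- c("digraph feature_network {", "  rankdir=BT;")
  for (nd in net$nodes) {
    col <- if (is.na(nd$assessment)) "grey" else .assessment_colours[[nd$assessment]]
    label <- if (!is.null(nd$fragment)) nd$fragment$key
      else paste0("{", paste(nd$payload, collapse = ","), "}")
    pred <- if (is.na(nd$prediction)) "" else paste0("\\n", nd$prediction)
    lines <- c(lines, sprintf(
      "  n%d [label=\"%d: %s%s\", style=filled, fillcolor=%s];",
      nd$index, nd$index, label, pred, col))
  }
  for (nd in net$nodes) {
    for (p in nd$parents)
      lines <- c(lines, sprintf("  n%d -> n%d;", nd$index, p))
  }
  paste(c(lines, "}"), collapse = "\n")
}
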