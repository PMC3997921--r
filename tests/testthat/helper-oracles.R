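# Independent oracles used to check the implementation. These deliberately
# use different algorithms (fixpoint iteration, exhaustive enumeration,
# pairwise brute force) from the code paths they verify.

# Fixpoint re-implementation of the six assessment rules: evaluate every
# node's rule on the current assessment state until nothing changes.
oracle_classify_fixpoint <- function(net) {
  n <- length(net$nodes)
  active <- vapply(net$nodes, `[[`, "", "prediction") == "active"
  assessment <- rep(NA_character_, n)
  repeat {
    prev <- assessment
    for (i in seq_len(n)) {
      nd <- net$nodes[[i]]
      if (!active[i]) {
        assessment[i] <- if (any(active[nd$children + 1])) "DEACTIVATING" else "IGNORE"
      } else if (any(!active[nd$parents + 1])) {
        assessment[i] <- "DEACTIVATED"
      } else if (any(assessment[nd$descendants + 1] == "ACTIVATING", na.rm = TRUE)) {
        assessment[i] <- "ACTIVITY_IDENTIFIED"
      } else if (any(!active[nd$ascendants + 1])) {
        assessment[i] <- "NEGATED"
      } else {
        assessment[i] <- "ACTIVATING"
      }
    }
    if (identical(prev, assessment)) break
  }
  assessment
}

# Exhaustive connected-subset count of an undirected graph given as a 0-based
# edge list: tries every non-empty subset and checks connectivity by BFS.
oracle_connected_subset_count <- function(n_vertices, edges) {
  adj <- rep(list(integer(0)), n_vertices)
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1] + 1; v <- edges[e, 2] + 1
      adj[[u]] <- c(adj[[u]], v - 1); adj[[v]] <- c(adj[[v]], u - 1)
    }
  }
  count <- 0L
  for (mask in seq_len(2^n_vertices - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n_vertices - 1))) > 0) - 1
    seen <- members[1]; queue <- seen
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nxt <- setdiff(intersect(adj[[u + 1]], members), seen)
      seen <- c(seen, nxt); queue <- c(queue, nxt)
    }
    if (length(seen) == length(members)) count <- count + 1L
  }
  count
}

# Brute-force minimal strict superset relation over a list of integer-set
# payloads: parent[i, j] is TRUE iff payload i is a strict subset of j with
# no payload strictly between.
oracle_minimal_supersets <- function(payloads) {
  n <- length(payloads)
  strict_sub <- function(a, b) length(a) < length(b) && all(a %in% b)
  parent <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!strict_sub(payloads[[i]], payloads[[j]])) next
    between <- FALSE
    for (l in seq_len(n)) {
      if (l == i || l == j) next
      if (strict_sub(payloads[[i]], payloads[[l]]) &&
          strict_sub(payloads[[l]], payloads[[j]])) { between <- TRUE; break }
    }
    parent[i, j] <- !between
  }
  parent
}

# convenience accessors
net_assessments <- function(net) {
  out <- vapply(net$nodes, `[[`, "", "assessment")
  names(out) <- vapply(net$nodes, `[[`, 0L, "index")
  out
}

net_predictions <- function(net) vapply(net$nodes, `[[`, "", "prediction")
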