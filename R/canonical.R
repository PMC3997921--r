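# Canonical SMILES writer. Canonical ranks come from iterative neighbourhood
# refinement (Morgan-style) of an initial invariant (element, aromaticity,
# charge, degree, effective H count); remaining ties are split one atom at a
# time, lowest current rank first. The string is then emitted by a DFS that
# always visits the lowest-ranked unvisited neighbour first. This is not
# RDKit-canonical; it is deterministic and structure-invariant for the
# molecule classes in scope, which is all fragment keys require.

canonical_ranks <- function(s) {
  na <- n_atoms(s)
  hs <- implicit_h_counts(s)
  deg <- if (n_bonds(s)) tabulate(c(s$bonds$begin, s$bonds$end) + 1, nbins = na) else integer(na)
  inv <- paste(s$atoms$element, s$atoms$aromatic, s$atoms$charge, deg, hs, sep = "|")
  rank <- as.integer(factor(inv, levels = sort(unique(inv)))) - 1L
  adj <- structure_adjacency(s)
  bond_lab <- if (n_bonds(s)) ifelse(s$bonds$aromatic, "a", as.character(s$bonds$order)) else character(0)

  refine <- function(rank) {
    repeat {
      sig <- vapply(seq_len(na), function(i) {
        nb <- adj[[i]]$nbr; bd <- adj[[i]]$bond
        if (length(nb)) {
          # zero-padded ranks so string order equals numeric order
          pairs <- sort(paste0(bond_lab[bd + 1], ":", sprintf("%05d", rank[nb + 1])))
          paste0(sprintf("%05d", rank[i]), "|", paste(pairs, collapse = ","))
        } else sprintf("%05d", rank[i])
      }, "")
      new_rank <- as.integer(factor(sig, levels = sort(unique(sig)))) - 1L
      if (identical(new_rank, rank)) return(rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  # tie-break until discrete
  while (length(unique(rank)) < na) {
    tied <- which(duplicated(rank) | duplicated(rank, fromLast = TRUE))
    pick <- tied[order(rank[tied], tied)][1]
    rank <- rank * 2L
    rank[pick] <- rank[pick] - 1L
    rank <- as.integer(factor(rank, levels = sort(unique(rank)))) - 1L
    rank <- refine(rank)
  }
  rank
}

#' Canonical SMILES of a structure
#'
#' @param s a `Structure`.
#' @return single SMILES string, identical for identically-connected inputs
#'   regardless of atom order.
#' @examples
#' canonical_smiles(parse_structure("C(N)(C)O"))
#' @export
canonical_smiles <- function(s) {
  stopifnot(inherits(s, "Structure"))
  na <- n_atoms(s)
  comp <- structure_components(s)
  if (max(comp) > 1) {
    parts <- vapply(sort(unique(comp)), function(k) {
      canonical_smiles(subset_structure(s, s$atoms$atom_id[comp == k]))
    }, "")
    return(paste(sort(parts), collapse = "."))
  }
  rank <- canonical_ranks(s)
  adj <- structure_adjacency(s)
  hs <- implicit_h_counts(s)

  bond_sym <- function(bid) {
    b <- s$bonds[bid + 1, ]
    if (b$aromatic) return("")
    if (b$order == 2L) return("=")
    if (b$order == 3L) return("#")
    # single bond between two aromatic atoms needs explicit '-'
    if (s$atoms$aromatic[b$begin + 1] && s$atoms$aromatic[b$end + 1]) return("-")
    ""
  }

  atom_token <- function(i) {   # i is 1-based row
    el <- s$atoms$element[i]
    arom <- s$atoms$aromatic[i]
    ch <- s$atoms$charge[i]
    sym <- if (arom) tolower(el) else el
    organic <- el %in% .organic_subset && !(arom && !(tolower(el) %in% .aromatic_organic))
    # does a bare token re-parse to the right H count?
    needs_h <- FALSE
    if (!is.na(s$atoms$hcount[i])) {
      probe <- s
      probe$atoms$hcount[i] <- NA_integer_
      needs_h <- implicit_h_counts(probe)[i] != s$atoms$hcount[i]
    }
    if (organic && ch == 0L && !needs_h) return(sym)
    hpart <- if (hs[i] == 0L) "" else if (hs[i] == 1L) "H" else paste0("H", hs[i])
    cpart <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
      else if (ch > 0) paste0("+", ch) else as.character(ch)
    paste0("[", sym, hpart, cpart, "]")
  }

  # assign ring-closure digits: DFS over spanning tree from the rank-0 atom,
  # non-tree edges become ring closures
  visited <- rep(FALSE, na)
  bond_done <- rep(FALSE, max(1L, n_bonds(s)))
  ring_digit <- 0L
  tree_children <- vector("list", na)
  closure_at <- vector("list", na)  # per atom: list of (digit, bond)

  start <- which(rank == min(rank))[1]
  dfs_assign <- function(u) {   # u 1-based
    visited[u] <<- TRUE
    nb <- adj[[u]]$nbr; bd <- adj[[u]]$bond
    ord <- order(rank[nb + 1])
    for (k in ord) {
      v <- nb[k] + 1L; bid <- bd[k]
      if (bond_done[bid + 1]) next
      if (!visited[v]) {
        bond_done[bid + 1] <<- TRUE
        tree_children[[u]] <<- c(tree_children[[u]], list(list(child = v, bond = bid)))
        dfs_assign(v)
      } else {
        # back edge: becomes a ring closure at both endpoints
        bond_done[bid + 1] <<- TRUE
        ring_digit <<- ring_digit + 1L
        closure_at[[v]] <<- c(closure_at[[v]], list(list(digit = ring_digit, bond = bid)))
        closure_at[[u]] <<- c(closure_at[[u]], list(list(digit = ring_digit, bond = bid)))
      }
    }
  }
  dfs_assign(start)

  digit_token <- function(d) if (d < 10) as.character(d) else paste0("%", sprintf("%02d", d))

  emit <- function(u, in_bond) {
    out <- paste0(in_bond, atom_token(u))
    for (cl in closure_at[[u]]) {
      # bond symbol on the closure is written at the opening atom only when
      # non-default; writing at both ends is legal, we write at first site
      out <- paste0(out, bond_sym(cl$bond), digit_token(cl$digit))
    }
    kids <- tree_children[[u]]
    if (length(kids)) {
      for (k in seq_along(kids)[-length(kids)]) {
        kid <- kids[[k]]
        out <- paste0(out, "(", emit(kid$child, bond_sym(kid$bond)), ")")
      }
      last <- kids[[length(kids)]]
      out <- paste0(out, emit(last$child, bond_sym(last$bond)))
    }
    out
  }
  emit(start, "")
}
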