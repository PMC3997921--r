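# Ring and aromaticity perception.
#
# SSSR: candidate rings are the shortest cycles through every bond; a basis of
# |E| - |V| + components rings is selected smallest-first under GF(2) linear
# independence of bond-incidence vectors. Adequate and deterministic for the
# small organic molecules in scope.

#' Smallest set of smallest rings
#'
#' @param s a `Structure`.
#' @return list of rings; each ring is a list with `atom_ids` (ordered around
#'   the ring, 0-based) and `bond_ids`.
#' @export
sssr <- function(s) {
  nb <- n_bonds(s)
  na <- n_atoms(s)
  if (nb == 0) return(list())
  ncomp <- max(structure_components(s))
  n_rings <- nb - na + ncomp
  if (n_rings <= 0) return(list())
  adj <- structure_adjacency(s)

  shortest_cycle_through <- function(bid) {
    # BFS from begin to end avoiding bond bid
    src <- s$bonds$begin[bid + 1]; dst <- s$bonds$end[bid + 1]
    prev_atom <- rep(NA_integer_, na); prev_bond <- rep(NA_integer_, na)
    seen <- rep(FALSE, na)
    seen[src + 1] <- TRUE
    queue <- src
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      ent <- adj[[a + 1]]
      for (k in seq_along(ent$nbr)) {
        if (ent$bond[k] == bid) next
        nb_atom <- ent$nbr[k]
        if (!seen[nb_atom + 1]) {
          seen[nb_atom + 1] <- TRUE
          prev_atom[nb_atom + 1] <- a
          prev_bond[nb_atom + 1] <- ent$bond[k]
          if (nb_atom == dst) {
            path_atoms <- dst; path_bonds <- integer(0)
            cur <- dst
            while (cur != src) {
              path_bonds <- c(path_bonds, prev_bond[cur + 1])
              cur <- prev_atom[cur + 1]
              path_atoms <- c(path_atoms, cur)
            }
            return(list(atom_ids = rev(path_atoms), bond_ids = c(rev(path_bonds), bid)))
          }
          queue <- c(queue, nb_atom)
        }
      }
    }
    NULL
  }

  cands <- list()
  for (bid in 0:(nb - 1)) {
    r <- shortest_cycle_through(bid)
    if (!is.null(r)) cands[[length(cands) + 1]] <- r
  }
  if (!length(cands)) return(list())
  sizes <- vapply(cands, function(r) length(r$atom_ids), 0L)
  keys <- vapply(cands, function(r) paste(sort(r$bond_ids), collapse = ","), "")
  ord <- order(sizes, keys)
  cands <- cands[ord][!duplicated(keys[ord])]

  # greedy GF(2) independence on bond incidence vectors
  basis <- matrix(FALSE, nrow = 0, ncol = nb)
  chosen <- list()
  for (r in cands) {
    vec <- rep(FALSE, nb)
    vec[r$bond_ids + 1] <- TRUE
    red <- vec
    if (nrow(basis) > 0) {
      for (row in seq_len(nrow(basis))) {
        pivot <- which(basis[row, ])[1]
        if (red[pivot]) red <- xor(red, basis[row, ])
      }
    }
    if (any(red)) {
      basis <- rbind(basis, red)
      chosen[[length(chosen) + 1]] <- r
      if (length(chosen) == n_rings) break
    }
  }
  chosen
}

# Aromaticity perception over SSSR rings of size 5-6. An atom contributes
# 1 pi electron when it has a double/triple bond to another ring-member atom,
# 2 when it is a heteroatom (N with an H or three single-bonded neighbours,
# O, S) with no multiple bond, and fails otherwise. A ring is aromatic when
# every member contributes and the total is 6. Exocyclic double bonds (e.g.
# quinone C=O) contribute nothing, so quinones stay non-aromatic.
perceive_aromaticity <- function(s) {
  rings <- sssr(s)
  if (!length(rings)) return(demote_stray_aromatic(s, rings))
  ring_atoms_all <- unique(unlist(lapply(rings, `[[`, "atom_ids")))
  hs <- implicit_h_counts(s)
  deg <- tabulate(c(s$bonds$begin, s$bonds$end) + 1, nbins = n_atoms(s))

  atom_multibond_to_ring <- function(a) {
    idx <- which((s$bonds$begin == a | s$bonds$end == a) &
                   (s$bonds$order >= 2L | s$bonds$aromatic))
    if (!length(idx)) return(FALSE)
    others <- ifelse(s$bonds$begin[idx] == a, s$bonds$end[idx], s$bonds$begin[idx])
    any(others %in% ring_atoms_all)
  }

  for (r in rings) {
    sz <- length(r$atom_ids)
    if (!(sz %in% c(5L, 6L))) next
    pi <- 0L
    ok <- TRUE
    for (a in r$atom_ids) {
      el <- s$atoms$element[a + 1]
      if (atom_multibond_to_ring(a)) {
        pi <- pi + 1L
      } else if (el %in% c("O", "S", "Se")) {
        pi <- pi + 2L
      } else if (el == "N" && (hs[a + 1] > 0 || deg[a + 1] >= 3)) {
        pi <- pi + 2L
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && pi == 6L) {
      s$atoms$aromatic[r$atom_ids + 1] <- TRUE
      s$bonds$aromatic[r$bond_ids + 1] <- TRUE
      s$bonds$order[r$bond_ids + 1] <- 1L
    }
  }
  demote_stray_aromatic(s, rings)
}

# Aromatic flags are only meaningful inside rings: demote aromatic bonds not
# in any SSSR ring (e.g. a biphenyl bridge written without '-') and aromatic
# atoms with no aromatic ring bond.
demote_stray_aromatic <- function(s, rings = sssr(s)) {
  ring_bonds <- unique(unlist(lapply(rings, `[[`, "bond_ids")))
  if (n_bonds(s) > 0) {
    stray <- s$bonds$aromatic & !(s$bonds$bond_id %in% ring_bonds)
    if (any(stray)) {
      s$bonds$aromatic[stray] <- FALSE
      s$bonds$order[stray] <- 1L
    }
    arom_atoms <- unique(c(s$bonds$begin[s$bonds$aromatic], s$bonds$end[s$bonds$aromatic]))
    s$atoms$aromatic <- s$atoms$atom_id %in% arom_atoms
  } else {
    s$atoms$aromatic <- FALSE
  }
  s
}

#' Standardize a structure
#'
#' Applies the curation conventions assumed by the interpretation pipeline:
#' explicit hydrogen atoms are folded into neighbour H counts, aromaticity is
#' perceived (stereo was already stripped at parse), and optionally only the
#' largest organic component is retained (salt stripping, largest-fragment
#' rule with canonical-SMILES tie-break).
#'
#' @param s a `Structure`.
#' @param strip_salts keep only the largest organic component.
#' @return a standardized `Structure`; idempotent under re-application.
#' @export
standardize <- function(s, strip_salts = FALSE) {
  stopifnot(inherits(s, "Structure"))
  s <- remove_explicit_h(s)
  if (strip_salts) s <- keep_largest_component(s)
  s <- perceive_aromaticity(s)
  validate_structure(s)
}

remove_explicit_h <- function(s) {
  h_ids <- s$atoms$atom_id[s$atoms$element == "H"]
  if (!length(h_ids)) return(s)
  h_bond <- s$bonds$begin %in% h_ids | s$bonds$end %in% h_ids
  # implicit counts with every H-incident bond removed, so H neighbours can
  # be added back exactly once
  tmp <- s
  tmp$bonds <- tmp$bonds[!h_bond, , drop = FALSE]
  imp <- implicit_h_counts(tmp)
  n_h_nbr <- integer(n_atoms(s))
  for (b in which(h_bond)) {
    u <- s$bonds$begin[b]; v <- s$bonds$end[b]
    if (u %in% h_ids && !(v %in% h_ids)) n_h_nbr[v + 1] <- n_h_nbr[v + 1] + 1L
    if (v %in% h_ids && !(u %in% h_ids)) n_h_nbr[u + 1] <- n_h_nbr[u + 1] + 1L
  }
  for (i in which(n_h_nbr > 0)) {
    base <- if (is.na(s$atoms$hcount[i])) imp[i] else s$atoms$hcount[i]
    s$atoms$hcount[i] <- base + n_h_nbr[i]
  }
  subset_structure(s, setdiff(s$atoms$atom_id, h_ids))
}

# Re-index a structure to a subset of atom ids (keeps relative order).
subset_structure <- function(s, keep_atom_ids) {
  keep_atom_ids <- sort(keep_atom_ids)
  old2new <- rep(NA_integer_, n_atoms(s))
  old2new[keep_atom_ids + 1] <- seq_along(keep_atom_ids) - 1L
  atoms <- s$atoms[s$atoms$atom_id %in% keep_atom_ids, , drop = FALSE]
  atoms$atom_id <- old2new[atoms$atom_id + 1]
  keep_b <- s$bonds$begin %in% keep_atom_ids & s$bonds$end %in% keep_atom_ids
  bonds <- s$bonds[keep_b, , drop = FALSE]
  if (nrow(bonds)) {
    bonds$begin <- old2new[bonds$begin + 1]
    bonds$end <- old2new[bonds$end + 1]
    bonds$bond_id <- seq_len(nrow(bonds)) - 1L
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  new_structure(atoms, bonds, s$name)
}

keep_largest_component <- function(s) {
  comp <- structure_components(s)
  if (max(comp) == 1) return(s)
  carbon <- s$atoms$element == "C"
  organic <- sort(unique(comp[carbon]))
  cand <- if (length(organic)) organic else stop(
    "multi-component structure with no organic component", call. = FALSE)
  sizes <- vapply(cand, function(k) sum(comp == k), 0L)
  best <- cand[sizes == max(sizes)]
  if (length(best) > 1) {
    smi <- vapply(best, function(k) {
      canonical_smiles(perceive_aromaticity(
        subset_structure(s, s$atoms$atom_id[comp == k])))
    }, "")
    best <- best[order(smi)][1]
  }
  subset_structure(s, s$atoms$atom_id[comp == best[1]])
}
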