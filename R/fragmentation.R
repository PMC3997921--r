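# Reduced-graph fragmentation. A molecule is condensed to structural units
# (SSSR rings, functional groups from the key library's unit patterns, and
# single-atom linkers); connected subsets of units are then expanded back to
# molecular fragments. Rings are never broken, so every fragment is a valid
# standalone molecule and fragment fingerprints stay subsets of the parent's.

#' Build the reduced graph of structural units
#'
#' Unit assignment precedence: (1) each SSSR ring is a unit (fused rings are
#' separate units joined through their shared atoms); (2) functional groups
#' matching the library's unit-flagged patterns, restricted to unclaimed
#' non-ring atoms, longest pattern first, ties by lowest atom id; (3) every
#' remaining atom is a single-atom linker unit. Two units are connected when
#' they share an atom or a parent bond joins them.
#'
#' @param s standardized `Structure`.
#' @param lib `KeyLibrary` supplying unit patterns.
#' @return a `ReducedGraph`: list with `units`, `edges` (2-column matrix of
#'   0-based unit ids) and `parent`.
#' @export
build_reduced_graph <- function(s, lib = default_key_library()) {
  stopifnot(inherits(s, "Structure"))
  units <- list()
  claimed <- rep(FALSE, n_atoms(s))

  rings <- sssr(s)
  for (r in rings) {
    units[[length(units) + 1]] <- list(kind = "ring",
                                       atom_ids = sort(r$atom_ids),
                                       bond_ids = sort(r$bond_ids))
    claimed[r$atom_ids + 1] <- TRUE
  }
  ring_atom <- claimed

  fg_rows <- which(lib$unit == 1L)
  if (length(fg_rows)) {
    pats <- key_patterns(lib)[fg_rows]
    sizes <- vapply(pats, function(p) length(p$atoms), 0L)
    for (i in order(-sizes)) {
      for (w in match_pattern(pats[[i]], s)) {
        ids <- sort(w$atom_ids)
        if (any(ring_atom[ids + 1]) || any(claimed[ids + 1])) next
        units[[length(units) + 1]] <- list(kind = "functional_group",
                                           atom_ids = ids,
                                           bond_ids = sort(w$bond_ids))
        claimed[ids + 1] <- TRUE
      }
    }
  }

  for (a in s$atoms$atom_id[!claimed]) {
    units[[length(units) + 1]] <- list(kind = "linker", atom_ids = a,
                                       bond_ids = integer(0))
  }
  # deterministic unit order: rings, then groups, then linkers, each by
  # lowest atom id
  kind_rank <- c(ring = 1L, functional_group = 2L, linker = 3L)
  ord <- order(kind_rank[vapply(units, `[[`, "", "kind")],
               vapply(units, function(u) min(u$atom_ids), 0L))
  units <- units[ord]
  for (i in seq_along(units)) units[[i]]$unit_id <- i - 1L

  nu <- length(units)
  edges <- matrix(integer(0), ncol = 2)
  if (nu > 1) {
    atom_sets <- lapply(units, `[[`, "atom_ids")
    for (i in seq_len(nu - 1)) {
      for (j in (i + 1):nu) {
        share <- length(intersect(atom_sets[[i]], atom_sets[[j]])) > 0
        joined <- share || any(
          (s$bonds$begin %in% atom_sets[[i]] & s$bonds$end %in% atom_sets[[j]]) |
          (s$bonds$begin %in% atom_sets[[j]] & s$bonds$end %in% atom_sets[[i]])
        )
        if (joined) edges <- rbind(edges, c(i - 1L, j - 1L))
      }
    }
  }
  structure(list(units = units, edges = edges, parent = s), class = "ReducedGraph")
}

#' @exportS3Method base::print
print.ReducedGraph <- function(x, ...) {
  kinds <- table(vapply(x$units, `[[`, "", "kind"))
  cat(sprintf("<ReducedGraph: %d units (%s), %d edges>\n", length(x$units),
              paste(names(kinds), kinds, sep = "=", collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

rg_adjacency <- function(rg) {
  nu <- length(rg$units)
  adj <- rep(list(integer(0)), nu)
  if (nrow(rg$edges)) {
    for (e in seq_len(nrow(rg$edges))) {
      i <- rg$edges[e, 1]; j <- rg$edges[e, 2]
      adj[[i + 1]] <- c(adj[[i + 1]], j)
      adj[[j + 1]] <- c(adj[[j + 1]], i)
    }
  }
  adj
}

#' Expand a unit subset back to a molecular fragment
#'
#' @param rg a `ReducedGraph`.
#' @param unit_subset integer vector of 0-based unit ids, connected in `rg`.
#' @return a `Fragment`: atom/bond/unit id sets plus a canonical-SMILES key.
#' @export
expand_fragment <- function(rg, unit_subset) {
  unit_subset <- sort(unique(as.integer(unit_subset)))
  if (!length(unit_subset)) stop("empty unit subset", call. = FALSE)
  adj <- rg_adjacency(rg)
  seen <- unit_subset[1]; queue <- seen
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nxt <- setdiff(intersect(adj[[u + 1]], unit_subset), seen)
    seen <- c(seen, nxt); queue <- c(queue, nxt)
  }
  if (length(seen) != length(unit_subset))
    stop("unit subset is not connected in the reduced graph", call. = FALSE)
  atom_ids <- sort(unique(unlist(lapply(rg$units[unit_subset + 1], `[[`, "atom_ids"))))
  s <- rg$parent
  bond_ids <- s$bonds$bond_id[s$bonds$begin %in% atom_ids & s$bonds$end %in% atom_ids]
  frag <- structure(list(atom_ids = atom_ids, bond_ids = sort(bond_ids),
                         unit_ids = unit_subset, key = NA_character_),
                    class = "Fragment")
  frag$key <- canonical_smiles(fragment_as_structure(s, frag))
  frag
}

#' Materialise a fragment as a standalone Structure
#'
#' Atoms keep their aromatic flags and charges; attachment points are closed
#' with implicit hydrogens. Attributes `atom_map` / `bond_map` give, for each
#' fragment atom/bond index (0-based), the corresponding parent id.
#'
#' @param parent parent `Structure`.
#' @param frag a `Fragment` (or list with `atom_ids`).
#' @return a `Structure` with mapping attributes.
#' @export
fragment_as_structure <- function(parent, frag) {
  atom_ids <- sort(frag$atom_ids)
  sub <- subset_structure(parent, atom_ids)
  sub <- demote_stray_aromatic(sub)   # safety; whole rings are never broken
  keep_b <- parent$bonds$begin %in% atom_ids & parent$bonds$end %in% atom_ids
  attr(sub, "atom_map") <- atom_ids
  attr(sub, "bond_map") <- parent$bonds$bond_id[keep_b]
  sub
}

#' @exportS3Method base::print
print.Fragment <- function(x, ...) {
  cat(sprintf("<Fragment %s: atoms {%s}>\n", x$key,
              paste(x$atom_ids, collapse = ",")))
  invisible(x)
}

#' Enumerate connected fragments of a reduced graph
#'
#' Returns every connected subset of units of size at most `max_depth`
#' (unlimited by default), expanded to molecular fragments and deduplicated
#' by atom-id set. The full structure is always included as the root
#' fragment, even when `max_depth` would exclude it.
#'
#' @param rg a `ReducedGraph`.
#' @param max_depth maximum units per fragment, or `Inf`.
#' @param unit_cap refuse unlimited enumeration above this many units.
#' @return list of `Fragment`s, ordered by (size, atom ids).
#' @export
enumerate_fragments <- function(rg, max_depth = Inf, unit_cap = 25L) {
  nu <- length(rg$units)
  if (is.infinite(max_depth) && nu > unit_cap)
    stop("reduced graph has ", nu, " units; unlimited enumeration refused ",
         "(set max_depth or raise unit_cap)", call. = FALSE)
  adj <- rg_adjacency(rg)
  subsets <- connected_unit_subsets(adj, nu, max_depth)
  full <- paste(0:(nu - 1), collapse = ",")
  if (!full %in% vapply(subsets, paste, "", collapse = ","))
    subsets <- c(subsets, list(0:(nu - 1)))
  frags <- lapply(subsets, function(ss) expand_fragment(rg, ss))
  keys <- vapply(frags, function(f) paste(f$atom_ids, collapse = ","), "")
  frags <- frags[!duplicated(keys)]
  sizes <- vapply(frags, function(f) length(f$atom_ids), 0L)
  keys <- vapply(frags, function(f) paste(sprintf("%06d", f$atom_ids), collapse = ","), "")
  frags[order(sizes, keys)]
}

# All connected subsets of an undirected graph up to a size limit, by
# breadth-first growth with canonical deduplication.
connected_unit_subsets <- function(adj, nu, max_depth) {
  out <- list()
  seen <- new.env(parent = emptyenv())
  frontier <- lapply(0:(nu - 1), function(u) u)
  for (ss in frontier) assign(paste(ss, collapse = ","), TRUE, envir = seen)
  size <- 1L
  while (length(frontier) && size <= max_depth) {
    out <- c(out, frontier)
    if (size == max_depth) break
    nxt <- list()
    for (ss in frontier) {
      nbrs <- setdiff(sort(unique(unlist(adj[ss + 1]))), ss)
      for (v in nbrs) {
        grown <- sort(c(ss, v))
        key <- paste(grown, collapse = ",")
        if (!exists(key, envir = seen, inherits = FALSE)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1]] <- grown
        }
      }
    }
    frontier <- nxt
    size <- size + 1L
  }
  out
}
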