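# Subgraph matching of restricted-SMARTS patterns against Structures.
#
# The pattern dialect is deliberately monotone: an atom constrains element,
# aromaticity and (optionally) charge; a bond constrains type. No H-count,
# degree, ring-membership or negation primitives. Monotonicity guarantees
# that any match inside a fragment is also a match inside its parent, which
# is what makes the fragment fingerprint-subset property exact.

#' Parse a pattern in the restricted SMARTS dialect
#'
#' Supported atom primitives: organic-subset symbols (aromatic lowercase),
#' bracket atoms with element/aromatic case, `#n` atomic number (aromatic or
#' not), explicit charge (`[N+]`, `[O-]`, `[N+0]`), and the wildcard `*`.
#' Bonds: default (single-or-aromatic), `-`, `=`, `#`, `:`, `~`. Branches and
#' ring closures as in SMILES.
#'
#' @param smarts pattern string.
#' @return a `Pattern` object.
#' @export
parse_pattern <- function(smarts) {
  g <- parse_smiles_graph(smarts, pattern = TRUE)
  atoms <- lapply(g$atoms, function(a) {
    list(
      element = if (isTRUE(a$any)) NA_character_ else a$element,
      aromatic = if (isTRUE(a$any)) NA else a$aromatic,
      charge = if (isTRUE(a$charge_set)) a$charge else NA_integer_
    )
  })
  nb <- length(g$bonds)
  edges <- if (nb) data.frame(
    begin = vapply(g$bonds, `[[`, 0L, "begin"),
    end = vapply(g$bonds, `[[`, 0L, "end"),
    type = vapply(g$bonds, `[[`, "", "type"),
    stringsAsFactors = FALSE
  ) else data.frame(begin = integer(0), end = integer(0), type = character(0))
  structure(list(atoms = atoms, edges = edges, smarts = smarts), class = "Pattern")
}

pattern_atom_ok <- function(p, s, t) {   # p: pattern atom list; t: 1-based target row
  if (!is.na(p$element) && p$element != s$atoms$element[t]) return(FALSE)
  if (!is.na(p$aromatic) && p$aromatic != s$atoms$aromatic[t]) return(FALSE)
  if (!is.na(p$charge) && p$charge != s$atoms$charge[t]) return(FALSE)
  TRUE
}

pattern_bond_ok <- function(type, s, bid) {   # bid 0-based target bond id
  b <- s$bonds[bid + 1, ]
  switch(type,
    "any" = TRUE,
    "ar" = b$aromatic,
    "1" = !b$aromatic && b$order == 1L,
    "2" = !b$aromatic && b$order == 2L,
    "3" = !b$aromatic && b$order == 3L,
    "default" = b$aromatic || b$order == 1L,
    stop("unknown pattern bond type: ", type)
  )
}

#' Match a pattern against a structure
#'
#' Backtracking subgraph isomorphism. Matches that map to the same set of
#' target atoms (automorphic images) are collapsed to one witness.
#'
#' @param pattern a `Pattern` (or SMARTS string, parsed on the fly).
#' @param s a `Structure`.
#' @param first_only stop after one match (presence test).
#' @return list of witnesses; each has `atom_ids` (target ids in pattern-atom
#'   order) and `bond_ids` (target bonds realising the pattern edges).
#' @export
match_pattern <- function(pattern, s, first_only = FALSE) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "Pattern"), inherits(s, "Structure"))
  np <- length(pattern$atoms)
  na <- n_atoms(s)
  if (np > na) return(list())
  adj <- structure_adjacency(s)

  # pattern adjacency
  padj <- vector("list", np)
  for (i in seq_len(np)) padj[[i]] <- list(nbr = integer(0), type = character(0))
  if (nrow(pattern$edges)) {
    for (e in seq_len(nrow(pattern$edges))) {
      u <- pattern$edges$begin[e]; v <- pattern$edges$end[e]; ty <- pattern$edges$type[e]
      padj[[u + 1]]$nbr <- c(padj[[u + 1]]$nbr, v)
      padj[[u + 1]]$type <- c(padj[[u + 1]]$type, ty)
      padj[[v + 1]]$nbr <- c(padj[[v + 1]]$nbr, u)
      padj[[v + 1]]$type <- c(padj[[v + 1]]$type, ty)
    }
  }
  # visit order: BFS so each atom after the first touches a mapped neighbour
  ord <- integer(0)
  if (np > 0) {
    seen <- rep(FALSE, np); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]; ord <- c(ord, u)
      for (v in padj[[u]]$nbr + 1L) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
    }
    if (length(ord) < np) stop("pattern must be connected: ", pattern$smarts, call. = FALSE)
  }

  results <- list()
  seen_sets <- character(0)
  mapping <- rep(NA_integer_, np)   # pattern pos (1-based) -> target atom id (0-based)
  used <- rep(FALSE, na)

  try_extend <- function(step) {
    if (step > np) {
      key <- paste(sort(mapping), collapse = ",")
      if (!(key %in% seen_sets)) {
        seen_sets <<- c(seen_sets, key)
        bond_ids <- integer(0)
        if (nrow(pattern$edges)) {
          bond_ids <- vapply(seq_len(nrow(pattern$edges)), function(e) {
            tu <- mapping[pattern$edges$begin[e] + 1]
            tv <- mapping[pattern$edges$end[e] + 1]
            hit <- which((s$bonds$begin == tu & s$bonds$end == tv) |
                           (s$bonds$begin == tv & s$bonds$end == tu))
            s$bonds$bond_id[hit[1]]
          }, 0L)
        }
        results[[length(results) + 1]] <<- list(atom_ids = mapping, bond_ids = bond_ids)
      }
      return(first_only)
    }
    pi <- ord[step]
    patom <- pattern$atoms[[pi]]
    # candidates: neighbours of an already-mapped pattern neighbour, or all atoms
    mapped_nbr <- which(!is.na(mapping[padj[[pi]]$nbr + 1L]))
    cands <- if (length(mapped_nbr)) {
      anchor_p <- padj[[pi]]$nbr[mapped_nbr[1]]
      adj[[mapping[anchor_p + 1] + 1]]$nbr
    } else 0:(na - 1)
    for (t in cands) {
      if (used[t + 1]) next
      if (!pattern_atom_ok(patom, s, t + 1)) next
      ok <- TRUE
      for (k in seq_along(padj[[pi]]$nbr)) {
        q <- padj[[pi]]$nbr[k]
        tq <- mapping[q + 1]
        if (is.na(tq)) next
        hit <- which(adj[[t + 1]]$nbr == tq)
        if (!length(hit) || !pattern_bond_ok(padj[[pi]]$type[k], s, adj[[t + 1]]$bond[hit[1]])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      mapping[pi] <<- t; used[t + 1] <<- TRUE
      done <- try_extend(step + 1)
      mapping[pi] <<- NA_integer_; used[t + 1] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  try_extend(1L)
  results
}

#' Does a pattern occur in a structure?
#' @inheritParams match_pattern
#' @return logical scalar.
#' @export
has_match <- function(pattern, s) length(match_pattern(pattern, s, first_only = TRUE)) > 0
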