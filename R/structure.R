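#' Molecular structure container
#'
#' A `Structure` is the substrate of all atom/bond mapping in fragnet. Atoms
#' and bonds carry stable 0-based integer ids assigned in input order; every
#' downstream highlight, fragment and provenance record refers to these ids.
#'
#' @param atoms data.frame with columns `element` (character), `aromatic`
#'   (logical), `charge` (integer), `hcount` (integer, `NA` = implicit) and
#'   `atom_id` (0-based integer).
#' @param bonds data.frame with columns `begin`, `end` (0-based atom ids),
#'   `order` (integer 1/2/3), `aromatic` (logical) and `bond_id`
#'   (0-based integer).
#' @param name single character label.
#' @return An object of class `Structure`.
#' @keywords internal
new_structure <- function(atoms, bonds, name = "") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  structure(
    list(atoms = atoms, bonds = bonds, name = as.character(name)[1]),
    class = "Structure"
  )
}

#' Number of heavy atoms in a Structure
#' @param s a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Number of bonds in a Structure
#' @param s a `Structure`.
#' @return integer bond count.
#' @export
n_bonds <- function(s) nrow(s$bonds)

#' @exportS3Method base::print
print.Structure <- function(x, ...) {
  cat(sprintf(
    "<Structure%s: %d atoms, %d bonds> %s\n",
    if (nzchar(x$name)) paste0(" ", x$name) else "",
    n_atoms(x), n_bonds(x), canonical_smiles(x)
  ))
  invisible(x)
}

# Adjacency list: for each atom (1-based position), data on neighbours.
# Returns list of data.frames with columns nbr (0-based id), bond (0-based id).
structure_adjacency <- function(s) {
  na <- n_atoms(s)
  adj <- vector("list", na)
  for (i in seq_len(na)) adj[[i]] <- list(nbr = integer(0), bond = integer(0))
  if (n_bonds(s) > 0) {
    for (b in seq_len(n_bonds(s))) {
      u <- s$bonds$begin[b]; v <- s$bonds$end[b]; id <- s$bonds$bond_id[b]
      adj[[u + 1]]$nbr <- c(adj[[u + 1]]$nbr, v)
      adj[[u + 1]]$bond <- c(adj[[u + 1]]$bond, id)
      adj[[v + 1]]$nbr <- c(adj[[v + 1]]$nbr, u)
      adj[[v + 1]]$bond <- c(adj[[v + 1]]$bond, id)
    }
  }
  adj
}

# Connected components over atoms; returns integer component index per atom.
structure_components <- function(s) {
  na <- n_atoms(s)
  adj <- structure_adjacency(s)
  comp <- rep(NA_integer_, na)
  cur <- 0L
  for (start in seq_len(na)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (nb in adj[[a]]$nbr) {
        if (is.na(comp[nb + 1])) {
          comp[nb + 1] <- cur
          queue <- c(queue, nb + 1)
        }
      }
    }
  }
  comp
}

# Validate internal consistency; called from parser/standardizer.
validate_structure <- function(s) {
  na <- n_atoms(s)
  if (na == 0) stop("empty molecule", call. = FALSE)
  if (!identical(s$atoms$atom_id, 0:(na - 1)))
    stop("atom ids must be contiguous 0..A-1", call. = FALSE)
  if (n_bonds(s) > 0) {
    if (!identical(s$bonds$bond_id, 0:(n_bonds(s) - 1)))
      stop("bond ids must be contiguous 0..B-1", call. = FALSE)
    if (any(s$bonds$begin < 0 | s$bonds$begin >= na |
            s$bonds$end < 0 | s$bonds$end >= na))
      stop("bond endpoint references a non-existent atom", call. = FALSE)
  }
  invisible(s)
}

# Default valence lists per element (neutral). Used for implicit H counting.
.default_valences <- list(
  H = 1L, B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L, Se = c(2L, 4L, 6L)
)

# Sum of bond orders at each atom; aromatic bonds count 1.5, total is ceiled.
bond_order_sums <- function(s) {
  na <- n_atoms(s)
  tot <- numeric(na)
  if (n_bonds(s) > 0) {
    ord <- ifelse(s$bonds$aromatic, 1.5, s$bonds$order)
    for (b in seq_len(n_bonds(s))) {
      tot[s$bonds$begin[b] + 1] <- tot[s$bonds$begin[b] + 1] + ord[b]
      tot[s$bonds$end[b] + 1] <- tot[s$bonds$end[b] + 1] + ord[b]
    }
  }
  as.integer(ceiling(tot - 1e-9))
}

#' Implicit hydrogen counts
#'
#' Computes the effective hydrogen count of every atom: the explicit bracket
#' count when one was given, otherwise the lowest default valence of the
#' element (charge-adjusted) minus the bond-order sum, floored at zero.
#'
#' @param s a `Structure`.
#' @return integer vector, one entry per atom.
#' @export
implicit_h_counts <- function(s) {
  sums <- bond_order_sums(s)
  out <- integer(n_atoms(s))
  for (i in seq_len(n_atoms(s))) {
    if (!is.na(s$atoms$hcount[i])) {
      out[i] <- s$atoms$hcount[i]
      next
    }
    el <- s$atoms$element[i]
    vals <- .default_valences[[el]]
    if (is.null(vals)) { out[i] <- 0L; next }
    ch <- s$atoms$charge[i]
    vals <- if (el == "C") vals - abs(ch) else vals + ch
    v <- vals[vals >= sums[i]][1]
    out[i] <- if (is.na(v)) 0L else as.integer(v - sums[i])
  }
  out
}
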