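# Binary structural fingerprints whose set bits are traceable to atoms and
# bonds (structural keys) or derived from hashed linear paths (not
# individually traceable). Both schemes satisfy the fragment-subset property:
# the fingerprint of a connected fragment sets only bits set in its parent.

new_feature_vector <- function(bits, scheme, provenance = NULL, params = list()) {
  structure(
    list(bits = as.integer(bits), scheme = scheme,
         provenance = provenance, params = params),
    class = "FeatureVector"
  )
}

#' @exportS3Method base::print
print.FeatureVector <- function(x, ...) {
  cat(sprintf("<FeatureVector %s: %d/%d bits set> {%s}\n", x$scheme,
              sum(x$bits), length(x$bits),
              paste(set_bits(x), collapse = ",")))
  invisible(x)
}

#' Indices of set bits (0-based)
#' @param fv a `FeatureVector`.
#' @return integer vector.
#' @export
set_bits <- function(fv) which(fv$bits == 1L) - 1L

#' Structural-key fingerprint
#'
#' Bit `i` is set iff library pattern `i` matches the structure. Provenance
#' records every match witness (atom and bond ids), so set bits are traceable
#' to substructures of the query.
#'
#' @param s standardized `Structure`.
#' @param lib a `KeyLibrary` (default: the shipped library).
#' @return a `FeatureVector` with scheme `"structural_keys"`.
#' @export
structural_key_fp <- function(s, lib = default_key_library()) {
  stopifnot(inherits(s, "Structure"), inherits(lib, "KeyLibrary"))
  pats <- key_patterns(lib)
  bits <- integer(nrow(lib))
  prov <- vector("list", nrow(lib))
  for (i in seq_len(nrow(lib))) {
    m <- match_pattern(pats[[i]], s)
    if (length(m)) {
      bits[i] <- 1L
      prov[[i]] <- lapply(m, function(w) list(atoms = sort(w$atom_ids),
                                              bonds = sort(w$bond_ids)))
    }
  }
  new_feature_vector(bits, "structural_keys", provenance = prov,
                     params = list(n_keys = nrow(lib)))
}

# Deterministic string hash: polynomial accumulation kept below 2^31.
.str_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  h
}

#' Hashed linear-path fingerprint
#'
#' Enumerates simple heavy-atom paths of up to `max_depth` bonds, labels each
#' path with element / aromaticity / charge and bond-order symbols, takes the
#' lexicographically smaller direction as canonical, and hashes it onto
#' `n_bits` positions. Bits are not individually traceable (no provenance).
#'
#' @param s standardized `Structure`.
#' @param max_depth maximum path length in bonds (>= 1).
#' @param n_bits fingerprint length, a power of two.
#' @return a `FeatureVector` with scheme `"hashed_path"`.
#' @export
hashed_path_fp <- function(s, max_depth = 6L, n_bits = 1024L) {
  stopifnot(inherits(s, "Structure"), max_depth >= 1)
  if (bitwAnd(n_bits, n_bits - 1L) != 0L || n_bits <= 0)
    stop("n_bits must be a power of two", call. = FALSE)
  labels <- paste0(ifelse(s$atoms$aromatic, tolower(s$atoms$element), s$atoms$element),
                   ifelse(s$atoms$charge == 0, "",
                          sprintf("%+d", s$atoms$charge)))
  bsym <- if (n_bonds(s)) ifelse(s$bonds$aromatic, ":", c("-", "=", "#")[s$bonds$order]) else character(0)
  adj <- structure_adjacency(s)
  paths <- character(0)

  # forward and reverse strings grown together so the canonical direction
  # (lexicographic min) respects multi-character atom tokens
  grow <- function(atom, fwd, bwd, used, depth) {
    paths[[length(paths) + 1]] <<- if (bwd < fwd) bwd else fwd
    if (depth == max_depth) return()
    ent <- adj[[atom + 1]]
    for (k in seq_along(ent$nbr)) {
      v <- ent$nbr[k]
      if (used[v + 1]) next
      used2 <- used; used2[v + 1] <- TRUE
      bs <- bsym[ent$bond[k] + 1]
      grow(v, paste0(fwd, bs, labels[v + 1]), paste0(labels[v + 1], bs, bwd),
           used2, depth + 1L)
    }
  }
  for (a in s$atoms$atom_id) {
    used <- rep(FALSE, n_atoms(s)); used[a + 1] <- TRUE
    grow(a, labels[a + 1], labels[a + 1], used, 0L)
  }
  canon <- unique(unlist(paths))
  bits <- integer(n_bits)
  for (p in canon) bits[(.str_hash(p) %% n_bits) + 1] <- 1L
  new_feature_vector(bits, "hashed_path",
                     params = list(max_depth = as.integer(max_depth),
                                   n_bits = as.integer(n_bits)))
}

#' Fingerprint of a fragment, mapped to parent ids
#'
#' Computes the fingerprint of the fragment as a standalone molecule
#' (attachment points closed with implicit hydrogens, aromatic flags
#' retained) and remaps structural-key provenance back to parent atom and
#' bond ids. Every set bit is guaranteed to be set in the parent fingerprint.
#'
#' @param parent the parent `Structure`.
#' @param frag a `Fragment` of the parent.
#' @param scheme `"structural_keys"` or `"hashed_path"`.
#' @param lib key library (structural_keys scheme).
#' @param max_depth,n_bits hashed-path parameters.
#' @return a `FeatureVector`.
#' @export
fp_for_fragment <- function(parent, frag, scheme = c("structural_keys", "hashed_path"),
                            lib = default_key_library(), max_depth = 6L, n_bits = 1024L) {
  scheme <- match.arg(scheme)
  fs <- fragment_as_structure(parent, frag)
  if (scheme == "structural_keys") {
    fv <- structural_key_fp(fs, lib)
    map <- attr(fs, "atom_map")       # fragment id -> parent id
    bmap <- attr(fs, "bond_map")
    fv$provenance <- lapply(fv$provenance, function(wits) {
      if (is.null(wits)) return(NULL)
      lapply(wits, function(w) list(atoms = sort(map[w$atoms + 1]),
                                    bonds = sort(bmap[w$bonds + 1])))
    })
    fv
  } else {
    hashed_path_fp(fs, max_depth = max_depth, n_bits = n_bits)
  }
}

#' Export fingerprints as a bitstring TSV
#'
#' @param fvs list of `FeatureVector`s.
#' @param names character vector of structure names.
#' @param path output file.
#' @return invisibly, the written data.frame.
#' @export
write_fingerprints <- function(fvs, names, path) {
  stopifnot(length(fvs) == length(names))
  df <- data.frame(
    name = names,
    bits = vapply(fvs, function(f) paste(f$bits, collapse = ""), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
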