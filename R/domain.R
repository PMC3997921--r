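# Fragment-dictionary applicability domain: a query is in domain when every
# atom and bond is covered by at least one fragment seen sufficiently often
# in the training set.

#' Build a fragment dictionary from training structures
#'
#' Each training structure is fragmented with the same configuration as the
#' model; a structure contributes each distinct fragment key once (fragments
#' occurring twice in one molecule count once — occurrence is structure-level
#' support). Keys below `min_occurrence` are dropped.
#'
#' @param training list of standardized `Structure`s.
#' @param min_occurrence keep keys occurring in at least this many structures.
#' @param lib key library for unit detection.
#' @param max_depth fragmentation depth limit.
#' @return a `FragmentDictionary`.
#' @export
build_dictionary <- function(training, min_occurrence = 4L,
                             lib = default_key_library(), max_depth = Inf) {
  if (!length(training)) stop("empty training set", call. = FALSE)
  tally <- new.env(parent = emptyenv())
  for (s in training) {
    frags <- enumerate_fragments(build_reduced_graph(s, lib), max_depth = max_depth)
    for (key in unique(vapply(frags, `[[`, "", "key"))) {
      cur <- if (exists(key, envir = tally, inherits = FALSE)) get(key, envir = tally) else 0L
      assign(key, cur + 1L, envir = tally)
    }
  }
  keys <- ls(tally)
  counts <- vapply(keys, get, 0L, envir = tally)
  keep <- counts >= min_occurrence
  structure(
    list(counts = stats::setNames(as.integer(counts[keep]), keys[keep]),
         min_occurrence = as.integer(min_occurrence),
         max_depth = max_depth,
         lib_hash = key_library_hash(lib)),
    class = "FragmentDictionary"
  )
}

#' @exportS3Method base::print
print.FragmentDictionary <- function(x, ...) {
  cat(sprintf("<FragmentDictionary: %d keys, min_occurrence=%d>\n",
              length(x$counts), x$min_occurrence))
  invisible(x)
}

#' Applicability-domain check for a query structure
#'
#' Fragments the query; every fragment found in the dictionary removes its
#' atoms and bonds from the unmatched set. The query is in domain iff nothing
#' remains; otherwise the uncovered atoms/bonds are returned as a highlight.
#'
#' @param query a standardized `Structure`.
#' @param dict a `FragmentDictionary` built with the same configuration.
#' @param lib key library (must match the dictionary's).
#' @return list with `in_domain` (logical) and `uncovered` (`NULL` or a
#'   highlight list with `atom_ids` / `bond_ids`).
#' @export
in_domain <- function(query, dict, lib = default_key_library()) {
  stopifnot(inherits(dict, "FragmentDictionary"))
  if (dict$lib_hash != key_library_hash(lib))
    stop("dictionary was built with a different key library", call. = FALSE)
  frags <- enumerate_fragments(build_reduced_graph(query, lib),
                               max_depth = dict$max_depth)
  un_atoms <- query$atoms$atom_id
  un_bonds <- query$bonds$bond_id
  for (f in frags) {
    if (!is.null(dict$counts[f$key]) && !is.na(dict$counts[f$key])) {
      un_atoms <- setdiff(un_atoms, f$atom_ids)
      un_bonds <- setdiff(un_bonds, f$bond_ids)
    }
  }
  if (!length(un_atoms) && !length(un_bonds)) {
    list(in_domain = TRUE, uncovered = NULL)
  } else {
    list(in_domain = FALSE,
         uncovered = list(atom_ids = sort(un_atoms), bond_ids = sort(un_bonds)))
  }
}

#' Persist / load a fragment dictionary as TSV
#'
#' Two columns (key, count); the header line records the fragmentation
#' configuration hash so a mismatched library is refused at load time only
#' when checked against a library.
#'
#' @param dict a `FragmentDictionary`.
#' @param path file path.
#' @return `read_dictionary` returns the dictionary; `write_dictionary` the
#'   path, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fragnet dictionary min_occurrence=%d max_depth=%s lib_hash=%.0f",
                     dict$min_occurrence,
                     if (is.infinite(dict$max_depth)) "Inf" else dict$max_depth,
                     dict$lib_hash), con)
  writeLines("key\tcount", con)
  if (length(dict$counts))
    writeLines(paste(names(dict$counts), dict$counts, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  get_field <- function(name, conv = as.numeric) {
    m <- regmatches(hdr, regexpr(paste0(name, "=[^ ]+"), hdr))
    conv(sub(paste0(name, "="), "", m))
  }
  body <- lines[-(1:2)]
  counts <- integer(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    counts <- stats::setNames(as.integer(vapply(parts, `[[`, "", 2)),
                              vapply(parts, `[[`, "", 1))
  }
  structure(
    list(counts = counts,
         min_occurrence = as.integer(get_field("min_occurrence")),
         max_depth = get_field("max_depth"),
         lib_hash = get_field("lib_hash")),
    class = "FragmentDictionary"
  )
}
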