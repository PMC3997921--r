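# File I/O: SMILES and SDF reading/writing, highlight JSON serialisation.

#' Read structures from a file
#'
#' SMILES format: one record per line, optional whitespace-separated name.
#' SDF: V2000 records separated by `$$$$`. Records that fail parsing or
#' standardization are skipped with a warning carrying the skip count.
#'
#' @param path input file.
#' @param format `"smiles"` or `"sdf"`.
#' @param strip_salts keep only the largest organic component of each record.
#' @return list of `Structure`s (at least one, else an error).
#' @export
read_structures <- function(path, format = c("smiles", "sdf"), strip_salts = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  out <- list()
  skipped <- 0L
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      s <- tryCatch({
        st <- parse_structure(parts[1],
                              name = if (length(parts) > 1) parts[2] else "")
        standardize(st, strip_salts = strip_salts)
      }, error = function(e) NULL)
      if (is.null(s)) skipped <- skipped + 1L else out[[length(out) + 1]] <- s
    }
  } else {
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
    records <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
    records <- records[nzchar(trimws(records))]
    for (rec in records) {
      rec <- sub("^\n+", "", rec)
      s <- tryCatch(standardize(parse_molblock(rec), strip_salts = strip_salts),
                    error = function(e) NULL)
      if (is.null(s)) skipped <- skipped + 1L else out[[length(out) + 1]] <- s
    }
  }
  if (skipped > 0)
    warning(skipped, " record(s) skipped (parse/standardization failure)",
            call. = FALSE)
  if (!length(out)) stop("no valid records in ", path, call. = FALSE)
  out
}

#' Write structures to a SMILES file
#'
#' One canonical SMILES per line with the structure name when present.
#'
#' @param structures list of `Structure`s.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_structures <- function(structures, path) {
  lines <- vapply(structures, function(s) {
    smi <- canonical_smiles(s)
    if (nzchar(s$name)) paste(smi, s$name) else smi
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Serialise an interpretation summary as JSON
#'
#' Schema: `{structure, final_prediction, activations: [{atoms, bonds}],
#' deactivations: [{deactivated: {atoms, bonds}, deactivating: {atoms,
#' bonds}}]}`, all ids referring to the query structure.
#'
#' @param summary an `InterpretationSummary`.
#' @param structure the query `Structure` (for its name / SMILES).
#' @return JSON string.
#' @export
summary_to_json <- function(summary, structure = NULL) {
  payload <- list(
    structure = if (!is.null(structure)) {
      list(name = structure$name, smiles = canonical_smiles(structure))
    } else NULL,
    final_prediction = summary$final_prediction,
    activations = lapply(summary$activations, function(a)
      list(atoms = a$atom_ids, bonds = a$bond_ids)),
    deactivations = lapply(summary$deactivations, function(d)
      list(deactivated = list(atoms = d$deactivated$atom_ids,
                              bonds = d$deactivated$bond_ids),
           deactivating = list(atoms = d$deactivating$atom_ids,
                               bonds = d$deactivating$bond_ids)))
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                                digits = NA))
}
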