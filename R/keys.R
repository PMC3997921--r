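#' Key libraries
#'
#' A `KeyLibrary` is an ordered collection of named substructure patterns; bit
#' `i` of a structural-key fingerprint reports whether pattern `i` occurs in
#' the molecule. Patterns marked `unit` additionally seed functional-group
#' units during reduced-graph construction.
#'
#' @param path TSV file with columns `key_id`, `smarts`, `description` and
#'   optionally `unit` (0/1; defaults to 0 when the column is absent).
#' @return a `KeyLibrary`: data.frame with parsed patterns attached.
#' @export
load_key_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("key_id", "smarts", "description")
  if (!all(need %in% names(df)))
    stop("key library must have columns key_id, smarts, description", call. = FALSE)
  if (!"unit" %in% names(df)) df$unit <- 0L
  df$unit <- as.integer(df$unit)
  if (anyDuplicated(df$key_id) || !identical(sort(df$key_id), 0:(nrow(df) - 1)))
    stop("key_ids must be unique and contiguous from 0", call. = FALSE)
  df <- df[order(df$key_id), , drop = FALSE]
  rownames(df) <- NULL
  patterns <- lapply(df$smarts, function(p) {
    tryCatch(parse_pattern(p),
             error = function(e) stop("bad SMARTS for key library: ", p, " (",
                                      conditionMessage(e), ")", call. = FALSE))
  })
  attr(df, "patterns") <- patterns
  class(df) <- c("KeyLibrary", "data.frame")
  df
}

#' Default key library shipped with the package
#'
#' About forty monotone substructure keys covering the motifs that drive Ames
#' mutagenicity discussion: aromatic nitro, aromatic amines (primary /
#' one-substituent / two-substituent variants), epoxide, aziridine, azo,
#' nitroso, N-nitroso, aliphatic and aromatic halides, carboxylic acid, a
#' bay-region PAH proxy and common ring systems. Patterns avoid H-count and
#' degree primitives so that every key is monotone under substructure
#' inclusion (fragment matches imply parent matches).
#'
#' @return a `KeyLibrary`.
#' @export
default_key_library <- function() {
  if (!is.null(.fragnet_cache$default_lib)) return(.fragnet_cache$default_lib)
  lib <- load_key_library(system.file("extdata", "default_keys.tsv",
                                      package = "fragnet", mustWork = TRUE))
  .fragnet_cache$default_lib <- lib
  lib
}

.fragnet_cache <- new.env(parent = emptyenv())

key_patterns <- function(lib) attr(lib, "patterns")
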