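# ACTIVATING-feature mining across a labelled dataset, plus the standard
# binary-classification metrics.

#' Mine ACTIVATING features from a labelled dataset
#'
#' Interprets every structure with the given model, tallies per-fragment-key
#' statistics, and returns the fragment keys whose structure-level occurrence
#' and ACTIVATING count both exceed the (strict) thresholds. Feature identity
#' is the canonical fragment SMILES, so substitution variants stay distinct.
#'
#' @param structures list of standardized `Structure`s.
#' @param labels experimental labels (`"active"` / `"inactive"`).
#' @param model a predictor.
#' @param lib key library.
#' @param min_occurrence strict lower bound on structures containing the key.
#' @param min_activating strict lower bound on structures where the key was
#'   assessed ACTIVATING.
#' @param scheme fingerprint scheme for fragment nodes.
#' @param max_depth fragmentation depth limit.
#' @return data.frame with columns `key`, `occurrence`, `n_activating`,
#'   `experimental_signal` (fraction of supporting structures labelled
#'   active) and `model_accuracy` (fraction of supporting structures whose
#'   final prediction matched the label).
#' @export
mine_activating <- function(structures, labels, model,
                            lib = default_key_library(),
                            min_occurrence = 5L, min_activating = 5L,
                            scheme = "structural_keys", max_depth = Inf) {
  if (!length(structures)) stop("empty dataset", call. = FALSE)
  stopifnot(length(structures) == length(labels))
  occ <- new.env(parent = emptyenv())
  bump <- function(env, key, field, by = 1L) {
    cur <- if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env)
      else list(occurrence = 0L, n_activating = 0L, n_active_label = 0L, n_correct = 0L)
    cur[[field]] <- cur[[field]] + by
    assign(key, cur, envir = env)
  }
  for (i in seq_along(structures)) {
    res <- interpret(structures[[i]], model, approach = "fragment",
                     lib = lib, scheme = scheme, max_depth = max_depth)
    nodes <- res$network$nodes
    keys_here <- unique(vapply(nodes, function(nd) nd$fragment$key, ""))
    act_keys <- unique(vapply(
      nodes[vapply(nodes, function(nd) identical(nd$assessment, "ACTIVATING"), TRUE)],
      function(nd) nd$fragment$key, ""))
    correct <- res$summary$final_prediction == labels[i]
    for (key in keys_here) {
      bump(occ, key, "occurrence")
      if (labels[i] == "active") bump(occ, key, "n_active_label")
      if (correct) bump(occ, key, "n_correct")
      if (key %in% act_keys) bump(occ, key, "n_activating")
    }
  }
  keys <- ls(occ)
  rows <- lapply(keys, function(k) {
    v <- get(k, envir = occ)
    data.frame(key = k, occurrence = v$occurrence, n_activating = v$n_activating,
               experimental_signal = v$n_active_label / v$occurrence,
               model_accuracy = v$n_correct / v$occurrence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$occurrence > min_occurrence & out$n_activating > min_activating, ,
             drop = FALSE]
  out <- out[order(-out$n_activating, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binary classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and balanced accuracy
#' `(SEN+SPEC)/2`. A zero denominator yields `NA` for the affected metric
#' (and for BAC), not an error.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return named list with `SEN`, `SPEC`, `BAC`.
#' @examples
#' classification_metrics(tp = 8, fn = 2, tn = 6, fp = 4)
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) stop("no classifications to score", call. = FALSE)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bac <- if (is.na(sen) || is.na(spec)) NA_real_ else (sen + spec) / 2
  list(SEN = sen, SPEC = spec, BAC = bac)
}

#' Applicability-domain coverage percentage
#'
#' @param n_in_domain structures classed in domain.
#' @param n_total total structures (> 0).
#' @return `n_in_domain / n_total * 100`.
#' @export
coverage <- function(n_in_domain, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_in_domain < 0 || n_in_domain > n_total)
    stop("n_in_domain must be between 0 and n_total", call. = FALSE)
  n_in_domain / n_total * 100
}
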