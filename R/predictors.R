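# Built-in predictors honouring the predict_fv contract.

#' Constant predictor
#' @param label `"active"` or `"inactive"`.
#' @return a predictor returning `label` for every vector.
#' @export
constant_predictor <- function(label = "inactive") {
  stopifnot(label %in% c("active", "inactive"))
  structure(list(label = label), class = c("constant_predictor", "fragnet_predictor"))
}

#' @export
predict_fv.constant_predictor <- function(model, fv) {
  list(label = model$label, confidence = 1)
}

#' Rule-based mock predictor over structural keys
#'
#' Embodies the governing assumption of the interpretation method: activity
#' is caused by the presence of a structural alert and inactivity by its
#' absence or deactivation. The oracle predicts `active` iff at least one
#' alert key bit is set and no deactivating context paired with that alert is
#' set. Operating on key bits keeps the oracle inside the predictor contract
#' while remaining exactly computable by hand on fragments.
#'
#' @param lib the `KeyLibrary` the fingerprints are generated with.
#' @param alerts character vector of alert SMARTS (must be library keys).
#' @param deactivations named list: for each alert SMARTS, a character vector
#'   of context SMARTS (library keys) whose presence deactivates that alert.
#' @return a predictor object.
#' @export
rule_oracle <- function(lib = default_key_library(), alerts,
                        deactivations = list()) {
  alert_bits <- match(alerts, lib$smarts) - 1L
  if (anyNA(alert_bits)) stop("alert not present in key library: ",
                              paste(alerts[is.na(alert_bits)], collapse = ", "),
                              call. = FALSE)
  deact_bits <- lapply(deactivations, function(ctx) {
    b <- match(ctx, lib$smarts) - 1L
    if (anyNA(b)) stop("deactivating context not in key library", call. = FALSE)
    b
  })
  structure(list(alerts = alerts, alert_bits = alert_bits,
                 deactivations = deactivations, deact_bits = deact_bits),
            class = c("rule_oracle", "fragnet_predictor"))
}

#' @export
predict_fv.rule_oracle <- function(model, fv) {
  on <- set_bits(fv)
  for (i in seq_along(model$alert_bits)) {
    if (!(model$alert_bits[i] %in% on)) next
    ctx <- model$deact_bits[[model$alerts[i]]]
    if (is.null(ctx) || !any(ctx %in% on)) return(list(label = "active", confidence = 1))
  }
  list(label = "inactive", confidence = 1)
}

#' Default rule oracle: planted Ames-style alerts
#'
#' Alerts: nitro, epoxide, aziridine and aromatic amine; the aromatic amine
#' is deactivated by an ortho carboxylic acid (the localised-deactivation
#' motif of the worked interpretation examples).
#'
#' @param lib key library (must contain the alert patterns).
#' @return a `rule_oracle` predictor.
#' @export
default_rule_oracle <- function(lib = default_key_library()) {
  rule_oracle(
    lib,
    alerts = c("[N+](=O)[O-]", "C1CO1", "C1CN1", "[N+0]c1ccccc1"),
    deactivations = list("[N+0]c1ccccc1" = "[N+0]c1ccccc1C(=O)O")
  )
}

#' Train a toy binary classifier on structural-key fingerprints
#'
#' Ridge-penalised logistic regression (glmnet) behind the predictor
#' contract. A configuration hash of the key library is stored so that
#' interpreting with a mismatched fingerprint scheme fails loudly.
#'
#' @param structures list of `Structure`s.
#' @param labels character vector, `"active"` / `"inactive"`.
#' @param lib key library used for fingerprints.
#' @param lambda ridge penalty (small, data are tiny and clean).
#' @return a `toy_model` predictor.
#' @export
train_toy_model <- function(structures, labels, lib = default_key_library(),
                            lambda = 0.01) {
  stopifnot(length(structures) == length(labels))
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class", call. = FALSE)
  X <- t(vapply(structures, function(s) structural_key_fp(s, lib)$bits,
                integer(nrow(lib))))
  y <- as.integer(labels == "active")
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lambda)
  structure(list(fit = fit, lambda = lambda, n_keys = nrow(lib),
                 lib_hash = key_library_hash(lib)),
            class = c("toy_model", "fragnet_predictor"))
}

key_library_hash <- function(lib) {
  .str_hash(paste(lib$key_id, lib$smarts, collapse = ";"))
}

#' @export
predict_fv.toy_model <- function(model, fv) {
  if (length(fv$bits) != model$n_keys)
    stop("feature vector length does not match the trained scheme", call. = FALSE)
  p <- as.numeric(stats::predict(model$fit, matrix(fv$bits, nrow = 1),
                                 type = "response", s = model$lambda))
  list(label = if (p >= 0.5) "active" else "inactive",
       confidence = max(p, 1 - p))
}

#' Persist / restore a trained predictor
#'
#' Serialised with R's native RDS alongside the key-library hash; loading
#' into a session with a different library is refused at interpret time.
#'
#' @param model a predictor.
#' @param path file path.
#' @return `load_predictor` returns the predictor; `save_predictor` the path.
#' @export
save_predictor <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fragnet_predictor"))
    stop("file does not contain a fragnet predictor: ", path, call. = FALSE)
  model
}

#' Check model / library compatibility
#' @param model a predictor.
#' @param lib a `KeyLibrary`.
#' @return invisibly `TRUE`; errors on mismatch.
#' @export
check_model_compat <- function(model, lib) {
  if (inherits(model, "toy_model") && model$lib_hash != key_library_hash(lib))
    stop("model was trained with a different key library ",
         "(fingerprint configuration hash mismatch)", call. = FALSE)
  invisible(TRUE)
}
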