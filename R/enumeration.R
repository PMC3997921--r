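# Bit-combination enumeration for the feature-vector interpretation route,
# and the two counting laws it obeys.

#' Exact binomial coefficient
#'
#' Computed by the multiplicative rule with exact intermediate integers.
#' Results are exact up to 2^53 (the exact-integer range of a double); larger
#' results raise an error rather than silently losing precision.
#'
#' @param n,k non-negative integers with `k <= n`.
#' @return the number of k-subsets of an n-set.
#' @examples
#' combinations_count(4, 2)   # 6
#' @export
combinations_count <- function(n, k) {
  if (length(n) != 1 || length(k) != 1 || is.na(n) || is.na(k) ||
      n < 0 || k < 0 || n != floor(n) || k != floor(k))
    stop("n and k must be non-negative integers", call. = FALSE)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) {
    r <- r * (n - k + i) / i      # exact: the running product is integral
    if (r > 2^53) stop("result exceeds exact double range (2^53)", call. = FALSE)
  }
  r
}

#' Total number of enumerable bit combinations
#'
#' The power-set size `2^n`, counting the empty combination. The number of
#' combinations actually enumerated as network nodes is `2^n - 1`: an
#' all-zero feature vector has no structural meaning.
#'
#' @param n non-negative integer (number of set bits).
#' @return `2^n`, exact; errors above `n = 53`.
#' @export
total_combinations <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a non-negative integer", call. = FALSE)
  if (n > 53) stop("result exceeds exact double range (2^53)", call. = FALSE)
  2^n
}

#' Enumerate bit combinations of a feature vector
#'
#' Returns every subset of the set bits with cardinality between 1 and
#' `prune_level`, in (k, lexicographic) order, plus always the full set-bit
#' combination: the query itself must be a node of the network whatever the
#' pruning. With `prune_level = Inf` the enumeration is exhaustive
#' (`2^n - 1` combinations) and is refused above `max_bits` set bits.
#'
#' @param fv a `FeatureVector` (or integer vector of 0-based bit indices).
#' @param prune_level maximum combination cardinality, or `Inf`.
#' @param max_bits cap on set bits for unlimited enumeration.
#' @return list of `BitCombination`s (sorted integer vectors of bit indices
#'   with attribute `k`).
#' @export
enumerate_bitsets <- function(fv, prune_level = 4L, max_bits = 20L) {
  bits <- if (inherits(fv, "FeatureVector")) set_bits(fv) else sort(unique(as.integer(fv)))
  n <- length(bits)
  if (n < 1) stop("feature vector has no set bits", call. = FALSE)
  if (is.infinite(prune_level) && n > max_bits)
    stop(n, " set bits; exhaustive enumeration refused, set prune_level",
         call. = FALSE)
  kmax <- min(prune_level, n)
  out <- list()
  for (k in seq_len(kmax)) {
    cmb <- utils::combn(seq_len(n), k)   # index-based: combn(5, k) means 1:5
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1]] <- new_bit_combination(bits[cmb[, j]])
  }
  if (kmax < n) out[[length(out) + 1]] <- new_bit_combination(bits)
  out
}

new_bit_combination <- function(member_bits) {
  member_bits <- sort(as.integer(member_bits))
  structure(member_bits, k = length(member_bits), class = "BitCombination")
}

#' @exportS3Method base::print
print.BitCombination <- function(x, ...) {
  cat(sprintf("<BitCombination k=%d: {%s}>\n", attr(x, "k"),
              paste(unclass(x), collapse = ",")))
  invisible(x)
}
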