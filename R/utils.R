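`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical string key for an unordered pair, used for set membership
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}

# canonicalise an m x 2 index matrix so that column 1 < column 2 rowwise
canonicalize_pairs <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  storage.mode(pairs) <- "integer"
  cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
}

# derive a child seed from a base seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + k * 7919) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
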