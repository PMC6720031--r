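# Exact arithmetic and ordering for 64-bit hash values carried as decimal
# strings. R doubles lose exactness above 2^53, well below the retention
# threshold used at common scaled values, so hashes never become numeric.

HASH_SPACE_DEC <- "18446744073709551616" # 2^64

# floor(2^64 / s) as a decimal string, by schoolbook long division.
# Returns "" for s == 1, meaning "no cap" (every hash is below 2^64).
max_hash_for_scaled <- function(scaled) {
  stopifnot(length(scaled) == 1, scaled >= 1, scaled == floor(scaled))
  if (scaled == 1) return("")
  digits <- as.integer(strsplit(HASH_SPACE_DEC, "")[[1]])
  out <- integer(length(digits))
  carry <- 0
  for (i in seq_along(digits)) {
    cur <- carry * 10 + digits[i]
    out[i] <- cur %/% scaled
    carry <- cur %% scaled
  }
  res <- paste(out, collapse = "")
  sub("^0+(?=\\d)", "", res, perl = TRUE)
}

# Numeric order for non-negative decimal strings without leading zeros:
# shorter strings are smaller; equal lengths compare lexicographically.
sort_hashes <- function(x) {
  if (length(x) == 0) return(character(0))
  x[order(nchar(x), x, method = "radix")]
}

# x < y element-wise, both decimal strings (y may be scalar).
hash_lt <- function(x, y) {
  nx <- nchar(x)
  ny <- nchar(y)
  nx < ny | (nx == ny & x < y)
}

# Keep hashes strictly below a cap ("" = no cap).
hashes_below <- function(x, max_hash) {
  if (identical(max_hash, "")) return(x)
  x[hash_lt(x, max_hash)]
}

hash_union <- function(a, b) sort_hashes(unique(c(a, b)))
hash_intersect <- function(a, b) sort_hashes(intersect(a, b))
hash_setdiff <- function(a, b) sort_hashes(setdiff(a, b))
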