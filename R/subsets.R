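#' Variable-subset bitmask encoding
#'
#' Subsets of the variable domain are encoded as non-negative integers: bit
#' `i` (counting from 0) is set iff the variable with 0-based index `i` is a
#' member. The integer doubles as the hash value indexing every order-graph
#' and parent-graph table, so encode/decode form a bijection between
#' integers in `[0, 2^n)` and subsets of an `n`-variable domain. Masks are
#' stored in R integers, which caps the domain at `n <= 30`; the dynamic
#' program is memory-bound well below that (about `n <= 20`).
#'
#' @param members integer vector of 0-based variable indices (may be empty).
#' @param n domain size.
#' @return `encode_subset()`: a single integer mask. `decode_subset()`: a
#'   sorted integer vector of 0-based member indices.
#' @examples
#' encode_subset(c(0, 2), 4)   # 5
#' decode_subset(5L, 4)        # c(0, 2)
#' @export
encode_subset <- function(members, n) {
  stopifnot(n >= 0, n <= 30)
  members <- as.integer(members)
  if (length(members) == 0L) return(0L)
  if (anyNA(members) || any(members < 0L) || any(members >= n))
    stop("variable index out of range [0, ", n, ")", call. = FALSE)
  if (anyDuplicated(members)) members <- unique(members)
  sum(bitwShiftL(1L, members))
}

#' @rdname encode_subset
#' @param mask integer subset mask.
#' @export
decode_subset <- function(mask, n) {
  stopifnot(length(mask) == 1L, mask >= 0L)
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L) - 1L
}

# single-variable mask, 0-based index
mask_bit <- function(i) bitwShiftL(1L, as.integer(i))

mask_has <- function(mask, i) bitwAnd(mask, bitwShiftL(1L, as.integer(i))) != 0L

# population count; vectorised over masks
mask_size <- function(mask, n) {
  k <- integer(length(mask))
  for (i in seq_len(n) - 1L) k <- k + (bitwAnd(mask, bitwShiftL(1L, i)) != 0L)
  k
}

# all masks of the subsets of `ground` (a mask) with size <= kmax,
# returned in increasing popcount order
subsets_up_to <- function(ground, n, kmax) {
  vars <- decode_subset(ground, n)
  m <- length(vars)
  kmax <- min(kmax, m)
  out <- list(0L)
  if (kmax >= 1L) {
    for (k in seq_len(kmax)) {
      cmb <- combn(vars, k)
      out[[k + 1L]] <- as.integer(colSums(matrix(bitwShiftL(1L, cmb), nrow = k)))
    }
  }
  unlist(out)
}
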