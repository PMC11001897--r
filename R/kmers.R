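#' K-mer index over the RNA alphabet
#'
#' Lexicographic index of all k-mers over (A, C, G, U). The index fixes the
#' row/column ordering of all incidence matrices and vector blocks:
#' `AA...A` is first, `UU...U` is last.
#'
#' @param k k-mer size (1, 2 or 3).
#' @return Character vector of the 4^k k-mers in index order.
#' @examples
#' kmer_index(1)   # "A" "C" "G" "U"
#' head(kmer_index(2))
#' @export
kmer_index <- function(k) {
  k <- check_k(k)
  if (k == 1L) return(RNA_BASES)
  grids <- do.call(expand.grid,
                   c(rev(replicate(k, RNA_BASES, simplify = FALSE)),
                     list(stringsAsFactors = FALSE)))
  # expand.grid varies the first column fastest; reversed input + reversed
  # column order gives lexicographic order with the leftmost base slowest.
  apply(grids[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

check_k <- function(k) {
  if (length(k) != 1L || !k %in% c(1, 2, 3))
    stop("k must be 1, 2 or 3", call. = FALSE)
  as.integer(k)
}

# Integer codes 1..4 for one sequence string (assumed validated).
base_codes <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], RNA_BASES)
}

# Overlapping k-mer codes 1..4^k along a sequence; length n - k + 1.
# Code of a k-mer is its 1-based rank in kmer_index(k): base-4 positional
# encoding of the per-base codes.
kmer_codes <- function(sequence, k) {
  k <- check_k(k)
  b <- base_codes(sequence) - 1L
  n <- length(b)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  code <- integer(m)
  for (offset in 0:(k - 1L)) {
    code <- code + b[(1L + offset):(m + offset)] * 4L^(k - 1L - offset)
  }
  code + 1L
}

reverse_sequence <- function(sequence) {
  paste(rev(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = "")
}
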