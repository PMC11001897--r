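# Per-window feature encodings: frequency vector, AAPIV/RAAPIV, PRIM/RPRIM,
# 2D sequence matrices, and the assembled 522-value descriptor.
#
# Block layout of the assembled vector (sizes sum to 522):
#   PRIM moments (k = 1, 2, 3; raw + central + Hahn, 30 each)   90
#   RPRIM moments (same structure on the reversed sequence)     90
#   frequency vector (4 + 16 + 64 overlapping k-mer counts)     84
#   AAPIV (position sums, 4 + 16 + 64)                          84
#   RAAPIV (position sums of the reversed sequence)             84
#   2D sequence-matrix moments (k = 1, 2, 3; 30 each)           90

#' Overlapping k-mer frequency vector
#'
#' Counts of all mono-, di- and tri-nucleotides (overlapping) in a window,
#' in lexicographic [kmer_index()] order. For a 41-nt window the three
#' blocks sum to 41, 40 and 39.
#'
#' @param sequence a window sequence (or any RNA string).
#' @return Named integer vector of length 84.
#' @export
frequency_vector <- function(sequence) {
  out <- unlist(lapply(1:3, function(k) {
    counts <- tabulate(kmer_codes(sequence, k), nbins = 4L^k)
    names(counts) <- paste0("fv_k", k, "_", kmer_index(k))
    counts
  }))
  out
}

#' Accumulative absolute position incidence vector (AAPIV)
#'
#' For each k-mer, the sum of the 1-based start positions of its
#' (overlapping) occurrences. For k = 1 the four entries always sum to
#' 41 * 42 / 2 = 861 on a 41-nt window: every position counted once.
#'
#' @param sequence a window sequence.
#' @param k k-mer size (1, 2 or 3).
#' @return Named numeric vector of length 4^k.
#' @export
aapiv <- function(sequence, k) {
  k <- check_k(k)
  codes <- kmer_codes(sequence, k)
  sums <- vapply(seq_len(4L^k), function(i) sum(which(codes == i)), numeric(1))
  names(sums) <- paste0("aapiv_k", k, "_", kmer_index(k))
  sums
}

#' Reverse AAPIV (RAAPIV)
#'
#' [aapiv()] computed on the reversed sequence, exposing positional structure
#' anchored at the 3' end.
#'
#' @inheritParams aapiv
#' @return Named numeric vector of length 4^k.
#' @export
raapiv <- function(sequence, k) {
  out <- aapiv(reverse_sequence(sequence), k)
  names(out) <- sub("^aapiv_", "raapiv_", names(out))
  out
}

#' Position-relative incidence matrix (PRIM)
#'
#' A 4^k x 4^k matrix summarising the positions of each k-mer relative to
#' every other. Entry (i, j) is the sum over (overlapping) occurrences q of
#' k-mer j of the signed offset q - f_i, where f_i is the 1-based position
#' of the first occurrence of k-mer i; occurrences preceding f_i contribute
#' negatively. Rows and columns follow [kmer_index()] order; if k-mer i or j
#' is absent the entry is 0.
#'
#' @inheritParams aapiv
#' @return 4^k x 4^k numeric matrix with k-mer dimnames.
#' @export
prim <- function(sequence, k) {
  k <- check_k(k)
  codes <- kmer_codes(sequence, k)
  nk <- 4L^k
  counts <- tabulate(codes, nbins = nk)
  pos_sum <- vapply(seq_len(nk), function(i) sum(which(codes == i)), numeric(1))
  first <- match(seq_len(nk), codes)  # NA when absent
  W <- matrix(0, nk, nk, dimnames = list(kmer_index(k), kmer_index(k)))
  present <- which(!is.na(first))
  target <- which(counts > 0L)
  for (i in present)
    W[i, target] <- pos_sum[target] - counts[target] * first[i]
  W
}

#' Reverse PRIM (RPRIM)
#'
#' [prim()] computed on the reversed sequence.
#'
#' @inheritParams aapiv
#' @return 4^k x 4^k numeric matrix.
#' @export
rprim <- function(sequence, k) {
  prim(reverse_sequence(sequence), k)
}

#' Integer-encoded 2D sequence matrix
#'
#' The window's overlapping k-mer stream is encoded as integers 1..4^k
#' (lexicographic rank + 1) and written row-major into the smallest square
#' matrix that holds it (7 x 7 for the 41/40/39-long streams of a 41-nt
#' window), zero-padded at the tail.
#'
#' @inheritParams aapiv
#' @return Square numeric matrix with entries in \{0\} U [1, 4^k].
#' @export
sequence_matrix_2d <- function(sequence, k) {
  codes <- kmer_codes(sequence, k)
  side <- ceiling(sqrt(length(codes)))
  padded <- c(codes, rep(0L, side^2 - length(codes)))
  matrix(padded, side, side, byrow = TRUE)
}

prim_moment_block <- function(sequence, prefix, reverse = FALSE) {
  unlist(lapply(1:3, function(k) {
    M <- if (reverse) rprim(sequence, k) else prim(sequence, k)
    m <- suppressWarnings(moment_set(M))
    names(m) <- paste0(prefix, "_k", k, "_", names(m))
    m
  }))
}

#' Assemble the 522-dimensional feature vector of one window
#'
#' Concatenates, in fixed order: the 30 moments (raw, central, Hahn) of the
#' mono/di/tri PRIM matrices (90), the same for RPRIM (90), the frequency
#' vector (84), AAPIV (84), RAAPIV (84) and the 30 moments of the three 2D
#' sequence matrices (90). Component names are stable across runs. Degenerate
#' zero-mass matrices contribute zero central moments (with a warning
#' suppressed here and surfaced by [moment_set()] when called directly).
#'
#' @param sequence a validated 41-nt window sequence.
#' @return Named numeric vector of length 522.
#' @export
assemble_features <- function(sequence) {
  viol <- window_violation(gsub("T", "U", toupper(sequence), fixed = TRUE))
  if (!is.null(viol)) stop("invalid window: ", viol, call. = FALSE)
  sequence <- gsub("T", "U", toupper(sequence), fixed = TRUE)
  twod <- unlist(lapply(1:3, function(k) {
    m <- suppressWarnings(moment_set(sequence_matrix_2d(sequence, k)))
    names(m) <- paste0("mat2d_k", k, "_", names(m))
    m
  }))
  out <- c(prim_moment_block(sequence, "prim"),
           prim_moment_block(sequence, "rprim", reverse = TRUE),
           frequency_vector(sequence),
           unlist(lapply(1:3, aapiv, sequence = sequence)),
           unlist(lapply(1:3, raapiv, sequence = sequence)),
           twod)
  stopifnot(length(out) == 522L)
  out
}

#' Names of the 522 feature components
#'
#' @return Character vector of length 522 in assembly order.
#' @export
feature_names <- function() {
  names(assemble_features(strrep("A", 41)))
}

#' Encode a window dataset as a feature table
#'
#' One row per window: `id`, `label`, then the 522 named feature columns,
#' in input order.
#'
#' @param ds a `window_dataset`.
#' @return data.frame with 524 columns.
#' @export
encode_dataset <- function(ds) {
  if (nrow(ds) == 0L) stop("empty dataset", call. = FALSE)
  feats <- t(vapply(ds$sequence, assemble_features, numeric(522),
                    USE.NAMES = FALSE))
  colnames(feats) <- names(assemble_features(ds$sequence[1]))
  out <- data.frame(id = ds$id, label = ds$label, feats,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as CSV
#'
#' @param features data.frame from [encode_dataset()].
#' @param path CSV path.
#' @return `path` (write) or the feature data.frame (read).
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read features CSV: ", path, call. = FALSE)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
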