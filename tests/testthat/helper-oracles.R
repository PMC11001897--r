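# Independent brute-force oracles used to freeze expected values. These
# deliberately re-derive every quantity with naive loops / enumerations,
# separate from the package's vectorized implementations.

BASES <- c("A", "C", "G", "U")

random_window <- function() {
  chars <- sample(BASES, 41, replace = TRUE)
  chars[21] <- "A"
  paste(chars, collapse = "")
}

# naive double-loop moments, 1-based coordinates
oracle_raw_moment <- function(M, j, k) {
  s <- 0
  for (c in seq_len(nrow(M))) for (d in seq_len(ncol(M)))
    s <- s + c^j * d^k * M[c, d]
  s
}

oracle_central_moment <- function(M, i, j) {
  e00 <- oracle_raw_moment(M, 0, 0)
  xb <- oracle_raw_moment(M, 1, 0) / e00
  yb <- oracle_raw_moment(M, 0, 1) / e00
  s <- 0
  for (b in seq_len(nrow(M))) for (q in seq_len(ncol(M)))
    s <- s + (b - xb)^i * (q - yb)^j * M[b, q]
  s
}

MOMENT_IDX <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(0, 2),
                   c(2, 0), c(1, 2), c(2, 1), c(0, 3), c(3, 0))

# all k-mers in lexicographic order, naive construction
oracle_kmers <- function(k) {
  out <- BASES
  while (nchar(out[1]) < k)
    out <- as.vector(t(outer(out, BASES, paste0)))
  sort(out)
}

# 1-based start positions of overlapping occurrences of a k-mer
oracle_positions <- function(sequence, kmer) {
  k <- nchar(kmer)
  n <- nchar(sequence)
  which(vapply(seq_len(n - k + 1),
               function(i) substr(sequence, i, i + k - 1) == kmer,
               logical(1)))
}

oracle_aapiv <- function(sequence, k) {
  vapply(oracle_kmers(k), function(km) sum(oracle_positions(sequence, km)),
         numeric(1))
}

oracle_prim <- function(sequence, k) {
  kmers <- oracle_kmers(k)
  nk <- length(kmers)
  W <- matrix(0, nk, nk, dimnames = list(kmers, kmers))
  for (i in seq_len(nk)) {
    fi <- oracle_positions(sequence, kmers[i])[1]
    if (is.na(fi)) next
    for (j in seq_len(nk)) {
      occ <- oracle_positions(sequence, kmers[j])
      if (length(occ) > 0) W[i, j] <- sum(occ - fi)
    }
  }
  W
}

oracle_reverse <- function(sequence) {
  paste(rev(strsplit(sequence, "")[[1]]), collapse = "")
}

# pairwise Mann-Whitney AUROC, ties counted one half
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

tiny_dataset <- function(n_pos = 20, n_neg = 20, strength = 1, seed = 42) {
  generate_synthetic(n_pos, n_neg, bias = planted_profile(strength),
                     seed = seed)
}
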