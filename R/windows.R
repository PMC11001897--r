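#' Construct a dataset of labeled 41-nt windows
#'
#' A `window_dataset` is the package's sample container: a data frame with
#' columns `id`, `sequence`, `label` (1 = 6mA site, 0 = non-site) and
#' `species`, where every sequence is a 41-nt string over (A, C, G, U) with
#' the central position (21) an adenosine.
#'
#' @param id character record identifiers.
#' @param sequence character 41-nt sequences (T is coerced to U first).
#' @param label integer class labels in \{0, 1\}.
#' @param species optional per-record tag (e.g. "HS", "MM", "SC",
#'   "synthetic"); recycled if length 1.
#' @param name dataset label.
#' @return A `window_dataset` (data.frame subclass).
#' @export
window_dataset <- function(id, sequence, label, species = "unknown",
                           name = "dataset") {
  sequence <- toupper(as.character(sequence))
  sequence <- gsub("T", "U", sequence, fixed = TRUE)
  label <- as.integer(label)
  n <- length(sequence)
  if (length(id) != n || length(label) != n)
    stop("id, sequence and label must have equal length", call. = FALSE)
  if (length(species) == 1L) species <- rep(species, n)
  bad <- vapply(sequence, function(s) !is.null(window_violation(s)), logical(1))
  if (any(bad)) {
    reasons <- vapply(sequence[bad], window_violation, character(1))
    stop("invalid window(s): ", paste(unique(reasons), collapse = "; "),
         call. = FALSE)
  }
  if (any(!label %in% c(0L, 1L)))
    stop("labels must be 0 or 1", call. = FALSE)
  ds <- data.frame(id = as.character(id), sequence = sequence,
                   label = label, species = as.character(species),
                   stringsAsFactors = FALSE)
  attr(ds, "name") <- name
  class(ds) <- c("window_dataset", "data.frame")
  ds
}

# NULL when valid, else a reason string. Assumes T already coerced to U.
window_violation <- function(sequence) {
  if (is.na(sequence)) return("missing sequence")
  if (nchar(sequence) != WINDOW_LENGTH)
    return(sprintf("length %d != %d", nchar(sequence), WINDOW_LENGTH))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% RNA_BASES)) return("ambiguous base")
  if (chars[WINDOW_CENTER] != "A") return("central position is not A")
  NULL
}

#' @export
print.window_dataset <- function(x, ...) {
  cat(sprintf("window_dataset '%s': %d windows (%d positive, %d negative)\n",
              attr(x, "name") %||% "dataset", nrow(x),
              sum(x$label == 1L), sum(x$label == 0L)))
  if (nrow(x) > 0L) print(head(as.data.frame(x), 5L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class counts of a window dataset
#'
#' @param ds a `window_dataset`.
#' @return Named integer vector with elements `positive` and `negative`.
#' @export
class_counts <- function(ds) {
  c(positive = sum(ds$label == 1L), negative = sum(ds$label == 0L))
}

#' Read labeled windows from a FASTA file
#'
#' Reads a plain multi-record FASTA file of candidate windows, coerces T to U,
#' and keeps records that satisfy the window invariants (length 41, central A,
#' unambiguous bases). Records failing validation are skipped; each skip is
#' reported as a message with its reason.
#'
#' @param path FASTA file path.
#' @param label class label (1 = 6mA site, 0 = non-site) applied to all
#'   records in the file.
#' @param species species tag applied to all records.
#' @param name dataset label; defaults to the file name.
#' @return A [window_dataset()].
#' @export
read_fasta_windows <- function(path, label, species = "unknown", name = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  ids <- names(recs)
  if (is.null(ids)) ids <- paste0("record_", seq_along(recs))
  seqs <- toupper(as.character(recs))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  reasons <- vapply(seqs, function(s) window_violation(s) %||% "",
                    character(1), USE.NAMES = FALSE)
  keep <- reasons == ""
  for (i in which(!keep))
    message(sprintf("skipping record '%s': %s", ids[i], reasons[i]))
  if (!any(keep))
    stop(sprintf("no valid windows in %s (%d record(s) rejected)",
                 path, sum(!keep)), call. = FALSE)
  window_dataset(ids[keep], seqs[keep], rep(label, sum(keep)),
                 species = species, name = name %||% basename(path))
}

#' Read labeled windows from a TSV file
#'
#' Expects tab-separated columns `id`, `sequence`, `label` and optionally
#' `species`. Invalid rows are skipped with a message, as for FASTA input.
#'
#' @param path TSV file path.
#' @param name dataset label; defaults to the file name.
#' @return A [window_dataset()].
#' @export
read_windows_tsv <- function(path, name = NULL) {
  if (!file.exists(path)) stop("cannot read TSV file: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "sequence", "label")
  if (!all(need %in% names(tab)))
    stop("TSV must have columns id, sequence, label", call. = FALSE)
  seqs <- gsub("T", "U", toupper(tab$sequence), fixed = TRUE)
  reasons <- vapply(seqs, function(s) window_violation(s) %||% "",
                    character(1), USE.NAMES = FALSE)
  keep <- reasons == "" & tab$label %in% c("0", "1")
  for (i in which(!keep))
    message(sprintf("skipping row %d ('%s'): %s", i, tab$id[i],
                    if (reasons[i] != "") reasons[i] else "label not 0/1"))
  if (!any(keep))
    stop(sprintf("no valid windows in %s (%d row(s) rejected)",
                 path, sum(!keep)), call. = FALSE)
  window_dataset(tab$id[keep], seqs[keep], as.integer(tab$label[keep]),
                 species = if ("species" %in% names(tab))
                   tab$species[keep] else "unknown",
                 name = name %||% basename(path))
}

#' Write a window dataset to TSV
#'
#' @param ds a `window_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(ds, path) {
  write.table(as.data.frame(ds), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Remove exact duplicate windows
#'
#' Keeps the first occurrence of each (sequence, label) pair, preserving
#' order otherwise. The same sequence occurring under both labels is kept
#' under both (they are distinct pairs) but reported as a cross-label
#' conflict, since such records are mutually contradictory training signal.
#'
#' @param ds a `window_dataset`.
#' @return The deduplicated `window_dataset`; the number of removed records
#'   is reported as a message.
#' @export
deduplicate <- function(ds) {
  key <- paste(ds$sequence, ds$label, sep = "|")
  keep <- !duplicated(key)
  removed <- sum(!keep)
  if (removed > 0L)
    message(sprintf("deduplicate: removed %d exact duplicate(s)", removed))
  out <- ds[keep, , drop = FALSE]
  both <- intersect(out$sequence[out$label == 1L], out$sequence[out$label == 0L])
  if (length(both) > 0L)
    warning(sprintf("%d sequence(s) occur under both labels", length(both)),
            call. = FALSE)
  attr(out, "name") <- attr(ds, "name")
  class(out) <- class(ds)
  rownames(out) <- NULL
  out
}

#' Planted positional-composition bias profile
#'
#' Builds a 41 x 4 per-position nucleotide probability profile for the
#' positive class of the synthetic generator. At `positions`, the probability
#' of the consensus base G is raised from the uniform 0.25 to
#' `0.25 + 0.75 * strength` (deterministic G at `strength = 1`); all other
#' positions stay uniform. The central position 21 is always fixed to A.
#'
#' @param strength planted signal strength in [0, 1]; 0 gives the uniform
#'   background (classes indistinguishable), 1 plants a deterministic
#'   consensus (classes separable).
#' @param positions 1-based window positions carrying the planted bias.
#' @return 41 x 4 matrix of probabilities, columns A, C, G, U; rows sum to 1.
#' @export
planted_profile <- function(strength = 1,
                            positions = c(15:20, 22:27)) {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  prof <- matrix(0.25, WINDOW_LENGTH, 4L,
                 dimnames = list(NULL, RNA_BASES))
  pG <- 0.25 + 0.75 * strength
  prof[positions, ] <- (1 - pG) / 3
  prof[positions, "G"] <- pG
  prof[WINDOW_CENTER, ] <- c(1, 0, 0, 0)
  prof
}

#' Generate a synthetic labeled window dataset
#'
#' Draws positive windows from a per-position nucleotide probability profile
#' and negative windows from the uniform background (1/4 each base), with the
#' central position forced to A in both classes. Deterministic given `seed`.
#'
#' @param n_pos,n_neg numbers of positive / negative windows.
#' @param bias 41 x 4 probability matrix for the positive class (columns in
#'   A, C, G, U order); defaults to [planted_profile()] at full strength.
#' @param seed integer RNG seed.
#' @param name dataset label.
#' @return A [window_dataset()] with species tag "synthetic".
#' @export
generate_synthetic <- function(n_pos, n_neg, bias = planted_profile(1),
                               seed = 1L, name = "synthetic") {
  if (n_pos < 0 || n_neg < 0) stop("n_pos and n_neg must be >= 0")
  bias <- as.matrix(bias)
  if (!all(dim(bias) == c(WINDOW_LENGTH, 4L)))
    stop("bias must be a 41 x 4 matrix", call. = FALSE)
  if (any(abs(rowSums(bias) - 1) > 1e-9))
    stop("bias rows must each sum to 1", call. = FALSE)
  set.seed(as.integer(seed))
  draw <- function(n, prof) {
    if (n == 0L) return(character(0))
    mat <- vapply(seq_len(WINDOW_LENGTH), function(pos) {
      sample(RNA_BASES, n, replace = TRUE, prob = prof[pos, ])
    }, character(n))
    mat <- matrix(mat, nrow = n)
    mat[, WINDOW_CENTER] <- "A"
    apply(mat, 1L, paste0, collapse = "")
  }
  uniform <- matrix(0.25, WINDOW_LENGTH, 4L)
  pos_seqs <- draw(as.integer(n_pos), bias)
  neg_seqs <- draw(as.integer(n_neg), uniform)
  window_dataset(
    id = c(sprintf("pos_%d", seq_len(n_pos)), sprintf("neg_%d", seq_len(n_neg))),
    sequence = c(pos_seqs, neg_seqs),
    label = c(rep(1L, n_pos), rep(0L, n_neg)),
    species = "synthetic", name = name)
}

#' Stratified train/test split
#'
#' Splits a dataset into train and test partitions, sampling within each
#' class so that class proportions are preserved to within one sample.
#' Deterministic given `seed`.
#'
#' @param ds a `window_dataset` containing both classes.
#' @param test_fraction proportion of each class assigned to the test set
#'   (0 < test_fraction < 1).
#' @param seed integer RNG seed.
#' @return List with elements `train` and `test` (both `window_dataset`s);
#'   together they partition `ds`.
#' @export
stratified_split <- function(ds, test_fraction = 0.3, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be strictly between 0 and 1", call. = FALSE)
  for (cls in c(0L, 1L))
    if (sum(ds$label == cls) < 2L)
      stop("each class needs at least 2 members to split", call. = FALSE)
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(ds$label == cls)
    n_test <- round(length(idx) * test_fraction)
    n_test <- max(1L, min(length(idx) - 1L, n_test))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  subset_ds <- function(rows, suffix) {
    out <- ds[rows, , drop = FALSE]
    attr(out, "name") <- paste0(attr(ds, "name") %||% "dataset", suffix)
    class(out) <- class(ds)
    rownames(out) <- NULL
    out
  }
  list(train = subset_ds(setdiff(seq_len(nrow(ds)), test_idx), "_train"),
       test = subset_ds(test_idx, "_test"))
}

#' Stratified k-fold assignment
#'
#' @param labels binary label vector.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return Integer vector of fold ids in 1..k, one per sample, with each
#'   class spread as evenly as possible across folds.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  for (cls in c(0L, 1L))
    if (sum(labels == cls) < k)
      stop("each class needs at least k members", call. = FALSE)
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
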