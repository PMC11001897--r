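write_fasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

test_that("FASTA reader keeps valid windows and skips invalid ones with reasons", {
  good <- paste0(strrep("C", 20), "A", strrep("G", 20))
  fa <- write_fasta(list(ok = good), tempfile(fileext = ".fa"))
  ds <- read_fasta_windows(fa, label = 1L, species = "HS")
  expect_s3_class(ds, "window_dataset")
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$sequence, good)
  expect_equal(ds$label, 1L)

  # length-40 record and an ambiguous-base record are skipped, not fatal
  fa2 <- write_fasta(list(short = substr(good, 1, 40),
                          ambig = sub("C", "N", good),
                          ok = good),
                     tempfile(fileext = ".fa"))
  msgs <- capture_messages(ds2 <- read_fasta_windows(fa2, label = 0L))
  expect_equal(nrow(ds2), 1L)
  expect_match(msgs, "length 40", all = FALSE)
  expect_match(msgs, "ambiguous base", all = FALSE)

  # all-invalid file is fatal and names the rejection count
  fa3 <- write_fasta(list(bad = substr(good, 1, 40)), tempfile(fileext = ".fa"))
  expect_error(suppressMessages(read_fasta_windows(fa3, label = 1L)),
               "1 record")
  expect_error(read_fasta_windows(tempfile(), label = 1L), "cannot read")
})

test_that("DNA-alphabet input is coerced to RNA and the central base checked", {
  dna <- paste0(strrep("T", 20), "A", strrep("T", 20))
  fa <- write_fasta(list(r = dna), tempfile(fileext = ".fa"))
  ds <- read_fasta_windows(fa, label = 1L)
  expect_equal(ds$sequence, gsub("T", "U", dna))

  off_center <- paste0(strrep("G", 21), "A", strrep("G", 19))
  fa2 <- write_fasta(list(r = off_center, ok = dna), tempfile(fileext = ".fa"))
  msgs <- capture_messages(ds2 <- read_fasta_windows(fa2, label = 1L))
  expect_match(msgs, "central position", all = FALSE)
  expect_equal(nrow(ds2), 1L)
})

test_that("TSV round trip preserves the dataset", {
  ds <- tiny_dataset(5, 5)
  path <- tempfile(fileext = ".tsv")
  write_windows_tsv(ds, path)
  back <- read_windows_tsv(path)
  expect_equal(back$sequence, ds$sequence)
  expect_equal(back$label, ds$label)
  expect_equal(back$id, ds$id)
})

test_that("deduplication keeps first occurrences and flags cross-label conflicts", {
  seqs <- vapply(1:2, function(i) random_window(), character(1))
  ds <- window_dataset(id = c("a", "b", "c"),
                       sequence = c(seqs[1], seqs[2], seqs[1]),
                       label = c(1L, 1L, 1L))
  out <- suppressMessages(deduplicate(ds))
  expect_equal(nrow(out), 2L)
  expect_equal(out$id, c("a", "b"))

  # all-unique input is untouched
  ds_u <- tiny_dataset(6, 6, strength = 0)
  expect_equal(suppressMessages(deduplicate(ds_u))$sequence, ds_u$sequence)

  # same sequence under both labels: both kept, conflict warned
  ds_x <- window_dataset(id = c("p", "n"), sequence = c(seqs[1], seqs[1]),
                         label = c(1L, 0L))
  expect_warning(out_x <- deduplicate(ds_x), "both labels")
  expect_equal(nrow(out_x), 2L)
})

test_that("synthetic generator is seed-deterministic and honours the bias", {
  a <- generate_synthetic(5, 5, seed = 7)
  b <- generate_synthetic(5, 5, seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, generate_synthetic(5, 5, seed = 8)$sequence))

  # degenerate profile: G everywhere except the forced central A
  prof <- matrix(0, 41, 4, dimnames = list(NULL, c("A", "C", "G", "U")))
  prof[, "G"] <- 1
  prof[21, ] <- c(1, 0, 0, 0)
  ds <- generate_synthetic(3, 0, bias = prof, seed = 1)
  expect_true(all(ds$sequence ==
                    paste0(strrep("G", 20), "A", strrep("G", 20))))

  # malformed bias rows are rejected
  bad <- matrix(0.3, 41, 4)
  expect_error(generate_synthetic(1, 1, bias = bad, seed = 1), "sum to 1")

  # every emitted window satisfies the invariants
  ds2 <- generate_synthetic(50, 50, seed = 3)
  expect_true(all(nchar(ds2$sequence) == 41))
  expect_true(all(substr(ds2$sequence, 21, 21) == "A"))
  expect_true(all(grepl("^[ACGU]+$", ds2$sequence)))
})

test_that("uniform bias yields classes indistinguishable in expectation", {
  n <- 10000
  ds <- generate_synthetic(n, n, bias = planted_profile(0), seed = 99)
  # per-position base frequencies agree within 3 multinomial standard errors
  se3 <- 3 * sqrt(0.25 * 0.75 / n) * sqrt(2)  # difference of two proportions
  for (pos in c(1, 5, 15, 30, 41)) {
    base_p <- substr(ds$sequence[ds$label == 1], pos, pos)
    base_n <- substr(ds$sequence[ds$label == 0], pos, pos)
    for (b in c("A", "C", "G", "U")) {
      d <- abs(mean(base_p == b) - mean(base_n == b))
      expect_lt(d, se3)
    }
  }
})

test_that("stratified split preserves class balance, partitions, and is seeded", {
  ds <- tiny_dataset(100, 100, strength = 0, seed = 5)
  parts <- stratified_split(ds, 0.3, seed = 2)
  expect_equal(class_counts(parts$test), c(positive = 30L, negative = 30L))
  expect_equal(class_counts(parts$train), c(positive = 70L, negative = 70L))
  expect_length(intersect(parts$train$id, parts$test$id), 0L)
  expect_setequal(c(parts$train$id, parts$test$id), ds$id)

  again <- stratified_split(ds, 0.3, seed = 2)
  expect_identical(parts$test$id, again$test$id)

  tiny <- window_dataset("x", random_window(), 1L)
  expect_error(stratified_split(tiny, 0.3), "at least 2")
  expect_error(stratified_split(ds, 1.2), "between 0 and 1")
})

test_that("stratified folds are a reproducible exhaustive partition", {
  labels <- rep(c(0L, 1L), each = 50)
  f1 <- stratified_folds(labels, 10, seed = 3)
  f2 <- stratified_folds(labels, 10, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  expect_true(all(table(f1, labels) == 5))
  expect_error(stratified_folds(rep(1L, 10), 5), "each class")
})
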