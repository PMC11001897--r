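test_that("k-mer index is lexicographic and bijective", {
  expect_equal(kmer_index(1), c("A", "C", "G", "U"))
  for (k in 1:3) {
    idx <- kmer_index(k)
    expect_equal(idx, oracle_kmers(k))
    expect_equal(idx[1], strrep("A", k))
    expect_equal(idx[4^k], strrep("U", k))
    expect_equal(anyDuplicated(idx), 0L)
  }
  expect_error(kmer_index(4), "must be 1, 2 or 3")
})

test_that("frequency vector counts overlapping k-mers with conserved block sums", {
  homo <- strrep("A", 41)
  fv <- frequency_vector(homo)
  expect_length(fv, 84)
  expect_equal(unname(fv["fv_k1_A"]), 41)
  expect_equal(unname(fv["fv_k2_AA"]), 40)
  expect_equal(unname(fv["fv_k3_AAA"]), 39)
  expect_equal(sum(fv), 41 + 40 + 39)

  toy <- frequency_vector("ACAU")
  expect_equal(unname(toy[c("fv_k1_A", "fv_k1_C", "fv_k1_U")]), c(2, 1, 1))
  expect_equal(unname(toy[c("fv_k2_AC", "fv_k2_CA", "fv_k2_AU")]), c(1, 1, 1))

  set.seed(10)
  for (i in 1:5) {
    fv <- frequency_vector(random_window())
    expect_equal(unname(c(sum(fv[1:4]), sum(fv[5:20]), sum(fv[21:84]))),
                 c(41, 40, 39))
  }
})

test_that("AAPIV accumulates 1-based occurrence positions", {
  toy <- aapiv("ACAU", 1)
  expect_equal(unname(toy), c(4, 2, 0, 4))  # A: 1+3, C: 2, G: absent, U: 4

  homo <- aapiv(strrep("A", 41), 1)
  expect_equal(unname(homo), c(861, 0, 0, 0))

  set.seed(11)
  for (i in 1:5) {
    w <- random_window()
    expect_equal(sum(aapiv(w, 1)), 861)  # every position counted once
    for (k in 1:3) expect_equal(unname(aapiv(w, k)), unname(oracle_aapiv(w, k)))
  }
})

test_that("RAAPIV is AAPIV of the reversed sequence", {
  toy <- raapiv("ACAU", 1)                  # reversed: UACA
  expect_equal(unname(toy), c(6, 3, 0, 1))  # A: 2+4, C: 3, U: 1

  set.seed(12)
  for (i in 1:5) {
    w <- random_window()
    for (k in 1:3)
      expect_equal(unname(raapiv(w, k)),
                   unname(aapiv(oracle_reverse(w), k)))
  }

  pal <- "ACGCA"  # reads the same reversed
  expect_equal(unname(raapiv(pal, 1)), unname(aapiv(pal, 1)))
})

test_that("PRIM matches the brute-force convention on the toy and at scale", {
  W <- prim("ACAU", 1)
  expect_equal(W["A", "A"], 2)
  expect_equal(W["A", "C"], 1)
  expect_equal(W["A", "U"], 3)
  expect_equal(W["C", "A"], 0)  # signed offsets cancel: (1-2) + (3-2)
  expect_equal(unname(W["G", ]), rep(0, 4))

  homo <- prim(strrep("A", 41), 1)
  expect_equal(homo["A", "A"], sum((1:41) - 1))  # 820
  expect_equal(sum(homo != 0), 1L)

  expect_equal(length(prim(random_window(), 2)), 256L)
  expect_equal(length(prim(random_window(), 3)), 4096L)

  set.seed(13)
  for (i in 1:3) {
    w <- random_window()
    for (k in 1:2) expect_equal(prim(w, k), oracle_prim(w, k))
  }
})

test_that("RPRIM is PRIM of the reversed sequence", {
  R <- rprim("ACAU", 1)  # reversed: UACA
  expect_equal(R["U", "A"], 4)  # (2-1) + (4-1)
  set.seed(15)
  for (i in 1:3) {
    w <- random_window()
    for (k in 1:3)
      expect_equal(rprim(w, k), prim(oracle_reverse(w), k))
  }
})

test_that("2D sequence matrices reshape the integer-encoded k-mer stream", {
  homo <- sequence_matrix_2d(strrep("A", 41), 1)
  expect_equal(dim(homo), c(7, 7))
  expect_equal(as.vector(t(homo)), c(rep(1, 41), rep(0, 8)))

  w <- paste0("ACGU", strrep("C", 16), "A", strrep("G", 20))
  M <- sequence_matrix_2d(w, 1)
  expect_equal(M[1, 1:4], c(1, 2, 3, 4))  # A,C,G,U encode as 1..4 row-major

  set.seed(16)
  for (k in 1:3) {
    M <- sequence_matrix_2d(random_window(), k)
    expect_equal(dim(M), c(7, 7))
    expect_true(all(M == 0 | (M >= 1 & M <= 4^k)))
  }
})

test_that("assembled feature vector has the documented 522-block layout", {
  set.seed(17)
  w <- random_window()
  v <- assemble_features(w)
  expect_length(v, 522)
  expect_true(all(is.finite(v)))

  blocks <- c(prim = 90, rprim = 90, fv = 84, aapiv = 84, raapiv = 84,
              mat2d = 90)
  prefix <- sub("_.*", "", names(v))
  expect_equal(unname(table(prefix)[names(blocks)]), unname(blocks),
               ignore_attr = TRUE)
  # layout order: prim | rprim | fv | aapiv | raapiv | mat2d
  expect_equal(rle(prefix)$values,
               c("prim", "rprim", "fv", "aapiv", "raapiv", "mat2d"))

  expect_identical(v, assemble_features(w))  # pure function
  expect_error(assemble_features("ACGU"), "invalid window")
})

test_that("reversal swaps the PRIM/RPRIM and AAPIV/RAAPIV blocks", {
  set.seed(18)
  w <- random_window()
  v <- assemble_features(w)
  vr <- assemble_features(oracle_reverse(w))
  pick <- function(x, prefix) unname(x[startsWith(names(x), prefix)])
  expect_equal(pick(v, "prim_"), pick(vr, "rprim_"))
  expect_equal(pick(v, "rprim_"), pick(vr, "prim_"))
  expect_equal(pick(v, "aapiv_"), pick(vr, "raapiv_"))
  expect_equal(pick(v, "raapiv_"), pick(vr, "aapiv_"))
})

test_that("dataset encoding yields one stable named row per window", {
  ds <- tiny_dataset(5, 5)
  tab <- encode_dataset(ds)
  expect_equal(dim(tab), c(10, 524))
  expect_equal(names(tab)[1:2], c("id", "label"))
  expect_equal(anyDuplicated(names(tab)), 0L)
  expect_equal(names(tab)[-(1:2)], feature_names())
  for (i in c(1, 10))
    expect_equal(unlist(tab[i, -(1:2)]), assemble_features(ds$sequence[i]))

  # CSV round trip preserves names and values
  path <- tempfile(fileext = ".csv")
  write_features_csv(tab, path)
  back <- read_features_csv(path)
  expect_equal(names(back), names(tab))
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(tab[, -(1:2)]),
               tolerance = 1e-12, ignore_attr = TRUE)
})
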