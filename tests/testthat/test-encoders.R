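polyA <- function() {
  s <- strrep("A", 41); substr(s, 21, 21) <- "C"; s
}

test_that("feature lengths match the closed forms", {
  expect_equal(feature_length("BKF", 41), 500L)
  expect_equal(feature_length("DBPF", 41), 680L)
  expect_equal(feature_length("KNN", 41), 10L)
  expect_equal(feature_length("PCP", 41), 240L)
  expect_equal(feature_length("MMI", 41), 30L)
  expect_equal(feature_length("PseDNC", 41), 19L)
  expect_equal(feature_length("PseEIIP", 41), 64L)
  expect_equal(feature_length("RFHCP", 41), 164L)
  expect_error(feature_length("XYZ", 41), "unknown")
})

test_that("every encoder returns its declared length with finite values", {
  set.seed(31)
  s <- random_window()
  for (sc in setdiff(mc4_schemes, "KNN")) {
    v <- encode(s, sc)
    expect_length(v, feature_length(sc, 41))
    expect_true(all(is.finite(v)))
    expect_identical(v, encode(s, sc))  # purity
  }
})

test_that("BKF one-hot block sums to L and k-mer blocks are frequencies", {
  set.seed(32)
  s <- random_window()
  v <- encode(s, "BKF")
  expect_equal(sum(v[1:164]), 41)               # one hot bit per position
  expect_true(all(v[1:164] %in% c(0, 1)))
  expect_equal(sum(v[165:180]), 1)              # 16 dinucleotide freqs
  expect_equal(sum(v[181:244]), 1)              # 64 trinucleotide freqs
  expect_equal(sum(v[245:500]), 1)              # 256 tetranucleotide freqs

  # poly-A window: single A->C->A breakpoints, check the dinucleotide block
  v2 <- encode(polyA(), "BKF")
  dinuc <- v2[165:180]
  names(dinuc) <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
                    "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  expect_equal(unname(dinuc["AA"]), 38 / 40)
  expect_equal(unname(dinuc["AC"]), 1 / 40)
  expect_equal(unname(dinuc["CA"]), 1 / 40)
})

test_that("PseEIIP of a poly-A window is the hand-computed vector", {
  v <- encode(polyA(), "PseEIIP")
  tri <- apply(expand.grid(B3 = c("A", "C", "G", "T"), B2 = c("A", "C", "G", "T"),
                           B1 = c("A", "C", "G", "T"))[, 3:1], 1, paste0,
               collapse = "")
  names(v) <- tri
  # 39 trinucleotide windows: 36 AAA, and AAC, ACA, CAA once each
  eiip <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  expect_equal(unname(v["AAA"]), 3 * 0.1260 * (36 / 39))
  expect_equal(unname(v["AAC"]), (2 * eiip[["A"]] + eiip[["C"]]) * (1 / 39))
  expect_equal(sum(v > 0), 4L)
  expect_true(all(v >= 0))

  # pure homopolymer (no centre constraint at encoder level)
  v2 <- encode(strrep("A", 41), "PseEIIP")
  names(v2) <- tri
  expect_equal(unname(v2["AAA"]), 0.378)
  expect_equal(sum(v2 != 0), 1L)
})

test_that("MMI pair block is invariant under sequence reversal", {
  set.seed(33)
  for (i in 1:10) {
    s <- random_window()
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    v <- encode(s, "MMI"); vr <- encode(r, "MMI")
    # adjacent unordered pairs are preserved by reversal
    expect_equal(v[1:10], vr[1:10])
  }
})

test_that("DBPF one-hot and running-frequency blocks are coherent", {
  set.seed(34)
  s <- random_window()
  v <- encode(s, "DBPF")
  m <- matrix(v, nrow = 17)          # one column per dinucleotide position
  expect_equal(colSums(m[1:16, ]), rep(1, 40))
  expect_true(all(m[17, ] > 0 & m[17, ] <= 1))
  # last position's running frequency equals the dinucleotide's overall count/40
  chars <- strsplit(s, "")[[1]]
  last <- paste0(chars[40], chars[41])
  all_d <- paste0(chars[1:40], chars[2:41])
  expect_equal(m[17, 40], sum(all_d == last) / 40)
})

test_that("RFHCP channels encode chemistry bits plus nucleotide density", {
  s <- polyA()
  v <- encode(s, "RFHCP")
  m <- matrix(v, nrow = 4)           # ring, hbond, amino, density per position
  expect_equal(dim(m), c(4L, 41L))
  expect_equal(m[1:3, 1], c(1, 0, 1))          # A: purine, weak, amino
  expect_equal(m[1:3, 21], c(0, 1, 1))         # C: pyrimidine, strong, amino
  # density channel: cumulative frequency of the position's own base
  expect_equal(m[4, 1], 1)
  expect_equal(m[4, 21], 1 / 21)               # first C at position 21
  expect_equal(m[4, 41], 40 / 41)
  chars <- strsplit(s, "")[[1]]
  dens <- vapply(seq_along(chars),
                 function(i) mean(chars[seq_len(i)] == chars[i]), 0)
  expect_equal(m[4, ], dens)
})

test_that("PseDNC features are a normalized composition (sum to one)", {
  set.seed(35)
  for (i in 1:5) {
    v <- encode(random_window(), "PseDNC")
    expect_equal(sum(v), 1)
    expect_true(all(v >= 0))
    expect_length(v, 19L)
  }
})

test_that("KNN features match a brute-force neighbour sort", {
  set.seed(36)
  refs <- make_samples(replicate(10, random_window()),
                       sample(c("pos", "neg"), 10, TRUE))
  q <- random_window()
  got <- encode_knn(q, refs, k_fractions = 0.5)
  # exhaustive oracle: per-position identity, stable sort, top ceiling(0.5*10)
  sims <- sapply(refs$sequence, function(r) {
    mean(strsplit(r, "")[[1]] == strsplit(q, "")[[1]])
  })
  ord <- order(-sims)  # order() is stable: input-order tie-break
  expect_equal(got, mean(refs$label[ord][1:5] == "pos"))

  # query identical to one positive reference, single nearest
  refs2 <- make_samples(c(q, replicate(4, random_window())),
                        c("pos", rep("neg", 4)))
  expect_equal(encode_knn(q, refs2, k_fractions = 0.01), 1)
  # all-negative references
  refs3 <- make_samples(replicate(6, random_window()), rep("neg", 6))
  expect_equal(encode_knn(q, refs3), rep(0, 10))
  expect_error(encode_knn(q, refs3[0, ]), "non-empty")
})

test_that("dataset encoding preserves row order, width, and permutations", {
  set.seed(37)
  s <- make_samples(replicate(4, random_window()), c("pos", "neg", "pos", "neg"))
  M <- encode_dataset(s, "BKF")
  expect_equal(dim(M), c(4L, 500L))
  expect_equal(rownames(M), s$id)

  empty <- encode_dataset(s[0, ], "BKF")
  expect_equal(dim(empty), c(0L, 500L))

  perm <- c(3, 1, 4, 2)
  Mp <- encode_dataset(s[perm, ], "BKF")
  expect_equal(unclass(Mp), unclass(M)[perm, ], ignore_attr = TRUE)
})

test_that("out-of-fold KNN rows never use same-fold references", {
  set.seed(38)
  n <- 30
  s <- make_samples(replicate(n, random_window()),
                    rep(c("pos", "neg"), n / 2))
  f <- stratified_folds(s, k = 3, seed = 5)
  M <- encode_dataset(s, "KNN", fold_assignment = f)
  expect_equal(dim(M), c(n, 10L))
  # oracle: recompute each row restricting references to other folds
  for (i in sample(n, 6)) {
    refs <- s[f != f[i], ]
    expect_equal(unname(M[i, ]), encode_knn(s$sequence[i], refs))
  }
  expect_error(encode_dataset(s, "KNN"), "fold")
})

test_that("encoded matrices round-trip through TSV with sidecar metadata", {
  set.seed(39)
  s <- make_samples(replicate(3, random_window()), c("pos", "neg", "pos"))
  M <- encode_dataset(s, "PseEIIP")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_encoded(M, p)
  back <- read_encoded(p)
  expect_equal(unclass(back), unclass(M), ignore_attr = TRUE)
  expect_equal(attr(back, "scheme"), "PseEIIP")
})
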