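w41 <- function(base = "A") {
  s <- strrep(base, 41)
  substr(s, 21, 21) <- "C"
  s
}

test_that("FASTA with header tags parses to labelled windows", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">w1|pos", w41("A"), ">w2|neg", w41("G")), f)
  s <- read_samples(f)
  expect_s3_class(s, "mc4_samples")
  expect_equal(s$id, c("w1", "w2"))
  expect_equal(s$label, c("pos", "neg"))
  expect_equal(nchar(s$sequence), c(41L, 41L))
})

test_that("lowercase and U are normalized; other residues are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">w1|pos", tolower(gsub("A", "U", w41("A")))), f)
  s <- read_samples(f)
  expect_equal(s$sequence, gsub("U", "T", gsub("A", "T", w41("A"))))

  writeLines(c(">w1|pos", sub("A", "N", w41("A"))), f)
  expect_error(read_samples(f), "position 1")
})

test_that("wrong-length and unlabelled records raise errors naming the record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">short1|pos", substr(w41(), 1, 40)), f)
  expect_error(read_samples(f), "short1.*length 40")
  writeLines(c(">nolabel", w41()), f)
  expect_error(read_samples(f), "nolabel")
})

test_that("sidecar TSV labels and modQV metadata are joined by id", {
  d <- withr::local_tempdir()
  fasta <- file.path(d, "w.fasta")
  writeLines(c(">a", w41("A"), ">b", w41("T")), fasta)
  writeLines(c("a\t1", "b\tneg"), file.path(d, "labels.tsv"))
  writeLines(c("b\t12.5"), file.path(d, "meta.tsv"))
  s <- read_samples(fasta, labels_source = file.path(d, "labels.tsv"),
                    metadata_path = file.path(d, "meta.tsv"))
  expect_equal(s$label, c("pos", "neg"))
  expect_equal(s$modqv, c(NA, 12.5))

  writeLines(c("a\t1"), file.path(d, "labels.tsv"))
  expect_error(read_samples(fasta, labels_source = file.path(d, "labels.tsv")),
               "'b'")
})

test_that("write_benchmark -> read_samples round trip preserves samples", {
  cfg <- generator_config(n_pos = 6, n_neg = 6, seed = 9)
  s <- generate_samples(cfg)
  d <- withr::local_tempdir()
  paths <- write_benchmark(s, d)
  back <- read_samples(paths[["fasta"]], metadata_path = paths[["metadata"]])
  expect_equal(back$id, s$id)
  expect_equal(back$sequence, s$sequence)
  expect_equal(back$label, s$label)
  expect_equal(back$modqv, s$modqv)
})

test_that("modQV filter keeps the boundary value and supports both modes", {
  s <- make_samples(replicate(3, random_window()), c("pos", "neg", "pos"),
                    modqv = c(10, 30, 31))
  kept <- filter_by_modqv(s, 30, "drop_above")
  expect_equal(kept$modqv, c(10, 30))
  expect_equal(filter_by_modqv(s, 30, "drop_below")$modqv, c(30, 31))

  expect_equal(nrow(filter_by_modqv(s[0, ], 30)), 0L)
  s2 <- make_samples(replicate(2, random_window()), c("pos", "neg"))
  expect_equal(filter_by_modqv(s2, 30), s2)
  expect_error(filter_by_modqv(s, -1), "non-negative")
})

test_that("exact dedup keeps first occurrences", {
  set.seed(4)
  w <- random_window()
  s <- make_samples(c(w, random_window(), w), c("pos", "neg", "neg"))
  out <- dedup_exact(s, verbose = FALSE)
  expect_equal(out$id, c("s01", "s02"))

  uniq <- make_samples(replicate(5, random_window()), rep("pos", 5))
  expect_equal(dedup_exact(uniq, verbose = FALSE), uniq)

  # 100 windows with 10 planted duplicates -> 90 survivors (counted by hash)
  base <- replicate(90, random_window())
  seqs <- c(base, base[1:10])
  expected <- length(unique(seqs))
  expect_equal(expected, 90L)
  s100 <- make_samples(seqs, rep(c("pos", "neg"), 50))
  expect_equal(nrow(dedup_exact(s100, verbose = FALSE)), 90L)
})

test_that("modQV filter and dedup commute on distinct sequences", {
  set.seed(8)
  s <- make_samples(replicate(20, random_window()),
                    rep(c("pos", "neg"), 10),
                    modqv = sample(c(NA, 10, 40), 20, replace = TRUE))
  a <- dedup_exact(filter_by_modqv(s, 30), verbose = FALSE)
  b <- filter_by_modqv(dedup_exact(s, verbose = FALSE), 30)
  expect_equal(a, b)
})

test_that("stratified folds balance classes, partition rows, and are seeded", {
  s <- make_samples(replicate(9, random_window()),
                    rep(c("pos", "pos", "neg"), 3))
  f <- stratified_folds(s, k = 3, seed = 1)
  for (i in 0:2) {
    expect_equal(sum(f == i & s$label == "pos"), 2L)
    expect_equal(sum(f == i & s$label == "neg"), 1L)
  }
  expect_equal(as.integer(stratified_folds(s, k = 3, seed = 1)), as.integer(f))
  expect_false(identical(as.integer(stratified_folds(s, k = 3, seed = 2)),
                         as.integer(f)))

  # partition: every row in exactly one fold
  expect_equal(sort(unique(as.integer(f))), 0:2)
  expect_equal(length(f), nrow(s))

  # large sample: per-fold class ratio within 5% of global
  set.seed(2)
  big <- make_samples(replicate(1000, random_window()),
                      sample(c("pos", "neg"), 1000, TRUE, prob = c(0.63, 0.37)))
  fb <- stratified_folds(big, k = 3, seed = 3)
  global <- mean(big$label == "pos")
  for (i in 0:2) {
    expect_lt(abs(mean(big$label[fb == i] == "pos") - global), 0.05)
  }

  expect_error(stratified_folds(make_samples(replicate(3, random_window()),
                                             c("pos", "pos", "neg")), k = 2),
               "fewer than k")
})
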