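test_that("generated pools satisfy the pairwise distance constraints (DP oracle)", {
  pools <- build_barcode_pools(n = 8, length = 9, min_dist = 2,
                               min_hamming = 4, seed = 31)
  all_bc <- c(pools$bc1, pools$bc2, pools$bc3)
  expect_identical(length(unique(all_bc)), 24L)
  # exhaustive verification against base R's adist (independent oracle)
  lev <- adist(all_bc)
  expect_gte(min(lev[upper.tri(lev)]), 2)
  ham <- outer(all_bc, all_bc, function(a, b)
    mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
           a, b))
  expect_gte(min(ham[upper.tri(ham)]), 4)
})

test_that("tiny pools with an easy constraint are exactly verifiable", {
  pools <- build_barcode_pools(n = 2, length = 3, min_dist = 2,
                               min_hamming = 2, seed = 1)
  all_bc <- c(pools$bc1, pools$bc2, pools$bc3)
  lev <- adist(all_bc)
  expect_gte(min(lev[upper.tri(lev)]), 2)
})

test_that("an unsatisfiable constraint fails with a generation error", {
  expect_error(build_barcode_pools(n = 40, length = 3, min_dist = 3,
                                   min_hamming = 3, seed = 1,
                                   max_tries = 200),
               "constraint")
})

test_that("whitelists load from TSV and reject non-DNA", {
  pools <- tiny_pools()
  f <- tempfile()
  writeLines(paste(pools$bc1, pools$bc2, pools$bc3, sep = "\t"), f)
  back <- read_barcode_pools(f)
  expect_identical(back$bc2, pools$bc2)
  writeLines(c("ACGTACGTX"), f)
  f3 <- c(f, f, f)
  expect_error(read_barcode_pools(f3), "non-ACGT")
})

test_that("composed reference has the documented architecture", {
  ref <- tiny_reference()
  # 3 x 9 bp barcodes + 12 bp and 13 bp linkers = 52 bp label segment
  expect_identical(ref$label_len, 52L)
  # anchor + label + UMI + oligo-dT = 98 bases
  expect_identical(ref$ref_len, 98L)
  expect_identical(ref$n_labels, 64L)
  # single-barcode pools give exactly one label
  p1 <- structure(list(bc1 = "ACGTACGTA", bc2 = "TTGGCCAAT",
                       bc3 = "GGAATTCCG"), class = "barcode_pools")
  expect_identical(compose_reference(p1)$n_labels, 1L)
})

test_that("composed labels contain their barcodes in order at fixed offsets", {
  pools <- structure(list(bc1 = c("AAACCCGGG", "TTTAAACCC"),
                          bc2 = c("CCCGGGTTT", "GGGTTTAAA"),
                          bc3 = c("ACACACACA", "TGTGTGTGT")),
                     class = "barcode_pools")
  ref <- compose_reference(pools)
  n_seen <- 0
  for (a in 1:2) for (b in 1:2) for (c in 1:2) {
    lab <- label_sequence(ref, a, b, c)
    expect_identical(substr(lab, ref$offsets["bc1"] + 1,
                            ref$offsets["bc1"] + 9), pools$bc1[a])
    expect_identical(substr(lab, ref$offsets["bc2"] + 1,
                            ref$offsets["bc2"] + 9), pools$bc2[b])
    expect_identical(substr(lab, ref$offsets["bc3"] + 1,
                            ref$offsets["bc3"] + 9), pools$bc3[c])
    n_seen <- n_seen + 1
  }
  expect_equal(n_seen, 8)
  # padded form adds Ns at both ends
  lab <- label_sequence(ref, 1, 1, 1, pad = TRUE)
  expect_match(lab, "^N{10}.*N{10}$")
})

test_that("pool distance statistics match hand-computed values", {
  s <- pool_distance_stats(c("AAA", "AAT"))
  expect_identical(s$hamming_min, 1)
  expect_identical(s$hamming_mean, 1)
  expect_identical(s$levenshtein_min, 1L)
  expect_identical(pool_distance_stats(c("AC", "A"))$levenshtein_min, 1L)
  expect_identical(pool_distance_stats(c("ACGT", "TGCA"))$levenshtein_min, 4L)
  expect_identical(pool_distance_stats(c("AAA", "AAA"))$levenshtein_min, 0L)
  expect_error(pool_distance_stats("AAA"), "at least 2")
  # exact DP agrees with adist on random pairs
  set.seed(2)
  seqs <- regionvelo:::random_dna(12, 9)
  lev <- regionvelo:::cpp_lev_pairs(seqs)
  oracle <- adist(seqs)[upper.tri(adist(seqs))]
  # cpp_lev_pairs enumerates pairs (i,j) i<j in row-major order, adist
  # upper triangle is column-major: compare as sorted multisets
  expect_identical(sort(as.integer(lev)), sort(as.integer(oracle)))
})
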