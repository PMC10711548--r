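make_sim <- function(n_reads, err = 0, seed = 17, junk = 0,
                     strands = c(0.5, 0.5, 0), n = 24) {
  ref <- compose_reference(tiny_pools(seed = 77, n = n))
  rates <- c(0.6, 0.2, 0.2) * err
  sim <- simulate_barcoded_reads(ref, n_reads = n_reads,
                                 model = error_model(rates[1], rates[2],
                                                     rates[3]),
                                 strand_probs = strands,
                                 junk_prob = junk, seed = seed)
  list(ref = ref, sim = sim)
}

test_that("strand detection: intact oligo-dT, its reverse complement, and random sequence", {
  x <- make_sim(30, err = 0, junk = 0)
  fwd <- x$sim$reads[x$sim$truth$strand == "forward"]
  expect_true(all(detect_strand(fwd) == "forward"))
  expect_true(all(detect_strand(revcomp(fwd)) == "reverse"))
  set.seed(3)
  rand <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G"), 200, TRUE, prob = c(0.2, 0.4, 0.4)),
          collapse = ""), character(1))
  expect_true(all(detect_strand(rand, run_len = 8) == "none"))
})

test_that("at error rate zero every structurally intact read is assigned correctly in round 1", {
  x <- make_sim(120, err = 0)
  asg <- demux_reads(x$sim$reads, x$ref, demux_config("conservative"))
  m <- evaluate_demux(asg, x$sim$truth)
  expect_identical(m$tpr, 1)
  expect_identical(m$fpr, 0)
  expect_true(all(asg$round == 1L))
  # extracted UMIs are exact at zero error
  expect_identical(asg$umi, x$sim$truth$umi)
})

test_that("reads with two substitutions inside barcodes are still assigned correctly", {
  ref <- compose_reference(tiny_pools(seed = 77, n = 24))
  tr <- data.frame(b1 = 3L, b2 = 5L, b3 = 7L)
  lab <- label_sequence(ref, tr$b1, tr$b2, tr$b3, umi = "ACGTACGT")
  read <- paste0(lab, revcomp(regionvelo:::random_dna(1, 300)))
  # substitute one base inside bc1 and one inside bc3
  mutate_at <- function(s, pos) {
    old <- substr(s, pos, pos)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    paste0(substr(s, 1, pos - 1), new, substr(s, pos + 1, nchar(s)))
  }
  set.seed(9)
  read <- mutate_at(read, ref$offsets[["bc1"]] + 5)
  read <- mutate_at(read, ref$offsets[["bc3"]] + 3)
  asg <- demux_reads(read, ref, demux_config("conservative"))
  expect_identical(asg$b1, tr$b1)
  expect_identical(asg$b2, tr$b2)
  expect_identical(asg$b3, tr$b3)
  expect_identical(asg$round, 1L)
})

test_that("random sequence reads stay unassigned", {
  ref <- compose_reference(tiny_pools(seed = 77, n = 24))
  set.seed(4)
  rand <- regionvelo:::random_dna(60, 500)
  asg <- demux_reads(rand, ref, demux_config("conservative"))
  expect_identical(sum(!is.na(asg$cell_label)), 0L)
})

test_that("round 2 rescues a read whose label lies beyond the trim window", {
  ref <- compose_reference(tiny_pools(seed = 77, n = 24))
  lab <- label_sequence(ref, 2, 4, 6, umi = "TTGGAACC")
  set.seed(12)
  read <- paste0(regionvelo:::random_dna(1, 350), lab,
                 revcomp(regionvelo:::random_dna(1, 200)))
  asg <- demux_reads(read, ref, demux_config("conservative"))
  expect_identical(asg$round, 2L)
  expect_identical(asg$b1, 2L)
  expect_identical(asg$b2, 4L)
  expect_identical(asg$b3, 6L)
})

test_that("a read containing only two of three barcodes is not rescued", {
  ref <- compose_reference(tiny_pools(seed = 77, n = 24))
  # bc1 + linker1 + bc2 but no bc3 region
  partial <- paste0(ref$anchor, ref$pools$bc1[1], ref$linker1,
                    ref$pools$bc2[1])
  set.seed(13)
  read <- paste0(regionvelo:::random_dna(1, 350), partial,
                 regionvelo:::random_dna(1, 200))
  asg <- demux_reads(read, ref, demux_config("conservative"))
  expect_true(is.na(asg$cell_label))
})

test_that("round-1 and round-2 assignments are disjoint and compose the demux rate", {
  x <- make_sim(400, err = 0.08, junk = 0.3, seed = 23)
  asg <- demux_reads(x$sim$reads, x$ref, demux_config("conservative"))
  r1 <- which(asg$round == 1L)
  r2 <- which(asg$round == 2L)
  expect_length(intersect(r1, r2), 0)
  expect_gt(length(r2), 0)       # the junk reads exercise the rescue
  m <- evaluate_demux(asg, x$sim$truth)
  expect_equal(m$demux_rate, (length(r1) + length(r2)) / 400)
})

test_that("tightening the low-margin distance cap never increases false assignments", {
  x <- make_sim(500, err = 0.10, seed = 29)
  fp_of <- function(dlm) {
    asg <- demux_reads(x$sim$reads, x$ref,
                       demux_config("conservative",
                                    max_dist_low_margin = dlm,
                                    second_round = FALSE))
    evaluate_demux(asg, x$sim$truth)$fp
  }
  fps <- vapply(c(4, 7, 10), fp_of, numeric(1))
  expect_true(all(diff(fps) >= 0))
})

test_that("demux metrics reproduce a hand-counted confusion table", {
  truth <- data.frame(read_id = sprintf("r%02d", 1:10),
                      b1 = c(1, 1, 2, 2, 3, 3, 1, 2, NA, NA),
                      b2 = c(1, 1, 2, 2, 3, 3, 1, 2, NA, NA),
                      b3 = c(1, 1, 2, 2, 3, 3, 1, 2, NA, NA))
  asg <- data.frame(read_id = truth$read_id,
                    b1 = c(1, 1, 2, 9, NA, 3, 1, NA, 5, NA),
                    b2 = c(1, 1, 2, 2, NA, 3, 1, NA, 5, NA),
                    b3 = c(1, 1, 2, 2, NA, 3, 1, NA, 5, NA))
  m <- evaluate_demux(asg, truth)
  # TP: r1,r2,r3,r6,r7 = 5; FP: r4 (wrong) + r9 (not barcoded) = 2;
  # FN: r5, r8 = 2 of 8 barcoded
  expect_identical(m$tp, 5L)
  expect_identical(m$fp, 2L)
  expect_identical(m$fn, 2L)
  expect_equal(m$tpr, 5 / 8)
  expect_equal(m$fpr, 2 / 10)
  expect_equal(m$precision, 5 / 7)
  expect_equal(m$demux_rate, 7 / 10)
})

test_that("metric definitions are consistent with the printed validation quadruple", {
  # 1000 reads, all truly barcoded: TP 725, FP 64, FN 211
  tp <- 725; fp <- 64; fn <- 211
  expect_equal(tp / 1000, 0.725)            # TPR
  expect_equal(fp / 1000, 0.064)            # FPR
  expect_equal(fn / 1000, 0.211)            # FNR
  expect_equal(tp / (tp + fp), 0.919, tolerance = 5e-4)  # precision
  expect_equal(tp + fp + fn, 1000)
})
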