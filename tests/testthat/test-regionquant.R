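test_that("region index: single-exon genes have no introns; gaps become introns", {
  single <- data.frame(gene_id = "g", transcript_id = "g.t1",
                       chrom = "chr1", strand = "+",
                       start = 100L, end = 400L)
  idx <- build_region_index(structure(list(exons = single),
                                      class = "gene_annotation"))
  expect_identical(nrow(idx$genes$g$introns), 0L)

  idx2 <- build_region_index(two_exon_annotation())
  expect_equal(unname(idx2$genes$geneA$introns),
               unname(cbind(200L, 300L)))
})

test_that("the minimum-intron-length boundary: 20 bp is excluded, 21 bp retained", {
  mk <- function(gap) {
    data.frame(gene_id = "g", transcript_id = "g.t1", chrom = "chr1",
               strand = "+", start = c(100L, 200L + gap),
               end = c(200L, 300L + gap))
  }
  idx20 <- build_region_index(structure(list(exons = mk(20L)),
                                        class = "gene_annotation"))
  idx21 <- build_region_index(structure(list(exons = mk(21L)),
                                        class = "gene_annotation"))
  expect_identical(nrow(idx20$genes$g$introns), 0L)
  expect_identical(nrow(idx21$genes$g$introns), 1L)
  expect_identical(unname(idx21$genes$g$introns[1, "end"] -
                            idx21$genes$g$introns[1, "start"]), 21L)
})

test_that("exon precedence: merged exon coordinates are removed from introns", {
  # transcript 2 has an exon inside transcript 1's intron
  ex <- data.frame(gene_id = "g", transcript_id = c("t1", "t1", "t2"),
                   chrom = "chr1", strand = "+",
                   start = c(100L, 500L, 250L), end = c(200L, 600L, 330L))
  idx <- build_region_index(structure(list(exons = ex),
                                      class = "gene_annotation"))
  intr <- idx$genes$g$introns
  # intron [200,500) minus exon [250,330) -> [200,250) and [330,500)
  expect_equal(unname(intr), unname(cbind(c(200L, 330L), c(250L, 500L))))
})

test_that("classification follows the >20 bp intronic-overlap rule", {
  idx <- build_region_index(two_exon_annotation())
  cls <- classify_alignments(rbind(
    blocks_row("exonic", "120-180"),
    blocks_row("deep_intron", "150-200,200-225"),   # 25 bp into intron
    blocks_row("shallow_intron", "150-200,200-215"),# 15 bp into intron
    blocks_row("boundary20", "150-200,200-220"),    # exactly 20 bp
    blocks_row("boundary21", "150-200,200-221")),   # 21 bp
    idx)
  expect_identical(cls$spliced_call,
                   c("spliced", "unspliced", "spliced", "spliced",
                     "unspliced"))
  expect_equal(cls$intron_bp, c(0, 25, 15, 20, 21))
})

test_that("classification is invariant to block subdivision and strand-aware", {
  idx <- build_region_index(two_exon_annotation())
  whole <- classify_alignments(blocks_row("r", "120-380"), idx)
  split <- classify_alignments(blocks_row("r", "120-200,200-300,300-380"),
                               idx)
  expect_identical(whole$exon_bp, split$exon_bp)
  expect_identical(whole$intron_bp, split$intron_bp)
  expect_identical(whole$spliced_call, split$spliced_call)
  # antisense read is not assigned when strand-aware
  anti <- classify_alignments(blocks_row("r", "120-180", strand = "-"), idx)
  expect_true(is.na(anti$gene))
  ok <- classify_alignments(blocks_row("r", "120-180", strand = "-"), idx,
                            strand_aware = FALSE)
  expect_identical(ok$gene, "geneA")
})

test_that("accumulation composes molecules by the stated rules", {
  idx <- build_region_index(two_exon_annotation())
  rows <- rbind(
    blocks_row("r1", "120-180", umi = "AAAAAAAA"),  # spliced, exon-only
    blocks_row("r2", "120-180", umi = "AAAAAAAA"),  # duplicate read
    blocks_row("r3", "150-200,200-230", umi = "CCCCCCCC"))  # unspliced
  cls <- classify_alignments(rows, idx)
  cm <- accumulate_matrices(cls)
  expect_equal(as.numeric(cm$exon["c1", "geneA"]), 2)      # both molecules
  expect_equal(as.numeric(cm$intron["c1", "geneA"]), 1)
  expect_equal(as.numeric(cm$spliced["c1", "geneA"]), 1)
  expect_equal(as.numeric(cm$unspliced["c1", "geneA"]), 1)
  # spliced + unspliced = molecules
  expect_equal(as.numeric(cm$spliced + cm$unspliced)[1], 2)
})

test_that("counts are order-invariant and unknown barcodes go to background", {
  idx <- build_region_index(two_exon_annotation())
  rows <- rbind(
    blocks_row("r1", "120-180", cell = "c1", umi = "AAAAAAAA"),
    blocks_row("r2", "150-230", cell = "c2", umi = "GGGGGGGG"),
    blocks_row("r3", "300-380", cell = "c1", umi = "TTTTTTTT"))
  cls <- classify_alignments(rows, idx)
  a <- accumulate_matrices(cls)
  b <- accumulate_matrices(cls[c(3, 1, 2), ])
  expect_equal(as.matrix(a$exon), as.matrix(b$exon))
  expect_equal(as.matrix(a$unspliced), as.matrix(b$unspliced))
  bg <- accumulate_matrices(cls, cells = "c1")
  expect_identical(bg$n_background, 1L)
  expect_identical(rownames(bg$exon), "c1")
})

test_that("end-to-end: error-free synthetic reads reproduce the ground-truth matrices exactly", {
  ann <- generate_annotation(6, exons_per_gene_range = c(1, 4),
                             intron_len_range = c(10, 200), seed = 44)
  sim <- simulate_aligned_reads(ann, n_cells = 15,
                                molecules_per_cell_gene = 1.5,
                                spliced_fraction = 0.5,
                                reads_per_molecule = 2L, seed = 45)
  idx <- build_region_index(ann)
  cls <- classify_alignments(sim$blocks, idx)
  cm <- accumulate_matrices(cls, cells = rownames(sim$truth$exon))
  for (k in c("exon", "intron", "spliced", "unspliced")) {
    got <- as.matrix(cm[[k]])[rownames(sim$truth[[k]]),
                              colnames(sim$truth[[k]]), drop = FALSE]
    expect_equal(got, sim$truth[[k]] * 1.0, ignore_attr = TRUE,
                 label = k)
  }
})

test_that("blocks TSV round-trips", {
  rows <- rbind(blocks_row("r1", "120-180"), blocks_row("r2", "10-20,30-40"))
  f <- tempfile(fileext = ".tsv")
  write_blocks_tsv(rows, f)
  back <- read_blocks_tsv(f)
  expect_identical(back$blocks, rows$blocks)
  expect_identical(back$read_id, rows$read_id)
})

test_that("malformed coordinates are rejected", {
  bad <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                    strand = "+", start = 200L, end = 100L)
  expect_error(build_region_index(structure(list(exons = bad),
                                            class = "gene_annotation")),
               "malformed")
})
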