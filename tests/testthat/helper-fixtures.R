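# tiny fixtures shared across tests; everything is generated in code

tiny_pools <- function(seed = 42, n = 4) {
  build_barcode_pools(n = n, length = 9, min_dist = 2, min_hamming = 4,
                      seed = seed)
}

tiny_reference <- function(seed = 42, n = 4) {
  compose_reference(tiny_pools(seed, n))
}

# hand-built two-exon annotation: exons [100,200) and [300,400), i.e. one
# intron [200,300)
two_exon_annotation <- function() {
  ex <- data.frame(gene_id = "geneA", transcript_id = "geneA.t1",
                   chrom = "chr1", strand = "+",
                   start = c(100L, 300L), end = c(200L, 400L),
                   stringsAsFactors = FALSE)
  structure(list(exons = ex, truth = NULL), class = "gene_annotation")
}

blocks_row <- function(read_id, blocks, cell = "c1", umi = "AAAAAAAA",
                       chrom = "chr1", strand = "+") {
  data.frame(read_id = read_id, cell = cell, umi = umi, chrom = chrom,
             strand = strand, blocks = blocks, stringsAsFactors = FALSE)
}
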