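#' Generate a synthetic gene annotation
#'
#' Builds gene models (one or more transcripts of alternating exons and
#' introns) with coordinates drawn from the given ranges, spaced along
#' one chromosome. Coordinates are 0-based half-open internally;
#' \code{\link{write_gtf}} emits the 1-based inclusive convention.
#' Intron lengths down to 1 bp are allowed so the minimum-intron-length
#' rule of the quantifier can be exercised.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene_range integer range (min, max) of exons per
#'   transcript.
#' @param exon_len_range,intron_len_range bp ranges.
#' @param chrom chromosome name.
#' @param intergenic_gap bp between consecutive genes.
#' @param seed integer seed.
#' @return list of class \code{"gene_annotation"}:
#'   \item{exons}{data.frame gene_id, transcript_id, chrom, strand,
#'     start, end (0-based half-open).}
#'   \item{truth}{per-gene list of exon and intron interval matrices
#'     (columns start, end), the ground-truth region labels.}
#' @export
generate_annotation <- function(n_genes,
                                exons_per_gene_range = c(2, 5),
                                exon_len_range = c(100, 300),
                                intron_len_range = c(60, 400),
                                chrom = "chr1",
                                intergenic_gap = 1000,
                                seed = 1L) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 1
  if (!rng_ok(exons_per_gene_range) || !rng_ok(exon_len_range) ||
      !rng_ok(intron_len_range))
    stop("ranges must satisfy 1 <= min <= max")
  local_rng(seed)
  pos <- 1000
  rows <- list(); truth <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%04d", g)
    n_ex <- sample(seq(exons_per_gene_range[1], exons_per_gene_range[2]), 1)
    ex_len <- sample(seq(exon_len_range[1], exon_len_range[2]), n_ex,
                     replace = TRUE)
    in_len <- if (n_ex > 1)
      sample(seq(intron_len_range[1], intron_len_range[2]), n_ex - 1,
             replace = TRUE) else integer(0)
    starts <- ends <- integer(n_ex)
    p <- pos
    for (k in seq_len(n_ex)) {
      starts[k] <- p; ends[k] <- p + ex_len[k]
      p <- ends[k] + if (k < n_ex) in_len[k] else 0L
    }
    strand <- sample(c("+", "-"), 1)
    rows[[g]] <- data.frame(gene_id = gid,
                            transcript_id = paste0(gid, ".t1"),
                            chrom = chrom, strand = strand,
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
    introns <- if (n_ex > 1)
      cbind(start = ends[-n_ex], end = starts[-1]) else
      cbind(start = integer(0), end = integer(0))
    truth[[gid]] <- list(exons = cbind(start = starts, end = ends),
                         introns = introns, chrom = chrom,
                         strand = strand)
    pos <- p + intergenic_gap
  }
  structure(list(exons = do.call(rbind, rows), truth = truth),
            class = "gene_annotation")
}

#' Write gene models as GTF
#'
#' Exon features only, 1-based inclusive coordinates, with gene_id and
#' transcript_id attributes; the inverse of \code{\link{read_gtf}}.
#'
#' @param annotation a \code{"gene_annotation"} object or the
#'   \code{exons} data.frame (0-based half-open).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_gtf <- function(annotation, path) {
  ex <- if (inherits(annotation, "gene_annotation")) annotation$exons
        else annotation
  lines <- sprintf(
    '%s\tregionvelo\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
    ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Simulate aligned reads over an annotation
#'
#' Emulates the per-read aligned blocks that a spliced aligner would
#' report: each molecule is either spliced (blocks = the transcript's
#' exons) or unspliced (one block spanning the whole gene body, so it
#' carries intronic sequence); each molecule may be observed by several
#' reads sharing a UMI. Ground-truth exon/intron/spliced/unspliced
#' matrices are computed directly from the annotation arithmetic and the
#' minimum-intron-overlap rule, independent of the quantifier.
#'
#' @param annotation a \code{\link{generate_annotation}} result.
#' @param n_cells number of cells.
#' @param molecules_per_cell_gene Poisson mean molecule count per
#'   (cell, gene).
#' @param spliced_fraction probability a molecule is spliced.
#' @param reads_per_molecule integer >= 1; extra reads are exact
#'   duplicates with the same UMI (PCR duplicates).
#' @param min_intron_len introns must exceed this length (bp) to make a
#'   molecule's intronic signal count, matching the quantifier rule.
#' @param seed integer seed.
#' @return list of class \code{"simulated_alignments"}: \code{blocks}
#'   (data.frame read_id, cell, umi, chrom, strand, blocks string),
#'   \code{truth} (list of 4 cells x genes matrices).
#' @export
simulate_aligned_reads <- function(annotation, n_cells,
                                   molecules_per_cell_gene = 2,
                                   spliced_fraction = 0.6,
                                   reads_per_molecule = 1L,
                                   min_intron_len = 20L,
                                   seed = 1L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  if (spliced_fraction < 0 || spliced_fraction > 1)
    stop("spliced_fraction must be in [0, 1]")
  local_rng(seed)
  genes <- names(annotation$truth)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  mk <- function() matrix(0L, n_cells, length(genes),
                          dimnames = list(cells, genes))
  exon_m <- mk(); intron_m <- mk(); spliced_m <- mk(); unspliced_m <- mk()
  recs <- list(); rid <- 0L
  for (ci in seq_len(n_cells)) {
    for (gi in seq_along(genes)) {
      tr <- annotation$truth[[gi]]
      n_mol <- stats::rpois(1, molecules_per_cell_gene)
      if (n_mol == 0) next
      # qualifying intronic bases: only introns long enough to be kept in
      # the intron index (width > min_intron_len) can contribute
      w <- tr$introns[, "end"] - tr$introns[, "start"]
      intr_len <- sum(w[w > min_intron_len])
      used_umis <- character(0)
      for (m in seq_len(n_mol)) {
        spliced <- stats::runif(1) < spliced_fraction
        # molecules of one (cell, gene) group get UMIs at Hamming
        # distance >= 2, so directional UMI correction cannot merge two
        # distinct molecules and ground truth stays exact
        repeat {
          umi <- random_dna(1, 8)
          if (!length(used_umis) ||
              min(vapply(used_umis, function(u)
                sum(utf8ToInt(u) != utf8ToInt(umi)), integer(1))) >= 2)
            break
        }
        used_umis <- c(used_umis, umi)
        if (spliced || nrow(tr$introns) == 0) {
          blocks <- tr$exons
          spliced <- TRUE
        } else {
          blocks <- cbind(start = min(tr$exons[, "start"]),
                          end = max(tr$exons[, "end"]))
        }
        # rule-based truth: intronic iff summed known-intron overlap > cutoff
        intronic <- !spliced && intr_len > min_intron_len
        exon_m[ci, gi] <- exon_m[ci, gi] + 1L
        if (intronic) {
          intron_m[ci, gi] <- intron_m[ci, gi] + 1L
          unspliced_m[ci, gi] <- unspliced_m[ci, gi] + 1L
        } else {
          spliced_m[ci, gi] <- spliced_m[ci, gi] + 1L
        }
        bstr <- paste(sprintf("%d-%d", blocks[, "start"], blocks[, "end"]),
                      collapse = ",")
        for (r in seq_len(reads_per_molecule)) {
          rid <- rid + 1L
          recs[[rid]] <- data.frame(
            read_id = sprintf("aread%07d", rid), cell = cells[ci],
            umi = umi, chrom = tr$chrom, strand = tr$strand,
            blocks = bstr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  blocks_df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(read_id = character(0), cell = character(0),
               umi = character(0), chrom = character(0),
               strand = character(0), blocks = character(0))
  structure(list(blocks = blocks_df,
                 truth = list(exon = exon_m, intron = intron_m,
                              spliced = spliced_m,
                              unspliced = unspliced_m)),
            class = "simulated_alignments")
}
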