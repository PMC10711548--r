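## Interval helpers on 0-based half-open [start, end) matrices.
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0)
    return(cbind(start = integer(0), end = integer(0)))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (k in seq_len(nrow(m))[-1]) {
    last <- nrow(out)
    if (m[k, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], m[k, 2])
    } else out <- rbind(out, m[k, ])
  }
  colnames(out) <- c("start", "end")
  out
}

subtract_intervals <- function(a, b) {
  # a minus b; both merged/sorted
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  res <- list()
  for (k in seq_len(nrow(a))) {
    segs <- cbind(start = a[k, 1], end = a[k, 2])
    for (j in seq_len(nrow(b))) {
      new <- list()
      for (s in seq_len(nrow(segs))) {
        s1 <- segs[s, 1]; s2 <- segs[s, 2]
        b1 <- b[j, 1]; b2 <- b[j, 2]
        if (b2 <= s1 || b1 >= s2) { new[[length(new) + 1]] <- c(s1, s2); next }
        if (b1 > s1) new[[length(new) + 1]] <- c(s1, b1)
        if (b2 < s2) new[[length(new) + 1]] <- c(b2, s2)
      }
      segs <- if (length(new)) do.call(rbind, new) else
        cbind(start = integer(0), end = integer(0))
      if (nrow(segs) == 0) break
    }
    res[[k]] <- segs
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- cbind(start = integer(0), end = integer(0))
  colnames(out) <- c("start", "end")
  out
}

overlap_bp <- function(qs, qe, ss, se) {
  # total intersection of one query interval with subject intervals
  pmax(0, pmin(qe, se) - pmax(qs, ss))
}

#' Build the per-gene exon/intron region index
#'
#' Exon intervals are merged per gene across transcripts; introns (the
#' gaps between consecutive exons of each transcript) are merged
#' likewise. Where the merged sets would overlap, exons take precedence
#' (an exonic base in any transcript is evidence of mature sequence).
#' Introns of length <= \code{min_intron_len} are excluded from intronic
#' calling. Coordinates are 0-based half-open throughout.
#'
#' @param annotation a \code{"gene_annotation"} object, or an exon
#'   data.frame with columns gene_id, transcript_id, chrom, strand,
#'   start, end (0-based half-open).
#' @param min_intron_len minimum qualifying intron length in bp
#'   (default 20: only an intersection with a known intron longer than
#'   20 bp is treated as intronic).
#' @return list of class \code{"region_index"}: per-gene list with
#'   chrom, strand, \code{exons} and \code{introns} interval matrices.
#' @export
build_region_index <- function(annotation, min_intron_len = 20L) {
  ex <- if (inherits(annotation, "gene_annotation")) annotation$exons
        else annotation
  if (any(ex$end <= ex$start)) stop("malformed coordinates: end <= start")
  genes <- split(ex, ex$gene_id)
  idx <- lapply(genes, function(g) {
    exm <- merge_intervals(cbind(g$start, g$end))
    intr <- do.call(rbind, lapply(split(g, g$transcript_id), function(tx) {
      tx <- tx[order(tx$start), ]
      if (nrow(tx) < 2) return(NULL)
      cbind(tx$end[-nrow(tx)], tx$start[-1])
    }))
    inm <- merge_intervals(intr)
    inm <- subtract_intervals(inm, exm)          # exon precedence
    w <- inm[, "end"] - inm[, "start"]
    inm <- inm[w > min_intron_len, , drop = FALSE]
    list(chrom = g$chrom[1], strand = g$strand[1],
         exons = exm, introns = inm)
  })
  structure(list(genes = idx, min_intron_len = as.integer(min_intron_len)),
            class = "region_index")
}

#' @export
print.region_index <- function(x, ...) {
  n_in <- sum(vapply(x$genes, function(g) nrow(g$introns), integer(1)))
  cat(sprintf(
    "Region index: %d genes, %d qualifying introns (> %d bp)\n",
    length(x$genes), n_in, x$min_intron_len))
  invisible(x)
}

parse_blocks <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE),
                             function(p) as.integer(p)))
  colnames(m) <- c("start", "end")
  m
}

#' Classify aligned reads against the region index
#'
#' For each read (a set of aligned genomic blocks), the gene with the
#' largest total base-pair overlap of the read with the gene's merged
#' regions is assigned (ties are discarded as ambiguous); the read is
#' intronic iff its intersection with the gene's qualifying intron set
#' exceeds \code{min_intron_len} bp (summed by default; set
#' \code{per_intron = TRUE} to require a single intron's overlap to
#' exceed the cutoff), and a read with intronic sequence is an unspliced
#' transcript.
#'
#' @param blocks data.frame with columns read_id, cell, umi, chrom,
#'   strand and blocks ("start-end,start-end" 0-based half-open), as
#'   written by \code{\link{write_blocks_tsv}}.
#' @param index a \code{\link{build_region_index}} result.
#' @param strand_aware only match genes on the read's strand (set FALSE
#'   for strand-agnostic matching).
#' @param per_intron apply the minimum-overlap rule per intron instead of
#'   to the summed intronic overlap.
#' @return data.frame: read_id, cell, umi, gene (NA if unassigned or
#'   ambiguous), exon_bp, intron_bp, intronic, spliced_call.
#' @export
classify_alignments <- function(blocks, index, strand_aware = TRUE,
                                per_intron = FALSE) {
  stopifnot(inherits(index, "region_index"))
  cutoff <- index$min_intron_len
  gene_ids <- names(index$genes)
  n <- nrow(blocks)
  gene <- rep(NA_character_, n)
  exon_bp <- intron_bp <- integer(n)
  for (r in seq_len(n)) {
    bl <- parse_blocks(blocks$blocks[r])
    best_gene <- NA_character_; best_bp <- 0L; tie <- FALSE
    best_ex <- 0L; best_in <- 0L
    for (gid in gene_ids) {
      g <- index$genes[[gid]]
      if (g$chrom != blocks$chrom[r]) next
      if (strand_aware && !is.na(blocks$strand[r]) &&
          blocks$strand[r] %in% c("+", "-") && g$strand != blocks$strand[r])
        next
      ebp <- ibp <- 0L
      ibp_max <- 0L
      for (k in seq_len(nrow(bl))) {
        if (nrow(g$exons))
          ebp <- ebp + sum(overlap_bp(bl[k, 1], bl[k, 2],
                                      g$exons[, 1], g$exons[, 2]))
        if (nrow(g$introns)) {
          ov <- overlap_bp(bl[k, 1], bl[k, 2],
                           g$introns[, 1], g$introns[, 2])
          ibp <- ibp + sum(ov)
          ibp_max <- max(ibp_max, ov)
        }
      }
      tot <- ebp + ibp
      if (tot > best_bp) {
        best_bp <- tot; best_gene <- gid; tie <- FALSE
        best_ex <- ebp
        best_in <- if (per_intron) ibp_max else ibp
      } else if (tot == best_bp && tot > 0) tie <- TRUE
    }
    if (!tie && best_bp > 0) {
      gene[r] <- best_gene
      exon_bp[r] <- best_ex
      intron_bp[r] <- best_in
    }
  }
  intronic <- !is.na(gene) & intron_bp > cutoff
  data.frame(read_id = blocks$read_id, cell = blocks$cell,
             umi = blocks$umi, gene = gene,
             exon_bp = exon_bp, intron_bp = intron_bp,
             intronic = intronic,
             spliced_call = ifelse(is.na(gene), NA_character_,
                                   ifelse(intronic, "unspliced", "spliced")),
             stringsAsFactors = FALSE)
}

#' Accumulate cells-by-genes count matrices from classified reads
#'
#' Reads are collapsed to molecules by directional UMI correction within
#' each (cell, gene) group; each molecule then increments the spliced or
#' unspliced matrix (unspliced iff any of its reads carried qualifying
#' intronic sequence), the exon matrix if any read had exon overlap, and
#' the intron matrix if any read was intronic. Counts are invariant to
#' read order.
#'
#' @param classes output of \code{\link{classify_alignments}}.
#' @param cells optional character vector restricting the barcode set
#'   (e.g. from \code{\link{call_cells}}); other barcodes are tallied as
#'   background.
#' @return list of class \code{"count_matrices"} with sparse cells x
#'   genes matrices \code{exon}, \code{intron}, \code{spliced},
#'   \code{unspliced}, plus \code{n_background} and \code{n_unassigned}.
#' @export
accumulate_matrices <- function(classes, cells = NULL) {
  ok <- !is.na(classes$gene)
  n_unassigned <- sum(!ok)
  df <- classes[ok, ]
  n_background <- 0L
  if (!is.null(cells)) {
    bg <- !(df$cell %in% cells)
    n_background <- sum(bg)
    df <- df[!bg, ]
  }
  cell_ids <- if (is.null(cells)) sort(unique(df$cell)) else cells
  gene_ids <- sort(unique(df$gene))
  key <- paste(df$cell, df$gene, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  trip <- list(exon = NULL, intron = NULL, spliced = NULL, unspliced = NULL)
  rows <- character(0); cols <- character(0)
  ex <- intr <- sp <- un <- integer(0)
  for (k in names(groups)) {
    idx <- groups[[k]]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    cl <- umi_clusters(df$umi[idx])
    # map each read to its cluster representative (same directional pass)
    n_mol <- length(cl$umi)
    # per molecule flags: recompute membership by re-running assignment
    memb <- assign_to_clusters(df$umi[idx], cl$umi)
    mol_intronic <- vapply(seq_len(n_mol), function(m)
      any(df$intronic[idx][memb == m]), logical(1))
    mol_exonic <- vapply(seq_len(n_mol), function(m)
      any(df$exon_bp[idx][memb == m] > 0), logical(1))
    rows <- c(rows, parts[1]); cols <- c(cols, parts[2])
    ex <- c(ex, sum(mol_exonic))
    intr <- c(intr, sum(mol_intronic))
    un <- c(un, sum(mol_intronic))
    sp <- c(sp, n_mol - sum(mol_intronic))
  }
  mk <- function(vals) Matrix::sparseMatrix(
    i = match(rows, cell_ids), j = match(cols, gene_ids), x = vals,
    dims = c(length(cell_ids), length(gene_ids)),
    dimnames = list(cell_ids, gene_ids))
  structure(list(exon = mk(ex), intron = mk(intr), spliced = mk(sp),
                 unspliced = mk(un), n_background = n_background,
                 n_unassigned = n_unassigned),
            class = "count_matrices")
}

## Assign UMIs to the nearest cluster representative (Hamming <= 1,
## highest-count representative first), mirroring umi_clusters().
assign_to_clusters <- function(umis, reps) {
  vapply(umis, function(u) {
    d <- vapply(reps, function(r)
      if (nchar(r) == nchar(u)) sum(utf8ToInt(r) != utf8ToInt(u))
      else 2L, integer(1))
    j <- which(d <= 1L)
    if (length(j)) j[1] else which.min(d)
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.count_matrices <- function(x, ...) {
  cat(sprintf(
    "Count matrices: %d cells x %d genes; %d unassigned reads, %d background reads\n",
    nrow(x$exon), ncol(x$exon), x$n_unassigned, x$n_background))
  cat(sprintf("  molecules: %d spliced, %d unspliced\n",
              sum(x$spliced), sum(x$unspliced)))
  invisible(x)
}

#' Write / read aligned-read blocks as TSV
#'
#' The simplified exchange format for spliced alignments: one row per
#' read with its aligned genomic blocks as a comma-separated
#' "start-end" list (0-based half-open), so the quantifier can be used
#' without BAM input.
#'
#' @param blocks data.frame (read_id, cell, umi, chrom, strand, blocks).
#' @param path file path.
#' @return \code{read_blocks_tsv}: the data.frame; \code{write_blocks_tsv}:
#'   the path, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_blocks_tsv
#' @export
read_blocks_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Reduce a BAM file of spliced alignments to per-read blocks
#'
#' Requires the GenomicAlignments package; aligned blocks are derived
#' from the CIGAR string, and the cell label / UMI are taken from the CB
#' and UB tags.
#'
#' @param path BAM file.
#' @return blocks data.frame as accepted by
#'   \code{\link{classify_alignments}}.
#' @export
read_bam_blocks <- function(path) {
  if (!requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("read_bam_blocks requires the GenomicAlignments package")
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(tag = c("CB", "UB"),
                                          what = "qname"))
  bl <- GenomicAlignments::grglist(ga)
  blocks <- vapply(as.list(bl), function(gr)
    paste(sprintf("%d-%d", GenomicRanges::start(gr) - 1L,
                  GenomicRanges::end(gr)), collapse = ","), character(1))
  mc <- S4Vectors::mcols(ga)
  data.frame(read_id = mc$qname, cell = mc$CB, umi = mc$UB,
             chrom = as.character(GenomicAlignments::seqnames(ga)),
             strand = as.character(GenomicAlignments::strand(ga)),
             blocks = blocks, stringsAsFactors = FALSE)
}
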