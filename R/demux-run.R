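#' Demultiplexing configuration
#'
#' Thresholds of the two-round demultiplexer. Two calibrated presets are
#' provided: \code{"conservative"} (the default two-round operating
#' point, which only accepts high-confidence labels and relies on the
#' second round to rescue reads with displaced or defective linkers) and
#' \code{"optimized"} (the single-round operating point with a relaxed
#' distance cap, trading a little precision for sensitivity). Both were
#' calibrated on simulated error-injected reads against the validated
#' operating region (roughly 70 percent sensitivity at a false-positive
#' rate of a few percent).
#'
#' A read is assigned iff its full-label edit distance is at most
#' \code{max_dist} and its margin (extra edit cost of the best competing
#' label; ties give margin 0) is at least 2, or the margin is exactly 1
#' and the distance is at most the stricter \code{max_dist_low_margin}.
#'
#' @param mode preset name.
#' @param trim_len reads are trimmed to this many bases (from the
#'   oriented 5' end) before round 1; barcodes sit at theoretical
#'   positions inside this window.
#' @param max_dist maximum full-label edit distance (anchor + three
#'   barcodes + linkers) for any assignment.
#' @param max_dist_low_margin maximum distance when the margin is only 1.
#' @param slot_pad extra bases allowed on each side of a located barcode
#'   slot when prescreening the pool against it.
#' @param strand_run_len minimum homopolymer run length calling
#'   oligo-dT/dA strand evidence.
#' @param second_round run the rescue round on reads unassigned in
#'   round 1.
#' @param max_bc_edits round 2: maximum edits tolerated per barcode.
#' @param gap_window round 2: allowed deviation (bp) of inter-barcode
#'   gaps from the linker lengths.
#' @param hit_margin round 2: a barcode hit is used only if the
#'   second-best barcode at the same locus is at least this many edits
#'   worse (ambiguous loci are skipped).
#' @return list of class \code{"demux_config"}.
#' @export
demux_config <- function(mode = c("conservative", "optimized"),
                         trim_len = 300L,
                         max_dist = 12L, max_dist_low_margin = NULL,
                         slot_pad = 1L,
                         strand_run_len = 6L,
                         second_round = NULL,
                         max_bc_edits = 1L, gap_window = 5L,
                         hit_margin = 2L) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    conservative = list(max_dist_low_margin = 7L, second_round = TRUE),
    optimized    = list(max_dist_low_margin = 5L, second_round = FALSE))
  if (is.null(max_dist_low_margin))
    max_dist_low_margin <- defaults$max_dist_low_margin
  if (is.null(second_round)) second_round <- defaults$second_round
  structure(list(mode = mode, trim_len = as.integer(trim_len),
                 max_dist = as.integer(max_dist),
                 max_dist_low_margin = as.integer(max_dist_low_margin),
                 slot_pad = as.integer(slot_pad),
                 strand_run_len = as.integer(strand_run_len),
                 second_round = second_round,
                 max_bc_edits = as.integer(max_bc_edits),
                 gap_window = as.integer(gap_window),
                 hit_margin = as.integer(hit_margin)),
            class = "demux_config")
}

#' Classify read strand from oligo-dT / oligo-dA evidence
#'
#' A forward read carries the bead oligo at its 5' end, so a poly-T run
#' (the oligo-dT) appears within the expected 5' window; a reverse read
#' is the reverse complement, so a poly-A run appears near its 3' end.
#'
#' @param reads character vector.
#' @param run_len minimum run length counted as evidence.
#' @param window how far (bp) from the read end to search; default
#'   covers the library prefix.
#' @return character vector: "forward", "reverse" or "none".
#' @export
detect_strand <- function(reads, run_len = 6, window = 130) {
  vapply(reads, function(rd) {
    L <- nchar(rd)
    w <- min(window, L)
    t_run <- cpp_longest_run(rd, "T", 0L, as.integer(w - 1))
    a_run <- cpp_longest_run(rd, "A", as.integer(L - w), as.integer(L - 1))
    if (t_run >= run_len && t_run >= a_run) "forward"
    else if (a_run >= run_len) "reverse"
    else "none"
  }, character(1), USE.NAMES = FALSE)
}

#' Two-round demultiplexing of barcoded long reads
#'
#' Round 1: each read is strand-resolved (reverse reads are
#' reverse-complemented), trimmed to \code{trim_len} bases, and its three
#' barcode slots are aligned at their theoretical offsets against the
#' whole pool by banded semi-global edit-distance alignment; the
#' best-scoring composed label is assigned iff its score and its margin
#' over the second-best label pass the thresholds (ties are left
#' unassigned). The UMI is read off the end of the third barcode's
#' alignment.
#'
#' Round 2 (rescue): for reads left unassigned, the three pools are
#' aligned independently against the full read; a read is rescued iff
#' one barcode from each pool is found, in order, with inter-barcode
#' gaps within \code{gap_window} of the linker lengths.
#'
#' @param reads character vector (named by read id if available).
#' @param reference a \code{\link{compose_reference}} object.
#' @param config a \code{\link{demux_config}}.
#' @return data.frame of class \code{"demux_assignments"}: read_id, b1,
#'   b2, b3 (NA when unassigned), cell_label, umi, strand, score, round.
#' @export
demux_reads <- function(reads, reference, config = demux_config()) {
  stopifnot(inherits(reference, "cell_label_reference"),
            inherits(config, "demux_config"))
  if (reference$n_labels == 0) stop("empty reference")
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  strand <- detect_strand(reads, run_len = config$strand_run_len,
                          window = reference$ref_len + 40)
  oriented <- ifelse(strand == "reverse", revcomp(reads), reads)
  trimmed <- substr(oriented, 1L, config$trim_len)

  out <- data.frame(read_id = ids, b1 = NA_integer_, b2 = NA_integer_,
                    b3 = NA_integer_, cell_label = NA_character_,
                    umi = NA_character_, strand = strand,
                    score = NA_real_, round = NA_integer_,
                    stringsAsFactors = FALSE)

  cand <- which(strand != "none")
  if (length(cand)) {
    pools <- list(reference$pools$bc1, reference$pools$bc2,
                  reference$pools$bc3)
    bl <- as.integer(reference$bc_len)
    scaffold <- paste0(reference$anchor, strrep("N", bl),
                       reference$linker1, strrep("N", bl),
                       reference$linker2, strrep("N", bl))
    slot_start <- as.integer(reference$offsets[c("bc1", "bc2", "bc3")])
    m <- cpp_demux_round1(trimmed[cand], pools, scaffold,
                          slot_start, slot_start + bl, config$slot_pad)
    core_len <- nchar(scaffold)
    d <- m[, "label_dist"]
    score <- core_len - d
    ok <- !is.na(d) & d <= config$max_dist &
      (m[, "margin"] >= 2L |
         (m[, "margin"] >= 1L & d <= config$max_dist_low_margin))
    hit <- cand[ok]
    out$b1[hit] <- m[ok, "b1"]; out$b2[hit] <- m[ok, "b2"]
    out$b3[hit] <- m[ok, "b3"]
    out$score[hit] <- score[ok]
    out$round[hit] <- 1L
    us <- m[ok, "umi_start"]
    out$umi[hit] <- ifelse(us > 0,
                           substr(oriented[hit], us, us + reference$umi_len - 1L),
                           NA_character_)
    # reads whose label structure aligned inside the trim window but
    # whose barcodes were rejected as ambiguous are final round-1
    # decisions; only structurally unaligned reads may be rescued
    aligned_r1 <- rep(FALSE, n)
    aligned_r1[cand] <- !is.na(d) & d <= config$max_dist
  } else aligned_r1 <- rep(FALSE, n)

  if (config$second_round) {
    todo <- which(is.na(out$round) & !aligned_r1)
    if (length(todo)) {
      res <- rescue_round2(oriented[todo], strand[todo], reads[todo],
                           reference, config)
      got <- !is.na(res$b1)
      for (col in c("b1", "b2", "b3", "score", "umi"))
        out[[col]][todo[got]] <- res[[col]][got]
      out$round[todo[got]] <- 2L
      fix <- todo[got][out$strand[todo[got]] == "none"]
      out$strand[fix] <- res$strand[got][out$strand[todo[got]] == "none"]
    }
  }

  asg <- !is.na(out$b1)
  out$cell_label[asg] <- paste(out$b1[asg], out$b2[asg], out$b3[asg],
                               sep = "_")
  attr(out, "config") <- config
  class(out) <- c("demux_assignments", "data.frame")
  out
}

## Round-2 kernel wrapper: scans both orientations for strand-unknown
## reads; the kernel enforces the order/gap constraints.
rescue_round2 <- function(oriented, strand, raw, reference, config) {
  pools <- list(reference$pools$bc1, reference$pools$bc2,
                reference$pools$bc3)
  l1 <- nchar(reference$linker1); l2 <- nchar(reference$linker2)
  bl <- as.integer(reference$bc_len)
  scaffold <- paste0(reference$anchor, strrep("N", bl),
                     reference$linker1, strrep("N", bl),
                     reference$linker2, strrep("N", bl))
  slot_start <- as.integer(reference$offsets[c("bc1", "bc2", "bc3")])
  m <- cpp_demux_round2(oriented, pools, config$max_bc_edits,
                        l1, l2, config$gap_window, config$hit_margin,
                        scaffold, slot_start, slot_start + bl)
  ok <- !is.na(m[, "b1"]) & m[, "label_dist"] <= config$max_dist
  use_rev <- rep(FALSE, length(oriented))
  unk <- which(strand == "none" & !ok)
  if (length(unk)) {
    rc <- revcomp(raw[unk])
    mr <- cpp_demux_round2(rc, pools, config$max_bc_edits,
                           l1, l2, config$gap_window, config$hit_margin,
                           scaffold, slot_start, slot_start + bl)
    okr <- !is.na(mr[, "b1"]) & mr[, "label_dist"] <= config$max_dist
    m[unk[okr], ] <- mr[okr, , drop = FALSE]
    oriented[unk[okr]] <- rc[okr]
    ok[unk[okr]] <- TRUE
    use_rev[unk[okr]] <- TRUE
  }
  score <- 3L * reference$bc_len - m[, "dist"]
  umi_start <- m[, "umi_start"]
  umi <- ifelse(ok & !is.na(umi_start) & umi_start > 0,
                substr(oriented, umi_start,
                       umi_start + reference$umi_len - 1L),
                NA_character_)
  data.frame(b1 = ifelse(ok, m[, "b1"], NA_integer_),
             b2 = ifelse(ok, m[, "b2"], NA_integer_),
             b3 = ifelse(ok, m[, "b3"], NA_integer_),
             score = ifelse(ok, score, NA_real_),
             umi = umi,
             strand = ifelse(use_rev, "reverse",
                             ifelse(ok, "forward", "none")),
             stringsAsFactors = FALSE)
}

#' @export
print.demux_assignments <- function(x, ...) {
  n <- nrow(x)
  a <- sum(!is.na(x$cell_label))
  cat(sprintf("Demultiplexing: %d reads, %d assigned (%.1f%%)\n",
              n, a, 100 * a / n))
  if (a) {
    r1 <- sum(x$round == 1L, na.rm = TRUE)
    cat(sprintf("  round 1: %d (%.1f%%), round 2 rescue: %d (%.1f%%)\n",
                r1, 100 * r1 / n, a - r1, 100 * (a - r1) / n))
  }
  invisible(x)
}

#' Confusion metrics of a demultiplexing run against ground truth
#'
#' TP = assigned to the true label; FP = assigned to a wrong label (or
#' any label, for a read that truly carries none); FN = truly barcoded
#' but unassigned. TPR and FNR are fractions of truly barcoded reads;
#' FPR is the fraction of all reads assigned to a wrong label;
#' precision = TP / (TP + FP); demux_rate = assigned / total.
#'
#' @param assignments a \code{\link{demux_reads}} result.
#' @param truth data.frame with read_id, b1, b2, b3 (NA for reads without
#'   a label).
#' @return list of class \code{"demux_metrics"}.
#' @export
evaluate_demux <- function(assignments, truth) {
  if (!all(assignments$read_id %in% truth$read_id))
    stop("truth does not cover all reads")
  truth <- truth[match(assignments$read_id, truth$read_id), ]
  assigned <- !is.na(assignments$b1)
  barcoded <- !is.na(truth$b1)
  correct <- assigned & barcoded &
    assignments$b1 == truth$b1 & assignments$b2 == truth$b2 &
    assignments$b3 == truth$b3
  tp <- sum(correct)
  fp <- sum(assigned & !correct)
  fn <- sum(barcoded & !assigned)
  n <- nrow(assignments)
  structure(list(
    tp = tp, fp = fp, fn = fn, n_reads = n, n_barcoded = sum(barcoded),
    tpr = tp / sum(barcoded),
    fpr = fp / n,
    fnr = fn / sum(barcoded),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    demux_rate = sum(assigned) / n),
    class = "demux_metrics")
}

#' @export
print.demux_metrics <- function(x, ...) {
  cat(sprintf(
    "Demux metrics on %d reads (%d truly barcoded):\n", x$n_reads,
    x$n_barcoded))
  cat(sprintf(
    "  TPR %.1f%%  FPR %.1f%%  FNR %.1f%%  precision %.3f  demux rate %.1f%%\n",
    100 * x$tpr, 100 * x$fpr, 100 * x$fnr, x$precision,
    100 * x$demux_rate))
  invisible(x)
}

#' Collapse reads to molecules by directional UMI correction
#'
#' Within each (cell label, gene) group, UMIs within Hamming distance 1
#' are merged into the most frequent representative (directional merge:
#' the higher-count UMI absorbs the lower); the molecule count of the
#' group is the number of UMI clusters.
#'
#' @param assignments data.frame with columns \code{cell_label},
#'   \code{umi} and (optionally) \code{gene}; rows with missing UMIs are
#'   dropped with a warning.
#' @return data.frame with one row per molecule: cell_label, gene, umi
#'   (cluster representative), n_reads.
#' @export
correct_umis <- function(assignments) {
  df <- as.data.frame(assignments)
  if (!"gene" %in% names(df)) df$gene <- "NA"
  keep <- !is.na(df$umi) & !is.na(df$cell_label)
  if (any(!keep))
    warning(sum(!keep), " records without UMI or label excluded")
  df <- df[keep, c("cell_label", "gene", "umi")]
  if (!nrow(df))
    return(data.frame(cell_label = character(0), gene = character(0),
                      umi = character(0), n_reads = integer(0)))
  key <- paste(df$cell_label, df$gene, sep = "\r")
  res <- lapply(split(df$umi, key), umi_clusters)
  out <- do.call(rbind, Map(function(k, cl) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(cell_label = parts[1], gene = parts[2],
               umi = cl$umi, n_reads = cl$n,
               stringsAsFactors = FALSE)
  }, names(res), res))
  rownames(out) <- NULL
  out
}

## Directional single-linkage at Hamming distance 1 within one group.
umi_clusters <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  reps <- character(0); counts <- integer(0)
  for (k in seq_along(tab)) {
    u <- names(tab)[k]; cnt <- as.integer(tab[k])
    merged <- FALSE
    if (length(reps)) {
      same_len <- nchar(reps) == nchar(u)
      if (any(same_len)) {
        d <- vapply(reps[same_len], function(r)
          sum(utf8ToInt(r) != utf8ToInt(u)), integer(1))
        j <- which(same_len)[which(d <= 1L)[1]]
        if (!is.na(j)) {
          counts[j] <- counts[j] + cnt
          merged <- TRUE
        }
      }
    }
    if (!merged) { reps <- c(reps, u); counts <- c(counts, cnt) }
  }
  list(umi = reps, n = counts)
}
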