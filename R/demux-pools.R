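## Default library architecture of the composed cell label. The bead
## oligo reads, 5' to 3': anchor (primer binding site), barcode 1,
## linker 1 (12 bp), barcode 2, linker 2 (13 bp), barcode 3, an 8 bp UMI
## and a 20 bp oligo-dT, followed by the cDNA. Three 9 bp barcodes plus
## the two linkers give the 52 bp cell-label segment, and the composed
## reference (anchor + label + UMI + oligo-dT) is 98 bases.
DEFAULT_ANCHOR  <- "ACGTAACGGATCAGTCCA"      # 18 bp
DEFAULT_LINKER1 <- "ACTGGCCTGCGA"            # 12 bp
DEFAULT_LINKER2 <- "GGTAGCGGTGACA"           # 13 bp
DEFAULT_UMI_LEN <- 8L
DEFAULT_DT_LEN  <- 20L

#' Generate three pools of well barcodes with a minimum edit distance
#'
#' Rejection-samples \code{n} barcodes of the given length for each of
#' the three label positions such that every pair of barcodes, within and
#' across pools, is at least \code{min_dist} Levenshtein edits apart and
#' at least \code{min_hamming} substitutions apart. The defaults
#' reproduce the vendor pool geometry (minimum Hamming distance 4,
#' minimum Levenshtein distance 2 across three pools of 96), which is
#' what lets the composed labels survive an error-prone platform.
#' Three pools of 96 label up to 96^3 wells.
#'
#' @param n barcodes per pool (default 96).
#' @param length barcode length in bp (default 9).
#' @param min_dist minimum pairwise Levenshtein distance (default 2;
#'   larger values are safer on error-prone reads but harder to satisfy).
#' @param min_hamming minimum pairwise Hamming distance (default 4).
#' @param seed integer seed.
#' @param max_tries rejection-sampling retry cap per barcode.
#' @return list of class \code{"barcode_pools"} with elements
#'   \code{bc1}, \code{bc2}, \code{bc3} (character vectors).
#' @export
build_barcode_pools <- function(n = 96, length = 9, min_dist = 2,
                                min_hamming = 4, seed = 1L,
                                max_tries = 20000L) {
  if (n < 1 || length < 1) stop("n and length must be >= 1")
  local_rng(seed)
  accepted <- character(0)
  acc_chars <- NULL
  total <- 3L * n
  tries <- 0L
  while (base::length(accepted) < total) {
    cand <- random_dna(1, length)
    ok <- TRUE
    if (base::length(accepted)) {
      cc <- strsplit(cand, "", fixed = TRUE)[[1]]
      ham <- rowSums(acc_chars != matrix(cc, nrow(acc_chars), length,
                                         byrow = TRUE))
      ok <- min(ham) >= min_hamming &&
        min(vapply(accepted, cpp_levenshtein, integer(1), b = cand)) >=
          min_dist
    }
    if (ok) {
      acc_chars <- rbind(acc_chars, strsplit(cand, "", fixed = TRUE)[[1]])
      accepted <- c(accepted, cand)
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not satisfy the minimum-distance constraint; ",
             "lower min_dist or barcode count")
    }
  }
  structure(list(bc1 = accepted[seq_len(n)],
                 bc2 = accepted[n + seq_len(n)],
                 bc3 = accepted[2L * n + seq_len(n)]),
            class = "barcode_pools")
}

#' Load barcode pools from whitelist TSV files
#'
#' @param paths character vector of three files (one barcode per line),
#'   or one file with three columns (bc1, bc2, bc3 pools).
#' @return a \code{"barcode_pools"} object.
#' @export
read_barcode_pools <- function(paths) {
  if (length(paths) == 3) {
    pools <- lapply(paths, function(p) readLines(p))
  } else if (length(paths) == 1) {
    tab <- utils::read.table(paths, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 3) stop("single-file whitelist needs three columns")
    pools <- list(tab[[1]], tab[[2]], tab[[3]])
  } else stop("supply one three-column file or three files")
  pools <- lapply(pools, function(x) toupper(trimws(x[nzchar(trimws(x))])))
  bad <- unlist(lapply(pools, function(x) grepl("[^ACGT]", x)))
  if (any(bad)) stop("whitelist contains non-ACGT characters")
  structure(list(bc1 = pools[[1]], bc2 = pools[[2]], bc3 = pools[[3]]),
            class = "barcode_pools")
}

#' @export
print.barcode_pools <- function(x, ...) {
  cat(sprintf("Barcode pools: %d + %d + %d barcodes (%d bp); %s labels\n",
              length(x$bc1), length(x$bc2), length(x$bc3),
              nchar(x$bc1[1]),
              format(length(x$bc1) * length(x$bc2) * length(x$bc3),
                     big.mark = ",")))
  invisible(x)
}

#' Compose the cell-label reference architecture
#'
#' Describes the composed reference against which reads are
#' demultiplexed: anchor + barcode1 + linker1 + barcode2 + linker2 +
#' barcode3 + UMI (encoded as Ns) + oligo-dT, padded with Ns at both ends
#' so the reference is longer than the trimmed read window. With the
#' defaults the cell-label segment (three 9 bp barcodes + 12 bp and
#' 13 bp linkers) is 52 bp and the unpadded reference is 98 bases.
#'
#' The full label space is the Cartesian product of the pools; composed
#' label sequences are materialized lazily via \code{label_sequence}
#' because the 96^3 product is large.
#'
#' @param pools a \code{"barcode_pools"} object.
#' @param linker1,linker2 linker sequences between the barcodes.
#' @param anchor 5' anchor (binding-site) sequence.
#' @param umi_len,oligo_dt_len UMI and oligo-dT lengths (bp).
#' @param n_pad number of Ns appended at each end.
#' @return list of class \code{"cell_label_reference"} with the pools,
#'   the fixed segments, per-segment offsets (0-based) and total lengths.
#' @export
compose_reference <- function(pools,
                              linker1 = DEFAULT_LINKER1,
                              linker2 = DEFAULT_LINKER2,
                              anchor = DEFAULT_ANCHOR,
                              umi_len = DEFAULT_UMI_LEN,
                              oligo_dt_len = DEFAULT_DT_LEN,
                              n_pad = 10L) {
  stopifnot(inherits(pools, "barcode_pools"))
  if (!nzchar(linker1) || !nzchar(linker2)) stop("linkers must be nonempty")
  if (umi_len < 0 || oligo_dt_len < 0) stop("lengths must be >= 0")
  bc_len <- unique(nchar(c(pools$bc1, pools$bc2, pools$bc3)))
  if (length(bc_len) != 1) stop("all barcodes must have equal length")
  off_bc1 <- nchar(anchor)
  off_l1  <- off_bc1 + bc_len
  off_bc2 <- off_l1 + nchar(linker1)
  off_l2  <- off_bc2 + bc_len
  off_bc3 <- off_l2 + nchar(linker2)
  off_umi <- off_bc3 + bc_len
  off_dt  <- off_umi + umi_len
  ref_len <- off_dt + oligo_dt_len
  structure(list(pools = pools, anchor = anchor,
                 linker1 = linker1, linker2 = linker2,
                 bc_len = bc_len, umi_len = umi_len,
                 oligo_dt_len = oligo_dt_len, n_pad = as.integer(n_pad),
                 offsets = c(bc1 = off_bc1, linker1 = off_l1,
                             bc2 = off_bc2, linker2 = off_l2,
                             bc3 = off_bc3, umi = off_umi, oligo_dt = off_dt),
                 label_len = 3L * bc_len + nchar(linker1) + nchar(linker2),
                 ref_len = ref_len,
                 n_labels = length(pools$bc1) * length(pools$bc2) *
                   length(pools$bc3)),
            class = "cell_label_reference")
}

#' @export
print.cell_label_reference <- function(x, ...) {
  cat(sprintf(
    "Cell-label reference: %d labels; label segment %d bp; reference %d bases (+%d N pad per end)\n",
    x$n_labels, x$label_len, x$ref_len, x$n_pad))
  invisible(x)
}

#' Materialize the composed sequence of one cell label
#'
#' @param reference a \code{\link{compose_reference}} object.
#' @param b1,b2,b3 1-based barcode indices into the three pools.
#' @param umi UMI sequence (default a run of Ns, as in the reference).
#' @param pad include the N padding at both ends.
#' @return the composed label sequence.
#' @export
label_sequence <- function(reference, b1, b2, b3,
                           umi = strrep("N", reference$umi_len),
                           pad = FALSE) {
  stopifnot(inherits(reference, "cell_label_reference"))
  core <- paste0(reference$anchor,
                 reference$pools$bc1[b1], reference$linker1,
                 reference$pools$bc2[b2], reference$linker2,
                 reference$pools$bc3[b3], umi,
                 strrep("T", reference$oligo_dt_len))
  if (pad) paste0(strrep("N", reference$n_pad), core,
                  strrep("N", reference$n_pad)) else core
}
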