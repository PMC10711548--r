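#' Sequencing error model
#'
#' Independent per-base substitution, insertion and deletion
#' probabilities, the three-rate i.i.d. error model used to emulate
#' error-prone long reads.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities; their sum
#'   must not exceed 1.
#' @return list of class \code{"error_model"}.
#' @export
error_model <- function(sub_rate = 0.06, ins_rate = 0.02, del_rate = 0.02) {
  r <- c(sub_rate, ins_rate, del_rate)
  if (any(r < 0) || any(r > 1) || sum(r) > 1)
    stop("rates must lie in [0,1] with sub+ins+del <= 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate), class = "error_model")
}

#' Inject sequencing errors into DNA sequences
#'
#' Applies the three-rate i.i.d. error model to each base: deletion with
#' \code{del_rate}; otherwise substitution with \code{sub_rate}, drawn
#' uniformly from the three alternative bases; and, independently, a
#' uniform random base inserted after each position with \code{ins_rate}.
#'
#' @param sequences character vector over A/C/G/T.
#' @param model an \code{\link{error_model}}.
#' @param seed integer seed (optional; if NULL the current RNG stream is
#'   used, so callers that seeded already stay reproducible).
#' @return character vector of mutated sequences.
#' @export
#' @examples
#' inject_errors("ACGTACGT", error_model(0, 0, 0))   # identity
inject_errors <- function(sequences, model = error_model(), seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  if (any(grepl("[^ACGT]", sequences))) stop("sequences must be over ACGT")
  if (!is.null(seed)) local_rng(seed)
  chars <- strsplit(sequences, "", fixed = TRUE)
  lens <- lengths(chars)
  all_chars <- unlist(chars, use.names = FALSE)
  n <- length(all_chars)
  if (n == 0) return(sequences)

  u <- stats::runif(n)
  deleted <- u < model$del_rate
  substituted <- !deleted & u < model$del_rate + model$sub_rate
  if (any(substituted)) {
    # uniform over the three alternatives
    shift <- sample.int(3, sum(substituted), replace = TRUE)
    cur <- match(all_chars[substituted], DNA)
    all_chars[substituted] <- DNA[((cur - 1 + shift) %% 4) + 1]
  }
  inserted <- stats::runif(n) < model$ins_rate
  ins_base <- character(n)
  if (any(inserted))
    ins_base[inserted] <- sample(DNA, sum(inserted), replace = TRUE)

  out_chars <- ifelse(deleted, "", all_chars)
  out_chars <- paste0(out_chars, ins_base)
  grp <- rep.int(seq_along(lens), lens)
  out <- vapply(split(out_chars, grp), paste, character(1), collapse = "")
  names(out) <- NULL
  out
}

#' Simulate barcoded long reads for demultiplexer validation
#'
#' Emits reads with the full library structure (anchor + barcode1 +
#' linker1 + barcode2 + linker2 + barcode3 + UMI + oligo-dT + reverse-
#' complemented cDNA), on the forward or reverse strand with the stated
#' probabilities, plus a fraction of structureless (random) reads
#' emulating library debris; sequencing errors are injected per the
#' error model. A complete per-read truth table is returned.
#'
#' @param reference a \code{\link{compose_reference}} object.
#' @param n_reads number of reads.
#' @param cells data.frame with columns b1, b2, b3 (1-based barcode
#'   indices): the true cell labels to draw from. If NULL, labels are
#'   drawn uniformly over the whole pool space.
#' @param n_cells when \code{cells} is NULL, how many distinct labels to
#'   draw.
#' @param model an \code{\link{error_model}}; rates apply to the whole
#'   read, including the barcode region.
#' @param strand_probs probabilities of (forward, reverse, structureless)
#'   reads; defaults approximate the observed library composition
#'   (about 47\% forward, 40\% reverse, the remainder without library
#'   structure).
#' @param cdna_len_range uniform range of cDNA insert lengths (bp).
#' @param junk_prob fraction of barcoded reads carrying extraneous
#'   leading sequence (adapter remnants / chimeric starts) before the
#'   anchor, which can push the cell label outside a fixed trim window.
#' @param junk_len_range uniform range of the leading junk length (bp).
#' @param seed integer seed.
#' @return list of class \code{"simulated_reads"} with \code{reads}
#'   (character vector), \code{truth} (data.frame: read_id, b1, b2, b3,
#'   umi, strand; NA barcodes for structureless reads) and the reference.
#' @export
simulate_barcoded_reads <- function(reference, n_reads,
                                    cells = NULL, n_cells = 500,
                                    model = error_model(),
                                    strand_probs = c(forward = 0.47,
                                                     reverse = 0.40,
                                                     none = 0.13),
                                    cdna_len_range = c(150, 600),
                                    junk_prob = 0.1,
                                    junk_len_range = c(0, 400),
                                    seed = 1L) {
  stopifnot(inherits(reference, "cell_label_reference"))
  if (n_reads < 1) stop("n_reads must be >= 1")
  pools <- reference$pools
  if (length(pools$bc1) == 0) stop("empty whitelist")
  local_rng(seed)
  if (is.null(cells)) {
    cells <- data.frame(
      b1 = sample.int(length(pools$bc1), n_cells, replace = TRUE),
      b2 = sample.int(length(pools$bc2), n_cells, replace = TRUE),
      b3 = sample.int(length(pools$bc3), n_cells, replace = TRUE))
    cells <- unique(cells)
  }
  strand_probs <- strand_probs / sum(strand_probs)
  strand <- sample(c("forward", "reverse", "none"), n_reads,
                   replace = TRUE, prob = strand_probs)
  pick <- sample.int(nrow(cells), n_reads, replace = TRUE)
  umi <- random_dna(n_reads, reference$umi_len)
  cdna_len <- sample(seq(cdna_len_range[1], cdna_len_range[2]),
                     n_reads, replace = TRUE)

  reads <- character(n_reads)
  structureless <- strand == "none"
  junk <- !structureless & stats::runif(n_reads) < junk_prob
  junk_len <- sample(seq(junk_len_range[1], junk_len_range[2]),
                     n_reads, replace = TRUE)
  for (r in which(!structureless)) {
    core <- paste0(
      if (junk[r]) random_dna(1, junk_len[r]) else "",
      label_sequence(reference, cells$b1[pick[r]], cells$b2[pick[r]],
                     cells$b3[pick[r]], umi = umi[r]),
      revcomp(random_dna(1, cdna_len[r])))
    reads[r] <- core
  }
  if (any(structureless)) {
    base_len <- reference$ref_len
    for (r in which(structureless))
      reads[r] <- random_dna(1, base_len + cdna_len[r])
  }
  reads <- inject_errors(reads, model)
  rev_idx <- strand == "reverse"
  reads[rev_idx] <- revcomp(reads[rev_idx])

  truth <- data.frame(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    b1 = ifelse(structureless, NA_integer_, cells$b1[pick]),
    b2 = ifelse(structureless, NA_integer_, cells$b2[pick]),
    b3 = ifelse(structureless, NA_integer_, cells$b3[pick]),
    umi = ifelse(structureless, NA_character_, umi),
    strand = strand,
    stringsAsFactors = FALSE)
  names(reads) <- truth$read_id
  structure(list(reads = reads, truth = truth, reference = reference,
                 model = model, seed = seed),
            class = "simulated_reads")
}

#' Write reads to FASTQ
#'
#' Sanger-scaled qualities with a constant Q20 placeholder.
#'
#' @param reads named character vector of sequences.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  qual <- strrep("5", nchar(reads))  # '5' = Q20 in Sanger scaling
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file (uncompressed).
#' @return named character vector of sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ")
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  seqs <- toupper(lines[seq(2, length(lines), 4)])
  names(seqs) <- ids
  seqs
}
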