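DNA <- c("A", "C", "G", "T")

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA, len, replace = TRUE), collapse = ""), character(1))
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE))
}

#' Pairwise distance statistics of a barcode set
#'
#' Computes exact Levenshtein distances (full dynamic programme) over all
#' unordered pairs, and Hamming distances where both sequences have equal
#' length, and summarizes them. Long composed cell labels have larger
#' distances than their component barcodes, which is what makes them
#' demultiplexable on an error-prone platform.
#'
#' @param seqs character vector of >= 2 sequences.
#' @return list with \code{hamming_min}, \code{hamming_mean},
#'   \code{levenshtein_min}, \code{levenshtein_mean}.
#' @export
#' @examples
#' pool_distance_stats(c("AAA", "AAT", "TTT"))
pool_distance_stats <- function(seqs) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  lev <- cpp_lev_pairs(as.character(seqs))
  n <- length(seqs)
  lens <- nchar(seqs)
  ham <- c()
  if (length(unique(lens)) == 1) {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    idx <- utils::combn(n, 2)
    ham <- rowSums(m[idx[1, ], , drop = FALSE] != m[idx[2, ], , drop = FALSE])
  } else {
    # Hamming defined only for equal-length pairs
    idx <- utils::combn(n, 2)
    eq <- lens[idx[1, ]] == lens[idx[2, ]]
    if (any(eq)) {
      ham <- mapply(function(a, b) {
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      }, seqs[idx[1, eq]], seqs[idx[2, eq]])
    }
  }
  list(hamming_min = if (length(ham)) min(ham) else NA_real_,
       hamming_mean = if (length(ham)) mean(ham) else NA_real_,
       levenshtein_min = min(lev),
       levenshtein_mean = mean(lev))
}
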