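#' Write a count matrix as a matrix-market bundle
#'
#' The 10x-style exchange bundle: \code{matrix.mtx} (features x
#' barcodes, 1-based coordinate format), \code{barcodes.tsv},
#' \code{features.tsv} and a small \code{metadata.json} recording the
#' matrix kind.
#'
#' @param m cells x genes matrix (dense or sparse) with dimnames.
#' @param dir output directory (created if needed).
#' @param kind matrix kind recorded in the metadata (exon, intron,
#'   spliced, unspliced, velocity, ...).
#' @return invisibly, the directory.
#' @export
write_matrix_bundle <- function(m, dir, kind = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- Matrix::Matrix(t(as.matrix(m)), sparse = TRUE)
  sm <- methods::as(methods::as(sm, "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sm, file.path(dir, "matrix.mtx"))
  writeLines(colnames(m), file.path(dir, "features.tsv"))
  writeLines(rownames(m), file.path(dir, "barcodes.tsv"))
  jsonlite::write_json(list(kind = kind, n_cells = nrow(m),
                            n_genes = ncol(m)),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a matrix-market bundle
#'
#' @param dir directory written by \code{\link{write_matrix_bundle}}.
#' @return cells x genes sparse matrix with dimnames; the matrix kind is
#'   in attribute \code{"kind"}.
#' @export
read_matrix_bundle <- function(dir) {
  sm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  # readMM may pick a symmetric/pattern class; force a general numeric
  sm <- methods::as(sm, "generalMatrix")
  if (methods::is(sm, "nMatrix")) sm <- sm * 1
  features <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(sm) != length(features) || ncol(sm) != length(barcodes))
    stop("MTX dimensions do not match the barcode/feature files")
  out <- Matrix::t(sm)
  dimnames(out) <- list(barcodes, features)
  meta_path <- file.path(dir, "metadata.json")
  if (file.exists(meta_path))
    attr(out, "kind") <- jsonlite::read_json(meta_path)$kind
  out
}

#' Read gene models from a GTF file
#'
#' Exon features are parsed (via rtracklayer) and converted from the
#' 1-based inclusive GTF convention to the package's 0-based half-open
#' intervals; non-exon features are ignored.
#'
#' @param path GTF file.
#' @return a \code{"gene_annotation"}-compatible list with the exon
#'   data.frame (gene_id, transcript_id, chrom, strand, start, end).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  md <- as.data.frame(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id) ||
      anyNA(md$gene_id) || anyNA(md$transcript_id))
    stop("exon features must carry gene_id and transcript_id")
  ex <- data.frame(gene_id = md$gene_id,
                   transcript_id = md$transcript_id,
                   chrom = as.character(md$seqnames),
                   strand = as.character(md$strand),
                   start = md$start - 1L,   # to 0-based half-open
                   end = md$end,
                   stringsAsFactors = FALSE)
  structure(list(exons = ex, truth = NULL), class = "gene_annotation")
}

#' Read and write run configuration files
#'
#' Plain key=value files mirroring \code{\link{velocity_config}} and
#' \code{\link{demux_config}}; unknown keys are rejected so typos fail
#' loudly.
#'
#' @param path file path.
#' @param config named list of scalar values.
#' @return \code{read_run_config}: a named list with numeric values
#'   parsed; \code{write_run_config}: the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v) as.character(v)[1], character(1))
  writeLines(paste0(keys, "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  known <- c(names(formals(velocity_config)), names(formals(demux_config)),
             "seed", "n_grid", "sigma", "k", "n_neighbors",
             "min_intron_len")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- keys
  out
}

#' Write per-gene kinetics and velocity results
#'
#' Serializes a velocity fit: the per-gene kinetics as TSV and the
#' velocity and extrapolated matrices as matrix-market bundles.
#'
#' @param fit a \code{\link{region_velocity}} object.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_velocity_results <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$kinetics, file.path(dir, "kinetics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  v <- fit$velocity
  if (is.null(rownames(v)))
    dimnames(v) <- list(sprintf("cell%05d", seq_len(nrow(v))),
                        fit$kinetics$gene)
  e <- fit$extrapolated; dimnames(e) <- dimnames(v)
  write_matrix_bundle(v, file.path(dir, "velocity"), kind = "velocity")
  write_matrix_bundle(e, file.path(dir, "extrapolated"),
                      kind = "extrapolated")
  invisible(dir)
}
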