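#' Call cells from the barcode-rank curve
#'
#' Barcodes are ranked by total count; the knee (maximum negative
#' curvature) and inflection (minimum first derivative) of the smoothed
#' log-log rank curve are located. The ambient profile is estimated from
#' background barcodes (fewer than \code{background_genes} detected
#' genes, falling back to barcodes at or below the inflection if none
#' qualify); every non-background barcode is then tested against the
#' ambient multinomial with a Monte-Carlo deviance p-value and a
#' Benjamini-Hochberg correction at \code{fdr}. Barcodes at or above the
#' knee are always retained.
#'
#' @param counts cells x genes matrix (dense or sparse).
#' @param background_genes barcodes with fewer detected genes than this
#'   are treated as ambient background (default 20).
#' @param fdr false-discovery-rate threshold for the empty test
#'   (default 0.01).
#' @param mc_iter Monte-Carlo iterations per total-count bin.
#' @param n_bins number of total-count bins sharing a null distribution.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return list of class \code{"cell_calls"}: \code{cells} (called
#'   barcodes), \code{knee}, \code{inflection} (total counts at the
#'   landmarks), \code{stats} (per-barcode table), and summary stats
#'   (genes/cell, UMIs/cell, fraction of counts in cells).
#' @export
call_cells <- function(counts, background_genes = 20, fdr = 0.01,
                       mc_iter = 1000, n_bins = 20, seed = 1L) {
  m <- as.matrix(counts)
  totals <- rowSums(m)
  if (all(totals == 0)) stop("all-zero matrix")
  if (nrow(m) == 1) {
    warning("single barcode: knee undefined, returning it as a cell")
    return(structure(list(cells = rownames(m), knee = NA_real_,
                          inflection = NA_real_, stats = NULL,
                          summary = NULL), class = "cell_calls"))
  }
  local_rng(seed)
  ord <- order(totals, decreasing = TRUE)
  rk <- seq_along(ord)
  tt <- totals[ord]
  keep <- tt > 0
  lx <- log10(rk[keep]); ly <- log10(tt[keep])
  # collapse ties so the spline sees a function
  agg <- tapply(lx, ly, max)
  ux <- as.numeric(agg); uy <- as.numeric(names(agg))
  o <- order(ux)
  ux <- ux[o]; uy <- uy[o]
  knee <- inflection <- NA_real_
  if (length(ux) >= 4) {
    sp <- stats::smooth.spline(ux, uy, df = min(10, length(ux) - 1))
    grid <- seq(min(ux), max(ux), length.out = 200)
    d1 <- stats::predict(sp, grid, deriv = 1)$y
    d2 <- stats::predict(sp, grid, deriv = 2)$y
    curv <- d2 / (1 + d1^2)^1.5
    y_at <- stats::predict(sp, grid)$y
    infl_at <- which.min(d1)           # steepest point of the cliff
    inflection <- 10^y_at[infl_at]
    # the knee is the sharpest downward bend above the cliff (at a
    # smaller rank than the inflection)
    upper <- seq_len(max(infl_at - 1, 1))
    knee <- 10^y_at[upper[which.min(curv[upper])]]
  }

  genes_per_bc <- rowSums(m > 0)
  bg <- genes_per_bc < background_genes & totals > 0
  if (!any(bg)) bg <- totals <= inflection & totals > 0
  ambient <- colSums(m[bg, , drop = FALSE])
  if (sum(ambient) == 0) ambient <- colSums(m)
  p_amb <- (ambient + 1e-8) / sum(ambient + 1e-8)

  cand <- which(!bg & totals > 0)
  pval <- rep(NA_real_, nrow(m))
  if (length(cand)) {
    dev_stat <- function(x) -sum(x * log(p_amb))  # multinomial deviance core
    obs <- apply(m[cand, , drop = FALSE], 1, dev_stat)
    bins <- cut(rank(totals[cand], ties.method = "first"),
                breaks = min(n_bins, length(cand)), labels = FALSE)
    for (b in unique(bins)) {
      idx <- cand[bins == b]
      t_med <- stats::median(totals[idx])
      null <- replicate(mc_iter,
                        dev_stat(stats::rmultinom(1, t_med, p_amb)[, 1]))
      # scale observed stats to the bin's total so they are comparable
      sc <- obs[bins == b] * (t_med / totals[idx])
      pval[idx] <- (1 + vapply(sc, function(s) sum(null >= s),
                               numeric(1))) / (mc_iter + 1)
    }
  }
  padj <- rep(NA_real_, nrow(m))
  padj[cand] <- stats::p.adjust(pval[cand], method = "BH")
  called <- (!is.na(padj) & padj <= fdr) | (totals >= knee & totals > 0)
  bc <- rownames(m)
  if (is.null(bc)) bc <- sprintf("bc%06d", seq_len(nrow(m)))
  cells <- bc[called]
  stats_df <- data.frame(barcode = bc, total = totals,
                         genes = genes_per_bc, background = bg,
                         p_value = pval, fdr = padj, called = called,
                         stringsAsFactors = FALSE)
  summ <- list(
    n_cells = sum(called),
    mean_genes_per_cell = mean(genes_per_bc[called]),
    median_genes_per_cell = stats::median(genes_per_bc[called]),
    mean_umis_per_cell = mean(totals[called]),
    median_umis_per_cell = stats::median(totals[called]),
    fraction_counts_in_cells = sum(totals[called]) / sum(totals))
  structure(list(cells = cells, knee = knee, inflection = inflection,
                 stats = stats_df, summary = summ),
            class = "cell_calls")
}

#' @export
print.cell_calls <- function(x, ...) {
  cat(sprintf("Cell calling: %d cells (knee %.0f, inflection %.0f)\n",
              length(x$cells), x$knee, x$inflection))
  if (!is.null(x$summary))
    cat(sprintf(
      "  median UMIs/cell %.0f, median genes/cell %.0f, %.1f%% of counts in cells\n",
      x$summary$median_umis_per_cell, x$summary$median_genes_per_cell,
      100 * x$summary$fraction_counts_in_cells))
  invisible(x)
}
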