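#' Velocity estimation configuration
#'
#' @param fit_quantile extreme-quantile fraction used for the
#'   steady-state slope fit (default 0.05: cells in the top and bottom
#'   5 percent of exon expression).
#' @param min_corr minimum intron-exon (or unspliced-spliced) Pearson
#'   correlation for a gene to contribute to velocity (default 0.2).
#' @param min_slope minimum fitted slope (default 0.2).
#' @param k_cells kNN pooling size (default 10); 1 disables pooling.
#' @param delta_t extrapolation time step (default 1, in units of the
#'   splicing rate).
#' @param theta_cells which cells the intron-fraction estimator uses:
#'   \code{"top_quantile"} (cells above the 1 - fit_quantile quantile of
#'   total expression, a proxy for active transcription) or \code{"all"}.
#' @return list of class \code{"velocity_config"}.
#' @export
velocity_config <- function(fit_quantile = 0.05, min_corr = 0.2,
                            min_slope = 0.2, k_cells = 10, delta_t = 1,
                            theta_cells = c("top_quantile", "all")) {
  if (fit_quantile <= 0 || fit_quantile >= 0.5)
    stop("fit_quantile must be in (0, 0.5)")
  if (k_cells < 1) stop("k_cells must be >= 1")
  structure(list(fit_quantile = fit_quantile, min_corr = min_corr,
                 min_slope = min_slope, k_cells = as.integer(k_cells),
                 delta_t = delta_t,
                 theta_cells = match.arg(theta_cells)),
            class = "velocity_config")
}

#' Greedy balanced kNN pooling of count matrices
#'
#' Each cell's counts are replaced by the sum over itself and its k - 1
#' nearest neighbours in the given low-dimensional space. The balanced
#' variant caps how often any cell may serve as a neighbour (4 * k), so
#' dense regions do not dominate; neighbours over the cap are skipped in
#' favour of the next nearest.
#'
#' @param matrices a cells x genes matrix or list of such matrices
#'   (shared neighbourhood).
#' @param space cells x d numeric matrix (embedding or PCA scores).
#' @param k pool size (k = 1 returns the input).
#' @return pooled matrix or list of matrices.
#' @export
pool_knn <- function(matrices, space, k = 10) {
  single <- !is.list(matrices)
  mats <- if (single) list(matrices) else matrices
  n <- nrow(mats[[1]])
  if (k > n) stop("k must not exceed the number of cells")
  if (k == 1) return(if (single) mats[[1]] else mats)
  space <- as.matrix(space)
  d <- as.matrix(stats::dist(space))
  diag(d) <- Inf
  cap <- 4L * k
  usage <- integer(n)
  nb <- matrix(0L, n, k - 1)
  for (c in seq_len(n)) {
    ord <- order(d[c, ])
    picked <- integer(0)
    for (j in ord) {
      if (usage[j] >= cap) next
      picked <- c(picked, j)
      if (length(picked) == k - 1) break
    }
    if (length(picked) < k - 1)   # cap exhausted: fall back to nearest
      picked <- c(picked, setdiff(ord, picked)[seq_len(k - 1 - length(picked))])
    usage[picked] <- usage[picked] + 1L
    nb[c, ] <- picked
  }
  pool_one <- function(m) {
    m <- as.matrix(m)
    out <- m
    for (c in seq_len(n)) out[c, ] <- m[c, ] + colSums(m[nb[c, ], , drop = FALSE])
    out
  }
  res <- lapply(mats, pool_one)
  if (single) res[[1]] else res
}

#' Estimate the intron fraction of nascent transcription
#'
#' theta is the share of a gene's nascent output that is intronic; it is
#' estimated as the count ratio sum(i) / (sum(i) + sum(e)) over the
#' selected cells (by default the cells above the 1 - fit_quantile
#' quantile of total expression, a proxy for actively transcribing
#' cells), clamped away from the boundaries.
#'
#' @param e,i exon and intron count vectors across cells.
#' @param fit_quantile quantile used for the cell subset.
#' @param cells \code{"top_quantile"} or \code{"all"}.
#' @return theta estimate in (0, 1).
#' @export
estimate_theta <- function(e, i, fit_quantile = 0.05,
                           cells = c("top_quantile", "all")) {
  cells <- match.arg(cells)
  tot <- e + i
  if (sum(tot) == 0) stop("all-zero gene")
  sel <- if (cells == "top_quantile") {
    tot >= stats::quantile(tot, 1 - fit_quantile)
  } else rep(TRUE, length(e))
  th <- sum(i[sel]) / (sum(i[sel]) + sum(e[sel]))
  min(max(th, 1e-6), 1 - 1e-6)
}

#' Steady-state slope and degradation rate of one gene
#'
#' Cells in the top and bottom \code{fit_quantile} of exon expression
#' are selected (the robust extreme-quantile subset, close to the
#' steady state) and the zero-intercept least-squares slope of intron on
#' exon counts is fitted there. The degradation rate follows from the
#' steady-state relation gamma = (i/e) * (1 - theta) / theta.
#'
#' @param e,i exon and intron counts across cells.
#' @param theta_hat intron-fraction estimate.
#' @param fit_quantile extreme-quantile fraction.
#' @return list: slope_k, gamma_hat, corr_r (Pearson correlation of i
#'   and e across all cells), failed flag.
#' @export
fit_steady_state <- function(e, i, theta_hat, fit_quantile = 0.05) {
  if (stats::sd(e) == 0 || stats::sd(i) == 0)
    return(list(slope_k = NA_real_, gamma_hat = NA_real_,
                corr_r = NA_real_, failed = TRUE))
  lo <- stats::quantile(e, fit_quantile)
  hi <- stats::quantile(e, 1 - fit_quantile)
  sel <- e <= lo | e >= hi
  if (sum(e[sel]^2) == 0)
    return(list(slope_k = NA_real_, gamma_hat = NA_real_,
                corr_r = stats::cor(e, i), failed = TRUE))
  slope <- sum(e[sel] * i[sel]) / sum(e[sel]^2)
  list(slope_k = slope,
       gamma_hat = slope * (1 - theta_hat) / theta_hat,
       corr_r = stats::cor(e, i),
       failed = FALSE)
}

#' Filter genes for velocity estimation
#'
#' A gene contributes to velocity iff its intron-exon correlation and
#' fitted slope both reach their thresholds.
#'
#' @param kinetics per-gene kinetics data.frame (columns corr_r,
#'   slope_k).
#' @param min_corr,min_slope thresholds (defaults 0.2).
#' @return the kinetics data.frame with an updated passes_filter column.
#' @export
filter_genes <- function(kinetics, min_corr = 0.2, min_slope = 0.2) {
  kinetics$passes_filter <- !is.na(kinetics$slope_k) &
    !is.na(kinetics$corr_r) &
    kinetics$corr_r >= min_corr & kinetics$slope_k >= min_slope
  if (!any(kinetics$passes_filter))
    stop("no gene passes the correlation/slope filters")
  kinetics
}

## Shared engine behind region_velocity() and rna_velocity().
fit_velocity_engine <- function(x, y, config, estimate_theta_flag,
                                model, theta_known = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)))
  genes <- colnames(x)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(ncol(x)))
  n_genes <- ncol(x)
  theta <- slope <- gam <- corr <- rep(NA_real_, n_genes)
  for (g in seq_len(n_genes)) {
    e <- x[, g]; i <- y[, g]
    if (sum(e + i) == 0) next
    th <- if (!is.null(theta_known)) theta_known[g]
          else if (estimate_theta_flag)
            estimate_theta(e, i, config$fit_quantile, config$theta_cells)
          else 0.5
    fs <- fit_steady_state(e, i, th, config$fit_quantile)
    if (fs$failed) { corr[g] <- fs$corr_r; next }
    theta[g] <- th; slope[g] <- fs$slope_k
    gam[g] <- fs$gamma_hat; corr[g] <- fs$corr_r
  }
  kinetics <- data.frame(gene = genes, theta_hat = theta, slope_k = slope,
                         gamma_hat = gam, corr_r = corr,
                         passes_filter = FALSE, stringsAsFactors = FALSE)
  kinetics <- filter_genes(kinetics, config$min_corr, config$min_slope)
  ratio <- (1 - theta) / theta
  vel <- sweep(y, 2, ratio, "*") - sweep(x, 2, gam, "*")
  vel[, !kinetics$passes_filter] <- 0
  extrap <- pmax(x + vel * config$delta_t, 0)
  structure(list(kinetics = kinetics, velocity = vel,
                 extrapolated = extrap, x = x, y = y,
                 config = config, model = model),
            class = "region_velocity")
}

#' Fit the region velocity model
#'
#' The central fitting function. Per gene, the intron fraction theta and
#' the steady-state slope of intron on exon counts are estimated (the
#' extreme-quantile fit), the degradation rate follows as
#' \code{gamma = slope * (1 - theta) / theta}, genes are filtered on
#' intron-exon correlation and slope, and the per-cell exon velocity
#' \deqn{v_e = ((1-\theta)/\theta) i - \gamma e}
#' (the rate of change of mature signal implied by the intron
#' quasi-steady state, beta = 1) is computed for passing genes, together
#' with the linearly extrapolated exon state clipped at zero.
#'
#' Counts are kNN-pooled before fitting when \code{k_cells > 1}: each
#' cell is summed with its nearest neighbours in \code{space} (a PCA of
#' log counts is computed when \code{space} is NULL).
#'
#' @param exon,intron cells x genes count matrices (dense or sparse).
#' @param space optional cells x d matrix (embedding or PCA scores) for
#'   pooling.
#' @param config a \code{\link{velocity_config}}.
#' @param theta_known optional vector of known per-gene theta values
#'   (bypasses estimation; useful for calibration studies).
#' @return An object of class \code{"region_velocity"} with components
#'   \code{kinetics} (per-gene data.frame: theta_hat, slope_k, gamma_hat,
#'   corr_r, passes_filter), \code{velocity}, \code{extrapolated},
#'   the fitted (pooled) matrices \code{x} (exon) and \code{y} (intron),
#'   and the config. Methods: print, summary, coef, predict, residuals,
#'   plot.
#' @export
#' @examples
#' pop <- generate_population(300, 20, seed = 7)
#' fit <- region_velocity(pop$exon, pop$intron,
#'                        config = velocity_config(k_cells = 1))
#' fit
#' head(coef(fit))
region_velocity <- function(exon, intron, space = NULL,
                            config = velocity_config(),
                            theta_known = NULL) {
  exon <- as.matrix(exon); intron <- as.matrix(intron)
  if (config$k_cells > 1) {
    if (is.null(space)) space <- log_pca(exon + intron)
    pooled <- pool_knn(list(exon, intron), space, config$k_cells)
    exon <- pooled[[1]]; intron <- pooled[[2]]
  }
  fit <- fit_velocity_engine(exon, intron, config,
                             estimate_theta_flag = TRUE,
                             model = "region", theta_known = theta_known)
  fit$call <- match.call()
  fit
}

#' Fit the classic spliced/unspliced RNA velocity baseline
#'
#' The original steady-state framework: per gene, gamma is the
#' extreme-quantile zero-intercept slope of unspliced on spliced counts
#' (beta = 1) and the velocity is \code{v_s = u - gamma * s}. This is
#' the region model with theta fixed at 1/2, under which
#' \code{(1 - theta)/theta = 1} and gamma equals the slope.
#'
#' @param spliced,unspliced cells x genes count matrices.
#' @inheritParams region_velocity
#' @return a \code{"region_velocity"} object with \code{model = "classic"}.
#' @export
rna_velocity <- function(spliced, unspliced, space = NULL,
                         config = velocity_config()) {
  spliced <- as.matrix(spliced); unspliced <- as.matrix(unspliced)
  if (config$k_cells > 1) {
    if (is.null(space)) space <- log_pca(spliced + unspliced)
    pooled <- pool_knn(list(spliced, unspliced), space, config$k_cells)
    spliced <- pooled[[1]]; unspliced <- pooled[[2]]
  }
  fit <- fit_velocity_engine(spliced, unspliced, config,
                             estimate_theta_flag = FALSE,
                             model = "classic")
  fit$call <- match.call()
  fit
}

log_pca <- function(m, d = 10) {
  lm <- log1p(as.matrix(m))
  lm <- sweep(lm, 2, colMeans(lm))
  d <- min(d, ncol(lm), nrow(lm) - 1)
  p <- stats::prcomp(lm, rank. = d)
  p$x
}

#' @export
print.region_velocity <- function(x, ...) {
  k <- x$kinetics
  cat(sprintf("%s velocity fit: %d cells x %d genes\n",
              if (x$model == "region") "Region" else "Classic RNA",
              nrow(x$velocity), ncol(x$velocity)))
  cat(sprintf("  %d/%d genes pass filters (corr >= %g, slope >= %g)\n",
              sum(k$passes_filter), nrow(k), x$config$min_corr,
              x$config$min_slope))
  cat(sprintf("  median gamma %.3f, median theta %.3f (passing genes)\n",
              stats::median(k$gamma_hat[k$passes_filter], na.rm = TRUE),
              stats::median(k$theta_hat[k$passes_filter], na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.region_velocity <- function(object, ...) {
  k <- object$kinetics
  structure(list(model = object$model,
                 n_cells = nrow(object$velocity),
                 n_genes = nrow(k),
                 n_passing = sum(k$passes_filter),
                 gamma = summary(k$gamma_hat[k$passes_filter]),
                 theta = summary(k$theta_hat[k$passes_filter]),
                 corr = summary(k$corr_r),
                 config = object$config),
            class = "summary.region_velocity")
}

#' @export
print.summary.region_velocity <- function(x, ...) {
  cat(sprintf("%s velocity fit: %d cells, %d genes (%d passing)\n",
              if (x$model == "region") "Region" else "Classic RNA",
              x$n_cells, x$n_genes, x$n_passing))
  cat("gamma (passing genes):\n"); print(x$gamma)
  cat("theta (passing genes):\n"); print(x$theta)
  cat("intron-exon correlation (all genes):\n"); print(x$corr)
  invisible(x)
}

#' @export
coef.region_velocity <- function(object, ...) {
  k <- object$kinetics
  m <- as.matrix(k[, c("theta_hat", "slope_k", "gamma_hat", "corr_r")])
  rownames(m) <- k$gene
  m
}

#' Extrapolate expression along the fitted velocity
#'
#' @param object a \code{\link{region_velocity}} fit.
#' @param newdata optional list with elements \code{exon} and
#'   \code{intron} (or \code{spliced}/\code{unspliced}) to project with
#'   the fitted kinetics.
#' @param delta_t extrapolation step (defaults to the fitted config).
#' @param ... unused.
#' @return extrapolated exon (spliced) matrix, clipped at zero.
#' @export
predict.region_velocity <- function(object, newdata = NULL,
                                    delta_t = object$config$delta_t, ...) {
  if (is.null(newdata)) {
    x <- object$x; y <- object$y
  } else {
    x <- as.matrix(newdata[[if ("exon" %in% names(newdata)) "exon" else "spliced"]])
    y <- as.matrix(newdata[[if ("intron" %in% names(newdata)) "intron" else "unspliced"]])
  }
  k <- object$kinetics
  ratio <- (1 - k$theta_hat) / k$theta_hat
  vel <- sweep(y, 2, ratio, "*") - sweep(x, 2, k$gamma_hat, "*")
  vel[, !k$passes_filter] <- 0
  pmax(x + vel * delta_t, 0)
}

#' @export
residuals.region_velocity <- function(object, ...) {
  # deviation from the fitted steady-state line, i - slope * e
  k <- object$kinetics
  r <- object$y - sweep(object$x, 2, k$slope_k, "*")
  r[, is.na(k$slope_k)] <- NA_real_
  r
}

#' Phase portrait of one gene with its steady-state fit
#'
#' @param x a \code{\link{region_velocity}} fit.
#' @param gene gene name or column index.
#' @param ... passed to \code{plot}.
#' @export
plot.region_velocity <- function(x, gene = 1, ...) {
  g <- if (is.character(gene)) match(gene, x$kinetics$gene) else gene
  if (is.na(g)) stop("unknown gene")
  e <- x$x[, g]; i <- x$y[, g]
  graphics::plot(e, i, pch = 16, cex = 0.6,
                 col = ifelse(x$velocity[, g] >= 0, "steelblue", "firebrick"),
                 xlab = if (x$model == "region") "exon counts" else "spliced",
                 ylab = if (x$model == "region") "intron counts" else "unspliced",
                 main = x$kinetics$gene[g], ...)
  graphics::abline(0, x$kinetics$slope_k[g], lty = 2)
  invisible(x)
}

#' Simulate count matrices from a fitted velocity model
#'
#' Draws a synthetic population from the fitted per-gene kinetics:
#' gamma and theta from the fit, alpha scaled so the induction steady
#' state matches the observed upper expression quantile, cells at
#' uniform latent times, Poisson noise. Useful as a posterior-predictive
#' check of the spindle shape.
#'
#' @param object a \code{\link{region_velocity}} fit (region model).
#' @param nsim number of cells to simulate.
#' @param seed integer seed.
#' @param t_switch switch time used for all genes.
#' @param ... unused.
#' @return list with exon and intron matrices (cells x passing genes).
#' @export
simulate.region_velocity <- function(object, nsim = 500, seed = 1L,
                                     t_switch = 10, ...) {
  k <- object$kinetics[object$kinetics$passes_filter, ]
  local_rng(seed)
  tau <- stats::runif(nsim, 0, 4 * t_switch)
  E <- I <- matrix(0, nsim, nrow(k),
                   dimnames = list(NULL, k$gene))
  for (j in seq_len(nrow(k))) {
    gcol <- match(k$gene[j], object$kinetics$gene)
    e_hi <- stats::quantile(object$x[, gcol], 0.95)
    alpha <- max(k$gamma_hat[j] * e_hi / (1 - k$theta_hat[j]), 1e-8)
    p <- trajectory_params(alpha = alpha, gamma = k$gamma_hat[j],
                           theta = k$theta_hat[j], t_switch = t_switch)
    z <- kinetic_expectation(p, tau)
    E[, j] <- stats::rpois(nsim, z$e)
    I[, j] <- stats::rpois(nsim, z$i)
  }
  list(exon = E, intron = I, latent_time = tau)
}
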