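#' k-nearest-neighbour graph on a 2-D embedding
#'
#' @param embedding cells x 2 numeric matrix.
#' @param k neighbours per cell (self excluded); capped at n - 1.
#' @return integer matrix, one row of neighbour indices per cell.
#' @export
embedding_neighbors <- function(embedding, k = 50) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' Correlation-based transition probabilities
#'
#' For each cell c and neighbour j, the score is the Pearson correlation
#' between the predicted expression change (extrapolated - observed for
#' cell c) and the displacement towards the neighbour (expression_j -
#' expression_c), converted to probabilities with an exponential kernel
#' over the neighbourhood. Cells with zero predicted change get a
#' uniform row.
#'
#' @param expression,extrapolated cells x genes matrices on the same
#'   gene set.
#' @param neighbors integer matrix from \code{\link{embedding_neighbors}}.
#' @param sigma kernel width on the correlation scale (default 0.05).
#' @return list: \code{prob} (cells x k matrix of probabilities, rows
#'   sum to 1) and \code{neighbors}.
#' @export
transition_probabilities <- function(expression, extrapolated, neighbors,
                                     sigma = 0.05) {
  expression <- as.matrix(expression)
  extrapolated <- as.matrix(extrapolated)
  n <- nrow(expression)
  k <- ncol(neighbors)
  prob <- matrix(1 / k, n, k)
  for (c in seq_len(n)) {
    delta <- extrapolated[c, ] - expression[c, ]
    if (all(delta == 0) || stats::sd(delta) == 0) next
    nb <- neighbors[c, ]
    disp <- t(expression[nb, , drop = FALSE]) - expression[c, ]
    keep <- apply(disp, 2, stats::sd) > 0
    cors <- rep(0, k)
    if (any(keep)) cors[keep] <- suppressWarnings(
      as.numeric(stats::cor(delta, disp[, keep, drop = FALSE])))
    cors[is.na(cors)] <- 0
    w <- exp(cors / sigma)
    prob[c, ] <- w / sum(w)
  }
  list(prob = prob, neighbors = neighbors)
}

#' Project velocities onto the embedding as per-cell arrows
#'
#' The arrow of cell c is the transition-probability-weighted mean of
#' unit vectors towards its neighbours, minus the unweighted mean (the
#' null expectation under uniform transitions), so a cell with no
#' directional signal gets a zero arrow.
#'
#' @param transitions output of \code{\link{transition_probabilities}}.
#' @param embedding cells x 2 matrix.
#' @return cells x 2 matrix of arrows (dx, dy).
#' @export
project_velocity <- function(transitions, embedding) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  arrows <- matrix(0, n, 2)
  for (c in seq_len(n)) {
    nb <- transitions$neighbors[c, ]
    delta <- embedding[nb, , drop = FALSE] -
      matrix(embedding[c, ], length(nb), 2, byrow = TRUE)
    len <- sqrt(rowSums(delta^2))
    ok <- len > 0
    if (!any(ok)) next
    unit <- delta[ok, , drop = FALSE] / len[ok]
    p <- transitions$prob[c, ok]
    p <- p / sum(p)
    arrows[c, ] <- colSums(unit * p) - colMeans(unit)
  }
  arrows
}

#' Average arrows on a regular grid
#'
#' The embedding bounding box is split into n_grid x n_grid boxes; each
#' populated box (at least \code{min_cells} members) gets the mean of
#' its member-cell arrows.
#'
#' @param arrows cells x 2 matrix.
#' @param embedding cells x 2 matrix.
#' @param n_grid grid resolution per axis (default 20).
#' @param min_cells minimum members per box.
#' @return data.frame: x, y (box centres), dx, dy, n_cells.
#' @export
grid_flow <- function(arrows, embedding, n_grid = 20, min_cells = 1) {
  embedding <- as.matrix(embedding)
  bx <- cut(embedding[, 1], n_grid, labels = FALSE, include.lowest = TRUE)
  by <- cut(embedding[, 2], n_grid, labels = FALSE, include.lowest = TRUE)
  key <- paste(bx, by)
  xr <- range(embedding[, 1]); yr <- range(embedding[, 2])
  cx <- xr[1] + (seq_len(n_grid) - 0.5) * diff(xr) / n_grid
  cy <- yr[1] + (seq_len(n_grid) - 0.5) * diff(yr) / n_grid
  rows <- lapply(split(seq_len(nrow(arrows)), key), function(idx) {
    if (length(idx) < min_cells) return(NULL)
    b <- strsplit(key[idx[1]], " ")[[1]]
    data.frame(x = cx[as.integer(b[1])], y = cy[as.integer(b[2])],
               dx = mean(arrows[idx, 1]), dy = mean(arrows[idx, 2]),
               n_cells = length(idx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed per-cell directions from a local ordering
#'
#' For trajectories with a directional lined pattern, the observed
#' direction of each cell is the principal axis (total least squares) of
#' its embedding neighbourhood, with the sign oriented along increasing
#' values of the ordering (e.g. a pseudotime or known latent time).
#'
#' @param embedding cells x 2 matrix.
#' @param ordering numeric vector (one value per cell).
#' @param n_neighbors neighbourhood size for the local regression.
#' @return cells x 2 matrix of unit vectors; rows of degenerate
#'   neighbourhoods (zero variance) are NA.
#' @export
observed_directions <- function(embedding, ordering, n_neighbors = 30) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  nb <- embedding_neighbors(embedding, k = min(n_neighbors, n - 1))
  out <- matrix(NA_real_, n, 2)
  for (c in seq_len(n)) {
    idx <- c(c, nb[c, ])
    pts <- embedding[idx, , drop = FALSE]
    cv <- stats::cov(pts)
    if (!all(is.finite(cv)) || sum(diag(cv)) == 0) next
    ev <- eigen(cv, symmetric = TRUE)
    dir <- ev$vectors[, 1]
    proj <- pts %*% dir
    s <- suppressWarnings(stats::cor(proj, ordering[idx]))
    if (is.na(s)) next
    if (s < 0) dir <- -dir
    out[c, ] <- dir
  }
  out
}

#' Angular separation between predicted and observed directions
#'
#' The angle (degrees, in [0, 180]) between each cell's predicted
#' velocity arrow and its observed direction; a prediction counts as a
#' success iff the angle is strictly less than 90 degrees. Zero-length
#' arrows and undefined observed directions are excluded and counted.
#'
#' @param predicted cells x 2 arrows.
#' @param observed cells x 2 unit vectors.
#' @param clusters optional per-cell labels for a per-cluster breakdown.
#' @return list of class \code{"angular_report"}: \code{angles},
#'   \code{success} (overall fraction < 90), \code{per_cluster},
#'   \code{n_excluded}.
#' @export
angular_separation <- function(predicted, observed, clusters = NULL) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  lp <- sqrt(rowSums(predicted^2))
  lo <- sqrt(rowSums(observed^2))
  ok <- is.finite(lp) & is.finite(lo) & lp > 0 & lo > 0
  ang <- rep(NA_real_, nrow(predicted))
  dot <- rowSums(predicted * observed) / (lp * lo)
  ang[ok] <- acos(pmin(pmax(dot[ok], -1), 1)) * 180 / pi
  succ <- mean(ang[ok] < 90)
  per_cluster <- NULL
  if (!is.null(clusters)) {
    per_cluster <- vapply(split(which(ok), clusters[ok]), function(idx)
      mean(ang[idx] < 90), numeric(1))
    per_cluster <- c(All = succ, per_cluster)
  }
  structure(list(angles = ang, success = succ, per_cluster = per_cluster,
                 n_excluded = sum(!ok)),
            class = "angular_report")
}

#' @export
print.angular_report <- function(x, ...) {
  cat(sprintf(
    "Angular separation: %.1f%% of %d cells predicted within 90 degrees (%d excluded)\n",
    100 * x$success, sum(!is.na(x$angles)), x$n_excluded))
  if (!is.null(x$per_cluster)) {
    for (k in names(x$per_cluster))
      cat(sprintf("  %s: %.1f%%\n", k, 100 * x$per_cluster[k]))
  }
  invisible(x)
}

#' Per-gene tendency matching of extrapolated expression
#'
#' For each cell and gene, the sign of the predicted change
#' (extrapolated - observed) is compared with the sign of the change
#' towards the cell's ordering-forward neighbours (the mean expression
#' of the next cells along the ordering minus the cell's own); the
#' per-gene matched-hit percentage is the fraction of cells where the
#' signs agree.
#'
#' @param expression,extrapolated cells x genes matrices.
#' @param ordering numeric per-cell ordering (pseudotime/latent time).
#' @param n_neighbors how many ordering-forward cells define the local
#'   future.
#' @return named numeric vector of per-gene matched-hit fractions
#'   (genes with no defined comparisons are NA).
#' @export
tendency_match <- function(expression, extrapolated, ordering,
                           n_neighbors = 30) {
  expression <- as.matrix(expression)
  extrapolated <- as.matrix(extrapolated)
  n <- nrow(expression)
  ord <- order(ordering)
  rank_of <- match(seq_len(n), ord)
  match_cnt <- total_cnt <- numeric(ncol(expression))
  for (c in seq_len(n)) {
    r <- rank_of[c]
    if (r >= n) next
    fwd <- ord[seq(r + 1, min(r + n_neighbors, n))]
    future <- colMeans(expression[fwd, , drop = FALSE])
    pred_sign <- sign(extrapolated[c, ] - expression[c, ])
    obs_sign <- sign(future - expression[c, ])
    defined <- pred_sign != 0 & obs_sign != 0
    match_cnt[defined] <- match_cnt[defined] +
      (pred_sign[defined] == obs_sign[defined])
    total_cnt[defined] <- total_cnt[defined] + 1
  }
  out <- ifelse(total_cnt > 0, match_cnt / total_cnt, NA_real_)
  names(out) <- colnames(expression)
  out
}

#' Project a velocity fit onto an embedding as a gridded vector field
#'
#' Convenience wrapper: builds the neighbour graph, computes the
#' correlation-based transition probabilities, per-cell arrows and the
#' grid-averaged field.
#'
#' @param fit a \code{\link{region_velocity}} object.
#' @param embedding cells x 2 matrix.
#' @param k neighbours (default 50, or all cells if fewer).
#' @param sigma kernel width.
#' @param n_grid grid resolution (default 20).
#' @param min_cells minimum cells per grid box.
#' @param smooth_k per-cell arrows are averaged over this many embedding
#'   neighbours before gridding (0 disables); single-cell arrows from a
#'   finite neighbourhood are noisy where the true velocity is small, so
#'   the field is locally averaged, in the same spirit as the
#'   grid-averaged display.
#' @return list of class \code{"velocity_field"}: arrows (smoothed),
#'   arrows_raw, grid, embedding.
#' @export
velocity_field <- function(fit, embedding, k = 50, sigma = 0.05,
                           n_grid = 20, min_cells = 1, smooth_k = 30) {
  stopifnot(inherits(fit, "region_velocity"))
  genes <- fit$kinetics$passes_filter
  nb <- embedding_neighbors(embedding, k)
  tp <- transition_probabilities(fit$x[, genes, drop = FALSE],
                                 fit$extrapolated[, genes, drop = FALSE],
                                 nb, sigma = sigma)
  raw <- project_velocity(tp, embedding)
  arrows <- raw
  if (smooth_k > 0) {
    nbs <- embedding_neighbors(embedding, min(smooth_k, nrow(raw) - 1))
    arrows <- t(vapply(seq_len(nrow(raw)), function(c)
      colMeans(raw[c(c, nbs[c, ]), , drop = FALSE]), numeric(2)))
  }
  grid <- grid_flow(arrows, embedding, n_grid = n_grid,
                    min_cells = min_cells)
  structure(list(arrows = arrows, arrows_raw = raw, grid = grid,
                 embedding = as.matrix(embedding)),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field: %d cells, %d populated grid boxes\n",
              nrow(x$arrows), nrow(x$grid)))
  invisible(x)
}

#' @export
plot.velocity_field <- function(x, scale = 1, ...) {
  graphics::plot(x$embedding, pch = 16, cex = 0.4, col = "grey70",
                 xlab = "dim 1", ylab = "dim 2", ...)
  g <- x$grid
  nz <- sqrt(g$dx^2 + g$dy^2) > 0
  graphics::arrows(g$x[nz], g$y[nz],
                   g$x[nz] + scale * g$dx[nz], g$y[nz] + scale * g$dy[nz],
                   length = 0.05, col = "black")
  invisible(x)
}
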