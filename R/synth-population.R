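#' Priors for per-gene kinetic parameters
#'
#' Defines the distributions from which \code{\link{generate_population}}
#' draws each gene's kinetic parameters. With the splicing rate beta = 1
#' fixing the time unit, degradation is slower than splicing for typical
#' mRNAs (splicing completes within minutes while half-lives run to
#' hours), so gamma defaults to a log-normal centred near 0.3; this is
#' also the regime in which the intron/exon phase portrait traces the
#' wide spindle loop with induction above the steady-state line. The
#' intronic share of nascent output is broad, and the induction
#' steady-state exon level sits near \code{expr_scale} counts so that
#' Poisson noise at sequencing depth is realistic.
#'
#' @param gamma_meanlog,gamma_sdlog log-normal prior of the degradation
#'   rate gamma.
#' @param theta_min,theta_max uniform prior bounds of the intron
#'   fraction theta.
#' @param expr_scale target induction steady-state exon level (counts);
#'   per gene, \code{alpha = expr_scale * gamma / (1 - theta)} so that
#'   \code{e* = expr_scale}.
#' @param expr_sdlog log-normal spread of per-gene expression scale.
#' @param ts_min,ts_max uniform prior bounds of the switch time (in
#'   units of 1/beta).
#'
#' @return A list of class \code{"param_priors"}.
#' @export
param_priors <- function(gamma_meanlog = log(0.3), gamma_sdlog = 0.5,
                         theta_min = 0.2, theta_max = 0.8,
                         expr_scale = 50, expr_sdlog = 0.3,
                         ts_min = 6, ts_max = 12) {
  if (expr_scale <= 0) stop("expr_scale must be > 0")
  if (theta_min <= 0 || theta_max >= 1 || theta_min > theta_max)
    stop("theta prior must satisfy 0 < theta_min <= theta_max < 1")
  if (ts_min <= 0 || ts_min > ts_max) stop("invalid ts prior range")
  if (gamma_sdlog < 0 || expr_sdlog < 0) stop("sdlog must be >= 0")
  structure(list(gamma_meanlog = gamma_meanlog, gamma_sdlog = gamma_sdlog,
                 theta_min = theta_min, theta_max = theta_max,
                 expr_scale = expr_scale, expr_sdlog = expr_sdlog,
                 ts_min = ts_min, ts_max = ts_max),
            class = "param_priors")
}

#' Generate a synthetic cell population from the kinetic model
#'
#' Draws per-gene kinetic parameters from \code{priors}, places each cell
#' at a latent time drawn uniformly on \code{[0, 4 * t_switch]} (covering
#' induction, the approach to steady state, and repression), and emits
#' exon/intron count matrices: either the noiseless closed-form
#' expectations or Poisson counts around them.
#'
#' Matched spliced/unspliced matrices for the classic RNA-velocity
#' baseline are also emitted, derived from the standard one-gene
#' two-species model with the same alpha, gamma (beta = 1):
#' \code{u(t)} nascent and \code{s(t)} mature molecule expectations. A 3'
#' short-read quantification can be emulated by setting
#' \code{unspliced_detect < 1}: each unspliced molecule is recognized as
#' unspliced only with that probability and is otherwise counted as
#' spliced, mimicking the underestimation of unspliced transcripts in
#' 3'-tag data.
#'
#' @param n_cells,n_genes population dimensions (>= 1).
#' @param priors a \code{\link{param_priors}} object.
#' @param noise \code{"none"} (expectations) or \code{"poisson"}.
#' @param unspliced_detect probability an unspliced molecule is
#'   recognized as unspliced in the u/s matrices (1 = full-length
#'   detection).
#' @param shared_time if TRUE all genes share one latent-time axis per
#'   cell (a common differentiation clock, as along a developmental
#'   trajectory); cells are then drawn on \code{[0, 4*max(ts)]} and each
#'   gene is evaluated at the shared time.
#' @param seed integer seed; all randomness in this call derives from it.
#'
#' @return A list of class \code{"synthetic_population"}:
#'   \item{exon, intron}{cells x genes matrices (region model).}
#'   \item{spliced, unspliced}{cells x genes matrices (classic model,
#'     after the \code{unspliced_detect} thinning).}
#'   \item{cell_truth}{data.frame: \code{cell}, \code{latent_time}
#'     (per gene a matrix if not shared), \code{phase} per cell/gene.}
#'   \item{gene_params}{data.frame of the true per-gene
#'     alpha/beta/gamma/theta/t_switch.}
#' @export
generate_population <- function(n_cells, n_genes,
                                priors = param_priors(),
                                noise = c("poisson", "none"),
                                unspliced_detect = 1,
                                shared_time = TRUE,
                                seed = 1L) {
  noise <- match.arg(noise)
  if (n_cells < 1 || n_genes < 1) stop("n_cells and n_genes must be >= 1")
  if (!inherits(priors, "param_priors")) stop("priors must be param_priors()")
  if (unspliced_detect < 0 || unspliced_detect > 1)
    stop("unspliced_detect must be in [0, 1]")
  rng <- local_rng(seed)

  gamma <- stats::rlnorm(n_genes, priors$gamma_meanlog, priors$gamma_sdlog)
  theta <- stats::runif(n_genes, priors$theta_min, priors$theta_max)
  scale <- priors$expr_scale *
    stats::rlnorm(n_genes, -priors$expr_sdlog^2 / 2, priors$expr_sdlog)
  alpha <- scale * gamma / (1 - theta)
  ts <- stats::runif(n_genes, priors$ts_min, priors$ts_max)
  gene_params <- data.frame(
    gene = sprintf("gene%04d", seq_len(n_genes)),
    alpha = alpha, beta = 1, gamma = gamma, theta = theta, t_switch = ts,
    stringsAsFactors = FALSE)

  if (shared_time) {
    tau <- stats::runif(n_cells)          # common clock position in [0,1]
    lat <- outer(tau, 4 * ts)             # per gene: t = tau * 4*ts
  } else {
    lat <- matrix(stats::runif(n_cells * n_genes), n_cells, n_genes) *
      rep(4 * ts, each = n_cells)
  }

  E <- I <- U <- S <- matrix(0, n_cells, n_genes)
  phase <- matrix("", n_cells, n_genes)
  for (g in seq_len(n_genes)) {
    p <- trajectory_params(alpha = alpha[g], gamma = gamma[g],
                           theta = theta[g], t_switch = ts[g])
    z <- kinetic_expectation(p, lat[, g])
    E[, g] <- z$e; I[, g] <- z$i; phase[, g] <- z$phase
    us <- classic_expectation(alpha[g], 1, gamma[g], ts[g], lat[, g])
    U[, g] <- us$u; S[, g] <- us$s
  }

  if (noise == "poisson") {
    E[] <- stats::rpois(length(E), E)
    I[] <- stats::rpois(length(I), I)
    U[] <- stats::rpois(length(U), U)
    S[] <- stats::rpois(length(S), S)
  }
  if (unspliced_detect < 1) {
    if (noise == "poisson") {
      seen <- stats::rbinom(length(U), round(U), unspliced_detect)
    } else {
      seen <- U * unspliced_detect
    }
    S <- S + (U - seen)   # missed unspliced molecules read as spliced
    U <- matrix(seen, nrow(U), ncol(U))
  }

  cells <- sprintf("cell%05d", seq_len(n_cells))
  genes <- gene_params$gene
  dimnames(E) <- dimnames(I) <- dimnames(U) <- dimnames(S) <-
    list(cells, genes)
  cell_truth <- data.frame(cell = cells,
                           latent_time = if (shared_time) tau else NA_real_,
                           stringsAsFactors = FALSE)
  structure(list(exon = E, intron = I, spliced = S, unspliced = U,
                 cell_truth = cell_truth, latent_times = lat,
                 phase = phase, gene_params = gene_params,
                 priors = priors, noise = noise, seed = seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("Synthetic population: %d cells x %d genes (%s noise)\n",
              nrow(x$exon), ncol(x$exon), x$noise))
  cat(sprintf("  mean exon count %.1f, mean intron count %.1f\n",
              mean(x$exon), mean(x$intron)))
  invisible(x)
}

## Classic two-species model: du/dt = alpha - beta u, ds/dt = beta u - gamma s,
## alpha constant on [0, ts] then 0; closed form with u(0) = s(0) = 0.
classic_expectation <- function(alpha, beta, gamma, ts, t) {
  u_ind <- function(t) (alpha / beta) * (1 - exp(-beta * t))
  s_ind <- function(t) {
    if (abs(beta - gamma) < 1e-12) {
      (alpha / gamma) * (1 - exp(-gamma * t)) - alpha * t * exp(-gamma * t)
    } else {
      (alpha / gamma) * (1 - exp(-gamma * t)) +
        (alpha / (gamma - beta)) * (exp(-gamma * t) - exp(-beta * t))
    }
  }
  u0 <- u_ind(ts); s0 <- s_ind(ts)
  dec_u <- function(dt) u0 * exp(-beta * dt)
  dec_s <- function(dt) {
    if (abs(beta - gamma) < 1e-12) {
      (s0 + beta * u0 * dt) * exp(-gamma * dt)
    } else {
      s0 * exp(-gamma * dt) +
        (beta * u0 / (gamma - beta)) * (exp(-beta * dt) - exp(-gamma * dt))
    }
  }
  ind <- t <= ts
  list(u = ifelse(ind, u_ind(t), dec_u(t - ts)),
       s = ifelse(ind, s_ind(t), dec_s(t - ts)))
}

## Every stochastic entry point seeds R's generator explicitly; no hidden
## per-package RNG state.
local_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  set.seed(as.integer(seed))
  invisible(as.integer(seed))
}
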