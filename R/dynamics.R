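## Lean closed-form trajectory evaluator (no class construction), used in
## the EM inner loops. Returns list(e, i) at times t.
traj_eval <- function(alpha, gamma, theta, ts, t, beta = 1) {
  ie <- theta * alpha / beta
  ee <- (1 - theta) * alpha / gamma
  i_ts <- ie * (1 - exp(-beta * ts))
  e_ts <- ee * (1 - exp(-gamma * ts))
  ind <- t <= ts
  i_t <- e_t <- numeric(length(t))
  i_t[ind] <- ie * (1 - exp(-beta * t[ind]))
  e_t[ind] <- ee * (1 - exp(-gamma * t[ind]))
  dt <- t[!ind] - ts
  i_t[!ind] <- i_ts * exp(-beta * dt)
  e_t[!ind] <- e_ts * exp(-gamma * dt)
  list(e = e_t, i = i_t)
}

## Default EM initializer: steady-state estimates of theta and gamma.
em_default_init <- function(e, i) {
  th0 <- tryCatch(estimate_theta(e, i), error = function(...) 0.5)
  fs <- tryCatch(fit_steady_state(e, i, th0), error = function(...) NULL)
  g0 <- if (!is.null(fs) && !fs$failed && is.finite(fs$gamma_hat) &&
            fs$gamma_hat > 0) fs$gamma_hat else 1
  list(alpha = NA_real_, gamma = min(max(g0, 0.02), 5), theta = th0,
       t_switch = 10)
}

#' Dynamical fit of per-gene kinetics by expectation-maximization
#'
#' Fits the full two-phase kinetic model (alpha, gamma, theta, t_switch;
#' beta fixed at 1) to one gene's exon/intron counts across cells. The
#' E-step assigns each cell the latent time (and hence phase) that
#' maximizes its likelihood on the parametric trajectory; the M-step
#' updates alpha, gamma and theta given the assignments, with the switch
#' time updated by a one-dimensional search; iteration stops when the
#' objective improves by less than \code{tol} (relative).
#'
#' Because the counts are (near-)Poisson, the default residual model is
#' the Poisson likelihood kernel \code{mu - x log(mu)} per dimension,
#' which also handles continuous (noise-free) input; under an
#' equal-variance Gaussian model the free latent times can absorb the
#' count heteroscedasticity and drive the fit into a spurious thin-loop
#' optimum, so the Gaussian variant (residuals standardized per
#' dimension) is kept only as an option. Several EM starts with scaled
#' initial degradation rates are run and the best objective kept, since
#' the steady-state initializer is biased towards gamma = 1.
#'
#' The final log-likelihood (Poisson, or Gaussian for the gaussian
#' residual model) quantifies how well the spindle-shaped trajectory
#' explains the gene and can rank driver genes.
#'
#' @param e,i exon and intron counts across cells (>= 20 cells).
#' @param init optional list(alpha, gamma, theta, t_switch); by default
#'   initialized from the steady-state fit.
#' @param max_iter,tol EM iteration controls (tol is relative change of
#'   the objective).
#' @param n_grid resolution of the latent-time grid in the E-step.
#' @param polish refine each cell's grid assignment by golden-section
#'   search (default: automatically enabled for <= 500 cells, where the
#'   extra precision is cheap).
#' @param residual_model \code{"poisson"} (default) or
#'   \code{"gaussian"}.
#' @param start_factors multiplicative factors applied to the initial
#'   gamma for the multi-start schedule; the steady-state initializer is
#'   biased towards gamma = beta, so the schedule leans low.
#' @param m_maxit Nelder-Mead iteration cap inside each M-step.
#' @param reestimate_theta update theta in the M-step (default TRUE);
#'   FALSE keeps the initial estimate fixed.
#' @return list of class \code{"gene_dynamics"}: \code{params}
#'   (a \code{\link{trajectory_params}}), \code{latent_time},
#'   \code{phase}, \code{loglik}, \code{converged}, \code{n_iter}.
#' @export
#' @examples
#' pop <- generate_population(100, 1, noise = "none", seed = 2)
#' fit <- fit_dynamical_em(pop$exon[, 1], pop$intron[, 1])
#' fit
fit_dynamical_em <- function(e, i, init = NULL, max_iter = 40,
                             tol = 1e-6, n_grid = 220, polish = NULL,
                             residual_model = c("poisson", "gaussian"),
                             start_factors = c(1, 0.4, 0.15, 2.5),
                             m_maxit = 150,
                             reestimate_theta = TRUE) {
  residual_model <- match.arg(residual_model)
  if (length(e) < 20) stop("need at least 20 cells")
  if (is.null(polish)) polish <- length(e) <= 500
  sd_e <- max(stats::sd(e), 1e-8)
  sd_i <- max(stats::sd(i), 1e-8)
  kern <- if (residual_model == "poisson") {
    function(x, mu, s) mu - x * log(mu + 1e-9)
  } else {
    function(x, mu, s) ((x - mu) / s)^2
  }

  if (is.null(init)) init <- em_default_init(e, i)

  obj_at <- function(par, t) {
    z <- traj_eval(par$alpha, par$gamma, par$theta, par$t_switch, t)
    v <- sum(kern(e, z$e, sd_e) + kern(i, z$i, sd_i))
    if (!is.finite(v)) v <- .Machine$double.xmax / 1e6
    v
  }
  e_step <- function(par) {
    grid <- seq(0, 4 * par$t_switch, length.out = n_grid)
    z <- traj_eval(par$alpha, par$gamma, par$theta, par$t_switch, grid)
    d <- outer(e, z$e, kern, s = sd_e) + outer(i, z$i, kern, s = sd_i)
    best <- max.col(-d, ties.method = "first")
    t_hat <- grid[best]
    if (!polish) return(t_hat)
    step <- grid[2] - grid[1]
    vapply(seq_along(e), function(c) {
      f <- function(t) {
        z <- traj_eval(par$alpha, par$gamma, par$theta, par$t_switch, t)
        kern(e[c], z$e, sd_e) + kern(i[c], z$i, sd_i)
      }
      stats::optimize(f, c(max(t_hat[c] - step, 0),
                           min(t_hat[c] + step, 4 * par$t_switch)),
                      tol = 1e-6)$minimum
    }, numeric(1))
  }
  m_step <- function(par, t) {
    obj <- function(v) {
      th <- if (reestimate_theta) stats::plogis(v[3]) else par$theta
      obj_at(list(alpha = exp(v[1]), gamma = exp(v[2]), theta = th,
                  t_switch = par$t_switch), t)
    }
    v0 <- c(log(par$alpha), log(par$gamma), stats::qlogis(par$theta))
    o <- stats::optim(v0, obj, method = "Nelder-Mead",
                      control = list(maxit = m_maxit, reltol = 1e-9))
    par$alpha <- exp(o$par[1]); par$gamma <- exp(o$par[2])
    if (reestimate_theta) par$theta <- stats::plogis(o$par[3])
    # switch time: global search over phase-boundary candidates (the
    # objective in ts is multimodal), then local refinement
    ts_obj <- function(ts) obj_at(modifyList(par, list(t_switch = ts)), t)
    hi <- max(max(t) * 1.3, 1)
    cand <- seq(max(min(t), 1e-3) + 1e-3, hi, length.out = 40)
    vals <- vapply(cand, ts_obj, numeric(1))
    k <- which.min(vals)
    lo_b <- cand[max(k - 1, 1)]; hi_b <- cand[min(k + 1, length(cand))]
    par$t_switch <- stats::optimize(ts_obj, c(lo_b, hi_b),
                                    tol = 1e-7)$minimum
    par
  }
  # coarse E-step used only when profiling switch-time candidates
  e_step_coarse <- function(par, ng = 80) {
    grid <- seq(0, 4 * par$t_switch, length.out = ng)
    z <- traj_eval(par$alpha, par$gamma, par$theta, par$t_switch, grid)
    d <- outer(e, z$e, kern, s = sd_e) + outer(i, z$i, kern, s = sd_i)
    grid[max.col(-d, ties.method = "first")]
  }
  run_one <- function(par0) {
    par <- par0
    if (!is.finite(par$alpha))
      par$alpha <- max(par$gamma * stats::quantile(e, 0.98) /
                         (1 - par$theta), 1e-6)
    t_hat <- e_step(par)
    converged <- FALSE; iter <- 0; obj <- Inf
    for (round in 1:5) {
      obj_old <- Inf
      repeat {
        iter <- iter + 1
        par <- m_step(par, t_hat)
        t_hat <- e_step(par)
        obj <- obj_at(par, t_hat)
        if (is.finite(obj) && abs(obj_old - obj) < tol * (abs(obj) + 1e-8)) {
          converged <- TRUE; break
        }
        if (iter >= max_iter) break
        obj_old <- obj
      }
      # alternating updates cannot move the switch time across basins
      # (times and ts are coupled); profile ts with fresh assignments
      # and restart the EM from a better basin if one exists
      cands <- c(par$t_switch,
                 seq(max(par$t_switch / 6, 0.2), par$t_switch * 2,
                     length.out = 12))
      prof <- vapply(cands, function(ts) {
        p2 <- par; p2$t_switch <- ts
        obj_at(p2, e_step_coarse(p2))   # same coarse grid for all
      }, numeric(1))
      k <- which.min(prof)
      if (k > 1 && prof[k] < prof[1] - tol * (abs(prof[1]) + 1e-8) &&
          iter < max_iter) {
        par$t_switch <- cands[k]
        t_hat <- e_step(par)
        next
      }
      # fine polish of the switch time against the profile objective
      # (times re-assigned for every candidate)
      ts_prof <- function(ts) {
        p2 <- par; p2$t_switch <- ts
        obj_at(p2, e_step_coarse(p2, ng = n_grid))
      }
      o <- stats::optimize(ts_prof,
                           c(par$t_switch / 1.4, par$t_switch * 1.4),
                           tol = 1e-6)
      cur <- obj_at(par, e_step_coarse(par, ng = n_grid))
      if (o$objective < cur - tol * (abs(cur) + 1e-8) && iter < max_iter) {
        par$t_switch <- o$minimum
        t_hat <- e_step(par)
      } else break
    }
    list(par = par, t = t_hat, obj = obj_at(par, t_hat),
         converged = converged, iter = iter)
  }

  runs <- lapply(start_factors, function(f) {
    p0 <- init
    p0$gamma <- max(init$gamma * f, 1e-4)
    p0$alpha <- NA_real_
    run_one(p0)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "obj"))]]
  par <- best$par; t_hat <- best$t
  z <- traj_eval(par$alpha, par$gamma, par$theta, par$t_switch, t_hat)
  ll <- if (residual_model == "poisson" && all(e == round(e) & i == round(i))) {
    sum(stats::dpois(e, z$e + 1e-9, log = TRUE) +
          stats::dpois(i, z$i + 1e-9, log = TRUE))
  } else {
    n <- length(e)
    s2e <- max(mean((e - z$e)^2), 1e-12)
    s2i <- max(mean((i - z$i)^2), 1e-12)
    -n / 2 * (log(2 * pi * s2e) + log(2 * pi * s2i)) - n
  }
  structure(list(
    params = trajectory_params(par$alpha, par$gamma, par$theta,
                               t_switch = par$t_switch),
    latent_time = t_hat,
    phase = ifelse(t_hat <= par$t_switch, "induction", "repression"),
    fitted = data.frame(e = z$e, i = z$i),
    loglik = ll, objective = best$obj,
    converged = best$converged, n_iter = best$iter),
    class = "gene_dynamics")
}

#' @export
print.gene_dynamics <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Dynamical fit (%s after %d EM iterations): alpha %.3g, gamma %.3g, theta %.3g, t_switch %.3g; loglik %.2f\n",
    if (x$converged) "converged" else "not converged", x$n_iter,
    p$alpha, p$gamma, p$theta, p$t_switch, x$loglik))
  invisible(x)
}

#' Dynamical EM fit across the genes of a velocity fit
#'
#' Runs \code{\link{fit_dynamical_em}} for each passing gene of a
#' \code{\link{region_velocity}} fit, initialized from its steady-state
#' estimates, and returns per-gene parameters, likelihoods (for
#' driver-gene ranking) and per-cell latent times.
#'
#' @param object a region_velocity fit.
#' @param genes genes to fit (default: all passing genes).
#' @param ... passed to \code{\link{fit_dynamical_em}}.
#' @return data.frame of class \code{"dynamics_table"} with per-gene
#'   alpha, gamma, theta, t_switch, loglik, converged; per-gene cell
#'   times in attribute \code{"latent_time"}.
#' @export
fit_dynamics <- function(object,
                         genes = object$kinetics$gene[object$kinetics$passes_filter],
                         ...) {
  stopifnot(inherits(object, "region_velocity"))
  res <- lapply(genes, function(g) {
    j <- match(g, object$kinetics$gene)
    k <- object$kinetics[j, ]
    init <- if (!is.na(k$gamma_hat) && k$gamma_hat > 0) {
      list(alpha = NA_real_, gamma = k$gamma_hat, theta = k$theta_hat,
           t_switch = 10)
    } else NULL
    fit_dynamical_em(object$x[, j], object$y[, j], init = init, ...)
  })
  out <- data.frame(
    gene = genes,
    alpha = vapply(res, function(r) r$params$alpha, numeric(1)),
    gamma = vapply(res, function(r) r$params$gamma, numeric(1)),
    theta = vapply(res, function(r) r$params$theta, numeric(1)),
    t_switch = vapply(res, function(r) r$params$t_switch, numeric(1)),
    loglik = vapply(res, function(r) r$loglik, numeric(1)),
    converged = vapply(res, function(r) r$converged, logical(1)),
    stringsAsFactors = FALSE)
  attr(out, "latent_time") <- lapply(res, function(r) r$latent_time)
  class(out) <- c("dynamics_table", "data.frame")
  out
}
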