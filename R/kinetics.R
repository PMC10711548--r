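#' Kinetic parameters of one gene's RNA lifecycle
#'
#' Container for the rate constants of the exon/intron kinetic model
#' \deqn{di/dt = \theta \alpha(t) - \beta i(t)}
#' \deqn{de/dt = (1-\theta) \alpha(t) - \gamma e(t)}
#' where transcription runs at rate \code{alpha} until the switch time
#' \code{t_switch} (induction) and is zero afterwards (repression).
#'
#' @param alpha transcription rate during induction (molecules per unit
#'   time, > 0).
#' @param gamma degradation rate of the exonic (mature) signal
#'   (per unit time, > 0).
#' @param theta fraction of nascent transcriptional output that is
#'   intronic, in (0, 1).
#' @param beta splicing rate (per unit time); fixed at 1 by convention,
#'   which sets the time unit.
#' @param t_switch time at which transcription switches off (> 0).
#'
#' @return An object of class \code{"trajectory_params"}: a list with
#'   fields \code{alpha}, \code{beta}, \code{gamma}, \code{theta},
#'   \code{t_switch}.
#' @export
#' @examples
#' p <- trajectory_params(alpha = 10, gamma = 0.8, theta = 0.4, t_switch = 8)
#' tr <- simulate_trajectory(p, n_points = 100)
#' head(tr)
trajectory_params <- function(alpha, gamma, theta, beta = 1, t_switch = 10) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(gamma <= 0)) stop("gamma must be > 0")
  if (any(beta <= 0)) stop("beta must be > 0")
  if (any(theta <= 0 | theta >= 1)) stop("theta must be in (0, 1)")
  if (any(t_switch <= 0)) stop("t_switch must be > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 theta = theta, t_switch = t_switch),
            class = "trajectory_params")
}

#' @export
print.trajectory_params <- function(x, ...) {
  cat("Kinetic parameters (beta fixes the time unit):\n")
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g, theta = %g, t_switch = %g\n",
              x$alpha, x$beta, x$gamma, x$theta, x$t_switch))
  cat(sprintf("  induction steady state: i* = %g, e* = %g\n",
              x$theta * x$alpha / x$beta,
              (1 - x$theta) * x$alpha / x$gamma))
  invisible(x)
}

## Closed-form expectations of the two-phase kinetic ODEs at times t.
## Induction (t <= ts, alpha constant):
##   i(t) = i0 exp(-beta t) + (theta alpha / beta)(1 - exp(-beta t))
##   e(t) = e0 exp(-gamma t) + ((1-theta) alpha / gamma)(1 - exp(-gamma t))
## Repression (t > ts, alpha = 0): exponential decay from the phase
## boundary values i(ts), e(ts).
kinetic_expectation <- function(params, t, e0 = 0, i0 = 0) {
  stopifnot(inherits(params, "trajectory_params"))
  a <- params$alpha; b <- params$beta; g <- params$gamma
  th <- params$theta; ts <- params$t_switch
  i_ind <- function(t) i0 * exp(-b * t) + (th * a / b) * (1 - exp(-b * t))
  e_ind <- function(t) e0 * exp(-g * t) + ((1 - th) * a / g) * (1 - exp(-g * t))
  i_ts <- i_ind(ts); e_ts <- e_ind(ts)
  ind <- t <= ts
  i_t <- ifelse(ind, i_ind(t), i_ts * exp(-b * (t - ts)))
  e_t <- ifelse(ind, e_ind(t), e_ts * exp(-g * (t - ts)))
  list(e = e_t, i = i_t, phase = ifelse(ind, "induction", "repression"))
}

#' Simulate the expected exon/intron trajectory of one gene
#'
#' Evaluates the closed-form solution of the two-phase kinetic model on a
#' regular time grid spanning \code{[0, 4 * t_switch]}: transcription at
#' rate \code{alpha} up to the switch time, then decay. The span covers
#' the approach to the induction steady state
#' (\code{i* = theta*alpha/beta}, \code{e* = (1-theta)*alpha/gamma}) and
#' the repression return to the origin, tracing the spindle-shaped
#' phase portrait.
#'
#' @param params a \code{\link{trajectory_params}} object.
#' @param n_points number of grid points.
#' @param e0,i0 initial exon/intron expectations at t = 0.
#' @param t_max end of the time grid; default \code{4 * t_switch}.
#'
#' @return A data.frame of class \code{"kinetic_trajectory"} with columns
#'   \code{t}, \code{e}, \code{i}, \code{phase}.
#' @export
simulate_trajectory <- function(params, n_points = 200, e0 = 0, i0 = 0,
                                t_max = 4 * params$t_switch) {
  stopifnot(inherits(params, "trajectory_params"), n_points >= 2)
  t <- seq(0, t_max, length.out = n_points)
  z <- kinetic_expectation(params, t, e0 = e0, i0 = i0)
  out <- data.frame(t = t, e = z$e, i = z$i, phase = z$phase,
                    stringsAsFactors = FALSE)
  class(out) <- c("kinetic_trajectory", "data.frame")
  out
}

#' @export
plot.kinetic_trajectory <- function(x, ...) {
  col <- ifelse(x$phase == "induction", "steelblue", "firebrick")
  graphics::plot(x$e, x$i, col = col, pch = 16, cex = 0.6,
                 xlab = "exon counts e(t)", ylab = "intron counts i(t)", ...)
  graphics::legend("topleft", legend = c("induction", "repression"),
                   col = c("steelblue", "firebrick"), pch = 16, bty = "n")
  invisible(x)
}
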