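test_that("EM recovers all kinetic parameters on noise-free data", {
  # switch before the induction branch saturates (t_switch ~ 2/gamma),
  # so the switch time is identified by the turning point of the loop
  p <- trajectory_params(alpha = 60, gamma = 0.5, theta = 0.4,
                         t_switch = 5)
  set.seed(51)
  t_true <- runif(400, 0, 4 * p$t_switch)
  z <- regionvelo:::kinetic_expectation(p, t_true)
  fit <- fit_dynamical_em(z$e, z$i, polish = TRUE, max_iter = 120,
                          tol = 1e-9, n_grid = 500)
  expect_lt(abs(fit$params$alpha - p$alpha) / p$alpha, 0.02)
  expect_lt(abs(fit$params$gamma - p$gamma) / p$gamma, 0.01)
  expect_lt(abs(fit$params$theta - p$theta) / p$theta, 0.01)
  # the switch time is only weakly identified once the branches
  # saturate (see the methods vignette); 10% is its honest tolerance
  expect_lt(abs(fit$params$t_switch - p$t_switch) / p$t_switch, 0.10)
  # latent times track the truth up to grid/assignment resolution
  expect_gt(cor(fit$latent_time, t_true), 0.999)
})

test_that("a symmetric gene (theta = 1/2, gamma = beta) has coinciding trajectories", {
  p <- trajectory_params(alpha = 40, gamma = 1, theta = 0.5, t_switch = 9)
  tr <- simulate_trajectory(p, 200)
  expect_equal(tr$e, tr$i, tolerance = 1e-12)
})

test_that("EM under Poisson noise recovers gamma and theta within tolerance (small panel)", {
  pop <- generate_population(800, 4, seed = 52)
  err_g <- err_t <- numeric(4)
  for (g in 1:4) {
    f <- fit_dynamical_em(pop$exon[, g], pop$intron[, g], polish = FALSE)
    tp <- pop$gene_params[g, ]
    err_g[g] <- abs(f$params$gamma - tp$gamma) / tp$gamma
    err_t[g] <- abs(f$params$theta - tp$theta) / tp$theta
  }
  expect_lt(median(err_g), 0.15)
  expect_lt(median(err_t), 0.15)
})

test_that("EM input validation and convergence flagging", {
  pop <- generate_population(30, 1, seed = 53)
  expect_error(fit_dynamical_em(1:10, 1:10), "20 cells")
  f <- fit_dynamical_em(pop$exon[, 1], pop$intron[, 1], max_iter = 1)
  expect_false(f$converged)
  expect_identical(f$n_iter, 1)
})

test_that("fit_dynamics table carries per-gene parameters and likelihoods", {
  pop <- generate_population(150, 3, seed = 54)
  base <- region_velocity(pop$exon, pop$intron,
                          config = velocity_config(k_cells = 1))
  dyn <- fit_dynamics(base, genes = base$kinetics$gene[1:2],
                      max_iter = 8, polish = FALSE)
  expect_identical(nrow(dyn), 2L)
  expect_true(all(is.finite(dyn$loglik)))
  expect_true(all(dyn$gamma > 0))
  expect_length(attr(dyn, "latent_time"), 2L)
})
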