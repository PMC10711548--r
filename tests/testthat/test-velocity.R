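test_that("theta is the count ratio over the selected cells, with boundary clamps", {
  e <- c(rep(7, 90), rep(70, 10))
  i <- c(rep(3, 90), rep(30, 10))
  # top-decile cells have intron 30, exon 70 -> theta 0.3
  expect_equal(estimate_theta(e, i, fit_quantile = 0.1), 0.3)
  expect_equal(estimate_theta(e, i, cells = "all"), 0.3)
  expect_equal(estimate_theta(rep(0, 10), rep(5, 10)), 1 - 1e-6)
  expect_error(estimate_theta(rep(0, 4), rep(0, 4)), "all-zero")
})

test_that("steady-state fit recovers the slope and gamma in closed form", {
  set.seed(1)
  e <- runif(200, 1, 100)
  i <- 2 * e                      # exactly on i = 2e
  fs <- fit_steady_state(e, i, theta_hat = 0.5)
  expect_equal(fs$slope_k, 2)
  expect_equal(fs$gamma_hat, 2)   # (1-theta)/theta = 1 at theta = 0.5
  expect_equal(fs$corr_r, 1)
  # theta != 0.5 scales gamma by (1-theta)/theta
  fs2 <- fit_steady_state(e, i, theta_hat = 0.25)
  expect_equal(fs2$gamma_hat, 2 * 3)
  # degenerate input flags failure
  expect_true(fit_steady_state(rep(1, 50), rep(2, 50), 0.5)$failed)
})

test_that("gene filters apply the correlation and slope thresholds at the boundary", {
  k <- data.frame(gene = c("a", "b", "c"),
                  slope_k = c(0.5, 0.21, 0.19),
                  corr_r = c(0.19, 0.9, 0.9))
  out <- filter_genes(k)
  expect_identical(out$passes_filter, c(FALSE, TRUE, FALSE))
  k$corr_r <- 0.1
  expect_error(filter_genes(k), "no gene")
})

test_that("velocity is exactly zero on the fitted steady-state line", {
  set.seed(2)
  e <- matrix(runif(300, 5, 100), ncol = 3)
  i <- e * rep(c(0.5, 1.2, 2), each = 100)
  fit <- region_velocity(e, i, config = velocity_config(k_cells = 1))
  expect_lt(max(abs(fit$velocity)), 1e-10)
  expect_equal(fit$extrapolated, fit$x, tolerance = 1e-12)
})

test_that("the velocity formula evaluates as stated and signs follow the line", {
  # theta = 0.5, gamma = 1, i = 4, e = 2 -> velocity = 4 - 2 = 2
  expect_equal(((1 - 0.5) / 0.5) * 4 - 1 * 2, 2)
  set.seed(3)
  e <- matrix(runif(400, 5, 100), ncol = 1)
  i <- 0.8 * e
  jitter <- c(rep(10, 200), rep(-10, 200))
  fit <- region_velocity(e, i + jitter,
                         config = velocity_config(k_cells = 1))
  v <- fit$velocity[, 1]
  expect_true(all(v[1:200] > 0))        # above the line: induction-like
  expect_true(all(v[201:400] < 0))      # below: repression-like
})

test_that("gamma and theta estimates are invariant to count scaling", {
  pop <- generate_population(400, 5, seed = 31)
  f1 <- region_velocity(pop$exon, pop$intron,
                        config = velocity_config(k_cells = 1))
  f2 <- region_velocity(pop$exon * 7, pop$intron * 7,
                        config = velocity_config(k_cells = 1))
  expect_equal(coef(f1)[, "gamma_hat"], coef(f2)[, "gamma_hat"],
               tolerance = 1e-12)
  expect_equal(coef(f1)[, "theta_hat"], coef(f2)[, "theta_hat"],
               tolerance = 1e-12)
})

test_that("the classic baseline matches its closed-form examples", {
  set.seed(4)
  s <- matrix(runif(200, 5, 80), ncol = 1)
  u <- 0.5 * s
  fit <- rna_velocity(s, u, config = velocity_config(k_cells = 1))
  expect_equal(unname(coef(fit)[, "gamma_hat"]), 0.5)
  expect_lt(max(abs(fit$velocity)), 1e-10)
  # u = 3, gamma = 0.5, s = 4 -> velocity 1
  expect_equal(3 - 0.5 * 4, 1)
})

test_that("baseline and region models agree when theta = 1/2 and (u,s) = (i,e)", {
  pop <- generate_population(300, 4, seed = 8,
                             priors = param_priors(theta_min = 0.499,
                                                   theta_max = 0.501))
  cfg <- velocity_config(k_cells = 1)
  # with theta at 1/2 the (1-theta)/theta factor is 1, so feeding the
  # exon/intron matrices through the classic model must reproduce the
  # region fit exactly
  fr <- region_velocity(pop$exon, pop$intron, config = cfg,
                        theta_known = rep(0.5, 4))
  fc <- rna_velocity(pop$exon, pop$intron, config = cfg)
  expect_equal(coef(fr)[, "gamma_hat"], coef(fc)[, "gamma_hat"],
               tolerance = 1e-12)
  expect_equal(fr$velocity, fc$velocity, tolerance = 1e-10)
})

test_that("velocity sign matches the true phase for nearly all cells at zero noise", {
  pop <- generate_population(1000, 10, noise = "none", seed = 13)
  fit <- region_velocity(pop$exon, pop$intron,
                         config = velocity_config(k_cells = 1))
  ok <- 0; tot <- 0
  for (g in which(fit$kinetics$passes_filter)) {
    v <- fit$velocity[, g]
    ph <- pop$phase[, g]
    nz <- abs(v) > 1e-6 * max(abs(v))
    ok <- ok + sum((v > 0) == (ph == "induction") & nz)
    tot <- tot + sum(nz)
  }
  expect_gte(ok / tot, 0.95)
})

test_that("kNN pooling: identity at k = 1 and hand-checked collinear case", {
  m <- matrix(c(1, 10, 100), ncol = 1)
  space <- cbind(c(0, 1, 2.1), 0)
  expect_equal(pool_knn(m, space, k = 1), m)
  pooled <- pool_knn(m, space, k = 2)
  # nearest neighbours: cell1 -> cell2, cell2 -> cell1, cell3 -> cell2
  expect_equal(as.numeric(pooled), c(11, 11, 110))
  expect_error(pool_knn(m, space, k = 5), "exceed")
})

test_that("prediction extrapolates new data with the fitted kinetics", {
  pop <- generate_population(300, 3, seed = 17)
  fit <- region_velocity(pop$exon, pop$intron,
                         config = velocity_config(k_cells = 1))
  pred <- predict(fit)
  expect_identical(dim(pred), dim(pop$exon))
  expect_true(all(pred >= 0))
  new <- list(exon = pop$exon[1:5, ], intron = pop$intron[1:5, ])
  pred2 <- predict(fit, newdata = new, delta_t = 2)
  expect_identical(nrow(pred2), 5L)
  # residuals are deviations from the fitted line
  r <- residuals(fit)
  k <- fit$kinetics
  expect_equal(r[, 1],
               fit$y[, 1] - k$slope_k[1] * fit$x[, 1])
})
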