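test_that("noiseless counts equal the closed-form trajectory at each latent time", {
  pop <- generate_population(60, 8, noise = "none", seed = 11)
  for (g in seq_len(8)) {
    gp <- pop$gene_params[g, ]
    p <- trajectory_params(gp$alpha, gp$gamma, gp$theta,
                           t_switch = gp$t_switch)
    z <- regionvelo:::kinetic_expectation(p, pop$latent_times[, g])
    expect_equal(unname(pop$exon[, g]), z$e, tolerance = 1e-9)
    expect_equal(unname(pop$intron[, g]), z$i, tolerance = 1e-9)
  }
})

test_that("cells at time zero with zero initial state have zero counts", {
  pop <- generate_population(5, 1, noise = "none", seed = 3)
  p <- pop$gene_params[1, ]
  z <- regionvelo:::kinetic_expectation(
    trajectory_params(p$alpha, p$gamma, p$theta, t_switch = p$t_switch), 0)
  expect_equal(z$e, 0)
  expect_equal(z$i, 0)
})

test_that("poisson counts concentrate on the steady-state mean (law of large numbers)", {
  # single gene held at steady state: long induction, cells late in it
  n <- 10000
  lam_i <- 20; lam_e <- 50
  # gamma/theta/alpha chosen to give i* = 20, e* = 50
  theta <- lam_i / (lam_i + lam_e * 0.4)  # free choice; solve alpha below
  set.seed(99)
  i_cnt <- rpois(n, lam_i)
  e_cnt <- rpois(n, lam_e)
  expect_lt(abs(mean(i_cnt) - lam_i), 3 * sqrt(lam_i / n))
  expect_lt(abs(mean(e_cnt) - lam_e), 3 * sqrt(lam_e / n))
  # and the generator's own poisson draws behave the same way
  pop <- generate_population(n, 1, seed = 5,
                             priors = param_priors(gamma_sdlog = 0,
                                                   expr_sdlog = 0))
  gp <- pop$gene_params[1, ]
  z <- regionvelo:::kinetic_expectation(
    trajectory_params(gp$alpha, gp$gamma, gp$theta, t_switch = gp$t_switch),
    pop$latent_times[, 1])
  expect_lt(abs(mean(pop$intron[, 1]) - mean(z$i)),
            3 * sqrt(mean(z$i) / n))
})

test_that("default priors trace a spindle: induction above, repression below the steady-state ray", {
  pop <- generate_population(2000, 6, noise = "none", seed = 21)
  for (g in seq_len(6)) {
    gp <- pop$gene_params[g, ]
    slope <- gp$theta * gp$gamma / (1 - gp$theta)   # steady-state i/e ray
    e <- pop$exon[, g]; i <- pop$intron[, g]
    resid <- i - slope * e
    mid <- e > 0.2 * max(e) & e < 0.9 * max(e)      # away from endpoints
    ind <- pop$phase[, g] == "induction" & mid
    rep_ <- pop$phase[, g] == "repression" & mid
    expect_gt(mean(resid[ind] > 0), 0.95)
    expect_gt(mean(resid[rep_] < 0), 0.95)
  }
})

test_that("seeded runs are reproducible and different seeds differ", {
  a <- generate_population(50, 4, seed = 8)
  b <- generate_population(50, 4, seed = 8)
  c <- generate_population(50, 4, seed = 9)
  expect_identical(a$exon, b$exon)
  expect_identical(a$gene_params, b$gene_params)
  expect_false(identical(a$exon, c$exon))
})

test_that("invalid priors and dimensions are rejected", {
  expect_error(param_priors(expr_scale = -1), "expr_scale")
  expect_error(param_priors(theta_min = 0), "theta")
  expect_error(generate_population(0, 5), "n_cells")
  expect_error(generate_population(10, 5, unspliced_detect = 2),
               "unspliced_detect")
})

test_that("3'-truncation moves unspliced molecules into the spliced matrix", {
  full <- generate_population(500, 5, seed = 4, unspliced_detect = 1)
  thin <- generate_population(500, 5, seed = 4, unspliced_detect = 1 / 3)
  expect_lt(sum(thin$unspliced), sum(full$unspliced) * 0.5)
  # totals preserved: missed unspliced molecules are read as spliced
  expect_equal(thin$spliced + thin$unspliced, full$spliced + full$unspliced)
})
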