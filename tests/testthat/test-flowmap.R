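ring_embedding <- function(n = 60, seed = 1) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(cos(th), sin(th))
}

test_that("transition rows sum to one and zero velocity gives uniform rows and zero arrows", {
  set.seed(11)
  expr <- matrix(runif(40 * 6, 1, 50), 40, 6)
  nb <- embedding_neighbors(ring_embedding(40), k = 8)
  tp <- transition_probabilities(expr, expr, nb)   # extrapolated == expr
  expect_true(all(abs(rowSums(tp$prob) - 1) < 1e-12))
  expect_true(all(abs(tp$prob - 1 / 8) < 1e-12))
  arrows <- project_velocity(tp, ring_embedding(40))
  nb_any <- embedding_neighbors(ring_embedding(40), k = 39)
  tp_all <- transition_probabilities(expr, expr, nb_any)
  arr_all <- project_velocity(tp_all, ring_embedding(40))
  # uniform probabilities on the full symmetric ring: arrows vanish
  expect_lt(max(abs(arr_all)), 1e-10)
})

test_that("probability mass concentrates on the best-matching neighbour as sigma shrinks", {
  # 3-cell toy: velocity points exactly at neighbour A
  expr <- rbind(c(0, 0), c(1, 0), c(0, 1))
  extr <- rbind(c(1, 0), c(1, 0), c(0, 1))  # cell 1 moves towards cell 2
  nb <- matrix(c(2, 3, 1, 3, 1, 2), 3, 2, byrow = TRUE)
  tp <- transition_probabilities(expr, extr, nb, sigma = 0.01)
  expect_gt(tp$prob[1, 1], 0.999)  # neighbour 2 (expression direction match)
  # hand-computed: corr(delta=(1,0), expr_2-expr_1=(1,0)) = 1;
  # corr with expr_3-expr_1=(0,1) = -1 -> weights exp(+-1/sigma)
  w <- exp(c(1, -1) / 0.01)
  expect_equal(tp$prob[1, ], w / sum(w), tolerance = 1e-9)
})

test_that("arrows are translation-invariant and follow an all-mass neighbour", {
  emb <- ring_embedding(30)
  set.seed(12)
  expr <- matrix(runif(30 * 5, 1, 50), 30, 5)
  extr <- expr + matrix(rnorm(150), 30, 5)
  nb <- embedding_neighbors(emb, 6)
  tp <- transition_probabilities(expr, extr, nb)
  a1 <- project_velocity(tp, emb)
  a2 <- project_velocity(tp, emb + 100)
  expect_equal(a1, a2, tolerance = 1e-12)
  # all mass on one neighbour: arrow = unit vector minus null mean
  tp$prob[1, ] <- c(1, rep(0, 5))
  a <- project_velocity(tp, emb)
  delta <- emb[nb[1, ], ] - matrix(emb[1, ], 6, 2, byrow = TRUE)
  unit <- delta / sqrt(rowSums(delta^2))
  expect_equal(a[1, ], unit[1, ] - colMeans(unit), tolerance = 1e-12)
})

test_that("grid averaging reproduces hand-computed box means", {
  emb <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  arrows <- rbind(c(1, 0), c(3, 0), c(0, 2), c(0, 4))
  g <- grid_flow(arrows, emb, n_grid = 2)
  expect_identical(nrow(g), 2L)
  expect_equal(g$dx, c(2, 0))
  expect_equal(g$dy, c(0, 3))
  expect_identical(g$n_cells, c(2L, 2L))
  # constant arrows: every populated box equals the constant
  g2 <- grid_flow(matrix(rep(c(5, -1), each = 4), 4, 2), emb, n_grid = 2)
  expect_true(all(g2$dx == 5) && all(g2$dy == -1))
})

test_that("observed directions recover a straight line and flip with reversed ordering", {
  n <- 40
  emb <- cbind(seq_len(n) / 5, 0.001 * sin(seq_len(n)))
  ord <- seq_len(n)
  dirs <- observed_directions(emb, ord, n_neighbors = 8)
  inner <- 10:30
  expect_true(all(abs(dirs[inner, 1] - 1) < 0.01))
  rev_dirs <- observed_directions(emb, rev(ord), n_neighbors = 8)
  expect_equal(dirs[inner, ], -rev_dirs[inner, ], tolerance = 1e-9)
})

test_that("angular separation: exact angles, strict 90-degree rule, scale invariance", {
  pred <- rbind(c(1, 0), c(-2, 0), c(0, 3), c(0, 0))
  obs <- rbind(c(2, 0), c(1, 0), c(5, 0), c(1, 0))
  rep_ <- angular_separation(pred, obs)
  expect_equal(rep_$angles[1:3], c(0, 180, 90))
  expect_equal(rep_$success, 1 / 3)      # 90 degrees counts as failure
  expect_identical(rep_$n_excluded, 1L)  # the zero-length arrow
  rep2 <- angular_separation(pred * 10, obs / 3)
  expect_equal(rep2$angles, rep_$angles)
  # per-cluster breakdown
  rep3 <- angular_separation(pred, obs, clusters = c("a", "a", "b", "b"))
  expect_equal(unname(rep3$per_cluster["a"]), 0.5)
})

test_that("tendency match: perfect extrapolation scores 100%, random velocities about 50%", {
  n <- 200
  set.seed(13)
  ord <- runif(n)
  expr <- matrix(5 + 10 * ord + rnorm(n, 0, 0.01), ncol = 1)
  # forward neighbours have higher expression; extrapolation that also
  # rises matches everywhere
  extr <- expr + 1
  tm <- tendency_match(expr, extr, ord, n_neighbors = 10)
  expect_equal(unname(tm), 1)
  # random-signed extrapolation is a coin flip
  set.seed(14)
  extr_rand <- expr + sample(c(-1, 1), n, TRUE)
  tm2 <- tendency_match(expr, extr_rand, ord, n_neighbors = 10)
  expect_gt(tm2, 0.35); expect_lt(tm2, 0.65)
})

test_that("velocity_field wraps the pipeline and plots without error", {
  pop <- generate_population(150, 10, seed = 15)
  tau <- pop$cell_truth$latent_time
  set.seed(16)
  emb <- cbind(tau * 10, rnorm(150, 0, 0.5))
  fit <- region_velocity(pop$exon, pop$intron, space = emb,
                         config = velocity_config(k_cells = 5))
  vf <- velocity_field(fit, emb, k = 20, smooth_k = 10)
  expect_identical(dim(vf$arrows), c(150L, 2L))
  expect_true(all(c("x", "y", "dx", "dy", "n_cells") %in% names(vf$grid)))
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(vf); grDevices::dev.off()
  expect_true(file.exists(tmp))
})
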