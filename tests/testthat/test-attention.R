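# Hierarchical attention: projections, softmax weights, aggregation, and the
# composite objective.

test_that("level projections apply the level-specific affine maps", {
  z <- matrix(rnorm(6), 3, 2)
  W <- matrix(c(1, 0, 0, 1), 2)
  p <- list(W_l = list(W, W, W), b_l = rep(list(matrix(0, 1, 2)), 3))
  h <- level_projections(z, p, activation = "gelu")
  expect_equal(h[[1]], h[[2]])  # identical maps -> identical states
  expect_equal(h[[1]], z * pnorm(z), tolerance = 1e-12)

  p0 <- list(W_l = list(matrix(0, 2, 2)), b_l = list(matrix(0, 1, 2)))
  expect_equal(level_projections(z, p0)[[1]], matrix(0, 3, 2))  # f(0) = 0

  pk <- list(W_l = list(matrix(c(1, 2, 3, 4), 2)), b_l = list(matrix(c(1, -1), 1)))
  expect_equal(level_projections(matrix(c(1, 2), 1), pk, activation = "linear")[[1]],
               matrix(c(1 + 4 + 1, 3 + 8 - 1), 1))
})

test_that("attention weights are a shift-invariant softmax over levels", {
  h <- rep(list(matrix(1, 4, 2)), 3)
  u <- rep(list(matrix(0, 2, 1)), 3)
  expect_equal(as.numeric(attention_weights(h, u)), rep(1 / 3, 3), tolerance = 1e-12)

  # scores (ln 2, 0, 0) -> (0.5, 0.25, 0.25)
  h2 <- list(matrix(log(2), 1, 1), matrix(0, 1, 1), matrix(0, 1, 1))
  u2 <- rep(list(matrix(1, 1, 1)), 3)
  expect_equal(as.numeric(attention_weights(h2, u2)), c(0.5, 0.25, 0.25), tolerance = 1e-12)

  # adding a constant to all scores changes nothing
  h3 <- lapply(h2, function(m) m + 5)
  expect_equal(attention_weights(h3, u2), attention_weights(h2, u2), tolerance = 1e-10)

  # weights always sum to one and are non-negative
  set.seed(41)
  hr <- lapply(1:3, function(l) matrix(rnorm(8), 4, 2))
  ur <- lapply(1:3, function(l) matrix(rnorm(2), 2, 1))
  a <- attention_weights(hr, ur)
  expect_equal(sum(a), 1, tolerance = 1e-8)
  expect_true(all(a >= 0))
})

test_that("aggregation is the attention-weighted embedding of level predictions", {
  hier <- hierarchy_spec(list(a = 1:2, b = 3L, c = 4L))
  y_levels <- list(matrix(1:4, 2, 2), matrix(c(9, 9), 2, 1), matrix(c(-1, -1), 2, 1))
  # degenerate attention picks out level 1
  y1 <- aggregate_predictions(y_levels, c(1, 0, 0), hier, d_y = 4)
  expect_equal(y1[, 1:2], matrix(1:4, 2, 2))
  expect_equal(y1[, 3:4], matrix(0, 2, 2))

  # overlapping levels (hierarchy = NULL: every level spans the full space)
  y2 <- aggregate_predictions(list(matrix(0, 1, 1), matrix(1, 1, 1)),
                              c(0.5, 0.5), hierarchy = NULL, d_y = 1)
  expect_equal(as.numeric(y2), 0.5)

  # brute-force oracle on a random instance
  set.seed(42)
  yl <- lapply(list(1:2, 3L, 4L), function(ix) matrix(rnorm(3 * length(ix)), 3))
  al <- as.numeric(attention_weights(lapply(1:3, function(l) matrix(rnorm(6), 3, 2)),
                                     lapply(1:3, function(l) matrix(rnorm(2), 2, 1))))
  got <- aggregate_predictions(yl, al, hier, d_y = 4)
  brute <- matrix(0, 3, 4)
  for (l in 1:3) brute[, hier$level_dims[[l]]] <- brute[, hier$level_dims[[l]]] + al[l] * yl[[l]]
  expect_equal(got, brute, tolerance = 1e-12)

  # aggregate stays in the convex hull columnwise for overlapping levels
  y3 <- aggregate_predictions(list(matrix(c(0, 2), 2, 1), matrix(c(1, 5), 2, 1)),
                              c(0.3, 0.7), hierarchy = NULL, d_y = 1)
  expect_true(all(y3 >= pmin(c(0, 2), c(1, 5)) & y3 <= pmax(c(0, 2), c(1, 5))))
})

test_that("attention objective itemizes and its literal L1 term is 1 under softmax", {
  set.seed(43)
  yt <- matrix(rnorm(8), 2, 4); yf <- matrix(rnorm(8), 2, 4)
  alpha <- as.numeric(attention_weights(lapply(1:3, function(l) matrix(rnorm(4), 2, 2)),
                                        lapply(1:3, function(l) matrix(rnorm(2), 2, 1))))
  out <- attention_objective(yt, yf, latent_term = 0.4, graph_term = 0.9, alpha = alpha,
                             lambdas = list(latent = 2, graph = 3, attention = 5))
  expect_equal(out$components$attention, 5 * 1, tolerance = 1e-12)  # L1 of softmax = 1
  expect_equal(Reduce(`+`, out$components), out$total, tolerance = 1e-12)
  expect_equal(out$components$latent, 0.8, tolerance = 1e-12)

  out0 <- attention_objective(yt, yf, alpha = alpha,
                              lambdas = list(latent = 0, graph = 0, attention = 0))
  expect_equal(out0$total, mean(rowSums((yt - yf)^2)), tolerance = 1e-12)
  expect_error(attention_objective(yt, yf, alpha = alpha,
                                   lambdas = list(latent = -1, graph = 0, attention = 0)),
               "non-negative")
})

test_that("attention objective gradient w.r.t. context vectors matches finite differences", {
  set.seed(44)
  wex <- make_worked_example()
  z <- wex$truth$z_true  # 4 x 1
  hier <- wex$truth$level_map
  Wl <- lapply(1:2, function(l) matrix(rnorm(3), 1, 3))
  bl <- lapply(1:2, function(l) matrix(rnorm(3), 1, 3))
  Wh <- lapply(1:2, function(l) matrix(rnorm(3), 3, 1))
  bh <- lapply(1:2, function(l) matrix(0, 1, 1))
  u0 <- lapply(1:2, function(l) matrix(rnorm(3), 3, 1))

  loss_of_u1 <- function(u1) {
    u <- list(u1, u0[[2]])
    h <- level_projections(z, list(W_l = Wl, b_l = bl))
    a <- attention_weights(h, u)
    yl <- lapply(1:2, function(l) h[[l]] %*% Wh[[l]] + matrix(bh[[l]], 4, 1))
    yf <- aggregate_predictions(yl, a, hier, d_y = 2)
    attention_objective(wex$phenotypes$values, yf, alpha = a,
                        lambdas = list(latent = 0, graph = 0, attention = 0.3))$total
  }

  tp <- ad_tape()
  un <- ad_const(tp, u0[[1]])
  h <- level_projections(ad_const(tp, z), list(W_l = Wl, b_l = bl))
  a <- attention_weights(h, list(un, ad_const(tp, u0[[2]])))
  yl <- lapply(1:2, function(l) ad_add_rvec(ad_matmul(h[[l]], ad_const(tp, Wh[[l]])),
                                            ad_const(tp, bh[[l]])))
  yf <- aggregate_predictions(yl, a, hier, d_y = 2)
  obj <- attention_objective(ad_const(tp, wex$phenotypes$values), yf, alpha = a,
                             lambdas = list(latent = 0, graph = 0, attention = 0.3))
  g <- ad_backward(tp, obj$total)
  ga <- ad_grad(g, un)
  gn <- fd_grad(loss_of_u1, u0[[1]])
  expect_lt(max_rel_err(ga, gn), 1e-4)
})

test_that("training concentrates attention on the signal-bearing level", {
  # phenotypes: level-1 columns carry the latent signal, levels 2-3 are noise
  set.seed(45)
  n <- 300; k <- 3; d_y <- 6
  z <- matrix(rnorm(n * k), n, k)
  W1 <- matrix(rnorm(2 * k), 2, k)
  y <- cbind(z %*% t(W1), matrix(rnorm(n * 4, sd = 0.1), n, 4))
  x <- z %*% t(matrix(rnorm(10 * k), 10, k)) + matrix(rnorm(n * 10, sd = 0.05), n, 10)
  hier <- hierarchy_spec(list(sensorimotor = 1:2, control = 3:4, executive = 5:6))
  cfg <- lcen_config(
    encoder = list(layer_widths = c(16L, 3L), dropout_rate = 0,
                   dropout_after = integer(0), activation = "gelu",
                   batch_norm = FALSE),
    decoder = list(residual_block = FALSE),
    attention = list(enabled = TRUE, level_hidden = 8L, entropy_weight = 0.05),
    lambdas = list(kl = 0.001, graph = 0, hierarchy = 0),
    multi_task = list(enabled = FALSE),
    training = list(max_epochs = 120L, patience = 120L, lr = 0.01, batch_size = 64L)
  )
  fit <- lcen(x, y, hierarchy = hier, config = cfg, seed = 2)
  expect_gte(fit$alpha[1], 0.6)
  expect_equal(sum(fit$alpha), 1, tolerance = 1e-8)
})
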