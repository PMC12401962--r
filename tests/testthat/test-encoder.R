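# Variational encoder, posterior sampling, and latent regularizers.

small_spec <- function(...) {
  encoder_spec(layer_widths = c(8L, 4L), dropout_rate = 0,
               dropout_after = integer(0), batch_norm = FALSE, ...)
}

test_that("encode produces posterior heads of the latent dimension and is deterministic", {
  spec <- encoder_spec()  # reference widths 512/256/128/64
  set.seed(1)
  params <- lcen:::init_encoder_params(10, spec)
  x <- matrix(rnorm(30), 3, 10)
  post <- encode(x, spec, params)
  expect_equal(ncol(post$mu), 64L)
  expect_equal(ncol(post$log_var), 64L)
  post2 <- encode(x, spec, params)
  expect_identical(post$mu, post2$mu)  # eval mode is bitwise deterministic
  expect_identical(post$log_var, post2$log_var)
  expect_error(encode(matrix(0, 2, 7), spec, params), "10")
})

test_that("zero-initialized posterior heads map every input to mu = 0, log_var = 0", {
  spec <- small_spec()
  set.seed(2)
  params <- lcen:::init_encoder_params(6, spec)
  params$W_mu[] <- 0; params$b_mu[] <- 0
  params$W_lv[] <- 0; params$b_lv[] <- 0
  post <- encode(matrix(rnorm(60), 10, 6), spec, params)
  expect_equal(post$mu, matrix(0, 10, 4))
  expect_equal(post$log_var, matrix(0, 10, 4))
})

test_that("encode is permutation-equivariant over the batch", {
  spec <- small_spec()
  set.seed(3)
  params <- lcen:::init_encoder_params(6, spec)
  x <- matrix(rnorm(36), 6, 6)
  perm <- c(4, 1, 6, 2, 5, 3)
  p1 <- encode(x[perm, ], spec, params)
  p2 <- encode(x, spec, params)
  expect_equal(p1$mu, p2$mu[perm, ], tolerance = 1e-12)
})

test_that("reparameterization is seeded and degenerate variance collapses to the mean", {
  post <- list(mu = matrix(1:6 / 2, 2, 3), log_var = matrix(-40, 2, 3))
  z <- reparameterize(post, noise_seed = 5)
  expect_equal(z, post$mu, tolerance = 1e-8)
  post$log_var <- matrix(0, 2, 3)
  expect_identical(reparameterize(post, 7), reparameterize(post, 7))
  expect_false(identical(reparameterize(post, 7), reparameterize(post, 8)))
})

test_that("reparameterized draws reproduce standard-normal moments", {
  n <- 1e5
  post <- list(mu = matrix(0, n, 1), log_var = matrix(0, n, 1))
  z <- reparameterize(post, noise_seed = 11)
  expect_lt(abs(mean(z)), 4 * 10^-2.5)
  expect_lt(abs(var(as.numeric(z)) - 1), 0.05)
})

test_that("KL to the standard normal matches the closed form and 1-D quadrature", {
  expect_equal(kl_standard_normal(list(mu = matrix(0), log_var = matrix(0))), 0)
  expect_equal(kl_standard_normal(list(mu = matrix(1), log_var = matrix(0))), 0.5)

  # quadrature oracle on random 1-D posteriors
  set.seed(13)
  for (rep in 1:5) {
    mu <- rnorm(1); lv <- rnorm(1, sd = 0.5)
    s <- exp(lv / 2)
    grid <- seq(mu - 10 * s - 10, mu + 10 * s + 10, length.out = 200001)
    q <- dnorm(grid, mu, s)
    kl_num <- sum(q * (dnorm(grid, mu, s, log = TRUE) - dnorm(grid, log = TRUE))) * diff(grid[1:2])
    expect_equal(kl_standard_normal(list(mu = matrix(mu), log_var = matrix(lv))),
                 kl_num, tolerance = 1e-4)
  }

  # non-negativity, zero iff standard normal
  set.seed(14)
  for (rep in 1:20) {
    mu <- matrix(rnorm(6), 2, 3); lv <- matrix(rnorm(6), 2, 3)
    expect_gte(kl_standard_normal(list(mu = mu, log_var = lv)), 0)
  }
  expect_lt(kl_standard_normal(list(mu = matrix(0, 2, 3), log_var = matrix(0, 2, 3))), 1e-10)
})

test_that("latent regularizer equals brute-force variance plus proximity", {
  z_same <- matrix(1, 4, 3)
  expect_equal(latent_regularizer(z_same, z_same, beta = 0), 0)
  set.seed(15)
  z <- matrix(rnorm(20), 5, 4)
  prior <- draw_latent_prior(5, 4, seed = 2)
  got <- latent_regularizer(z, prior, beta = 1.7)
  brute <- sum(apply(z, 2, var)) + 1.7 * mean(rowSums((z - prior)^2))
  expect_equal(got, brute, tolerance = 1e-10)
  # z equal to the prior draw: proximity term vanishes
  expect_equal(latent_regularizer(prior, prior, beta = 3),
               sum(apply(prior, 2, var)), tolerance = 1e-10)
  expect_warning(latent_regularizer(matrix(1, 1, 2), matrix(0, 1, 2)), "batch of 1")
})

test_that("MI bound reduces to the Gaussian entropy when the decoder is flat", {
  set.seed(16)
  n <- 6; d <- 3
  lv <- matrix(rnorm(n * d, sd = 0.3), n, d)
  post <- list(mu = matrix(rnorm(n * d), n, d), log_var = lv)
  got <- mi_lower_bound(NULL, post, function(x, z) matrix(0, n, 1),
                        n_samples = 200, seed = 3)
  # E[-log q] is the differential entropy, independent of the sample draw
  ent <- mean(rowSums(0.5 * (1 + log(2 * pi) + lv)))
  expect_equal(got, ent, tolerance = 0.05)
})

test_that("MI bound never exceeds the analytic MI of a linear-Gaussian toy", {
  # x = z + e, z ~ N(0,1), e ~ N(0, s2): MI = 0.5 log(1 + 1/s2).
  set.seed(17)
  n <- 4000; s2 <- 0.25
  z_true <- rnorm(n); x <- z_true + rnorm(n, sd = sqrt(s2))
  # exact posterior q(z|x) = N(x/(1+s2), s2/(1+s2))
  post_var <- s2 / (1 + s2)
  post <- list(mu = matrix(x / (1 + s2), n, 1),
               log_var = matrix(log(post_var), n, 1))
  loglik <- function(xx, zn) {
    # log N(x; z, s2) built on the tape so gradients would flow
    tp <- zn$tape
    diff2 <- ad_square(ad_sub(ad_const(tp, matrix(x, n, 1)), zn))
    ad_add(ad_scale(diff2, -0.5 / s2),
           ad_const(tp, matrix(-0.5 * log(2 * pi * s2), n, 1)))
  }
  vals <- vapply(1:8, function(s) {
    mi_lower_bound(x, post, loglik, n_samples = 1, seed = s)
  }, numeric(1))
  mi_true <- 0.5 * log(1 + 1 / s2)
  se <- sd(vals) / sqrt(length(vals))
  # with the exact posterior and true decoder the bound's expectation is
  # E[log p(x|z)] + H(q) = -0.5 log(1 + s2), strictly below the true MI
  expect_lt(abs(mean(vals) - (-0.5 * log(1 + s2))), 5 * se + 0.03)
  expect_lt(mean(vals) - 3 * se, mi_true)
  expect_true(all(is.finite(vals)))
})

test_that("composite latent objective is linear in its components and differentiable", {
  set.seed(18)
  z <- matrix(rnorm(12), 4, 3)
  prior <- draw_latent_prior(4, 3, seed = 9)
  a <- latent_regularizer(z, prior)
  post <- list(mu = z, log_var = matrix(-1, 4, 3))
  ll0 <- function(x, zz) if (lcen:::is_ad(zz)) ad_const(zz$tape, matrix(0, 4, 1)) else matrix(0, 4, 1)
  b <- -mi_lower_bound(NULL, post, ll0, seed = 4)
  out <- latent_total(z, post, NULL, ll0, prior, lambda_mutual = 2, seed = 4)
  expect_equal(out$total, a + 2 * b, tolerance = 1e-10)
  out0 <- latent_total(z, post, prior_draw = prior, lambda_mutual = 0)
  expect_equal(out0$total, a, tolerance = 1e-12)
  expect_error(latent_total(z, post, prior_draw = prior, lambda_mutual = -1), "non-negative")
})

test_that("losses stay finite on extreme inputs thanks to the log-variance clamp", {
  post <- list(mu = matrix(c(1e6, -1e6), 1, 2), log_var = matrix(c(1e6, -1e6), 1, 2))
  v <- kl_standard_normal(post)
  expect_true(is.finite(v))
})
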