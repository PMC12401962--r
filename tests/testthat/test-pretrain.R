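# Self-supervised pretraining: reconstruction, auxiliary KL, augmentation
# policies, and the contrastive objective.

test_that("input reconstruction loss matches the batch-mean squared norm", {
  # zero decoder on unit-norm rows -> loss 1
  spec <- encoder_spec(layer_widths = c(4L, 3L), dropout_rate = 0,
                       dropout_after = integer(0), batch_norm = FALSE)
  set.seed(61)
  enc_p <- lcen:::init_encoder_params(4, spec)
  dec_p <- lcen:::init_input_decoder_params(spec, 4)
  for (l in seq_along(dec_p$W)) { dec_p$W[[l]][] <- 0; dec_p$b[[l]][] <- 0 }
  x <- matrix(rnorm(20), 5, 4)
  x <- x / sqrt(rowSums(x^2))
  out <- reconstruct_input(x, list(spec = spec, params = enc_p), dec_p)
  expect_equal(out$x_hat, matrix(0, 5, 4))
  expect_equal(out$loss, 1, tolerance = 1e-12)

  # arbitrary decoder: loss equals the brute-force mean squared norm
  dec_p2 <- lcen:::init_input_decoder_params(spec, 4)
  out2 <- reconstruct_input(x, list(spec = spec, params = enc_p), dec_p2)
  expect_equal(out2$loss, mean(rowSums((x - out2$x_hat)^2)), tolerance = 1e-12)
})

test_that("identity-regime linear autoencoder reconstructs perfectly", {
  # d_x <= d_z with identity weights end-to-end
  spec <- encoder_spec(layer_widths = 3L, dropout_rate = 0,
                       dropout_after = integer(0), batch_norm = FALSE,
                       activation = "linear")
  enc_p <- list(W = list(diag(3)), b = list(matrix(0, 1, 3)),
                W_mu = diag(3), b_mu = matrix(0, 1, 3),
                W_lv = matrix(0, 3, 3), b_lv = matrix(0, 1, 3))
  dec_p <- list(W = list(diag(3)), b = list(matrix(0, 1, 3)))
  x <- matrix(rnorm(15), 5, 3)
  out <- reconstruct_input(x, list(spec = spec, params = enc_p), dec_p)
  expect_lt(out$loss, 1e-10)
})

test_that("auxiliary KL is additive over priors and matches the closed form", {
  post0 <- list(mu = matrix(0, 2, 3), log_var = matrix(0, 2, 3))
  expect_equal(kl_auxiliary(post0, list(list(mean = 0, log_var = 0))), 0)
  one <- kl_auxiliary(post0, list(list(mean = 1, log_var = 0)))
  two <- kl_auxiliary(post0, list(list(mean = 1, log_var = 0), list(mean = 1, log_var = 0)))
  expect_equal(two, 2 * one, tolerance = 1e-12)
  # d = 1, standard posterior, prior mean 1 -> 0.5
  expect_equal(kl_auxiliary(list(mu = matrix(0), log_var = matrix(0)),
                            list(list(mean = 1, log_var = 0))), 0.5)
  # agreement with kl_standard_normal for the standard prior
  set.seed(62)
  post <- list(mu = matrix(rnorm(6), 2, 3), log_var = matrix(rnorm(6, sd = 0.3), 2, 3))
  expect_equal(kl_auxiliary(post, list(list(mean = 0, log_var = 0))),
               kl_standard_normal(post), tolerance = 1e-10)
})

test_that("augmentation policies are seeded and match their stated distributions", {
  set.seed(63)
  x <- matrix(rnorm(400), 20, 20)
  expect_identical(augment(x, policy = character(0)), x)
  expect_equal(augment(x, policy = "mask", mask_prob = 1), matrix(0, 20, 20))
  expect_identical(augment(x, "jitter", seed = 4), augment(x, "jitter", seed = 4))
  expect_error(augment(x, policy = "rotate"), "unknown augmentation")

  # jitter SD: per-column SD of (x' - x) within 5% of 0.05 * column SD
  xb <- matrix(rnorm(1e4 * 4), 1e4, 4)
  xa <- augment(xb, "jitter", seed = 9)
  ratio <- apply(xa - xb, 2, sd) / (0.05 * apply(xb, 2, sd))
  expect_true(all(abs(ratio - 1) < 0.05))

  # mask probability ~ 0.1
  xm <- augment(xb + 10, "mask", seed = 10)
  expect_lt(abs(mean(xm == 0) - 0.1), 0.01)

  # scale factors within the stated range, one per subject
  xs <- augment(matrix(1, 50, 3), "scale", seed = 11)
  expect_true(all(xs >= 0.9 & xs <= 1.1))
  expect_equal(xs[, 1], xs[, 2])
})

test_that("contrastive loss matches closed forms and is scale invariant", {
  d <- 4
  z <- matrix(c(1, rep(0, d - 1)), 1)
  # K orthogonal negatives, positive = anchor, tau = 1 -> log(1 + K/e)
  K <- 3
  negs <- diag(d)[2:(K + 1), , drop = FALSE]
  expect_equal(contrastive_loss(z, z, negs, tau = 1), log(1 + K / exp(1)), tolerance = 1e-10)

  # one negative identical to the positive -> log 2
  expect_equal(contrastive_loss(z, z, z, tau = 0.37), log(2), tolerance = 1e-12)

  # cosine: invariant to positive rescaling of any embedding
  set.seed(64)
  zb <- matrix(rnorm(12), 3, 4); zp <- matrix(rnorm(12), 3, 4)
  expect_equal(contrastive_loss(zb, zp, tau = 0.1),
               contrastive_loss(5 * zb, zp, tau = 0.1), tolerance = 1e-10)
  expect_gte(contrastive_loss(zb, zp, tau = 0.1), 0)

  # -> 0 as the positive similarity dominates (tau -> small, aligned pair)
  expect_lt(contrastive_loss(z, z, negs, tau = 0.05), 1e-8)
  expect_warning(contrastive_loss(matrix(0, 1, d), z, negs), "zero-norm")
})

test_that("pretraining objective is linear in its components", {
  out <- pretrain_objective(1.1, 0.5, 2.0, lambda_kl = 0.5, lambda_contrast = 2)
  expect_equal(out$total, 1.1 + 0.5 * 0.5 + 2 * 2.0, tolerance = 1e-12)
  expect_equal(Reduce(`+`, out$components), out$total, tolerance = 1e-12)
  out0 <- pretrain_objective(1.1, 0.5, 2.0, lambda_kl = 0, lambda_contrast = 0)
  expect_equal(out0$total, 1.1)
  expect_error(pretrain_objective(1, 1, 1, lambda_kl = -1), "non-negative")
})

test_that("temperature sweep never produces non-finite losses on a default cohort", {
  cohort <- simulate_cohort(n = 40, d_x = 10, d_y = 6, k = 3, seed = 3)
  x <- scale(cohort$features$values)
  set.seed(65)
  spec <- encoder_spec(layer_widths = c(8L, 4L), dropout_rate = 0,
                       dropout_after = integer(0), batch_norm = FALSE)
  p <- lcen:::init_encoder_params(10, spec)
  z <- encode(x, spec, p)$mu
  zp <- encode(augment(x, c("jitter", "mask"), seed = 1), spec, p)$mu
  for (tau in c(0.05, 0.1, 0.5, 1.0)) {
    expect_true(is.finite(contrastive_loss(z, zp, tau = tau)))
  }
})

test_that("pretraining initialization lowers downstream RMSE after short fine-tuning", {
  # noisy-feature cohorts, where the encoder must denoise and a
  # self-supervised init matters most; majority of seeds must improve
  wins <- 0L
  for (s in 1:10) {
    cohort <- simulate_cohort(n = 300, d_x = 12, d_y = 6, k = 3, seed = 100 + s,
                              noise_sd_x = 0.4, noise_sd_y = 0.2)
    cfg <- lcen_config(
      encoder = list(layer_widths = c(10L, 3L), dropout_rate = 0,
                     dropout_after = integer(0), activation = "gelu",
                     batch_norm = FALSE),
      decoder = list(residual_block = FALSE),
      attention = list(enabled = FALSE),
      lambdas = list(kl = 0.001, graph = 0, hierarchy = 0),
      multi_task = list(enabled = FALSE),
      training = list(max_epochs = 10L, patience = 10L, lr = 0.01, batch_size = 32L),
      pretrain = list(epochs = 25L, lr = 0.01)
    )
    pre <- lcen_pretrain(cohort$features, config = cfg, seed = s)
    fit_pre <- lcen(cohort$features, cohort$phenotypes, config = cfg, seed = s, init = pre)
    fit_raw <- lcen(cohort$features, cohort$phenotypes, config = cfg, seed = s)
    if (fit_pre$metrics$val_rmse < fit_raw$metrics$val_rmse) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
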