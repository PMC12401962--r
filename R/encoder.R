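# Variational encoder: MLP trunk with GELU/batch-norm/dropout, Gaussian
# posterior heads, reparameterized sampling, and the latent-space regularizers
# (variance/proximity control, KL to the isotropic prior, and the variational
# mutual-information bound).

LOGVAR_MIN <- -20
LOGVAR_MAX <- 20

#' Encoder architecture specification
#'
#' Fully connected trunk; the last width is the latent dimension `d_z`, from
#' which two linear heads produce the posterior mean and log-variance. The
#' defaults follow the reference architecture: widths 512/256/128/64, GELU,
#' batch normalization after every layer, dropout 0.3 after layers 2 and 3.
#'
#' @param layer_widths Integer vector of trunk widths; last entry is `d_z`.
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param dropout_after Integer indices of trunk layers followed by dropout.
#' @param activation One of `"gelu"`, `"relu"`, `"tanh"`, `"linear"`.
#' @param batch_norm Apply batch normalization after each trunk layer.
#' @return An object of class `lcen_encoder_spec`.
#' @export
encoder_spec <- function(layer_widths = c(512L, 256L, 128L, 64L),
                         dropout_rate = 0.3,
                         dropout_after = c(2L, 3L),
                         activation = "gelu",
                         batch_norm = TRUE) {
  stopifnot(length(layer_widths) >= 1L, all(layer_widths >= 1L))
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)", call. = FALSE)
  activation_fun(activation)  # validates the name
  structure(list(layer_widths = as.integer(layer_widths),
                 dropout_rate = dropout_rate,
                 dropout_after = as.integer(dropout_after),
                 activation = activation,
                 batch_norm = batch_norm,
                 d_z = as.integer(layer_widths[length(layer_widths)])),
            class = "lcen_encoder_spec")
}

xavier <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

# Initialize encoder parameters (call inside with_seed()).
init_encoder_params <- function(d_x, spec) {
  widths <- spec$layer_widths
  L <- length(widths)
  p <- list(W = vector("list", L), b = vector("list", L))
  fan <- d_x
  for (l in seq_len(L)) {
    p$W[[l]] <- xavier(fan, widths[l])
    p$b[[l]] <- matrix(0, 1, widths[l])
    fan <- widths[l]
  }
  if (spec$batch_norm) {
    p$bn_gamma <- lapply(widths, function(w) matrix(1, 1, w))
    p$bn_beta <- lapply(widths, function(w) matrix(0, 1, w))
    p$bn_rmean <- lapply(widths, function(w) matrix(0, 1, w))
    p$bn_rvar <- lapply(widths, function(w) matrix(1, 1, w))
  }
  d_z <- spec$d_z
  p$W_mu <- xavier(d_z, d_z); p$b_mu <- matrix(0, 1, d_z)
  # posterior starts near-deterministic (sigma ~ 0.14) so early reconstruction
  # gradients are not swamped by reparameterization noise
  p$W_lv <- matrix(0, d_z, d_z); p$b_lv <- matrix(-4, 1, d_z)
  p
}

# Differentiable encoder forward. `pn` holds node-wrapped parameters; in
# training mode batch statistics drive the normalization and `dropout_masks`
# (inverted-dropout multipliers) are applied; in eval mode running statistics
# are used and dropout is off. Returns list(mu, log_var, bn_stats).
encode_node <- function(tape, xn, spec, pn, training = FALSE, dropout_masks = NULL) {
  act <- activation_fun(spec$activation)
  h <- xn
  bn_stats <- list()
  for (l in seq_along(spec$layer_widths)) {
    h <- ad_add_rvec(ad_matmul(h, pn$W[[l]]), pn$b[[l]])
    h <- act(h)
    if (spec$batch_norm) {
      if (training && nrow(h$value) > 1L) {
        mu_b <- ad_colmeans(h)
        var_b <- ad_scale(ad_colsums(ad_square(ad_sub_rvec(h, mu_b))), 1 / nrow(h$value))
        bn_stats[[l]] <- list(mean = ad_value(mu_b), var = ad_value(var_b))
        hc <- ad_sub_rvec(h, mu_b)
        h <- ad_mul_rvec(hc, ad_pow(ad_add(var_b, ad_const(tape, matrix(1e-5, 1, ncol(h$value)))), -0.5))
      } else {
        rm_ <- ad_value(pn$bn_rmean[[l]])
        rv_ <- ad_value(pn$bn_rvar[[l]])
        h <- ad_mul_rvec(ad_sub_rvec(h, ad_const(tape, rm_)),
                         ad_const(tape, 1 / sqrt(rv_ + 1e-5)))
      }
      h <- ad_add_rvec(ad_mul_rvec(h, pn$bn_gamma[[l]]), pn$bn_beta[[l]])
    }
    if (training && l %in% spec$dropout_after && spec$dropout_rate > 0 &&
        !is.null(dropout_masks[[as.character(l)]])) {
      h <- ad_mul(h, ad_const(tape, dropout_masks[[as.character(l)]]))
    }
  }
  mu <- ad_add_rvec(ad_matmul(h, pn$W_mu), pn$b_mu)
  lv <- ad_clamp(ad_add_rvec(ad_matmul(h, pn$W_lv), pn$b_lv), LOGVAR_MIN, LOGVAR_MAX)
  list(mu = mu, log_var = lv, bn_stats = bn_stats)
}

#' Encode a feature batch into a variational posterior
#'
#' Runs the encoder trunk and posterior heads in evaluation mode (dropout off,
#' running batch-norm statistics), returning per-subject Gaussian posterior
#' parameters. Deterministic: repeated calls on the same batch are identical.
#'
#' @param x A [feature_matrix()] or numeric matrix (subjects in rows).
#' @param spec An [encoder_spec()].
#' @param params Encoder parameters (from a fitted model's `$params$encoder`
#'   or [init_lcen_params()]).
#' @return An object of class `lcen_posterior`: list with `mu` and `log_var`
#'   matrices (batch x d_z).
#' @export
encode <- function(x, spec, params) {
  xv <- if (inherits(x, "lcen_features")) x$values else as.matrix(x)
  if (ncol(xv) != nrow(params$W[[1]])) {
    stop(sprintf("encoder expects %d input features, got %d",
                 nrow(params$W[[1]]), ncol(xv)), call. = FALSE)
  }
  tp <- ad_tape()
  pn <- wrap_params(tp, params)
  out <- encode_node(tp, ad_const(tp, xv), spec, pn, training = FALSE)
  structure(list(mu = ad_value(out$mu), log_var = ad_value(out$log_var)),
            class = "lcen_posterior")
}

#' Reparameterized sample from a posterior
#'
#' Draws `z = mu + sigma * eps` with `eps ~ N(0, I)` from a seeded stream, so
#' the same seed reproduces the same sample.
#'
#' @param post An `lcen_posterior` (or list with `mu`, `log_var`).
#' @param noise_seed Integer seed for the noise draw.
#' @return Matrix of latent samples, same shape as `post$mu`.
#' @export
reparameterize <- function(post, noise_seed = 1L) {
  mu <- post$mu; lv <- post$log_var
  eps <- with_seed(noise_seed, matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  mu + exp(0.5 * lv) * eps
}

#' KL divergence of the posterior from the standard-normal prior
#'
#' Closed-form diagonal-Gaussian KL to `N(0, I)`, summed over latent
#' dimensions and averaged over the batch. Always non-negative; zero iff the
#' posterior is exactly standard normal.
#'
#' @param post An `lcen_posterior`; `mu`/`log_var` may be matrices or tape
#'   nodes (then a differentiable node is returned).
#' @return Non-negative scalar (or node).
#' @export
#' @examples
#' kl_standard_normal(list(mu = matrix(1), log_var = matrix(0)))  # 0.5
kl_standard_normal <- function(post) {
  plain <- !is_ad(post$mu) && !is_ad(post$log_var)
  tp <- tape_of(post$mu, post$log_var)
  mu <- as_node(tp, post$mu); lv <- as_node(tp, post$log_var)
  lv <- ad_clamp(lv, LOGVAR_MIN, LOGVAR_MAX)
  n <- nrow(mu$value)
  per <- ad_sub(ad_add(ad_square(mu), ad_exp(lv)),
                ad_add(lv, ad_const(tp, matrix(1, n, ncol(mu$value)))))
  kl <- ad_scale(ad_sum(per), 0.5 / n)
  if (plain) ad_value(kl)[1] else kl
}

#' Latent variance/proximity regularizer
#'
#' Sum over latent dimensions of the batch variance of `z`, plus `beta` times
#' the mean squared distance between each `z_i` and a standard-normal prior
#' draw paired with it. The variance term's sign is configurable
#' (`variance_sign = -1` rewards diversity instead of penalizing it).
#'
#' @param z Latent batch (matrix or node), at least 2 rows for the variance
#'   term (a single row yields variance 0 with a warning).
#' @param prior_draw Matrix of prior draws, same shape as `z` (see
#'   [draw_latent_prior()]).
#' @param beta Weight of the proximity term.
#' @param variance_sign `+1` (as printed) or `-1`.
#' @return Scalar (or node).
#' @export
latent_regularizer <- function(z, prior_draw, beta = 1, variance_sign = 1) {
  stopifnot(variance_sign %in% c(-1, 1))
  plain <- !is_ad(z)
  tp <- tape_of(z)
  zn <- as_node(tp, z)
  n <- nrow(zn$value)
  if (n < 2L) {
    warning("batch of 1: variance term defined as 0")
    var_term <- ad_const(tp, 0)
  } else {
    var_term <- ad_sum(ad_colvars(zn))
  }
  prox <- ad_scale(ad_sum(ad_square(ad_sub(zn, as_node(tp, prior_draw)))), 1 / n)
  total <- ad_add(ad_scale(var_term, variance_sign), ad_scale(prox, beta))
  if (plain) ad_value(total)[1] else total
}

#' Seeded standard-normal prior draw paired with a batch
#' @param n,d Batch size and latent dimension.
#' @param seed Integer seed.
#' @return n x d matrix of N(0, 1) draws.
#' @export
draw_latent_prior <- function(n, d, seed = 1L) {
  with_seed(seed, matrix(stats::rnorm(n * d), n, d))
}

# log q(z | x) under a diagonal Gaussian posterior, per subject (n x 1).
gaussian_logq_node <- function(zn, mu, lv) {
  tp <- zn$tape
  d <- ncol(mu$value)
  diff2 <- ad_square(ad_sub(zn, mu))
  quad <- ad_mul(diff2, ad_exp(ad_scale(lv, -1)))
  per <- ad_scale(ad_rowsums(ad_add(quad, lv)), -0.5)
  ad_add(per, ad_const(tp, matrix(-0.5 * d * log(2 * pi), nrow(mu$value), 1)))
}

#' Variational lower bound on the latent/input mutual information
#'
#' Monte-Carlo estimate of `E_q[log p(x|z)] - E_q[log q(z|x)]` using `S`
#' reparameterized samples. The mutual-information regularizer used in the
#' composite latent objective is the negative of this bound.
#'
#' @param x Feature batch (matrix or [feature_matrix()]); passed to
#'   `decoder_loglik`.
#' @param post An `lcen_posterior` (matrices or nodes).
#' @param decoder_loglik Function `(x, z) -> n x 1` per-subject
#'   log-likelihood `log p(x_i | z_i)`; must return a node when given one.
#' @param n_samples Number of Monte-Carlo samples (default 1).
#' @param seed Seed for the sample draws.
#' @return Scalar bound (or node). Larger is better.
#' @export
mi_lower_bound <- function(x, post, decoder_loglik, n_samples = 1L, seed = 1L) {
  plain <- !is_ad(post$mu) && !is_ad(post$log_var)
  tp <- tape_of(post$mu, post$log_var)
  mu <- as_node(tp, post$mu)
  lv <- ad_clamp(as_node(tp, post$log_var), LOGVAR_MIN, LOGVAR_MAX)
  n <- nrow(mu$value); d <- ncol(mu$value)
  acc <- NULL
  for (s in seq_len(n_samples)) {
    eps <- with_seed(derive_seed(seed, s), matrix(stats::rnorm(n * d), n, d))
    zn <- ad_add(mu, ad_mul(ad_exp(ad_scale(lv, 0.5)), ad_const(tp, eps)))
    ll <- decoder_loglik(x, zn)
    if (!is_ad(ll)) ll <- ad_const(tp, matrix(ll, ncol = 1))
    if (any(!is.finite(ad_value(ll)))) {
      stop(sprintf("non-finite decoder log-likelihood at batch index %d",
                   which(!is.finite(ad_value(ll)))[1]), call. = FALSE)
    }
    term <- ad_mean(ad_sub(ll, gaussian_logq_node(zn, mu, lv)))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  bound <- ad_scale(acc, 1 / n_samples)
  if (plain) ad_value(bound)[1] else bound
}

#' Composite latent objective
#'
#' `R_latent + lambda_mutual * R_mutual`, where `R_latent` is
#' [latent_regularizer()] and `R_mutual` is the negated
#' [mi_lower_bound()]. Components are itemized in the result.
#'
#' @param z Latent batch (matrix or node).
#' @param post Posterior used for the mutual-information bound.
#' @param x Feature batch for the decoder log-likelihood.
#' @param decoder_loglik See [mi_lower_bound()]; required when
#'   `lambda_mutual > 0`.
#' @param prior_draw Prior draw for the proximity term.
#' @param lambda_mutual Non-negative weight of the mutual-information term.
#' @param beta,variance_sign Passed to [latent_regularizer()].
#' @param n_samples,seed Passed to [mi_lower_bound()].
#' @return List `total` (scalar or node) and `components` (named).
#' @export
latent_total <- function(z, post, x = NULL, decoder_loglik = NULL, prior_draw,
                         lambda_mutual = 0.1, beta = 1, variance_sign = 1,
                         n_samples = 1L, seed = 1L) {
  check_nonneg(lambda_mutual, "lambda_mutual")
  r_latent <- latent_regularizer(z, prior_draw, beta = beta, variance_sign = variance_sign)
  if (lambda_mutual > 0) {
    if (is.null(decoder_loglik)) stop("decoder_loglik required when lambda_mutual > 0", call. = FALSE)
    bound <- mi_lower_bound(x, post, decoder_loglik, n_samples = n_samples, seed = seed)
    r_mutual <- if (is_ad(bound)) ad_scale(bound, -1) else -bound
  } else {
    r_mutual <- if (is_ad(r_latent)) ad_const(r_latent$tape, 0) else 0
  }
  total <- if (is_ad(r_latent) || is_ad(r_mutual)) {
    ad_add(r_latent, ad_scale(as_node(tape_of(r_latent, r_mutual), r_mutual), lambda_mutual))
  } else {
    r_latent + lambda_mutual * r_mutual
  }
  list(total = total, components = list(latent = r_latent, mutual = r_mutual))
}

# Wrap a (possibly nested) parameter list as tape nodes.
wrap_params <- function(tape, params) {
  rapply(params, function(m) ad_const(tape, m), classes = "matrix", how = "replace")
}
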