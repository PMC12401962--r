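# Self-supervised pretraining: input reconstruction through a mirrored
# decoder, auxiliary-prior KL regularization, augmentation policies for
# positive pairs, and the contrastive (InfoNCE-style) objective.

init_input_decoder_params <- function(spec, d_x) {
  widths <- rev(spec$layer_widths)  # mirror the encoder
  L <- length(widths)
  p <- list(W = vector("list", L), b = vector("list", L))
  fan <- spec$d_z
  for (l in seq_len(L)) {
    out <- if (l < L) widths[l + 1L] else d_x
    p$W[[l]] <- xavier(fan, out)
    p$b[[l]] <- matrix(0, 1, out)
    fan <- out
  }
  p
}

# Differentiable mirrored decoder: hidden layers use the encoder activation,
# the output layer is linear.
input_decode_node <- function(zn, pn, activation = "gelu") {
  act <- activation_fun(activation)
  h <- zn
  L <- length(pn$W)
  for (l in seq_len(L)) {
    h <- ad_add_rvec(ad_matmul(h, pn$W[[l]]), pn$b[[l]])
    if (l < L) h <- act(h)
  }
  h
}

#' Input reconstruction through the mirrored decoder
#'
#' Encodes the batch (posterior mean, eval mode), decodes it back to feature
#' space with a decoder mirroring the encoder widths in reverse, and returns
#' the reconstruction and the batch-mean squared reconstruction norm.
#'
#' @param x Feature batch (matrix or [feature_matrix()]).
#' @param encoder List with `spec` ([encoder_spec()]) and `params`.
#' @param input_decoder Parameters from the fitted model (mirror layout; see
#'   the pretraining trainer).
#' @return List `x_hat` (matrix) and `loss` (scalar).
#' @export
reconstruct_input <- function(x, encoder, input_decoder) {
  xv <- if (inherits(x, "lcen_features")) x$values else as.matrix(x)
  post <- encode(xv, encoder$spec, encoder$params)
  tp <- ad_tape()
  pn <- wrap_params(tp, input_decoder)
  xh <- ad_value(input_decode_node(ad_const(tp, post$mu), pn, encoder$spec$activation))
  loss <- mean(rowSums((xv - xh)^2))
  list(x_hat = xh, loss = loss)
}

#' KL divergence to a set of auxiliary diagonal-Gaussian priors
#'
#' Sums, over the supplied priors, the closed-form KL divergence of the
#' posterior from each prior, averaged over the batch. With a single
#' standard-normal prior this reduces to [kl_standard_normal()].
#'
#' @param post An `lcen_posterior` (matrices or nodes).
#' @param priors List of priors, each a list with `mean` and `log_var`
#'   (scalars, length-d_z vectors, or 1 x d_z matrices).
#' @return Non-negative scalar (or node).
#' @export
#' @examples
#' p <- list(mu = matrix(0), log_var = matrix(0))
#' kl_auxiliary(p, list(list(mean = 1, log_var = 0)))  # 0.5
kl_auxiliary <- function(post, priors = list(list(mean = 0, log_var = 0))) {
  plain <- !is_ad(post$mu) && !is_ad(post$log_var)
  tp <- tape_of(post$mu, post$log_var)
  mu <- as_node(tp, post$mu)
  lv <- ad_clamp(as_node(tp, post$log_var), LOGVAR_MIN, LOGVAR_MAX)
  n <- nrow(mu$value); d <- ncol(mu$value)
  acc <- NULL
  for (pr in priors) {
    pm <- matrix(rep_len(as.numeric(pr$mean), d), n, d, byrow = TRUE)
    plv <- matrix(rep_len(as.numeric(pr$log_var), d), n, d, byrow = TRUE)
    # KL(N(mu, s^2) || N(m, t^2)) = 0.5 [ log t^2/s^2 + (s^2 + (mu-m)^2)/t^2 - 1 ]
    s2 <- ad_exp(lv)
    quad <- ad_mul(ad_add(s2, ad_square(ad_sub(mu, ad_const(tp, pm)))),
                   ad_const(tp, exp(-plv)))
    per <- ad_scale(ad_sub(ad_add(ad_sub(ad_const(tp, plv), lv), quad),
                           ad_const(tp, matrix(1, n, d))), 0.5)
    term <- ad_scale(ad_sum(per), 1 / n)
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  if (plain) ad_value(acc)[1] else acc
}

#' Stochastic feature augmentations for contrastive pretraining
#'
#' Applies the selected policies in order: `jitter` adds Gaussian noise with
#' SD `0.05 * column SD`; `mask` zeroes each entry independently with
#' probability 0.1; `scale` multiplies each subject's row by a
#' `U(0.9, 1.1)` factor. Seeded and reproducible.
#'
#' @param x Feature batch (matrix or [feature_matrix()]).
#' @param policy Character subset of `c("jitter", "mask", "scale")`.
#' @param seed Integer seed.
#' @param jitter_sd_frac,mask_prob,scale_range Policy parameters.
#' @return Augmented matrix, same shape as the input values.
#' @export
augment <- function(x, policy = c("jitter", "mask"), seed = 1L,
                    jitter_sd_frac = 0.05, mask_prob = 0.1,
                    scale_range = c(0.9, 1.1)) {
  xv <- if (inherits(x, "lcen_features")) x$values else as.matrix(x)
  if (length(policy) && !all(policy %in% c("jitter", "mask", "scale"))) {
    stop(sprintf("unknown augmentation policy: %s",
                 paste(setdiff(policy, c("jitter", "mask", "scale")), collapse = ", ")),
         call. = FALSE)
  }
  with_seed(seed, {
    for (p in policy) {
      if (p == "jitter") {
        sds <- apply(xv, 2, stats::sd); sds[!is.finite(sds)] <- 0
        noise <- matrix(stats::rnorm(length(xv)), nrow(xv), ncol(xv))
        xv <- xv + noise * matrix(jitter_sd_frac * sds, nrow(xv), ncol(xv), byrow = TRUE)
      } else if (p == "mask") {
        keep <- matrix(stats::runif(length(xv)) >= mask_prob, nrow(xv), ncol(xv))
        xv <- xv * keep
      } else if (p == "scale") {
        f <- stats::runif(nrow(xv), scale_range[1], scale_range[2])
        xv <- xv * f
      }
    }
    xv
  })
}

#' Contrastive (InfoNCE) loss with cosine similarity
#'
#' For each anchor embedding, the positive is its augmented counterpart and
#' the negatives are the other rows of `z_negs` (in-batch negatives by
#' default). The loss is the mean over anchors of
#' `-log[ exp(sim+/tau) / (exp(sim+/tau) + sum_k exp(sim-_k/tau)) ]` with
#' cosine similarity; it is invariant to positive rescaling of any embedding.
#'
#' @param z Anchor embeddings (matrix or node), one row per anchor.
#' @param z_pos Positive embeddings, aligned rows.
#' @param z_negs Negative embeddings; defaults to the other rows of `z_pos`
#'   (in-batch negatives). Each anchor uses every row except its own index.
#' @param tau Temperature (> 0), default 0.1.
#' @return Non-negative scalar (or node).
#' @export
contrastive_loss <- function(z, z_pos, z_negs = NULL, tau = 0.1) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  plain <- !is_ad(z) && !is_ad(z_pos) && !is_ad(z_negs)
  tp <- tape_of(z, z_pos, z_negs)
  zn <- as_node(tp, z); zp <- as_node(tp, z_pos)
  inbatch <- is.null(z_negs)
  ng <- if (inbatch) zp else as_node(tp, z_negs)
  n <- nrow(zn$value)
  # row-normalize (epsilon-guarded against zero-norm embeddings)
  normalize <- function(a) {
    nrm2 <- ad_rowsums(ad_square(a))
    if (any(ad_value(nrm2) < 1e-24)) warning("zero-norm embedding; cosine epsilon-guarded")
    inv <- ad_pow(ad_add(nrm2, ad_const(tp, matrix(1e-12, nrow(a$value), 1))), -0.5)
    ad_mul_cvec(a, inv)
  }
  zu <- normalize(zn); pu <- normalize(zp); gu <- if (inbatch) pu else normalize(ng)
  sim_pos <- ad_rowsums(ad_mul(zu, pu))              # n x 1 cosine with positive
  sims <- ad_matmul(zu, ad_t(gu))                    # n x K similarities
  e_pos <- ad_exp(ad_scale(sim_pos, 1 / tau))
  e_all <- ad_exp(ad_scale(sims, 1 / tau))
  if (inbatch) {
    # negatives are the other subjects' positives: drop own column
    mask <- matrix(1, n, n); diag(mask) <- 0
    denom_neg <- ad_rowsums(ad_mul(e_all, ad_const(tp, mask)))
  } else {
    denom_neg <- ad_rowsums(e_all)
  }
  frac <- ad_mul(e_pos, ad_pow(ad_add(e_pos, denom_neg), -1))
  loss <- ad_scale(ad_sum(ad_log(frac)), -1 / n)
  if (plain) ad_value(loss)[1] else loss
}

#' Composite pretraining objective
#'
#' `L_recon + lambda_kl * L_KL + lambda_contrast * L_contrast`; components
#' are itemized and sum exactly to the total. Used to initialize the encoder
#' before supervised training.
#'
#' @param recon,kl,contrast Precomputed component values (scalars or nodes).
#' @param lambda_kl,lambda_contrast Non-negative weights.
#' @return List `total` and `components`.
#' @export
pretrain_objective <- function(recon, kl, contrast,
                               lambda_kl = 0.1, lambda_contrast = 1) {
  check_nonneg(c(lambda_kl, lambda_contrast), "pretrain lambdas")
  plain <- !is_ad(recon) && !is_ad(kl) && !is_ad(contrast)
  tp <- tape_of(recon, kl, contrast)
  comps <- list(reconstruction = as_node(tp, recon),
                kl = ad_scale(as_node(tp, kl), lambda_kl),
                contrast = ad_scale(as_node(tp, contrast), lambda_contrast))
  total <- Reduce(ad_add, comps)
  if (plain) {
    list(total = ad_value(total)[1], components = lapply(comps, function(c) ad_value(c)[1]))
  } else {
    list(total = total, components = comps)
  }
}
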