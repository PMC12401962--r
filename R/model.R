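# The fitting surface: configuration, parameter initialization, the
# differentiable forward pass assembling all objective components, the Adam
# trainer with early stopping, and pretraining.

#' Model and training configuration
#'
#' Returns the full default configuration as a nested list; any subset can be
#' overridden via `...` (e.g. `lcen_config(encoder = list(layer_widths =
#' c(32, 8)))`). Unknown keys are rejected. Defaults follow the reference
#' setup: encoder 512/256/128/64 with GELU + batch norm and dropout 0.3 after
#' layers 2 and 3; Adam with learning rate 0.001, batch size 32, at most 100
#' epochs, early-stopping patience 10; 70/15/15 train/validation/test split.
#'
#' @param ... Named overrides, nested lists merged onto the defaults.
#' @return Configuration list of class `lcen_config`.
#' @export
lcen_config <- function(...) {
  defaults <- list(
    encoder = list(layer_widths = c(512L, 256L, 128L, 64L), dropout_rate = 0.3,
                   dropout_after = c(2L, 3L), activation = "gelu", batch_norm = TRUE),
    decoder = list(hidden_widths = c(64L, 128L), residual_block = TRUE,
                   adjacency_mode = "fixed", solver = "closed_form",
                   unroll_steps = 8L, delta = 0.05),
    attention = list(enabled = TRUE, level_hidden = 32L, shared_alpha = TRUE,
                     entropy_weight = 0),
    lambdas = list(kl = 0.1, latent = 0, mutual = 0.1, beta = 1,
                   graph = 0.01, sparsity = 0.01, symmetry = 0.01,
                   smooth = 0.01, disentangle = 0, sparse = 0,
                   hierarchy = 0.1, uncertainty = 0, attention = 0.01),
    multi_task = list(enabled = TRUE, ema_beta = 0.9, epsilon = 1e-8),
    training = list(lr = 0.001, batch_size = 32L, max_epochs = 100L,
                    patience = 10L, optimizer = "adam",
                    split = c(0.7, 0.15, 0.15), structural_residual = NA),
    pretrain = list(epochs = 30L, lr = 0.001, tau = 0.1,
                    policy = c("jitter", "mask"), lambda_kl = 0.1,
                    lambda_contrast = 1),
    latent_variance_sign = 1
  )
  merged <- merge_config(defaults, list(...))
  class(merged) <- "lcen_config"
  merged
}

merge_config <- function(defaults, overrides, path = "") {
  if (!length(overrides)) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown config key%s: %s%s", if (length(bad) > 1) "s" else "",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Read a configuration from a YAML file
#' @param path YAML file with (a subset of) the [lcen_config()] keys.
#' @return Validated configuration.
#' @export
read_config <- function(path) {
  do.call(lcen_config, yaml::read_yaml(path))
}

# ---- parameters --------------------------------------------------------------

#' Initialize all model parameters
#'
#' @param d_x,d_y Input and phenotype dimensions.
#' @param config An [lcen_config()].
#' @param hierarchy A [hierarchy_spec()] (needed when attention or multi-task
#'   objectives are enabled).
#' @param seed Integer seed for the weight draws.
#' @return Nested parameter list (`encoder`, `decoder`, optional `attention`,
#'   `log_var_task`).
#' @export
init_lcen_params <- function(d_x, d_y, config = lcen_config(), hierarchy = NULL,
                             seed = 1L) {
  enc_spec <- do.call(encoder_spec, config$encoder)
  dec_spec <- do.call(decoder_spec, config$decoder[c("hidden_widths", "residual_block",
                                                     "adjacency_mode", "solver",
                                                     "unroll_steps")])
  with_seed(seed, {
    p <- list(encoder = init_encoder_params(d_x, enc_spec),
              decoder = init_decoder_params(enc_spec$d_z, d_y, dec_spec,
                                            config$encoder$activation))
    if (isTRUE(config$attention$enabled)) {
      if (is.null(hierarchy)) hierarchy <- default_hierarchy(d_y)
      p$attention <- init_attention_params(enc_spec$d_z, hierarchy,
                                           config$attention$level_hidden, d_y)
    }
    if (!is.null(hierarchy)) {
      p$log_var_task <- matrix(0, 1, hierarchy$n_levels)
    }
    p
  })
}

nested_map <- function(x, fn) {
  if (is.list(x)) {
    out <- x
    for (i in seq_along(x)) {
      v <- nested_map(x[[i]], fn)
      if (is.null(v)) out[i] <- list(NULL) else out[[i]] <- v
    }
    out
  } else if (is.null(x)) NULL else fn(x)
}

nested_map2 <- function(x, y, fn) {
  if (is.list(x)) {
    out <- x
    for (i in seq_along(x)) {
      v <- nested_map2(x[[i]], if (i <= length(y)) y[[i]] else NULL, fn)
      if (is.null(v)) out[i] <- list(NULL) else out[[i]] <- v
    }
    out
  } else if (is.null(x)) NULL else fn(x, y)
}

# ---- optimizer ---------------------------------------------------------------

adam_init <- function(params) {
  list(m = nested_map(params, function(p) array(0, dim(p))),
       v = nested_map(params, function(p) array(0, dim(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- nested_map2(state$m, grads, function(m, g) {
    if (is.null(g)) m else beta1 * m + (1 - beta1) * g
  })
  state$v <- nested_map2(state$v, grads, function(v, g) {
    if (is.null(g)) v else beta2 * v + (1 - beta2) * g * g
  })
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  params <- nested_map2(params, nested_map2(state$m, state$v, function(m, v) list(m = m, v = v)),
                        function(p, mv) {
                          p - lr * (mv$m / corr1) / (sqrt(mv$v / corr2) + eps)
                        })
  list(params = params, state = state)
}

sgd_step <- function(params, grads, lr) {
  nested_map2(params, grads, function(p, g) if (is.null(g)) p else p - lr * g)
}

# ---- forward + loss ----------------------------------------------------------

# Assemble the full differentiable objective for one batch. Returns nodes for
# the total loss, the itemized components, the per-task losses (for adaptive
# weighting), alpha, and the encoder trunk parameter nodes (for gradient
# statistics).
lcen_loss_node <- function(tape, xb, yb, params, config, specs, hierarchy,
                           A_fixed, task_lambdas, training = TRUE,
                           noise_seed = 1L) {
  lam <- config$lambdas
  pn <- wrap_params(tape, params)
  n <- nrow(xb)

  masks <- NULL
  if (training && specs$encoder$dropout_rate > 0) {
    masks <- with_seed(derive_seed(noise_seed, 17), {
      ms <- list()
      for (l in intersect(specs$encoder$dropout_after,
                          seq_along(specs$encoder$layer_widths))) {
        w <- specs$encoder$layer_widths[l]
        keep <- matrix(stats::runif(n * w) >= specs$encoder$dropout_rate, n, w)
        ms[[as.character(l)]] <- keep / (1 - specs$encoder$dropout_rate)
      }
      ms
    })
  }

  enc <- encode_node(tape, ad_const(tape, xb), specs$encoder, pn$encoder,
                     training = training, dropout_masks = masks)
  eps <- with_seed(derive_seed(noise_seed, 29),
                   matrix(stats::rnorm(n * specs$encoder$d_z), n, specs$encoder$d_z))
  z <- ad_add(enc$mu, ad_mul(ad_exp(ad_scale(enc$log_var, 0.5)), ad_const(tape, eps)))

  # adjacency: fixed constant or symmetric-by-construction learnable
  learnable <- specs$decoder$adjacency_mode == "learnable"
  an <- if (learnable) symmetrize_adjacency(pn$decoder$A_raw)
        else ad_const(tape, A_fixed)

  # base drive in phenotype space
  alpha <- NULL
  if (isTRUE(config$attention$enabled)) {
    h <- level_projections(z, pn$attention, specs$encoder$activation)
    alpha <- attention_weights(h, pn$attention$u_l, config$attention$shared_alpha)
    y_levels <- lapply(seq_len(hierarchy$n_levels), function(l) {
      ad_add_rvec(ad_matmul(h[[l]], pn$attention$W_head[[l]]), pn$attention$b_head[[l]])
    })
    base <- aggregate_predictions(y_levels, alpha, hierarchy,
                                  d_y = ncol(yb))
  } else {
    base <- ad_add_rvec(ad_matmul(z, ad_t(pn$decoder$W_d)), pn$decoder$b_d)
  }

  structural <- isTRUE(config$training$structural_residual) ||
    (is.na(config$training$structural_residual) && learnable)
  y_pred <- if (structural && training) {
    # teacher-forced structural residual: y_hat = base + A y_obs; fitting this
    # is sparse symmetric regression of the message-passing equation itself
    ad_add(base, ad_matmul(ad_const(tape, yb), ad_t(an)))
  } else {
    decode_node(base, an, specs$decoder$solver, specs$decoder$unroll_steps)
  }
  if (specs$decoder$residual_block) {
    y_pred <- residual_refine_node(y_pred, pn$decoder, specs$encoder$activation)
  }

  ytn <- ad_const(tape, yb)
  task_cols <- hierarchy$level_dims
  task_losses <- lapply(task_cols, function(cols) {
    ad_scale(ad_sum(ad_square(ad_sub(ad_cols(ytn, cols), ad_cols(y_pred, cols)))), 1 / n)
  })

  comps <- list()
  mt <- NULL
  for (t in seq_along(task_losses)) {
    term <- ad_scale(task_losses[[t]], task_lambdas[t])
    mt <- if (is.null(mt)) term else ad_add(mt, term)
  }
  comps$reconstruction <- mt
  comps$kl <- ad_scale(kl_standard_normal(list(mu = enc$mu, log_var = enc$log_var)), lam$kl)

  if (lam$graph > 0) comps$graph <- ad_scale(graph_smoothness(y_pred, an), lam$graph)
  if (learnable) {
    pen <- graph_penalties(an)
    comps$sparsity <- ad_scale(pen$sparsity, lam$sparsity)
    comps$symmetry <- ad_scale(pen$asymmetry, lam$symmetry)
  }
  if (lam$latent > 0) {
    prior <- with_seed(derive_seed(noise_seed, 31),
                       matrix(stats::rnorm(n * specs$encoder$d_z), n, specs$encoder$d_z))
    comps$latent <- ad_scale(latent_regularizer(z, prior, beta = lam$beta,
                                                variance_sign = config$latent_variance_sign),
                             lam$latent)
  }
  if (lam$disentangle > 0 && n > 1) {
    comps$disentangle <- ad_scale(disentangle_penalty(z), lam$disentangle)
  }
  if (lam$sparse > 0) {
    comps$sparse <- ad_scale(ad_scale(ad_sum(ad_abs(y_pred)), 1 / n), lam$sparse)
  }
  if (lam$hierarchy > 0 && length(hierarchy$task_edges)) {
    preds_by_task <- lapply(task_cols, function(cols) ad_cols(y_pred, cols))
    ts <- task_spec(task_cols, hierarchy$task_edges)
    comps$hierarchy <- ad_scale(hierarchy_consistency(preds_by_task, ts), lam$hierarchy)
  }
  if (lam$uncertainty > 0 && !is.null(pn$log_var_task)) {
    preds_by_task <- lapply(task_cols, function(cols) ad_cols(y_pred, cols))
    true_by_task <- lapply(task_cols, function(cols) ad_cols(ytn, cols))
    comps$uncertainty <- ad_scale(uncertainty_loss(preds_by_task, true_by_task,
                                                   pn$log_var_task),
                                  lam$uncertainty)
  }
  if (!is.null(alpha)) {
    comps$attention <- ad_scale(ad_sum(ad_abs(alpha)), lam$attention)
    if (config$attention$entropy_weight > 0) {
      comps$attention_entropy <- ad_scale(
        ad_scale(ad_sum(ad_mul(alpha, ad_log(alpha))), -1),
        config$attention$entropy_weight)
    }
  }

  total <- Reduce(ad_add, comps)
  list(total = total, components = comps, task_losses = task_losses,
       alpha = alpha, pn = pn, bn_stats = enc$bn_stats)
}

# Deterministic predictions in eval mode (plain matrices, no tape kept).
lcen_forward_eval <- function(x, params, config, specs, hierarchy, A_use) {
  tp <- ad_tape()
  pn <- wrap_params(tp, params)
  enc <- encode_node(tp, ad_const(tp, x), specs$encoder, pn$encoder, training = FALSE)
  z <- enc$mu
  if (isTRUE(config$attention$enabled)) {
    h <- level_projections(z, pn$attention, specs$encoder$activation)
    alpha <- attention_weights(h, pn$attention$u_l, config$attention$shared_alpha)
    y_levels <- lapply(seq_len(hierarchy$n_levels), function(l) {
      ad_add_rvec(ad_matmul(h[[l]], pn$attention$W_head[[l]]), pn$attention$b_head[[l]])
    })
    base <- aggregate_predictions(y_levels, alpha, hierarchy, d_y = nrow(A_use))
  } else {
    base <- ad_add_rvec(ad_matmul(z, ad_t(pn$decoder$W_d)), pn$decoder$b_d)
    alpha <- NULL
  }
  y <- decode_node(base, ad_const(tp, A_use), specs$decoder$solver,
                   specs$decoder$unroll_steps)
  if (specs$decoder$residual_block) {
    y <- residual_refine_node(y, pn$decoder, specs$encoder$activation)
  }
  list(y = ad_value(y), z = ad_value(z), mu = ad_value(enc$mu),
       log_var = ad_value(enc$log_var),
       alpha = if (!is.null(alpha)) ad_value(alpha) else NULL)
}

# Current usable adjacency: learnable parameters are symmetrized and
# spectrally projected so the closed-form solve is defined.
current_adjacency <- function(params, config, A_fixed) {
  if (config$decoder$adjacency_mode == "learnable") {
    project_adjacency(symmetrize_adjacency(params$decoder$A_raw),
                      delta = config$decoder$delta, mode = "learnable")$adjacency
  } else {
    A_fixed
  }
}

#' Fit a latent cognitive embedding network
#'
#' Trains the full model -- variational encoder, graph-guided phenotype
#' decoder (fixed or learnable sparse symmetric adjacency), optional
#' hierarchical attention head -- by minimizing the composite objective
#' (multi-task reconstruction with gradient-norm adaptive weights, KL to the
#' standard-normal prior, graph smoothness, adjacency sparsity/symmetry,
#' hierarchy consistency, and optional latent/uncertainty terms) with
#' minibatch Adam, early stopping on validation loss, and full seeding.
#'
#' @param x Features: [feature_matrix()] or numeric matrix (subjects in
#'   rows). Columns are standardized internally; the scaling is stored and
#'   reapplied by `predict()`.
#' @param y Phenotypes: [phenotype_matrix()] or numeric matrix.
#' @param graph Optional fixed [phenotype_graph()] (projected to spectral
#'   radius `1 - delta` before use). Ignored when the adjacency is learnable.
#' @param hierarchy Optional [hierarchy_spec()]; defaults to three contiguous
#'   level groups over the phenotype columns.
#' @param config An [lcen_config()].
#' @param seed Integer seed controlling initialization, splits, minibatch
#'   order, dropout and reparameterization noise.
#' @param init Optional pretrained initialization from [lcen_pretrain()].
#' @param verbose Print a line per epoch.
#' @return An object of class `lcen` with elements `params`, `config`,
#'   `history` (one row per epoch with every loss component), `adjacency`
#'   (the usable adjacency), `alpha`, `split` (train/val/test indices),
#'   `hierarchy`, `metrics` (validation/test summaries) and scaling info.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n = 120, d_x = 12, d_y = 6, k = 2, seed = 1)
#' cfg <- lcen_config(encoder = list(layer_widths = c(16L, 4L), dropout_rate = 0,
#'                                   batch_norm = FALSE),
#'                    decoder = list(residual_block = FALSE),
#'                    attention = list(enabled = FALSE),
#'                    training = list(max_epochs = 5L))
#' fit <- lcen(cohort$features, cohort$phenotypes, graph = cohort$graph,
#'             config = cfg, seed = 1)
#' print(fit)
#' }
lcen <- function(x, y, graph = NULL, hierarchy = NULL, config = lcen_config(),
                 seed = 1L, init = NULL, verbose = FALSE) {
  xv <- if (inherits(x, "lcen_features")) x$values else as.matrix(x)
  yobj <- if (inherits(y, "lcen_phenotypes")) y else phenotype_matrix(y)
  yv <- yobj$values
  stopifnot(nrow(xv) == nrow(yv))
  n <- nrow(xv); d_x <- ncol(xv); d_y <- ncol(yv)

  # standardize features (constant columns -> zeros)
  centers <- colMeans(xv)
  scales <- apply(xv, 2, stats::sd)
  scales[!is.finite(scales) | scales == 0] <- 1
  xs <- sweep(sweep(xv, 2, centers), 2, scales, "/")

  specs <- list(encoder = do.call(encoder_spec, config$encoder),
                decoder = do.call(decoder_spec,
                                  config$decoder[c("hidden_widths", "residual_block",
                                                   "adjacency_mode", "solver",
                                                   "unroll_steps")]))
  hierarchy <- hierarchy %||% default_hierarchy(d_y)

  A_fixed <- if (!is.null(graph)) {
    project_adjacency(if (inherits(graph, "lcen_graph")) graph$adjacency else graph,
                      delta = config$decoder$delta)$adjacency
  } else {
    matrix(0, d_y, d_y)
  }

  params <- init_lcen_params(d_x, d_y, config, hierarchy, seed = derive_seed(seed, 1))
  if (!is.null(init)) {
    params$encoder <- init$encoder$params
  }

  sp <- split_dataset(n, config$training$split, seed = derive_seed(seed, 2))
  idx_tr <- sp$train; idx_val <- sp$val

  opt <- adam_init(params)
  tspec <- task_spec(hierarchy$level_dims, hierarchy$task_edges,
                     ema_beta = config$multi_task$ema_beta,
                     epsilon = config$multi_task$epsilon)
  task_lambdas <- rep(1, hierarchy$n_levels)

  bsz <- min(config$training$batch_size, length(idx_tr))
  best_val <- Inf; best_params <- params; patience_left <- config$training$patience
  history <- list()
  step_id <- 0L

  for (epoch in seq_len(config$training$max_epochs)) {
    ord <- with_seed(derive_seed(seed, 100 + epoch), sample(idx_tr))
    batches <- split(ord, ceiling(seq_along(ord) / bsz))
    comp_sums <- NULL; nb <- 0L
    alpha_last <- NULL
    for (b in batches) {
      if (length(b) < 2L) next  # batch statistics need two rows
      step_id <- step_id + 1L
      tp <- ad_tape()
      out <- lcen_loss_node(tp, xs[b, , drop = FALSE], yv[b, , drop = FALSE],
                            params, config, specs, hierarchy, A_fixed,
                            task_lambdas, training = TRUE,
                            noise_seed = derive_seed(seed, 1000 + step_id))
      vals <- vapply(out$components, function(c) ad_value(c)[1], numeric(1))
      if (any(!is.finite(vals))) {
        stop(sprintf("non-finite loss component '%s' at epoch %d",
                     names(vals)[which(!is.finite(vals))[1]], epoch), call. = FALSE)
      }
      g <- ad_backward(tp, out$total)
      grads <- nested_map(out$pn, function(nd) ad_grad(g, nd))
      if (config$training$optimizer == "adam") {
        upd <- adam_step(params, grads, opt, config$training$lr)
        params <- upd$params; opt <- upd$state
      } else {
        params <- sgd_step(params, grads, config$training$lr)
      }
      # batch-norm running statistics (momentum 0.9)
      if (specs$encoder$batch_norm && length(out$bn_stats)) {
        for (l in seq_along(out$bn_stats)) {
          st <- out$bn_stats[[l]]
          if (is.null(st)) next
          params$encoder$bn_rmean[[l]] <- 0.9 * params$encoder$bn_rmean[[l]] + 0.1 * st$mean
          params$encoder$bn_rvar[[l]] <- 0.9 * params$encoder$bn_rvar[[l]] + 0.1 * st$var
        }
      }
      # adaptive task weights from per-task gradient norms on the encoder trunk
      if (isTRUE(config$multi_task$enabled) && hierarchy$n_levels > 1L) {
        stats_t <- vapply(out$task_losses, function(lt) {
          gt <- ad_backward(tp, lt)
          s <- 0
          for (l in seq_along(out$pn$encoder$W)) {
            s <- s + sum(ad_grad(gt, out$pn$encoder$W[[l]])^2)
          }
          s
        }, numeric(1))
        aw <- adaptive_task_weights(stats_t, tspec)
        tspec <- aw$spec; task_lambdas <- aw$lambda
      }
      comp_sums <- if (is.null(comp_sums)) vals else {
        all_n <- union(names(comp_sums), names(vals))
        out_s <- setNames(numeric(length(all_n)), all_n)
        out_s[names(comp_sums)] <- comp_sums
        out_s[names(vals)] <- out_s[names(vals)] + vals
        out_s
      }
      nb <- nb + 1L
      if (!is.null(out$alpha)) alpha_last <- ad_value(out$alpha)
    }
    comp_means <- comp_sums / nb

    # validation loss: deterministic predictions through the solve path
    A_use <- current_adjacency(params, config, A_fixed)
    ev <- lcen_forward_eval(xs[idx_val, , drop = FALSE], params, config, specs,
                            hierarchy, A_use)
    val_loss <- mean(rowSums((yv[idx_val, , drop = FALSE] - ev$y)^2))

    row <- c(epoch = epoch, total = sum(comp_means), comp_means,
             val_loss = val_loss)
    if (!is.null(alpha_last)) {
      row <- c(row, setNames(as.numeric(alpha_last),
                             paste0("alpha_", seq_along(alpha_last))))
    }
    if (isTRUE(config$multi_task$enabled)) {
      row <- c(row, setNames(task_lambdas, paste0("lambda_task_", seq_along(task_lambdas))))
    }
    if (config$lambdas$uncertainty > 0 && !is.null(params$log_var_task)) {
      row <- c(row, setNames(exp(as.numeric(params$log_var_task)),
                             paste0("sigma2_task_", seq_len(ncol(params$log_var_task)))))
    }
    history[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, sum(comp_means), val_loss))
    }

    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- params
      patience_left <- config$training$patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }

  params <- best_params
  A_use <- current_adjacency(params, config, A_fixed)
  ev_val <- lcen_forward_eval(xs[idx_val, , drop = FALSE], params, config, specs,
                              hierarchy, A_use)
  ev_test <- lcen_forward_eval(xs[sp$test, , drop = FALSE], params, config, specs,
                               hierarchy, A_use)
  hist_df <- as.data.frame(do.call(rbind, lapply(history, function(r) {
    all_n <- unique(unlist(lapply(history, names)))
    out <- setNames(rep(NA_real_, length(all_n)), all_n)
    out[names(r)] <- r
    out
  })))

  structure(list(
    params = params, config = config, specs = specs, hierarchy = hierarchy,
    adjacency = A_use,
    A_fixed = A_fixed,
    alpha = ev_val$alpha,
    split = sp,
    history = hist_df,
    centers = centers, scales = scales,
    x = xv, y = yobj,
    metrics = list(
      val_rmse = sqrt(mean((yv[idx_val, , drop = FALSE] - ev_val$y)^2)),
      test_rmse = sqrt(mean((yv[sp$test, , drop = FALSE] - ev_test$y)^2)),
      best_val_loss = best_val,
      epochs_run = length(history)
    ),
    seed = seed
  ), class = "lcen")
}

#' Self-supervised pretraining of the encoder
#'
#' Optimizes input reconstruction through a mirrored decoder plus the
#' auxiliary-prior KL and a contrastive objective over augmented views
#' (InfoNCE with in-batch negatives, cosine similarity), initializing the
#' encoder before supervised fitting.
#'
#' @param x Features ([feature_matrix()] or matrix); standardized internally.
#' @param config An [lcen_config()]; the `pretrain` block sets epochs,
#'   learning rate, temperature, augmentation policy and loss weights.
#' @param seed Integer seed.
#' @param priors Auxiliary priors for [kl_auxiliary()]; default one standard
#'   normal.
#' @param verbose Print a line per epoch.
#' @return List with `encoder` (`spec`, `params`), `input_decoder`, and
#'   `history` (data.frame of loss components per epoch). Pass as `init =` to
#'   [lcen()].
#' @export
lcen_pretrain <- function(x, config = lcen_config(), seed = 1L,
                          priors = list(list(mean = 0, log_var = 0)),
                          verbose = FALSE) {
  xv <- if (inherits(x, "lcen_features")) x$values else as.matrix(x)
  centers <- colMeans(xv)
  scales <- apply(xv, 2, stats::sd)
  scales[!is.finite(scales) | scales == 0] <- 1
  xs <- sweep(sweep(xv, 2, centers), 2, scales, "/")
  n <- nrow(xs); d_x <- ncol(xs)
  spec <- do.call(encoder_spec, config$encoder)
  params <- with_seed(derive_seed(seed, 3), {
    list(encoder = init_encoder_params(d_x, spec),
         input_decoder = init_input_decoder_params(spec, d_x))
  })
  opt <- adam_init(params)
  bsz <- min(config$training$batch_size, n)
  pt <- config$pretrain
  history <- list()
  step_id <- 0L
  for (epoch in seq_len(pt$epochs)) {
    ord <- with_seed(derive_seed(seed, 5000 + epoch), sample(n))
    batches <- split(ord, ceiling(seq_along(ord) / bsz))
    sums <- c(reconstruction = 0, kl = 0, contrast = 0, total = 0); nb <- 0L
    for (b in batches) {
      if (length(b) < 2L) next
      step_id <- step_id + 1L
      xb <- xs[b, , drop = FALSE]
      x_aug <- augment(xb, policy = pt$policy, seed = derive_seed(seed, 9000 + step_id))
      tp <- ad_tape()
      pn <- wrap_params(tp, params)
      enc <- encode_node(tp, ad_const(tp, xb), spec, pn$encoder, training = FALSE)
      enc_aug <- encode_node(tp, ad_const(tp, x_aug), spec, pn$encoder, training = FALSE)
      xh <- input_decode_node(enc$mu, pn$input_decoder, spec$activation)
      recon <- ad_scale(ad_sum(ad_square(ad_sub(ad_const(tp, xb), xh))), 1 / length(b))
      klv <- kl_auxiliary(list(mu = enc$mu, log_var = enc$log_var), priors)
      ctr <- contrastive_loss(enc$mu, enc_aug$mu, tau = pt$tau)
      obj <- pretrain_objective(recon, klv, ctr, lambda_kl = pt$lambda_kl,
                                lambda_contrast = pt$lambda_contrast)
      vals <- vapply(obj$components, function(c) ad_value(c)[1], numeric(1))
      if (any(!is.finite(vals))) {
        stop(sprintf("non-finite pretraining component '%s' at epoch %d",
                     names(vals)[which(!is.finite(vals))[1]], epoch), call. = FALSE)
      }
      g <- ad_backward(tp, obj$total)
      grads <- nested_map(pn, function(nd) ad_grad(g, nd))
      upd <- adam_step(params, grads, opt, pt$lr)
      params <- upd$params; opt <- upd$state
      sums <- sums + c(vals, total = sum(vals)); nb <- nb + 1L
    }
    history[[epoch]] <- c(epoch = epoch, sums / nb)
    if (verbose) message(sprintf("pretrain epoch %3d  total %.5f", epoch, sums["total"] / nb))
  }
  list(encoder = list(spec = spec, params = params$encoder),
       input_decoder = params$input_decoder,
       history = as.data.frame(do.call(rbind, history)))
}
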