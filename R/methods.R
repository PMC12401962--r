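# S3 methods for fitted models.

#' @export
print.lcen <- function(x, ...) {
  cat("Latent cognitive embedding network\n")
  cat(sprintf("  subjects: %d   features: %d   phenotypes: %d   latent dim: %d\n",
              nrow(x$x), ncol(x$x), ncol(x$y$values), x$specs$encoder$d_z))
  cat(sprintf("  adjacency: %s   attention: %s   epochs run: %d\n",
              x$config$decoder$adjacency_mode,
              if (isTRUE(x$config$attention$enabled)) "on" else "off",
              x$metrics$epochs_run))
  cat(sprintf("  validation RMSE: %.4f   test RMSE: %.4f\n",
              x$metrics$val_rmse, x$metrics$test_rmse))
  if (!is.null(x$alpha)) {
    cat("  attention weights:", paste(sprintf("%.3f", x$alpha), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.lcen <- function(object, ...) {
  ans <- list(
    dims = c(n = nrow(object$x), d_x = ncol(object$x),
             d_y = ncol(object$y$values), d_z = object$specs$encoder$d_z),
    metrics = object$metrics,
    alpha = object$alpha,
    adjacency_edges = sum(abs(object$adjacency[upper.tri(object$adjacency)]) > 1e-3),
    final_components = utils::tail(object$history, 1),
    config = object$config
  )
  class(ans) <- "summary.lcen"
  ans
}

#' @export
print.summary.lcen <- function(x, ...) {
  cat("Latent cognitive embedding network -- summary\n\n")
  cat(sprintf("Subjects %d, features %d, phenotypes %d, latent dimension %d\n",
              x$dims["n"], x$dims["d_x"], x$dims["d_y"], x$dims["d_z"]))
  cat(sprintf("Epochs run: %d (early stopping patience %s)\n",
              x$metrics$epochs_run, x$config$training$patience))
  cat(sprintf("Validation RMSE %.4f, test RMSE %.4f\n",
              x$metrics$val_rmse, x$metrics$test_rmse))
  cat(sprintf("Adjacency edges above 1e-3: %d\n", x$adjacency_edges))
  if (!is.null(x$alpha)) {
    cat("Attention weights:", paste(sprintf("%.3f", x$alpha), collapse = " "), "\n")
  }
  cat("\nFinal-epoch loss components:\n")
  print(round(x$final_components, 5), row.names = FALSE)
  invisible(x)
}

#' Model coefficients: decoder loadings and adjacency
#'
#' @param object A fitted [lcen()] model.
#' @param ... Unused.
#' @return List with `W_d` (phenotype loadings, when the plain decoder head
#'   is active), `adjacency` (the usable, spectrally projected adjacency),
#'   and `alpha` (attention weights, when attention is enabled).
#' @export
coef.lcen <- function(object, ...) {
  list(W_d = object$params$decoder$W_d,
       adjacency = object$adjacency,
       alpha = object$alpha)
}

#' Predict phenotypes (or latent codes) for new subjects
#'
#' Applies the stored feature standardization, encodes in eval mode
#' (posterior mean), and decodes through the closed-form graph solve (plus
#' residual refinement when enabled).
#'
#' @param object A fitted [lcen()] model.
#' @param newdata Feature matrix or [feature_matrix()]; defaults to the
#'   training-time features.
#' @param type `"response"` (phenotype predictions), `"latent"` (posterior
#'   means), or `"posterior"` (list with mu and log_var).
#' @param ... Unused.
#' @return Matrix of predictions, or posterior list.
#' @export
predict.lcen <- function(object, newdata = NULL, type = c("response", "latent", "posterior"),
                         ...) {
  type <- match.arg(type)
  xv <- if (is.null(newdata)) object$x
        else if (inherits(newdata, "lcen_features")) newdata$values
        else as.matrix(newdata)
  xs <- sweep(sweep(xv, 2, object$centers), 2, object$scales, "/")
  ev <- lcen_forward_eval(xs, object$params, object$config, object$specs,
                          object$hierarchy, object$adjacency)
  switch(type,
         response = ev$y,
         latent = ev$mu,
         posterior = structure(list(mu = ev$mu, log_var = ev$log_var),
                               class = "lcen_posterior"))
}

#' @export
fitted.lcen <- function(object, ...) {
  predict(object, newdata = object$x)
}

#' @export
residuals.lcen <- function(object, ...) {
  object$y$values - fitted(object)
}

#' Training diagnostics and adjacency heatmap
#'
#' Two base-graphics panels: loss trajectories (training components and
#' validation loss per epoch) and an image of the learned/used adjacency.
#'
#' @param x A fitted [lcen()] model.
#' @param which Subset of `c("history", "adjacency")`.
#' @param ... Unused.
#' @export
plot.lcen <- function(x, which = c("history", "adjacency"), ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if ("history" %in% which) {
    h <- x$history
    graphics::plot(h$epoch, h$total, type = "l", lwd = 2,
                   xlab = "epoch", ylab = "loss",
                   ylim = range(c(h$total, h$val_loss), finite = TRUE),
                   main = "training trajectory")
    graphics::lines(h$epoch, h$val_loss, col = 2, lwd = 2)
    graphics::legend("topright", c("train total", "validation"),
                     col = c(1, 2), lwd = 2, bty = "n")
  }
  if ("adjacency" %in% which) {
    A <- x$adjacency
    graphics::image(t(A)[, rev(seq_len(nrow(A)))], axes = FALSE,
                    main = "phenotype adjacency", col = grDevices::hcl.colors(25, "RdBu"))
  }
  invisible(x)
}

#' Simulate phenotype draws from the fitted generative model
#'
#' Draws latent codes from each subject's posterior, decodes them through the
#' structural solve, and adds observation noise estimated from the training
#' residuals -- one matrix per simulation.
#'
#' @param object A fitted [lcen()] model.
#' @param nsim Number of simulated datasets.
#' @param seed Integer seed.
#' @param newdata Optional feature matrix (defaults to training features).
#' @param ... Unused.
#' @return List of `nsim` simulated phenotype matrices.
#' @export
simulate.lcen <- function(object, nsim = 1, seed = 1L, newdata = NULL, ...) {
  xv <- if (is.null(newdata)) object$x
        else if (inherits(newdata, "lcen_features")) newdata$values
        else as.matrix(newdata)
  xs <- sweep(sweep(xv, 2, object$centers), 2, object$scales, "/")
  post <- predict(object, newdata = xv, type = "posterior")
  res_sd <- apply(residuals(object), 2, stats::sd)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    z <- reparameterize(post, noise_seed = derive_seed(seed, s))
    tp <- ad_tape()
    pn <- wrap_params(tp, object$params)
    base <- if (isTRUE(object$config$attention$enabled)) {
      h <- level_projections(ad_const(tp, z), pn$attention,
                             object$specs$encoder$activation)
      alpha <- attention_weights(h, pn$attention$u_l,
                                 object$config$attention$shared_alpha)
      y_levels <- lapply(seq_len(object$hierarchy$n_levels), function(l) {
        ad_add_rvec(ad_matmul(h[[l]], pn$attention$W_head[[l]]),
                    pn$attention$b_head[[l]])
      })
      aggregate_predictions(y_levels, alpha, object$hierarchy,
                            d_y = nrow(object$adjacency))
    } else {
      ad_add_rvec(ad_matmul(ad_const(tp, z), ad_t(pn$decoder$W_d)), pn$decoder$b_d)
    }
    y <- ad_value(decode_node(base, ad_const(tp, object$adjacency),
                              object$specs$decoder$solver,
                              object$specs$decoder$unroll_steps))
    noise <- with_seed(derive_seed(seed, 1000 + s),
                       matrix(stats::rnorm(length(y)), nrow(y), ncol(y)))
    out[[s]] <- y + sweep(noise, 2, res_sd, "*")
  }
  out
}
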