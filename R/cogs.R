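# Optimization and generalization objectives: domain-aware regularization,
# gradient-norm adaptive multi-task weighting, hierarchy consistency across
# parent/child tasks, and the heteroscedastic uncertainty-aware loss.

#' Multi-task specification
#'
#' Tasks are groups of phenotype columns (by default the hierarchy levels).
#' Carries the running statistics for adaptive weighting and the learnable
#' per-task log-variances for the uncertainty loss.
#'
#' @param task_to_columns Named list mapping task to phenotype column indices.
#' @param dag_edges List of `c(parent_task, child_task)` index pairs (DAG).
#' @param ema_beta Smoothing factor of the gradient-statistic EMA in `[0, 1)`.
#' @param epsilon Stabilizer added to the statistic before inversion.
#' @return An object of class `lcen_task_spec` with fields `n_tasks`,
#'   `task_to_columns`, `dag_edges`, `ema_beta`, `epsilon`, `ema` (running
#'   statistic, NA until first update) and `log_var_task`.
#' @export
task_spec <- function(task_to_columns, dag_edges = list(),
                      ema_beta = 0.9, epsilon = 1e-8) {
  stopifnot(is.list(task_to_columns), length(task_to_columns) >= 1L)
  if (ema_beta < 0 || ema_beta >= 1) stop("ema_beta must be in [0, 1)", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  Tn <- length(task_to_columns)
  if (is.null(names(task_to_columns))) names(task_to_columns) <- paste0("task", seq_len(Tn))
  if (length(dag_edges)) {
    em <- do.call(rbind, dag_edges)
    if (any(em < 1L) || any(em > Tn)) stop("dag edge references unknown task", call. = FALSE)
    # reuse the peel check from hierarchy_spec
    remaining <- seq_len(Tn); edges <- em
    repeat {
      if (!nrow(edges)) break
      leaves <- setdiff(remaining, edges[, 1])
      if (!length(leaves)) stop("dag_edges contain a cycle", call. = FALSE)
      remaining <- setdiff(remaining, leaves)
      edges <- edges[!(edges[, 2] %in% leaves) & !(edges[, 1] %in% leaves), , drop = FALSE]
    }
  }
  structure(list(n_tasks = Tn, task_to_columns = task_to_columns,
                 dag_edges = dag_edges, ema_beta = ema_beta, epsilon = epsilon,
                 ema = rep(NA_real_, Tn),
                 log_var_task = matrix(0, 1, Tn)),
            class = "lcen_task_spec")
}

#' Squared-covariance disentanglement penalty
#'
#' Sum over ordered pairs of distinct latent dimensions of the squared batch
#' covariance, `sum_{k != l} Cov(z^(k), z^(l))^2`. Zero when latent
#' dimensions are uncorrelated (and exactly zero for a single column).
#'
#' @param z Latent batch (matrix or node), at least 2 rows (a single row
#'   yields 0 with a warning).
#' @return Non-negative scalar (or node).
#' @export
disentangle_penalty <- function(z) {
  plain <- !is_ad(z)
  tp <- tape_of(z)
  zn <- as_node(tp, z)
  d <- ncol(zn$value)
  if (nrow(zn$value) < 2L) {
    warning("batch of 1: disentangle penalty defined as 0")
    out <- ad_const(tp, 0)
  } else if (d < 2L) {
    out <- ad_const(tp, 0)
  } else {
    C <- ad_covmat(zn)
    offdiag <- matrix(1, d, d); diag(offdiag) <- 0
    out <- ad_sum(ad_mul(ad_square(C), ad_const(tp, offdiag)))
  }
  if (plain) ad_value(out)[1] else out
}

#' Domain-aware regularization
#'
#' `lambda_smooth * R_smooth + lambda_disentangle * R_disentangle +
#' lambda_sparse * R_sparse`, with `R_smooth` the [graph_smoothness()] of the
#' predictions over the phenotype graph, `R_disentangle` the
#' [disentangle_penalty()] of the latent batch, and `R_sparse` the batch-mean
#' L1 norm of the predictions. Components are itemized.
#'
#' @param y_pred Prediction batch (matrix or node).
#' @param z Latent batch (matrix or node).
#' @param graph A [phenotype_graph()] or adjacency (matrix or node).
#' @param lambdas Named non-negative weights `smooth`, `disentangle`,
#'   `sparse`.
#' @return List `total` and `components`.
#' @export
domain_regularizer <- function(y_pred, z, graph,
                               lambdas = list(smooth = 0.01, disentangle = 0.01, sparse = 0)) {
  check_nonneg(unlist(lambdas), "domain_regularizer lambdas")
  A <- if (inherits(graph, "lcen_graph")) graph$adjacency else graph
  plain <- !is_ad(y_pred) && !is_ad(z) && !is_ad(A)
  tp <- tape_of(y_pred, z, A)
  yp <- as_node(tp, y_pred)
  smooth <- graph_smoothness(yp, as_node(tp, A))
  disent <- disentangle_penalty(as_node(tp, z))
  sparse <- ad_scale(ad_sum(ad_abs(yp)), 1 / nrow(yp$value))
  comps <- list(smooth = ad_scale(smooth, lambdas$smooth),
                disentangle = ad_scale(disent, lambdas$disentangle),
                sparse = ad_scale(sparse, lambdas$sparse))
  total <- Reduce(ad_add, comps)
  if (plain) {
    list(total = ad_value(total)[1], components = lapply(comps, function(c) ad_value(c)[1]))
  } else {
    list(total = total, components = comps)
  }
}

#' Gradient-norm adaptive task weights
#'
#' Updates the per-task exponential moving average of the gradient statistic
#' and returns `lambda_t = 1 / (EMA_t + epsilon)`, rescaled to sum to the
#' number of tasks so the total loss scale stays stable. As printed in the
#' weighting rule, a larger gradient statistic yields a strictly smaller raw
#' weight.
#'
#' @param grad_sq_norms Non-negative per-task statistics (e.g. squared
#'   gradient norms on the shared trunk for the current batch).
#' @param spec A [task_spec()]; its `ema` field carries the running state.
#' @param rescale Rescale weights to sum to `n_tasks` (default TRUE).
#' @return List with `lambda` (numeric vector) and `spec` (updated state).
#' @export
#' @examples
#' ts <- task_spec(list(a = 1, b = 2))
#' adaptive_task_weights(c(1, 3), ts)$lambda
adaptive_task_weights <- function(grad_sq_norms, spec, rescale = TRUE) {
  check_nonneg(grad_sq_norms, "grad_sq_norms")
  stopifnot(length(grad_sq_norms) == spec$n_tasks)
  ema <- spec$ema
  new_ema <- ifelse(is.na(ema), grad_sq_norms,
                    spec$ema_beta * ema + (1 - spec$ema_beta) * grad_sq_norms)
  lambda <- 1 / (new_ema + spec$epsilon)
  if (rescale) lambda <- lambda * spec$n_tasks / sum(lambda)
  spec$ema <- new_ema
  list(lambda = lambda, spec = spec)
}

# Child -> parent aggregation matrix: child columns are split into
# length(parent) contiguous groups (as even as possible) and averaged.
aggregation_matrix <- function(parent_cols, child_cols) {
  np <- length(parent_cols); nc <- length(child_cols)
  groups <- split(seq_len(nc), rep(seq_len(np), length.out = nc, each = ceiling(nc / np))[seq_len(nc)])
  M <- matrix(0, np, nc)
  for (g in seq_along(groups)) M[g, groups[[g]]] <- 1 / length(groups[[g]])
  M
}

#' Hierarchy consistency penalty
#'
#' For every parent/child task edge, the squared difference between the
#' parent's predictions and the mean-aggregated child predictions (child
#' columns mapped onto the parent's dimensionality by fixed column-group
#' means), averaged over the batch.
#'
#' @param y_pred_by_task Named list of per-task prediction matrices (or
#'   nodes), columns in `task_to_columns` order.
#' @param spec A [task_spec()].
#' @return Non-negative scalar (or node).
#' @export
#' @examples
#' ts <- task_spec(list(parent = 1, child = 2:3), dag_edges = list(c(1, 2)))
#' hierarchy_consistency(list(matrix(0), matrix(c(1, 3), 1)), ts)  # (0-2)^2 = 4
hierarchy_consistency <- function(y_pred_by_task, spec) {
  if (!length(spec$dag_edges)) {
    if (is_ad(y_pred_by_task[[1]])) return(ad_const(y_pred_by_task[[1]]$tape, 0))
    return(0)
  }
  plain <- !is_ad(y_pred_by_task[[1]])
  tp <- tape_of(y_pred_by_task[[1]])
  acc <- NULL
  for (e in spec$dag_edges) {
    p <- e[1]; cidx <- e[2]
    if (p > length(y_pred_by_task) || cidx > length(y_pred_by_task)) {
      stop("edge references unknown task", call. = FALSE)
    }
    yp <- as_node(tp, y_pred_by_task[[p]])
    yc <- as_node(tp, y_pred_by_task[[cidx]])
    M <- aggregation_matrix(spec$task_to_columns[[p]], spec$task_to_columns[[cidx]])
    n <- nrow(yp$value)
    term <- ad_scale(ad_sum(ad_square(ad_sub(yp, ad_matmul(yc, ad_const(tp, t(M)))))), 1 / n)
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  if (plain) ad_value(acc)[1] else acc
}

#' Heteroscedastic uncertainty loss
#'
#' `sum_t [ (1 / (2 sigma_t^2)) * mean_i ||y_t - yhat_t||^2 +
#' 0.5 * log sigma_t^2 ]` with one learnable log-variance per task
#' (`sigma_t^2 = exp(log_var_task_t)`, log-variance clamped to `[-10, 10]`).
#' Minimizing over `sigma_t^2` analytically gives `sigma_t^2 = error_t`.
#'
#' @param y_pred_by_task,y_true_by_task Lists of per-task matrices (or
#'   nodes).
#' @param log_var_task 1 x T matrix (or node) of per-task log variances.
#' @return Scalar (or node).
#' @export
uncertainty_loss <- function(y_pred_by_task, y_true_by_task, log_var_task) {
  Tn <- length(y_pred_by_task)
  stopifnot(Tn == length(y_true_by_task))
  plain <- !is_ad(y_pred_by_task[[1]]) && !is_ad(log_var_task)
  tp <- tape_of(y_pred_by_task[[1]], log_var_task)
  lv <- ad_clamp(as_node(tp, log_var_task), -10, 10)
  acc <- NULL
  for (t in seq_len(Tn)) {
    yp <- as_node(tp, y_pred_by_task[[t]])
    yt <- as_node(tp, y_true_by_task[[t]])
    n <- nrow(yp$value)
    err <- ad_scale(ad_sum(ad_square(ad_sub(yt, yp))), 1 / n)
    lvt <- ad_cols(lv, t)
    inv2 <- ad_scale(ad_exp(ad_scale(lvt, -1)), 0.5)
    term <- ad_add(ad_scalar_mul(inv2, err), ad_scale(lvt, 0.5))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  if (plain) ad_value(acc)[1] else acc
}

#' Combined multi-task objective
#'
#' `sum_t lambda_t L_t + lambda_hierarchy * R_hierarchy +
#' lambda_uncertainty * R_uncertainty`, with the per-task losses weighted by
#' the adaptive weights. Components are itemized and sum exactly to the
#' total.
#'
#' @param task_losses List (or vector) of per-task losses (scalars or nodes).
#' @param task_lambdas Per-task weights (from [adaptive_task_weights()]).
#' @param hierarchy_term,uncertainty_term Precomputed penalties (scalar or
#'   node).
#' @param lambdas Named non-negative weights `hierarchy`, `uncertainty`.
#' @return List `total` and `components` (`multi_task`, `hierarchy`,
#'   `uncertainty`).
#' @export
total_objective <- function(task_losses, task_lambdas,
                            hierarchy_term = 0, uncertainty_term = 0,
                            lambdas = list(hierarchy = 0.1, uncertainty = 0)) {
  check_nonneg(unlist(lambdas), "total_objective lambdas")
  stopifnot(length(task_losses) == length(task_lambdas))
  plain <- !is_ad(task_losses[[1]]) && !is_ad(hierarchy_term) && !is_ad(uncertainty_term)
  tp <- tape_of(task_losses[[1]], hierarchy_term, uncertainty_term)
  mt <- NULL
  for (t in seq_along(task_losses)) {
    term <- ad_scale(as_node(tp, task_losses[[t]]), task_lambdas[t])
    mt <- if (is.null(mt)) term else ad_add(mt, term)
  }
  comps <- list(multi_task = mt,
                hierarchy = ad_scale(as_node(tp, hierarchy_term), lambdas$hierarchy),
                uncertainty = ad_scale(as_node(tp, uncertainty_term), lambdas$uncertainty))
  total <- Reduce(ad_add, comps)
  if (plain) {
    list(total = ad_value(total)[1], components = lapply(comps, function(c) ad_value(c)[1]))
  } else {
    list(total = total, components = comps)
  }
}
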