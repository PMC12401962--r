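# Hierarchical attention over abstraction levels: level-specific projections
# of the latent code, softmax attention across levels, aggregation of
# per-level phenotype predictions, and the attention-regularized composite
# objective.

init_attention_params <- function(d_z, hierarchy, level_hidden = 32L, d_y) {
  L <- hierarchy$n_levels
  p <- list(W_l = vector("list", L), b_l = vector("list", L),
            u_l = vector("list", L), W_head = vector("list", L),
            b_head = vector("list", L))
  for (l in seq_len(L)) {
    p$W_l[[l]] <- xavier(d_z, level_hidden)
    p$b_l[[l]] <- matrix(0, 1, level_hidden)
    p$u_l[[l]] <- matrix(stats::rnorm(level_hidden, sd = 1 / sqrt(level_hidden)), level_hidden, 1)
    nd <- length(hierarchy$level_dims[[l]])
    p$W_head[[l]] <- xavier(level_hidden, nd)
    p$b_head[[l]] <- matrix(0, 1, nd)
  }
  p
}

#' Level-specific projections of the latent code
#'
#' Computes `h_l = f(W_l z + b_l)` for each abstraction level.
#'
#' @param z Latent batch (matrix or node).
#' @param params List with per-level `W_l` and `b_l` (lists of matrices or
#'   nodes).
#' @param activation Nonlinearity name (default `"gelu"`).
#' @return List of per-level matrices (or nodes), each batch x level width.
#' @export
level_projections <- function(z, params, activation = "gelu") {
  plain <- !is_ad(z) && !is_ad(params$W_l[[1]])
  tp <- tape_of(z, params$W_l[[1]])
  zn <- as_node(tp, z)
  act <- activation_fun(activation)
  out <- lapply(seq_along(params$W_l), function(l) {
    act(ad_add_rvec(ad_matmul(zn, as_node(tp, params$W_l[[l]])),
                    as_node(tp, params$b_l[[l]])))
  })
  if (plain) lapply(out, ad_value) else out
}

#' Softmax attention weights over levels
#'
#' Compatibility scores `u_l' h_l` are computed per subject; with
#' `shared_alpha` (the default) the scores are averaged over the batch before
#' a single softmax across levels, giving one weight vector per batch.
#'
#' @param h List of per-level latent states (matrices or nodes).
#' @param u List of per-level context vectors (column matrices or nodes).
#' @param shared_alpha Average scores over the batch before the softmax.
#' @return With `shared_alpha`, a 1 x L row of weights summing to one (or a
#'   node); otherwise an n x L matrix with rows summing to one.
#' @export
#' @examples
#' h <- list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2))
#' u <- list(matrix(0, 2, 1), matrix(0, 2, 1), matrix(0, 2, 1))
#' attention_weights(h, u)  # uniform 1/3
attention_weights <- function(h, u, shared_alpha = TRUE) {
  L <- length(h)
  stopifnot(L == length(u))
  plain <- !is_ad(h[[1]]) && !is_ad(u[[1]])
  tp <- tape_of(h[[1]], u[[1]])
  scores <- lapply(seq_len(L), function(l) {
    s <- ad_matmul(as_node(tp, h[[l]]), as_node(tp, u[[l]]))  # n x 1
    if (shared_alpha) ad_mean(s) else s
  })
  if (shared_alpha) {
    alpha <- ad_softmax(cbind_nodes(tp, scores))
    if (plain) ad_value(alpha) else alpha
  } else {
    sm <- cbind_nodes(tp, scores)
    alpha <- rowwise_softmax_node(sm)
    if (plain) ad_value(alpha) else alpha
  }
}

cbind_nodes <- function(tape, nodes) {
  Reduce(function(a, b) {
    na <- ncol(a$value)
    ad_node(tape, cbind(a$value, b$value), list(a, b),
            function(g) list(g[, seq_len(na), drop = FALSE],
                             g[, -seq_len(na), drop = FALSE]))
  }, nodes)
}

rowwise_softmax_node <- function(a) {
  av <- a$value
  e <- exp(av - apply(av, 1, max))
  s <- e / rowSums(e)
  ad_node(a$tape, s, list(a),
          function(g) list(s * (g - rowSums(g * s))))
}

#' Aggregate per-level predictions with attention weights
#'
#' Each level's prediction covers its own phenotype columns (per the
#' hierarchy); predictions are embedded into the full phenotype space
#' (zero-filled outside the level's columns) and combined as
#' `y_final = sum_l alpha_l y^(l)` -- a convex combination columnwise where
#' levels overlap.
#'
#' @param y_levels List of per-level prediction matrices (or nodes), each
#'   batch x |level columns|.
#' @param alpha Attention weights (1 x L row, vector, or node).
#' @param hierarchy A [hierarchy_spec()]; its `level_dims` place each level's
#'   columns. If omitted, all levels must already span the full space.
#' @param d_y Total number of phenotype columns (required with `hierarchy`).
#' @return Aggregated prediction matrix (or node), batch x d_y.
#' @export
aggregate_predictions <- function(y_levels, alpha, hierarchy = NULL, d_y = NULL) {
  L <- length(y_levels)
  plain <- !is_ad(y_levels[[1]]) && !is_ad(alpha)
  tp <- tape_of(y_levels[[1]], alpha)
  if (!is_ad(alpha)) alpha <- ad_const(tp, matrix(as.numeric(ad_value(alpha)), 1))
  stopifnot(ncol(alpha$value) == L)
  if (is.null(hierarchy)) {
    d_y <- d_y %||% ncol(ad_value(y_levels[[1]]))
    idx <- rep(list(seq_len(d_y)), L)
  } else {
    idx <- hierarchy$level_dims
    d_y <- d_y %||% max(unlist(idx))
    for (l in seq_len(L)) {
      if (length(idx[[l]]) != ncol(ad_value(y_levels[[l]]))) {
        stop(sprintf("level %d predicts %d columns but level_dims lists %d",
                     l, ncol(ad_value(y_levels[[l]])), length(idx[[l]])), call. = FALSE)
      }
    }
  }
  acc <- NULL
  for (l in seq_len(L)) {
    yl <- ad_embed_cols(as_node(tp, y_levels[[l]]), idx[[l]], d_y)
    term <- ad_scalar_mul(ad_cols(alpha, l), yl)
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  if (plain) ad_value(acc) else acc
}

#' Composite objective with hierarchical attention
#'
#' `L_reconstruction + lambda1 * R_latent + lambda2 * R_graph +
#' lambda3 * R_attention`, where the reconstruction term is the batch-mean
#' squared error of the aggregated prediction, `R_attention = sum_l |alpha_l|`
#' is computed literally (identically 1 for softmax weights), and the latent
#' and graph terms are passed in precomputed (scalars or nodes). Components
#' are itemized and sum exactly to the total.
#'
#' @param y_true,y_final Matrices (or nodes) of identical shape.
#' @param latent_term,graph_term Precomputed regularizer values (or nodes).
#' @param alpha Attention weights (row vector or node).
#' @param lambdas Named list of non-negative `latent`, `graph`, `attention`
#'   weights.
#' @param attention_entropy_weight Optional extra penalty
#'   `-sum_l alpha_l log alpha_l` providing an effective sparsity pressure
#'   (the literal L1 term has zero gradient under softmax); off by default.
#' @return List `total` and itemized `components`.
#' @export
attention_objective <- function(y_true, y_final, latent_term = 0, graph_term = 0,
                                alpha,
                                lambdas = list(latent = 0.01, graph = 0.01, attention = 0.01),
                                attention_entropy_weight = 0) {
  check_nonneg(unlist(lambdas), "attention_objective lambdas")
  check_nonneg(attention_entropy_weight, "attention_entropy_weight")
  plain <- !is_ad(y_true) && !is_ad(y_final) && !is_ad(alpha) &&
    !is_ad(latent_term) && !is_ad(graph_term)
  tp <- tape_of(y_true, y_final, alpha, latent_term, graph_term)
  yt <- as_node(tp, y_true); yf <- as_node(tp, y_final)
  n <- nrow(yt$value)
  recon <- ad_scale(ad_sum(ad_square(ad_sub(yt, yf))), 1 / n)
  an <- if (is_ad(alpha)) alpha else ad_const(tp, matrix(as.numeric(alpha), 1))
  r_att <- ad_sum(ad_abs(an))
  comps <- list(
    reconstruction = recon,
    latent = ad_scale(as_node(tp, latent_term), lambdas$latent),
    graph = ad_scale(as_node(tp, graph_term), lambdas$graph),
    attention = ad_scale(r_att, lambdas$attention)
  )
  if (attention_entropy_weight > 0) {
    ent <- ad_scale(ad_sum(ad_mul(an, ad_log(an))), -1)
    comps$attention_entropy <- ad_scale(ent, attention_entropy_weight)
  }
  total <- Reduce(ad_add, comps)
  if (plain) {
    list(total = ad_value(total)[1], components = lapply(comps, function(c) ad_value(c)[1]))
  } else {
    list(total = total, components = comps)
  }
}
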