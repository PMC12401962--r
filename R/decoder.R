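# Graph-guided phenotype decoder: the implicit message-passing system
# y = W_d z + A y, resolved either by an exact linear solve or by unrolled
# fixed-point iterations, plus the residual refinement block and the decoding
# objective with graph/sparsity/symmetry penalties.

#' Decoder specification
#'
#' @param hidden_widths Widths of the two-layer residual block.
#' @param residual_block Enable the residual refinement stage.
#' @param adjacency_mode `"fixed"` (graph supplied) or `"learnable"`.
#' @param solver `"closed_form"` (exact solve of `y = W z + A y`) or
#'   `"unrolled"` (fixed-point iterations `y <- W z + A y`).
#' @param unroll_steps Number of fixed-point iterations for the unrolled
#'   solver; the iteration error decays like `rho^steps` with `rho` the
#'   spectral radius.
#' @return An object of class `lcen_decoder_spec`.
#' @export
decoder_spec <- function(hidden_widths = c(64L, 128L),
                         residual_block = TRUE,
                         adjacency_mode = c("fixed", "learnable"),
                         solver = c("closed_form", "unrolled"),
                         unroll_steps = 8L) {
  adjacency_mode <- match.arg(adjacency_mode)
  solver <- match.arg(solver)
  stopifnot(unroll_steps >= 1L)
  structure(list(hidden_widths = as.integer(hidden_widths),
                 residual_block = residual_block,
                 adjacency_mode = adjacency_mode,
                 solver = solver,
                 unroll_steps = as.integer(unroll_steps)),
            class = "lcen_decoder_spec")
}

init_decoder_params <- function(d_z, d_y, spec, activation = "gelu") {
  p <- list(W_d = xavier(d_y, d_z), b_d = matrix(0, 1, d_y))  # y_i = W_d z_i
  if (spec$residual_block) {
    w <- spec$hidden_widths
    p$R_W1 <- xavier(d_y, w[1]); p$R_b1 <- matrix(0, 1, w[1])
    if (length(w) > 1L) {
      p$R_W1b <- xavier(w[1], w[2]); p$R_b1b <- matrix(0, 1, w[2])
      p$R_W2 <- matrix(0, w[2], d_y)  # zero init: residual starts as identity
    } else {
      p$R_W1b <- NULL; p$R_b1b <- NULL
      p$R_W2 <- matrix(0, w[1], d_y)
    }
    p$R_b2 <- matrix(0, 1, d_y)
  }
  if (spec$adjacency_mode == "learnable") p$A_raw <- matrix(0, d_y, d_y)
  p
}

# Symmetric-by-construction adjacency from a free square parameter:
# A = (P + t(P))/2 with a zeroed diagonal. Works on nodes and matrices.
symmetrize_adjacency <- function(P) {
  if (is_ad(P)) {
    d <- ncol(P$value)
    mask <- matrix(1, d, d); diag(mask) <- 0
    ad_mul(ad_scale(ad_add(P, ad_t(P)), 0.5), ad_const(P$tape, mask))
  } else {
    A <- (P + t(P)) / 2; diag(A) <- 0; A
  }
}

# Differentiable decode given a base drive (batch x d_y) and adjacency node.
decode_node <- function(base, an, solver = "closed_form", unroll_steps = 8L) {
  if (solver == "closed_form") {
    ad_solve_net(base, an)
  } else {
    y <- base
    for (s in seq_len(unroll_steps)) y <- ad_add(base, ad_matmul(y, ad_t(an)))
    y
  }
}

#' Decode latent variables into phenotype predictions
#'
#' Resolves the implicit message-passing system `y = W_d z + A y`: with
#' `solver = "closed_form"` as `y = (I - A)^{-1} W_d z` (exact), with
#' `solver = "unrolled"` by `unroll_steps` fixed-point iterations
#' `y <- W_d z + A y` starting from `y = W_d z` (the truncated Neumann
#' series). Requires spectral radius strictly below 1; run the raw adjacency
#' through [project_adjacency()] first.
#'
#' @param z Latent batch (matrix, subjects in rows).
#' @param graph A [phenotype_graph()] or adjacency matrix.
#' @param spec A [decoder_spec()].
#' @param params Decoder parameters (`W_d`, `b_d`, optional residual block).
#' @param refine Apply the residual block when the spec enables it.
#' @return Matrix of phenotype predictions (batch x d_y).
#' @export
decode <- function(z, graph, spec = decoder_spec(), params, refine = spec$residual_block) {
  A <- if (inherits(graph, "lcen_graph")) graph$adjacency else as.matrix(graph)
  rho <- spectral_radius(A)
  if (rho >= 1) {
    stop(sprintf("adjacency spectral radius %.3f >= 1; run project_adjacency() first", rho),
         call. = FALSE)
  }
  z <- as.matrix(z)
  tp <- ad_tape()
  base <- ad_add_rvec(ad_matmul(ad_const(tp, z), ad_const(tp, t(params$W_d))),
                      ad_const(tp, params$b_d))
  y <- decode_node(base, ad_const(tp, A), spec$solver, spec$unroll_steps)
  y <- ad_value(y)
  if (isTRUE(refine)) y <- residual_refine(y, spec, params)
  y
}

# Differentiable residual block.
residual_refine_node <- function(yn, pn, activation = "gelu") {
  act <- activation_fun(activation)
  h <- act(ad_add_rvec(ad_matmul(yn, pn$R_W1), pn$R_b1))
  if (!is.null(pn$R_W1b)) h <- act(ad_add_rvec(ad_matmul(h, pn$R_W1b), pn$R_b1b))
  ad_add(yn, ad_add_rvec(ad_matmul(h, pn$R_W2), pn$R_b2))
}

#' Residual refinement of phenotype predictions
#'
#' Adds a two-layer nonlinear correction: `y + R(y)`. With the final layer
#' zero-initialized the block is the identity map, so refinement never hurts
#' at initialization.
#'
#' @param y_base Prediction batch (matrix).
#' @param spec A [decoder_spec()] with `residual_block = TRUE`.
#' @param params Decoder parameters containing the block weights.
#' @param activation Nonlinearity name (default `"gelu"`).
#' @return Refined prediction batch.
#' @export
residual_refine <- function(y_base, spec = decoder_spec(), params, activation = "gelu") {
  if (!spec$residual_block) stop("residual block disabled in spec", call. = FALSE)
  tp <- ad_tape()
  pn <- wrap_params(tp, params)
  ad_value(residual_refine_node(ad_const(tp, as.matrix(y_base)), pn, activation))
}

#' Decoding objective with graph penalties
#'
#' Mean (over the batch) squared reconstruction error summed over phenotype
#' dimensions, plus `lambda_graph` times the [graph_smoothness()] of the
#' predictions, `lambda_sparsity` times the adjacency L1 norm, and
#' `lambda_symmetry` times the squared asymmetry. Components are itemized and
#' sum exactly to the total.
#'
#' @param y_true,y_pred Matrices (or nodes) of identical shape.
#' @param graph A [phenotype_graph()], adjacency matrix, or adjacency node.
#' @param lambdas Named list with non-negative `graph`, `sparsity`,
#'   `symmetry` weights.
#' @return List `total` and `components` (named `reconstruction`, `graph`,
#'   `sparsity`, `symmetry`).
#' @export
decode_loss <- function(y_true, y_pred, graph,
                        lambdas = list(graph = 0.01, sparsity = 0.01, symmetry = 0.01)) {
  lam <- lambdas
  check_nonneg(unlist(lam), "decode_loss lambdas")
  A <- if (inherits(graph, "lcen_graph")) graph$adjacency else graph
  plain <- !is_ad(y_true) && !is_ad(y_pred) && !is_ad(A)
  tp <- tape_of(y_true, y_pred, A)
  yt <- as_node(tp, y_true); yp <- as_node(tp, y_pred); an <- as_node(tp, A)
  if (!all(dim(yt$value) == dim(yp$value))) stop("y_true / y_pred shapes differ", call. = FALSE)
  n <- nrow(yt$value)
  recon <- ad_scale(ad_sum(ad_square(ad_sub(yt, yp))), 1 / n)
  pen <- graph_penalties(an)
  smooth <- graph_smoothness(yp, an)
  total <- ad_add(recon,
                  ad_add(ad_scale(smooth, lam$graph),
                         ad_add(ad_scale(pen$sparsity, lam$sparsity),
                                ad_scale(pen$asymmetry, lam$symmetry))))
  comps <- list(reconstruction = recon,
                graph = ad_scale(smooth, lam$graph),
                sparsity = ad_scale(pen$sparsity, lam$sparsity),
                symmetry = ad_scale(pen$asymmetry, lam$symmetry))
  if (plain) {
    list(total = ad_value(total)[1], components = lapply(comps, function(c) ad_value(c)[1]))
  } else {
    list(total = total, components = comps)
  }
}
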