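# Reverse-mode differentiation on a flat tape of matrix nodes.
#
# Every quantity is a dense numeric matrix (scalars are 1x1). Operations append
# a node holding the forward value and a vector-Jacobian-product closure; a
# single reverse sweep over the tape yields exact gradients for all parameters.
# This is the differentiable substrate for every composite objective in the
# package, so each loss can be checked against central finite differences.

#' Create an empty differentiation tape
#'
#' A tape records the forward computation graph as an ordered list of matrix
#' nodes. Build values on it with [ad_const()] and the `ad_*` operators, then
#' call [ad_backward()] on a scalar node to obtain gradients.
#'
#' @return An object of class `ad_tape`.
#' @export
#' @examples
#' tp <- ad_tape()
#' w <- ad_const(tp, matrix(1:4, 2, 2))
#' s <- ad_sum(ad_mul(w, w))
#' g <- ad_backward(tp, s)
#' ad_grad(g, w)  # equals 2 * W
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$k <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_node <- function(tape, value, parents = list(), vjp = NULL) {
  stopifnot(inherits(tape, "ad_tape"))
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$vjp <- vjp
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  n$id <- tape$k
  n$tape <- tape
  tape$nodes[[tape$k]] <- n
  class(n) <- "ad_node"
  n
}

#' Wrap a numeric matrix as a tape node
#'
#' @param tape An [ad_tape()].
#' @param x Numeric matrix, vector (treated as a column), or scalar.
#' @return An `ad_node`.
#' @export
ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = if (length(x) == 1L) 1L else 1L)
  ad_node(tape, x)
}

is_ad <- function(x) inherits(x, "ad_node")

#' Numeric value of a node (or pass a plain matrix through)
#' @param x An `ad_node` or numeric.
#' @return Numeric matrix.
#' @export
ad_value <- function(x) if (is_ad(x)) x$value else x

# Coerce x onto the given tape if it is not already a node.
as_node <- function(tape, x) if (is_ad(x)) x else ad_const(tape, x)

# Find a tape among arguments, or create a fresh one.
tape_of <- function(...) {
  for (x in list(...)) if (is_ad(x)) return(x$tape)
  ad_tape()
}

#' Reverse sweep: gradients of a scalar node
#'
#' @param tape The tape the computation was built on.
#' @param root Scalar (1x1) node to differentiate.
#' @return Opaque gradient table; query with [ad_grad()].
#' @export
ad_backward <- function(tape, root) {
  stopifnot(is_ad(root), nrow(root$value) == 1L, ncol(root$value) == 1L)
  grads <- vector("list", tape$k)
  grads[[root$id]] <- matrix(1, 1, 1)
  for (i in seq(root$id, 1L)) {
    n <- tape$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || is.null(n$vjp)) next
    pg <- n$vjp(g)
    ps <- n$parents
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      id <- ps[[j]]$id
      grads[[id]] <- if (is.null(grads[[id]])) gj else grads[[id]] + gj
    }
  }
  structure(list(grads = grads), class = "ad_gradients")
}

#' Gradient of a node after [ad_backward()]
#' @param gradients Result of [ad_backward()].
#' @param node Node whose gradient is wanted.
#' @return Numeric matrix of the node's shape (zeros if unused).
#' @export
ad_grad <- function(gradients, node) {
  g <- gradients$grads[[node$id]]
  if (is.null(g)) array(0, dim(node$value)) else g
}

# ---- elementwise and linear-algebra primitives -------------------------------

ad_add <- function(a, b) {
  tp <- tape_of(a, b); a <- as_node(tp, a); b <- as_node(tp, b)
  ad_node(tp, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  tp <- tape_of(a, b); a <- as_node(tp, a); b <- as_node(tp, b)
  ad_node(tp, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  tp <- tape_of(a, b); a <- as_node(tp, a); b <- as_node(tp, b)
  av <- a$value; bv <- b$value
  ad_node(tp, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  stopifnot(is.numeric(s), length(s) == 1L)
  ad_node(a$tape, a$value * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  tp <- tape_of(a, b); a <- as_node(tp, a); b <- as_node(tp, b)
  av <- a$value; bv <- b$value
  ad_node(tp, av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

ad_t <- function(a) ad_node(a$tape, t(a$value), list(a), function(g) list(t(g)))

# Broadcast a 1 x m row vector across the rows of an n x m matrix.
ad_add_rvec <- function(a, v) {
  tp <- tape_of(a, v); a <- as_node(tp, a); v <- as_node(tp, v)
  n <- nrow(a$value)
  val <- a$value + matrix(v$value, n, ncol(a$value), byrow = TRUE)
  ad_node(tp, val, list(a, v),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_sub_rvec <- function(a, v) {
  tp <- tape_of(a, v); a <- as_node(tp, a); v <- as_node(tp, v)
  n <- nrow(a$value)
  val <- a$value - matrix(v$value, n, ncol(a$value), byrow = TRUE)
  ad_node(tp, val, list(a, v),
          function(g) list(g, matrix(-colSums(g), 1L)))
}

ad_mul_rvec <- function(a, v) {
  tp <- tape_of(a, v); a <- as_node(tp, a); v <- as_node(tp, v)
  n <- nrow(a$value); m <- ncol(a$value)
  vb <- matrix(v$value, n, m, byrow = TRUE)
  av <- a$value
  ad_node(tp, av * vb, list(a, v),
          function(g) list(g * vb, matrix(colSums(g * av), 1L)))
}

# Multiply each row i of an n x m matrix by entry i of an n x 1 vector.
ad_mul_cvec <- function(a, v) {
  tp <- tape_of(a, v); a <- as_node(tp, a); v <- as_node(tp, v)
  n <- nrow(a$value); m <- ncol(a$value)
  vb <- matrix(v$value, n, m)
  av <- a$value
  ad_node(tp, av * vb, list(a, v),
          function(g) list(g * vb, matrix(rowSums(g * av), ncol = 1)))
}

# Multiply a matrix node by a 1x1 scalar node.
ad_scalar_mul <- function(s, a) {
  tp <- tape_of(s, a); s <- as_node(tp, s); a <- as_node(tp, a)
  sv <- s$value[1]; av <- a$value
  ad_node(tp, sv * av, list(s, a),
          function(g) list(matrix(sum(g * av), 1, 1), g * sv))
}

ad_exp <- function(a) {
  val <- exp(a$value)
  ad_node(a$tape, val, list(a), function(g) list(g * val))
}

ad_log <- function(a) {
  av <- a$value
  ad_node(a$tape, log(av), list(a), function(g) list(g / av))
}

ad_sqrt <- function(a) {
  val <- sqrt(a$value)
  ad_node(a$tape, val, list(a), function(g) list(g * 0.5 / val))
}

ad_square <- function(a) {
  av <- a$value
  ad_node(a$tape, av * av, list(a), function(g) list(2 * g * av))
}

ad_pow <- function(a, p) {
  av <- a$value
  ad_node(a$tape, av^p, list(a), function(g) list(g * p * av^(p - 1)))
}

ad_abs <- function(a) {
  av <- a$value
  ad_node(a$tape, abs(av), list(a), function(g) list(g * sign(av)))
}

# Subgradient at clamp boundaries is zero outside the interval.
ad_clamp <- function(a, lo, hi) {
  av <- a$value
  val <- pmin(pmax(av, lo), hi)
  inside <- (av > lo & av < hi) * 1
  ad_node(a$tape, val, list(a), function(g) list(g * inside))
}

ad_gelu <- function(a) {
  av <- a$value
  phi <- stats::pnorm(av)
  ad_node(a$tape, av * phi, list(a),
          function(g) list(g * (phi + av * stats::dnorm(av))))
}

ad_relu <- function(a) {
  av <- a$value
  ad_node(a$tape, pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ad_tanh <- function(a) {
  val <- tanh(a$value)
  ad_node(a$tape, val, list(a), function(g) list(g * (1 - val^2)))
}

ad_identity_act <- function(a) a

# ---- reductions --------------------------------------------------------------

ad_sum <- function(a) {
  dm <- dim(a$value)
  ad_node(a$tape, matrix(sum(a$value), 1, 1), list(a),
          function(g) list(array(g[1], dm)))
}

ad_mean <- function(a) {
  dm <- dim(a$value); n <- length(a$value)
  ad_node(a$tape, matrix(mean(a$value), 1, 1), list(a),
          function(g) list(array(g[1] / n, dm)))
}

ad_rowsums <- function(a) {
  n <- nrow(a$value); m <- ncol(a$value)
  ad_node(a$tape, matrix(rowSums(a$value), n, 1), list(a),
          function(g) list(matrix(g, n, m)))
}

ad_colsums <- function(a) {
  n <- nrow(a$value); m <- ncol(a$value)
  ad_node(a$tape, matrix(colSums(a$value), 1, m), list(a),
          function(g) list(matrix(g, n, m, byrow = TRUE)))
}

ad_colmeans <- function(a) {
  n <- nrow(a$value); m <- ncol(a$value)
  ad_node(a$tape, matrix(colMeans(a$value), 1, m), list(a),
          function(g) list(matrix(g / n, n, m, byrow = TRUE)))
}

# Select columns; gradient scatters back into place.
ad_cols <- function(a, idx) {
  n <- nrow(a$value); m <- ncol(a$value)
  ad_node(a$tape, a$value[, idx, drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, n, m)
            out[, idx] <- out[, idx] + g
            list(out)
          })
}

# Embed an n x |idx| block into an n x d zero matrix at the given columns.
ad_embed_cols <- function(a, idx, d) {
  n <- nrow(a$value)
  val <- matrix(0, n, d)
  val[, idx] <- a$value
  ad_node(a$tape, val, list(a), function(g) list(g[, idx, drop = FALSE]))
}

# Softmax of a 1 x L row vector.
ad_softmax <- function(a) {
  av <- a$value
  e <- exp(av - max(av))
  s <- e / sum(e)
  ad_node(a$tape, s, list(a),
          function(g) list(s * (g - sum(g * s))))
}

# Y = B %*% t(solve(I - A)): row-wise solve y_i = (I - A)^-1 b_i.
# Gradients: dB = G S, dA = t(S) t(G) Y  with S = (I - A)^-1.
ad_solve_net <- function(b, a) {
  tp <- tape_of(b, a); b <- as_node(tp, b); a <- as_node(tp, a)
  d <- ncol(a$value)
  S <- solve(diag(d) - a$value)
  Y <- b$value %*% t(S)
  ad_node(tp, Y, list(b, a),
          function(g) list(g %*% S, t(S) %*% t(g) %*% Y))
}

# Per-column sample variance (denominator n - 1), returned as 1 x m.
ad_colvars <- function(a) {
  n <- nrow(a$value)
  if (n < 2L) stop("column variance needs at least two rows")
  c0 <- ad_sub_rvec(a, ad_colmeans(a))
  ad_scale(ad_colsums(ad_square(c0)), 1 / (n - 1))
}

# Sample covariance matrix t(C) C / (n - 1) with C the column-centered batch.
ad_covmat <- function(a) {
  n <- nrow(a$value)
  if (n < 2L) stop("covariance needs at least two rows")
  c0 <- ad_sub_rvec(a, ad_colmeans(a))
  ad_scale(ad_matmul(ad_t(c0), c0), 1 / (n - 1))
}

activation_fun <- function(name) {
  switch(name,
         gelu = ad_gelu,
         relu = ad_relu,
         tanh = ad_tanh,
         linear = ad_identity_act,
         stop(sprintf("unknown activation '%s'", name)))
}
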