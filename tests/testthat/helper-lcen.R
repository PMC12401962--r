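# Shared test utilities: central finite differences against tape gradients,
# and a lean configuration used by the training tests.

# Internal tape primitives used when tests compose losses by hand.
ad_sum <- lcen:::ad_sum
ad_mean <- lcen:::ad_mean
ad_square <- lcen:::ad_square
ad_mul <- lcen:::ad_mul
ad_add <- lcen:::ad_add
ad_sub <- lcen:::ad_sub
ad_scale <- lcen:::ad_scale
ad_matmul <- lcen:::ad_matmul
ad_gelu <- lcen:::ad_gelu
ad_tanh <- lcen:::ad_tanh
ad_exp <- lcen:::ad_exp
ad_abs <- lcen:::ad_abs
ad_add_rvec <- lcen:::ad_add_rvec
ad_mul_cvec <- lcen:::ad_mul_cvec
ad_softmax <- lcen:::ad_softmax
ad_colvars <- lcen:::ad_colvars
ad_covmat <- lcen:::ad_covmat

# Central finite-difference gradient of f (scalar-valued) at matrix m.
fd_grad <- function(f, m, h = 1e-5) {
  g <- array(0, dim(m))
  for (i in seq_along(m)) {
    mp <- m; mp[i] <- mp[i] + h
    mm <- m; mm[i] <- mm[i] - h
    g[i] <- (f(mp) - f(mm)) / (2 * h)
  }
  g
}

# Max relative error between analytic and numeric gradients.
max_rel_err <- function(ga, gn) {
  denom <- pmax(abs(gn), 1e-6)
  max(abs(ga - gn) / denom)
}

# Build a scalar loss node from a parameter matrix via `build(node)`, return
# list(value, grad).
tape_grad <- function(m, build) {
  tp <- ad_tape()
  nd <- ad_const(tp, m)
  root <- build(nd)
  g <- ad_backward(tp, root)
  list(value = ad_value(root)[1], grad = ad_grad(g, nd))
}

# Small fast config for training tests: lean linear-ish network, no dropout.
lean_config <- function(...) {
  lcen_config(
    encoder = list(layer_widths = c(16L, 5L), dropout_rate = 0,
                   dropout_after = integer(0), activation = "linear",
                   batch_norm = FALSE),
    decoder = list(residual_block = FALSE),
    attention = list(enabled = FALSE),
    lambdas = list(kl = 0.001, graph = 0, hierarchy = 0),
    multi_task = list(enabled = FALSE),
    ...
  )
}
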