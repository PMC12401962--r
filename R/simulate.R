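# Seeded synthetic cohorts with the statistical structure the model assumes:
# known latent factors, a known sparse symmetric phenotype adjacency, a
# three-level hierarchy, and two multimodal feature blocks. Ground truth is
# returned so parameter recovery can be scored.

default_hierarchy <- function(d_y) {
  # three contiguous groups, low -> high abstraction
  cuts <- largest_remainder(d_y, c(1, 1, 1) / 3)
  idx <- split(seq_len(d_y), rep(1:3, times = cuts))
  hierarchy_spec(list(sensorimotor = idx[[1]], control = idx[[2]], executive = idx[[3]]))
}

# Random symmetric adjacency with exactly m = round(density * npairs) edges,
# rescaled to the requested spectral radius.
random_adjacency <- function(d_y, edge_density, radius) {
  npairs <- d_y * (d_y - 1) / 2
  m <- max(1L, round(edge_density * npairs))
  pairs <- which(upper.tri(matrix(0, d_y, d_y)), arr.ind = TRUE)
  draw <- function() {
    sel <- sample(nrow(pairs), m)
    w <- stats::runif(m, 0.3, 1) * sample(c(-1, 1), m, replace = TRUE)
    A <- matrix(0, d_y, d_y)
    for (r in seq_len(m)) {
      i <- pairs[sel[r], 1]; j <- pairs[sel[r], 2]
      A[i, j] <- w[r]; A[j, i] <- w[r]
    }
    A
  }
  for (attempt in seq_len(100L)) {
    A <- draw()
    rho <- spectral_radius(A)
    if (rho > 0) return(A * (radius / rho))
  }
  stop("could not draw a usable adjacency after 100 attempts", call. = FALSE)
}

#' Simulate a multimodal cohort with known ground truth
#'
#' The generative model mirrors the decoder's fixed-point form:
#' latent factors `z* ~ N(0, I_k)`, phenotypes
#' `y = (I - A)^{-1} (W z* + eps_y)` with `eps_y ~ N(0, noise_sd_y^2)`
#' entering the structural equation (so connected phenotypes co-vary and the
#' marginal covariance is `(I-A)^{-1}(W W' + noise_sd_y^2 I)(I-A)^{-T}`), and
#' features `x = M z* + eps_x` with a block-structured mixing map split into
#' an EEG-PSD-like and an imaging-like modality block. Phenotype recovery is
#' identifiable up to a rotation of the latent factors.
#'
#' @param n Number of subjects (>= 2).
#' @param d_x,d_y,k Feature, phenotype, and latent dimensions (`k <= d_x`).
#' @param edge_density Fraction of phenotype pairs connected (edges drawn
#'   exactly, so realized density is within one edge of the request).
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @param noise_sd_x,noise_sd_y Noise SDs (> 0 unless `noiseless`).
#' @param spectral_radius Spectral radius the true adjacency is scaled to.
#' @param n_binary Number of trailing phenotype columns binarized by
#'   thresholding at 0.
#' @param hierarchy Optional [hierarchy_spec()]; defaults to three contiguous
#'   level groups.
#' @return List with `features`, `phenotypes`, `graph` (the true adjacency as
#'   a fixed graph) and `truth` (`W_true`, `A_true`, `mixing`, noise SDs,
#'   `z_true`, `level_map`, `seed`).
#' @export
#' @examples
#' cohort <- simulate_cohort(n = 50, d_x = 8, d_y = 6, k = 2, seed = 1)
#' dim(cohort$features$values)
simulate_cohort <- function(n = 800L, d_x = 40L, d_y = 10L, k = 5L,
                            edge_density = 0.2, seed = 7L,
                            noise_sd_x = 0.1, noise_sd_y = 0.1,
                            spectral_radius = 0.6, n_binary = 0L,
                            hierarchy = NULL) {
  stopifnot(n >= 2L, k <= d_x, d_y >= 2L, n_binary <= d_y)
  if (noise_sd_x < 0 || noise_sd_y < 0) stop("noise SDs must be >= 0", call. = FALSE)
  with_seed(seed, {
    A <- random_adjacency(d_y, edge_density, spectral_radius)
    W <- matrix(stats::rnorm(d_y * k), d_y, k) / sqrt(k)
    d1 <- ceiling(d_x / 2); d2 <- d_x - d1
    M1 <- matrix(stats::rnorm(d1 * k), d1, k) / sqrt(k)
    M2 <- matrix(stats::rnorm(d2 * k), d2, k) / sqrt(k)
    z <- matrix(stats::rnorm(n * k), n, k)
    eps_y <- matrix(stats::rnorm(n * d_y, sd = noise_sd_y), n, d_y)
    S <- solve(diag(d_y) - A)
    y <- (z %*% t(W) + eps_y) %*% t(S)
    x <- cbind(z %*% t(M1), z %*% t(M2)) +
      matrix(stats::rnorm(n * d_x, sd = noise_sd_x), n, d_x)
    kind <- rep("continuous", d_y)
    if (n_binary > 0L) {
      bcols <- seq(d_y - n_binary + 1L, d_y)
      y[, bcols] <- (y[, bcols] > 0) * 1
      kind[bcols] <- "binary"
    }
    hierarchy <- hierarchy %||% default_hierarchy(d_y)
    ids <- sprintf("S%04d", seq_len(n))
    blocks <- list(eeg_psd = seq_len(d1), imaging = d1 + seq_len(d2))
    list(
      features = feature_matrix(x, modality_blocks = blocks, subject_ids = ids),
      phenotypes = phenotype_matrix(y, column_kind = kind, subject_ids = ids),
      graph = phenotype_graph(A, mode = "fixed"),
      truth = list(W_true = W, A_true = A, mixing = list(eeg_psd = M1, imaging = M2),
                   noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
                   z_true = z, level_map = hierarchy, seed = seed)
    )
  })
}

#' Tiny fixed worked example
#'
#' A hand-enterable instance: 4 subjects, 3 features, 2 phenotypes, 1 latent
#' factor, adjacency `[[0, 0.5], [0.5, 0]]`, no noise. Its phenotypes equal
#' the closed-form 2x2 solve `y = (I - A)^{-1} W z`, e.g. the subject with
#' `z = 1` has `y = (4/3, 2/3)`. Byte-identical on every call.
#'
#' @return Same structure as [simulate_cohort()].
#' @export
make_worked_example <- function() {
  z <- matrix(c(1, -1, 0.5, 2), 4, 1)
  W <- matrix(c(1, 0), 2, 1)
  A <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  mix <- matrix(c(1, 0.5, -0.5), 3, 1)
  S <- solve(diag(2) - A)
  y <- (z %*% t(W)) %*% t(S)
  x <- z %*% t(mix)
  ids <- paste0("S", 1:4)
  hierarchy <- hierarchy_spec(list(sensorimotor = 1L, executive = 2L))
  list(
    features = feature_matrix(x, modality_blocks = list(eeg_psd = 1:2, imaging = 3L),
                              subject_ids = ids),
    phenotypes = phenotype_matrix(y, subject_ids = ids),
    graph = phenotype_graph(A, mode = "fixed"),
    truth = list(W_true = W, A_true = A, mixing = list(all = mix),
                 noise_sd_x = 0, noise_sd_y = 0, z_true = z,
                 level_map = hierarchy, seed = 0L)
  )
}

#' Deterministic fingerprint of a cohort
#'
#' md5 of a canonical fixed-precision text serialization of the feature and
#' phenotype matrices and the adjacency; used to pin generator reproducibility
#' across platforms.
#'
#' @param cohort Result of [simulate_cohort()].
#' @return Character md5 string.
#' @export
cohort_fingerprint <- function(cohort) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "w")
  writeLines(sprintf("%.8e", c(cohort$features$values,
                               cohort$phenotypes$values,
                               cohort$graph$adjacency)), con)
  close(con)
  unname(tools::md5sum(f))
}

#' Write a simulated cohort to delimited text files
#'
#' Emits `features.tsv`, `phenotypes.tsv`, `graph.tsv` (0-based edge list,
#' undirected edges once) and `truth-manifest.json` into `dir`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- data.frame(subject_id = cohort$features$subject_ids,
                   cohort$features$values, check.names = FALSE)
  fy <- data.frame(subject_id = rownames(cohort$phenotypes$values) %||%
                     cohort$features$subject_ids,
                   cohort$phenotypes$values, check.names = FALSE)
  p1 <- file.path(dir, "features.tsv"); p2 <- file.path(dir, "phenotypes.tsv")
  utils::write.table(fx, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(fy, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  A <- cohort$graph$adjacency
  ut <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  el <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L, w = A[ut])
  p3 <- file.path(dir, "graph.tsv")
  utils::write.table(el, p3, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  p4 <- file.path(dir, "truth-manifest.json")
  write_json_stable(list(seed = cohort$truth$seed,
                         noise_sd_x = cohort$truth$noise_sd_x,
                         noise_sd_y = cohort$truth$noise_sd_y,
                         d_x = ncol(cohort$features$values),
                         d_y = ncol(cohort$phenotypes$values),
                         k = ncol(cohort$truth$W_true),
                         fingerprint = cohort_fingerprint(cohort)), p4)
  invisible(c(p1, p2, p3, p4))
}
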