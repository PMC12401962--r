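# Core data model: feature tables, phenotype tables, the phenotype-dependency
# graph, and the graph penalty primitives shared by the decoder and the
# domain-aware regularizers.

#' Construct a feature matrix with modality blocks
#'
#' Observed per-subject features (rows = subjects). Columns are grouped into
#' named modality blocks (e.g. an EEG power-spectral-density block and an
#' imaging-derived block); the blocks only annotate column ranges, the values
#' are a single dense matrix.
#'
#' @param values Numeric matrix, subjects in rows.
#' @param modality_blocks Named list mapping block name to an integer vector of
#'   column indices. Defaults to a single block spanning all columns.
#' @param subject_ids Character vector of unique subject identifiers.
#' @return An object of class `lcen_features`.
#' @export
feature_matrix <- function(values,
                           modality_blocks = NULL,
                           subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_finite(values, "feature values")
  if (is.null(subject_ids)) subject_ids <- rownames(values) %||% paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique", call. = FALSE)
  if (length(subject_ids) != nrow(values)) stop("subject_ids length != number of rows", call. = FALSE)
  if (is.null(modality_blocks)) modality_blocks <- list(all = seq_len(ncol(values)))
  width <- sum(lengths(modality_blocks))
  if (width != ncol(values)) {
    stop(sprintf("modality blocks cover %d columns but matrix has %d", width, ncol(values)),
         call. = FALSE)
  }
  rownames(values) <- subject_ids
  structure(list(values = values, modality_blocks = modality_blocks,
                 subject_ids = subject_ids),
            class = "lcen_features")
}

#' Construct a phenotype matrix
#'
#' Per-subject phenotype targets. Each column is flagged continuous or binary;
#' binary columns must contain only 0/1 and are evaluated with classification
#' metrics, continuous ones with MAE/RMSE.
#'
#' @param values Numeric matrix, subjects in rows.
#' @param column_kind Character vector, one of `"continuous"`/`"binary"` per
#'   column; defaults to all continuous.
#' @param subject_ids Optional subject identifiers (must match a paired
#'   feature matrix when used together).
#' @return An object of class `lcen_phenotypes`.
#' @export
phenotype_matrix <- function(values, column_kind = NULL, subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  check_finite(values, "phenotype values")
  if (ncol(values) < 1L) stop("need at least one phenotype column", call. = FALSE)
  if (is.null(colnames(values))) colnames(values) <- paste0("y", seq_len(ncol(values)))
  if (is.null(column_kind)) column_kind <- rep("continuous", ncol(values))
  stopifnot(length(column_kind) == ncol(values), all(column_kind %in% c("continuous", "binary")))
  for (j in which(column_kind == "binary")) {
    if (!all(values[, j] %in% c(0, 1))) {
      stop(sprintf("binary phenotype column %d contains values outside {0,1}", j), call. = FALSE)
    }
  }
  if (!is.null(subject_ids)) rownames(values) <- subject_ids
  structure(list(values = values, column_names = colnames(values),
                 column_kind = column_kind),
            class = "lcen_phenotypes")
}

#' Construct a phenotype-dependency graph
#'
#' A weighted graph over phenotype dimensions. The adjacency drives
#' message-passing during decoding and the graph-smoothness regularizer; it is
#' either fixed (supplied as an edge list or matrix) or learnable (estimated
#' during fitting).
#'
#' @param adjacency Square numeric matrix (zero diagonal). For `mode = "fixed"`
#'   it must be symmetric.
#' @param mode `"fixed"` or `"learnable"`.
#' @param edge_list Optional 3-column matrix/data.frame `(i, j, weight)` with
#'   0-based node indices, undirected edges listed once; densified
#'   symmetrically into `adjacency` when the matrix is not given.
#' @param d Number of phenotype dimensions (required with `edge_list`).
#' @return An object of class `lcen_graph`.
#' @export
#' @examples
#' g <- phenotype_graph(edge_list = cbind(0, 1, 0.5), d = 2)
#' g$adjacency
phenotype_graph <- function(adjacency = NULL, mode = c("fixed", "learnable"),
                            edge_list = NULL, d = NULL) {
  mode <- match.arg(mode)
  if (is.null(adjacency)) {
    if (is.null(edge_list) || is.null(d)) {
      if (mode == "learnable" && !is.null(d)) {
        adjacency <- matrix(0, d, d)
      } else {
        stop("supply adjacency, or edge_list with d", call. = FALSE)
      }
    } else {
      edge_list <- as.matrix(edge_list)
      adjacency <- matrix(0, d, d)
      for (r in seq_len(nrow(edge_list))) {
        i <- edge_list[r, 1] + 1L; j <- edge_list[r, 2] + 1L
        if (i == j) stop("self-loops are not allowed", call. = FALSE)
        adjacency[i, j] <- edge_list[r, 3]
        adjacency[j, i] <- edge_list[r, 3]
      }
    }
  }
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square", call. = FALSE)
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  if (mode == "fixed" && max(abs(adjacency - t(adjacency))) > 1e-10) {
    stop("fixed adjacency must be symmetric", call. = FALSE)
  }
  structure(list(adjacency = adjacency, mode = mode, edge_list = edge_list),
            class = "lcen_graph")
}

#' Three-level hierarchy over phenotype columns
#'
#' Groups phenotype columns into abstraction levels (by default three:
#' sensorimotor, cognitive-control, executive) and records parent/child task
#' edges forming a DAG, used by the hierarchical attention head and the
#' hierarchy-consistency penalty.
#'
#' @param level_dims Named list mapping level (in order, low to high) to integer
#'   column indices; the levels must be disjoint.
#' @param task_edges List of `c(parent_level, child_level)` integer pairs;
#'   defaults to each level parenting the one below it.
#' @return An object of class `lcen_hierarchy`.
#' @export
#' @examples
#' hierarchy_spec(list(sensorimotor = 1:3, control = 4:6, executive = 7:10))
hierarchy_spec <- function(level_dims, task_edges = NULL) {
  stopifnot(is.list(level_dims), length(level_dims) >= 1L)
  all_cols <- unlist(level_dims)
  if (anyDuplicated(all_cols)) stop("levels must be disjoint column sets", call. = FALSE)
  L <- length(level_dims)
  if (is.null(names(level_dims))) names(level_dims) <- paste0("level", seq_len(L))
  if (is.null(task_edges) && L > 1L) {
    task_edges <- lapply(seq_len(L - 1L), function(l) c(l + 1L, l))
  }
  task_edges <- task_edges %||% list()
  # acyclicity: repeatedly peel nodes without incoming (parent) edges
  if (length(task_edges)) {
    em <- do.call(rbind, task_edges)
    if (any(em < 1L) || any(em > L)) stop("task edge references unknown level", call. = FALSE)
    remaining <- seq_len(L); edges <- em
    repeat {
      if (!nrow(edges)) break
      leaves <- setdiff(remaining, edges[, 1])
      if (!length(leaves)) stop("task_edges contain a cycle", call. = FALSE)
      remaining <- setdiff(remaining, leaves)
      edges <- edges[!(edges[, 2] %in% leaves) & !(edges[, 1] %in% leaves), , drop = FALSE]
    }
  }
  structure(list(n_levels = L, level_dims = level_dims, task_edges = task_edges),
            class = "lcen_hierarchy")
}

#' Read aligned feature/phenotype/graph tables from delimited text
#'
#' Reads a feature table and a phenotype table (TSV or CSV, auto-detected from
#' the file extension, header row required, first column = subject id), aligns
#' them by subject id, standardizes each feature column to mean 0 / SD 1, and
#' optionally reads a 3-column TSV edge list (`node_i`, `node_j`, `weight`,
#' 0-based indices) as the phenotype graph.
#'
#' Zero-variance feature columns standardize to all zeros (with a warning)
#' rather than erroring, so degenerate synthetic columns pass through.
#'
#' @param features_path,phenotypes_path Paths to delimited text tables.
#' @param graph_path Optional path to an edge-list TSV.
#' @param binary_cols Optional integer indices of phenotype columns to flag
#'   binary; by default columns containing only 0/1 are auto-flagged.
#' @return List with elements `features`, `phenotypes`, and `graph` (or NULL).
#' @export
load_tables <- function(features_path, phenotypes_path, graph_path = NULL,
                        binary_cols = NULL) {
  xt <- read_delim_auto(features_path)
  yt <- read_delim_auto(phenotypes_path)
  xid <- as.character(xt[[1]]); yid <- as.character(yt[[1]])
  if (!setequal(xid, yid)) {
    miss <- c(setdiff(xid, yid), setdiff(yid, xid))
    stop(sprintf("subject sets differ between tables; offending ids: %s",
                 paste(utils::head(miss, 10), collapse = ", ")), call. = FALSE)
  }
  yt <- yt[match(xid, yid), , drop = FALSE]
  xv <- numeric_block(xt, features_path)
  yv <- numeric_block(yt, phenotypes_path)
  # standardize features; constant columns map to zero
  sds <- apply(xv, 2, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature column(s) standardized to zeros", sum(zero)))
    sds[zero] <- 1
  }
  xv <- scale(xv, center = TRUE, scale = sds)
  attr(xv, "scaled:center") <- NULL; attr(xv, "scaled:scale") <- NULL
  fx <- feature_matrix(xv, subject_ids = xid)
  kind <- vapply(seq_len(ncol(yv)), function(j) {
    if (!is.null(binary_cols)) {
      if (j %in% binary_cols) "binary" else "continuous"
    } else if (all(yv[, j] %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  py <- phenotype_matrix(yv, column_kind = kind, subject_ids = xid)
  graph <- NULL
  if (!is.null(graph_path)) {
    el <- utils::read.table(graph_path, header = FALSE, sep = "\t")
    if (ncol(el) != 3L) stop("graph file must have 3 columns: node_i, node_j, weight", call. = FALSE)
    graph <- phenotype_graph(edge_list = el, d = ncol(yv))
  }
  list(features = fx, phenotypes = py, graph = graph)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

numeric_block <- function(df, path) {
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric cell in %s at row %d, column '%s'",
                     path, bad[1], names(vals)[j]), call. = FALSE)
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  m
}

#' Graph smoothness of a phenotype batch
#'
#' Sum over graph edges (undirected, counted once) and over the batch of the
#' squared difference between the phenotype values of the two endpoints,
#' weighted by `|A_kl|`. Acts as a weighted graph-Laplacian penalty on the
#' columns of `y`.
#'
#' Accepts plain matrices or tape nodes ([ad_const()]); with nodes the result
#' is a differentiable node.
#'
#' @param y Batch of phenotype (or predicted phenotype) vectors, subjects in
#'   rows; or an `ad_node`.
#' @param graph A [phenotype_graph()], adjacency matrix, or `ad_node`
#'   adjacency (gradients then flow into the adjacency too).
#' @return Non-negative scalar (or scalar node).
#' @export
#' @examples
#' g <- phenotype_graph(edge_list = cbind(0, 1, 1), d = 2)
#' graph_smoothness(matrix(c(0, 1), 1), g)  # (0 - 1)^2 = 1
graph_smoothness <- function(y, graph) {
  A <- if (inherits(graph, "lcen_graph")) graph$adjacency else graph
  plain <- !is_ad(y) && !is_ad(A)
  tp <- tape_of(y, A)
  yn <- as_node(tp, if (is_ad(y)) y else as.matrix(y))
  an <- as_node(tp, A)
  d <- ncol(yn$value)
  if (ncol(an$value) != d) {
    stop(sprintf("graph dimension %d does not match phenotype dimension %d",
                 ncol(an$value), d), call. = FALSE)
  }
  # D_kl = ||y^(k) - y^(l)||^2 over the batch = s_k + s_l - 2 (Y'Y)_kl;
  # total = sum over unordered edges of |A_kl| * D_kl (upper triangle once).
  gram <- ad_matmul(ad_t(yn), yn)
  s <- ad_colsums(ad_square(yn))                      # 1 x d
  D <- ad_add_rvec(ad_t(ad_add_rvec(ad_scale(gram, -2), s)), s)
  mask <- upper.tri(matrix(0, d, d))
  acc <- ad_sum(ad_mul(ad_mul(ad_abs(an), ad_const(tp, mask * 1)), D))
  if (plain) ad_value(acc)[1] else acc
}

#' Sparsity and asymmetry penalties of an adjacency
#'
#' `sparsity` is the entrywise L1 norm of the adjacency; `asymmetry` is the
#' squared Frobenius norm of `A - t(A)` (zero iff symmetric).
#'
#' @param graph A [phenotype_graph()], adjacency matrix, or `ad_node`.
#' @return List with scalar elements `sparsity` and `asymmetry` (nodes if the
#'   input was a node).
#' @export
graph_penalties <- function(graph) {
  A <- if (inherits(graph, "lcen_graph")) graph$adjacency else graph
  plain <- !is_ad(A)
  tp <- tape_of(A)
  an <- as_node(tp, A)
  if (nrow(an$value) != ncol(an$value)) stop("adjacency must be square", call. = FALSE)
  sparsity <- ad_sum(ad_abs(an))
  asym <- ad_sum(ad_square(ad_sub(an, ad_t(an))))
  if (plain) list(sparsity = ad_value(sparsity)[1], asymmetry = ad_value(asym)[1])
  else list(sparsity = sparsity, asymmetry = asym)
}

#' Project a raw matrix onto the valid adjacency set
#'
#' Symmetrizes (`(raw + t(raw))/2`), zeroes the diagonal, and, when the
#' spectral radius exceeds `1 - delta`, rescales so it equals `1 - delta`.
#' The result makes the fixed-point decoding equation `y = W z + A y`
#' well-posed (convergent Neumann series); the projection is idempotent on
#' already-valid graphs.
#'
#' @param raw Square numeric matrix.
#' @param delta Spectral margin in (0, 1); default 0.05.
#' @param mode Graph mode to stamp on the result.
#' @return A [phenotype_graph()].
#' @export
#' @examples
#' project_adjacency(matrix(c(0, 2, 2, 0), 2), delta = 0.05)$adjacency
project_adjacency <- function(raw, delta = 0.05, mode = "fixed") {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1) {
    stop("delta must lie in (0, 1)", call. = FALSE)
  }
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("raw adjacency must be square", call. = FALSE)
  A <- (raw + t(raw)) / 2
  diag(A) <- 0
  rho <- spectral_radius(A)
  if (rho > 1 - delta) A <- A * ((1 - delta) / rho)
  phenotype_graph(A, mode = mode)
}

spectral_radius <- function(A) {
  if (all(A == 0)) return(0)
  max(abs(eigen(A, only.values = TRUE)$values))
}

#' Write an adjacency as a dense TSV
#' @param graph A [phenotype_graph()] or matrix.
#' @param path Output path.
#' @export
write_adjacency <- function(graph, path) {
  A <- if (inherits(graph, "lcen_graph")) graph$adjacency else graph
  utils::write.table(A, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
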