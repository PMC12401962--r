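# Shared helpers: seeding, validation, metrics primitives.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state so library calls never disturb the
# caller's stream. All stochastic entry points route through this.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be finite and non-negative", what), call. = FALSE)
  }
  invisible(x)
}

check_finite <- function(x, what) {
  if (any(!is.finite(x))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed by integrating the empirical ROC curve with the trapezoidal rule
#' over score thresholds; ties in the scores contribute diagonal segments, so
#' the value agrees with the Mann-Whitney rank statistic exactly.
#'
#' @param scores Numeric vector of predicted scores (higher = more positive).
#' @param labels Vector of 0/1 (or logical) true labels.
#' @return AUROC in \[0, 1\], or `NA` with a warning if only one class present.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    warning("AUROC undefined: only one class present")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # Group tied scores: each distinct threshold adds one ROC vertex.
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np); fpr <- c(0, fp[last] / nn)
  sum((fpr[-1] - fpr[-length(fpr)]) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Largest-remainder apportionment of n into parts proportional to ratios;
# ties in the fractional parts go to the earlier part.
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, seq_along(frac))  # ties resolved in listed order
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

fmt_num <- function(x) sprintf("%.6g", x)
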