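# Data splitting, evaluation metrics, cross-validation, power analysis, and
# the statistical comparison protocol for metric tables from two runs.

#' Split subjects into train/validation/test index sets
#'
#' Seeded shuffle followed by largest-remainder apportionment of the sizes
#' (ties in the fractional parts resolved in train, validation, test order),
#' so e.g. 3,000 subjects at 70/15/15 give 2,100/450/450. Optional
#' stratification keeps the ratios within each stratum.
#'
#' @param n Number of subjects (>= 3).
#' @param ratios Length-3 positive vector summing to 1.
#' @param seed Integer seed for the shuffle.
#' @param stratify Optional factor/vector of length `n`; splits are computed
#'   within each level and concatenated.
#' @return List of integer index vectors `train`, `val`, `test` (disjoint,
#'   exhaustive).
#' @export
#' @examples
#' lengths(split_dataset(3000, seed = 1))  # 2100 / 450 / 450
split_dataset <- function(n, ratios = c(0.7, 0.15, 0.15), seed = 1L,
                          stratify = NULL) {
  if (n < 3) stop("need at least 3 subjects to split", call. = FALSE)
  if (length(ratios) != 3L || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be 3 positive numbers summing to 1", call. = FALSE)
  }
  if (!is.null(stratify)) {
    stopifnot(length(stratify) == n)
    groups <- split(seq_len(n), stratify)
    parts <- lapply(seq_along(groups), function(i) {
      idx <- groups[[i]]
      sizes <- largest_remainder(length(idx), ratios)
      ord <- with_seed(derive_seed(seed, i), sample(idx))
      list(train = ord[seq_len(sizes[1])],
           val = ord[sizes[1] + seq_len(sizes[2])],
           test = ord[sizes[1] + sizes[2] + seq_len(sizes[3])])
    })
    return(list(train = sort(unlist(lapply(parts, `[[`, "train"))),
                val = sort(unlist(lapply(parts, `[[`, "val"))),
                test = sort(unlist(lapply(parts, `[[`, "test")))))
  }
  sizes <- largest_remainder(n, ratios)
  ord <- with_seed(seed, sample(n))
  list(train = ord[seq_len(sizes[1])],
       val = ord[sizes[1] + seq_len(sizes[2])],
       test = ord[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Evaluate phenotype predictions
#'
#' Continuous columns get MAE and RMSE; binary columns get accuracy,
#' precision, recall, F1 (macro-averaged across binary columns) and AUROC
#' from the predicted scores (thresholded at 0.5 for the confusion counts).
#' A single-class binary column yields `NA` AUROC with a warning rather than
#' an error.
#'
#' @param y_true A [phenotype_matrix()] or numeric matrix.
#' @param y_pred Numeric matrix of predictions/scores, same shape.
#' @param column_kind Per-column `"continuous"`/`"binary"`; taken from
#'   `y_true` when it is a phenotype matrix.
#' @return List with `per_column` (data.frame) and `aggregate` (named list).
#' @export
evaluate_predictions <- function(y_true, y_pred, column_kind = NULL) {
  if (inherits(y_true, "lcen_phenotypes")) {
    column_kind <- column_kind %||% y_true$column_kind
    y_true <- y_true$values
  }
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  stopifnot(all(dim(y_true) == dim(y_pred)))
  d <- ncol(y_true)
  column_kind <- column_kind %||% rep("continuous", d)
  per <- vector("list", d)
  for (j in seq_len(d)) {
    if (column_kind[j] == "continuous") {
      per[[j]] <- data.frame(column = j, kind = "continuous",
                             mae = mean(abs(y_true[, j] - y_pred[, j])),
                             rmse = sqrt(mean((y_true[, j] - y_pred[, j])^2)),
                             accuracy = NA, precision = NA, recall = NA,
                             f1 = NA, auroc = NA)
    } else {
      lab <- y_true[, j]; sc <- y_pred[, j]
      pred <- as.numeric(sc >= 0.5)
      tp <- sum(pred == 1 & lab == 1); fp <- sum(pred == 1 & lab == 0)
      fn <- sum(pred == 0 & lab == 1)
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else NA_real_
      au <- if (length(unique(lab)) < 2) {
        warning(sprintf("AUROC undefined for single-class column %d", j))
        NA_real_
      } else auroc(sc, lab)
      per[[j]] <- data.frame(column = j, kind = "binary",
                             mae = NA, rmse = NA,
                             accuracy = mean(pred == lab),
                             precision = prec, recall = rec, f1 = f1, auroc = au)
    }
  }
  per <- do.call(rbind, per)
  cont <- per$kind == "continuous"; bin <- per$kind == "binary"
  agg <- list(
    mae = if (any(cont)) mean(per$mae[cont]) else NA_real_,
    rmse = if (any(cont)) sqrt(mean((y_true[, cont, drop = FALSE] -
                                       y_pred[, cont, drop = FALSE])^2)) else NA_real_,
    accuracy = if (any(bin)) mean(per$accuracy[bin]) else NA_real_,
    precision = if (any(bin)) mean(per$precision[bin], na.rm = TRUE) else NA_real_,
    recall = if (any(bin)) mean(per$recall[bin], na.rm = TRUE) else NA_real_,
    f1 = if (any(bin)) mean(per$f1[bin], na.rm = TRUE) else NA_real_,
    auroc = if (any(bin)) mean(per$auroc[bin], na.rm = TRUE) else NA_real_
  )
  list(per_column = per, aggregate = agg)
}

#' Evaluate a fitted model on one of its splits
#'
#' @param object A fitted [lcen()] model.
#' @param split `"val"`, `"test"`, `"train"`, or an integer index vector.
#' @param x,y Optional new data (defaults to the training-time data).
#' @return As [evaluate_predictions()].
#' @export
lcen_evaluate <- function(object, split = "test", x = NULL, y = NULL) {
  stopifnot(inherits(object, "lcen"))
  xv <- if (is.null(x)) object$x else if (inherits(x, "lcen_features")) x$values else as.matrix(x)
  yobj <- if (is.null(y)) object$y else if (inherits(y, "lcen_phenotypes")) y else phenotype_matrix(y)
  idx <- if (is.character(split)) object$split[[split]] else as.integer(split)
  preds <- predict(object, newdata = xv[idx, , drop = FALSE])
  evaluate_predictions(yobj$values[idx, , drop = FALSE], preds, yobj$column_kind)
}

#' k-fold cross-validation
#'
#' Seeded fold assignment; each fold trains a fresh model on the remaining
#' folds (internally re-split for validation-based early stopping) and is
#' evaluated on the held-out fold. Reports per-fold metrics and their
#' mean and SD.
#'
#' @param x,y Data as in [lcen()].
#' @param k Number of folds (>= 2, <= n).
#' @param graph,hierarchy,config Passed to [lcen()].
#' @param seed Integer seed (fold assignment and per-fold training).
#' @return List with `folds` (data.frame: fold, rmse, mae), `mean`, `sd`,
#'   and `assignments`.
#' @export
crossvalidate <- function(x, y, k = 5L, graph = NULL, hierarchy = NULL,
                          config = lcen_config(), seed = 1L) {
  xv <- if (inherits(x, "lcen_features")) x$values else as.matrix(x)
  yobj <- if (inherits(y, "lcen_phenotypes")) y else phenotype_matrix(y)
  n <- nrow(xv)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the number of subjects", call. = FALSE)
  fold_of <- with_seed(derive_seed(seed, 77), sample(rep(seq_len(k), length.out = n)))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- which(fold_of == f)
    keep <- which(fold_of != f)
    fit <- lcen(xv[keep, , drop = FALSE], yobj$values[keep, , drop = FALSE],
                graph = graph, hierarchy = hierarchy, config = config,
                seed = derive_seed(seed, 200 + f))
    preds <- predict(fit, newdata = xv[hold, , drop = FALSE])
    ev <- evaluate_predictions(yobj$values[hold, , drop = FALSE], preds,
                               yobj$column_kind)
    rows[[f]] <- data.frame(fold = f,
                            rmse = ev$aggregate$rmse,
                            mae = ev$aggregate$mae)
  }
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean = vapply(folds[-1], mean, numeric(1)),
       sd = vapply(folds[-1], stats::sd, numeric(1)),
       assignments = fold_of)
}

#' Minimum sample size for a paired t test
#'
#' Smallest integer `n` such that a paired t test with noncentrality
#' `d * sqrt(n)` and `n - 1` degrees of freedom attains the requested power,
#' computed from the noncentral t distribution. With a medium effect size
#' d = 0.5, alpha = 0.05 and 80% power (two-tailed), the answer is 34.
#'
#' @param effect_size Cohen's d of the paired differences (> 0).
#' @param alpha Type-I error rate in (0, 1).
#' @param power Target power in (0, 1).
#' @param two_tailed Two-tailed test (default TRUE).
#' @param max_n Search cap.
#' @return Integer minimal `n`.
#' @export
#' @examples
#' paired_ttest_power(0.5, 0.05, 0.80)  # 34
paired_ttest_power <- function(effect_size, alpha = 0.05, power = 0.80,
                               two_tailed = TRUE, max_n = 1e6) {
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  power_at <- function(n) {
    df <- n - 1
    ncp <- effect_size * sqrt(n)
    if (two_tailed) {
      crit <- stats::qt(1 - alpha / 2, df)
      stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
        stats::pt(-crit, df, ncp = ncp)
    } else {
      crit <- stats::qt(1 - alpha, df)
      stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
    }
  }
  n <- 2
  while (n <= max_n) {
    if (power_at(n) >= power) return(as.integer(n))
    n <- n + 1
  }
  stop(sprintf("requested power not attainable with n <= %g", max_n), call. = FALSE)
}

#' Statistical comparison of metric tables from two runs
#'
#' Implements the comparison protocol for paired per-fold (or per-dataset)
#' metrics: Shapiro-Wilk normality check of the paired differences, a
#' Brown-Forsythe (median-based Levene) variance-homogeneity check, a paired
#' two-tailed t test when normality holds and a Wilcoxon signed-rank test
#' otherwise, with Holm correction across metrics.
#'
#' @param a,b Data frames (or matrices) of metrics with identical columns;
#'   rows are paired observations.
#' @param alpha Significance level for the normality gate.
#' @return Data.frame with one row per metric: test used, statistic, raw and
#'   Holm-adjusted p values, and the normality/variance diagnostics.
#' @export
compare_runs <- function(a, b, alpha = 0.05) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  common <- intersect(names(a), names(b))
  common <- common[vapply(common, function(nm) is.numeric(a[[nm]]), logical(1))]
  if (!length(common)) stop("no shared numeric metric columns", call. = FALSE)
  rows <- lapply(common, function(nm) {
    x <- a[[nm]]; y <- b[[nm]]
    stopifnot(length(x) == length(y))
    d <- x - y
    sw_p <- if (length(d) >= 3 && stats::sd(d) > 0) stats::shapiro.test(d)$p.value else NA_real_
    lev_p <- brown_forsythe(x, y)
    if (!is.na(sw_p) && sw_p >= alpha) {
      tt <- stats::t.test(x, y, paired = TRUE)
      data.frame(metric = nm, test = "paired t", statistic = unname(tt$statistic),
                 p = tt$p.value, shapiro_p = sw_p, levene_p = lev_p)
    } else {
      wt <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
      data.frame(metric = nm, test = "wilcoxon", statistic = unname(wt$statistic),
                 p = wt$p.value, shapiro_p = sw_p, levene_p = lev_p)
    }
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

# Brown-Forsythe: ANOVA on absolute deviations from group medians.
brown_forsythe <- function(x, y) {
  g <- factor(rep(c("a", "b"), c(length(x), length(y))))
  v <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  if (stats::sd(v) == 0) return(NA_real_)
  stats::anova(stats::lm(v ~ g))[["Pr(>F)"]][1]
}
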