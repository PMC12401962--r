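# Splitting, metrics, cross-validation, power analysis, comparison protocol,
# and trainer bookkeeping/determinism.

test_that("70/15/15 splits reproduce the printed cohort tables and rounding rule", {
  s <- split_dataset(3000, seed = 1)
  expect_equal(lengths(s), c(train = 2100L, val = 450L, test = 450L))
  s2 <- split_dataset(10300, seed = 1)
  expect_equal(lengths(s2), c(train = 7210L, val = 1545L, test = 1545L))
  # largest remainder, ties resolved train > val > test
  s3 <- split_dataset(10, seed = 1)
  expect_equal(lengths(s3), c(train = 7L, val = 2L, test = 1L))
  # disjoint and exhaustive
  all_idx <- sort(unname(unlist(s3)))
  expect_equal(all_idx, 1:10)
  expect_error(split_dataset(2), "at least 3")
  expect_error(split_dataset(100, ratios = c(0.5, 0.2, 0.2)), "summing to 1")
  # seeded: reproducible
  expect_identical(split_dataset(100, seed = 9), split_dataset(100, seed = 9))
})

test_that("stratified splits keep the ratios within each stratum", {
  strata <- rep(c(0, 1), c(80, 20))
  s <- split_dataset(100, seed = 3, stratify = strata)
  expect_equal(sum(strata[s$train]), 14)  # 70% of 20 positives
  expect_equal(sum(strata[s$val]), 3)
  expect_equal(sum(strata[s$test]), 3)
})

test_that("evaluation metrics match their definitions, including AUROC tie handling", {
  # perfect continuous predictions
  y <- matrix(rnorm(12), 4, 3)
  ev <- evaluate_predictions(y, y)
  expect_equal(ev$aggregate$mae, 0)
  expect_equal(ev$aggregate$rmse, 0)

  # perfect ranking -> AUROC 1
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all-tied scores -> AUROC 0.5 by the rank statistic
  expect_equal(auroc(rep(0.6, 4), c(1, 0, 1, 0)), 0.5)

  # AUROC equals the Mann-Whitney rank formulation on random instances
  set.seed(71)
  for (rep in 1:20) {
    n <- 40
    sc <- round(rnorm(n), 1)  # coarse scores force ties
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    r <- rank(sc)
    np <- sum(lab == 1); nn <- sum(lab == 0)
    u <- sum(r[lab == 1]) - np * (np + 1) / 2
    expect_equal(auroc(sc, lab), u / (np * nn), tolerance = 1e-12)
  }

  # mixed-kind table
  yt <- phenotype_matrix(cbind(c(0.5, 1, 2), c(1, 0, 1)),
                         column_kind = c("continuous", "binary"))
  yp <- cbind(c(0.4, 1.3, 2.0), c(0.9, 0.2, 0.7))
  ev2 <- evaluate_predictions(yt, yp)
  expect_equal(ev2$per_column$mae[1], mean(abs(c(0.1, 0.3, 0))))
  expect_equal(ev2$per_column$auroc[2], 1)
  expect_equal(ev2$per_column$accuracy[2], 1)

  # single-class binary column: NA with a warning, not an error
  yt2 <- phenotype_matrix(cbind(c(1, 1, 1)), column_kind = "binary")
  expect_warning(ev3 <- evaluate_predictions(yt2, cbind(c(0.9, 0.8, 0.7))),
                 "single-class")
  expect_true(is.na(ev3$per_column$auroc[1]))
})

test_that("power analysis reproduces the printed minimum n and its limits", {
  expect_equal(paired_ttest_power(0.5, 0.05, 0.80), 34L)
  expect_equal(paired_ttest_power(50, 0.05, 0.80), 2L)  # saturation at minimum df
  expect_error(paired_ttest_power(1e-4, 0.05, 0.8, max_n = 1000), "not attainable")

  # Monte-Carlo oracle: simulated power at n and n-1 brackets the target
  with_seed <- lcen:::with_seed
  mc_power <- function(n, d, reps = 4000) {
    with_seed(1234, {
      hits <- 0L
      for (r in seq_len(reps)) {
        x <- rnorm(n, mean = d)
        if (abs(mean(x)) / (sd(x) / sqrt(n)) > qt(0.975, n - 1)) hits <- hits + 1L
      }
      hits / reps
    })
  }
  n_star <- paired_ttest_power(0.5, 0.05, 0.80)
  expect_gte(mc_power(n_star, 0.5), 0.80 - 0.02)
  expect_lt(mc_power(n_star - 1, 0.5), 0.80 + 0.02)
})

test_that("run comparison applies the documented normality-gated protocol", {
  set.seed(72)
  a <- data.frame(rmse = rnorm(8, 1, 0.05), mae = rnorm(8, 0.8, 0.05))
  b <- data.frame(rmse = a$rmse + 0.1, mae = a$mae + rexp(8) * 0.01)
  out <- compare_runs(a, b)
  expect_equal(nrow(out), 2)
  expect_true(all(out$test %in% c("paired t", "wilcoxon")))
  expect_true(all(out$p_holm >= out$p - 1e-15))
  expect_lt(out$p[out$metric == "rmse"], 0.01)  # constant shift is detected
})

test_that("training history logs every component and learning rate 0 freezes parameters", {
  cohort <- simulate_cohort(n = 60, d_x = 8, d_y = 6, k = 2, seed = 6)
  cfg <- lean_config(training = list(max_epochs = 5L, patience = 5L))
  fit <- lcen(cohort$features, cohort$phenotypes, graph = cohort$graph,
              config = cfg, seed = 4)
  expect_equal(nrow(fit$history), 5)
  expect_true(all(c("epoch", "total", "reconstruction", "kl", "val_loss")
                  %in% names(fit$history)))
  # aggregate equals the sum of logged components
  comp_cols <- setdiff(names(fit$history),
                       c("epoch", "total", "val_loss",
                         grep("^alpha_|^lambda_task_|^sigma2_task_", names(fit$history), value = TRUE)))
  expect_equal(rowSums(fit$history[comp_cols]), fit$history$total, tolerance = 1e-9)

  cfg0 <- lean_config(training = list(max_epochs = 2L, patience = 5L, lr = 0))
  fit0 <- lcen(cohort$features, cohort$phenotypes, config = cfg0, seed = 4)
  p_init <- init_lcen_params(8, 6, cfg0, fit0$hierarchy, seed = lcen:::derive_seed(4, 1))
  expect_identical(fit0$params$encoder$W[[1]], p_init$encoder$W[[1]])
  expect_identical(fit0$params$decoder$W_d, p_init$decoder$W_d)
})

test_that("identical config and seed give byte-identical metrics files", {
  cohort <- simulate_cohort(n = 60, d_x = 8, d_y = 6, k = 2, seed = 8)
  cfg <- lean_config(training = list(max_epochs = 3L, patience = 3L))
  run <- function(path) {
    fit <- lcen(cohort$features, cohort$phenotypes, config = cfg, seed = 11)
    ev <- lcen_evaluate(fit, "test")
    jsonlite::write_json(ev$aggregate, path, auto_unbox = TRUE, digits = NA)
    path
  }
  f1 <- run(tempfile(fileext = ".json"))
  f2 <- run(tempfile(fileext = ".json"))
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("five-fold cross-validation partitions exhaustively and reproducibly", {
  cohort <- simulate_cohort(n = 100, d_x = 8, d_y = 6, k = 2, seed = 9)
  cfg <- lean_config(training = list(max_epochs = 3L, patience = 3L))
  cv <- crossvalidate(cohort$features, cohort$phenotypes, k = 5, config = cfg, seed = 5)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(as.numeric(table(cv$assignments)), rep(20, 5))
  expect_true(all(is.finite(cv$folds$rmse)))
  expect_equal(cv$sd[["rmse"]], sd(cv$folds$rmse))
  cv2 <- crossvalidate(cohort$features, cohort$phenotypes, k = 5, config = cfg, seed = 5)
  expect_identical(cv$assignments, cv2$assignments)
  expect_error(crossvalidate(cohort$features, cohort$phenotypes, k = 200, config = cfg),
               "exceed")
})

test_that("a noiseless linear cohort is fit to near-zero validation RMSE", {
  cohort <- simulate_cohort(n = 400, d_x = 12, d_y = 6, k = 3, seed = 13,
                            noise_sd_x = 0, noise_sd_y = 0)
  cfg <- lean_config(training = list(max_epochs = 200L, patience = 200L,
                                     lr = 0.01, batch_size = 64L))
  fit <- lcen(cohort$features, cohort$phenotypes, graph = cohort$graph,
              config = cfg, seed = 3)
  expect_lt(fit$metrics$val_rmse, 0.05)
})
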