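# Panel selection and frozen-model transfer.

test_that("stratified split reproduces the published discovery-train counts", {
  s <- make_samples(2131, c(rep("CO", 1381), rep("AD", 750)))
  sp <- split_train_test(s, 0.7, seed = 5)
  tr <- s[s$sample_id %in% sp$train, ]
  expect_identical(sum(tr$clinical_status == "CO"), 967L)
  expect_identical(sum(tr$clinical_status == "AD"), 525L)
  expect_identical(split_train_test(s, 0.7, seed = 5)$train, sp$train)
  expect_false(identical(split_train_test(s, 0.7, seed = 6)$train, sp$train))
  # rounding bound per stratum
  for (frac in c(0.5, 0.63, 0.8)) {
    sp2 <- split_train_test(s, frac, seed = 1)
    tr2 <- s[s$sample_id %in% sp2$train, ]
    for (st in c("CO", "AD")) {
      n_st <- sum(s$clinical_status == st)
      expect_lte(abs(sum(tr2$clinical_status == st) - frac * n_st), 0.5)
    }
  }
  expect_error(split_train_test(s[1, ], 0.7), "fewer than 2")
})

test_that("rank AUC matches pairwise concordance", {
  expect_equal(plasmad:::auc_rank(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  # positives {0.9, 0.4}, negatives {0.8, 0.2}: 3 of 4 concordant pairs
  expect_equal(plasmad:::auc_rank(c(0.9, 0.4, 0.8, 0.2), c(1, 1, 0, 0)), 0.75)
  set.seed(19)
  aucs <- replicate(200, plasmad:::auc_rank(stats::rnorm(40), sample(rep(0:1, 20))))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the 90%-of-best rule picks the documented lambda", {
  path <- structure(list(lambda = c(4, 3, 2, 1),
                         cv_mean = c(0.70, 0.80, 0.86, 0.90),
                         metric = "auc",
                         selected = list("a", c("a", "b"), c("a", "b", "c"),
                                         c("a", "b", "c", "d"))),
                    class = "lasso_path")
  # chance-relative: best gini 0.40, threshold 0.36 -> AUC >= 0.86 -> 3rd entry
  sel <- select_lambda_90(path)
  expect_identical(sel$index, 3L)
  expect_identical(sel$selected, c("a", "b", "c"))
  # absolute ratio reading gives the same answer here (threshold 0.81)
  expect_identical(select_lambda_90(path, baseline = "absolute")$index, 3L)
  # flat path: largest lambda
  flat <- path; flat$cv_mean <- rep(0.8, 4)
  expect_identical(select_lambda_90(flat)$index, 1L)
  # retention = 1: largest lambda attaining the maximum
  expect_identical(select_lambda_90(path, retention = 1)$index, 4L)
  expect_error(select_lambda_90(path, retention = 0), "retention")
})

test_that("lasso path: separating candidate selected, noise stays near baseline", {
  set.seed(20)
  n <- 240
  s <- make_samples(n, sample(rep(c("CO", "AD"), n / 2)),
                    age = stats::rnorm(n, 70, 6))
  y <- as.numeric(s$clinical_status == "AD")
  z <- matrix(stats::rnorm(n * 30), n, 30,
              dimnames = list(s$sample_id, sprintf("N%02d", 1:30)))
  z <- cbind(z, sep = y * 4 + stats::rnorm(n, 0, 0.3))
  path <- suppressWarnings(lasso_path_cv(z, s, colnames(z), seed = 20))
  sel <- select_lambda_90(path)
  expect_true("sep" %in% sel$selected)
  # pure-noise candidates: best CV AUC close to the covariate-only baseline
  z0 <- z[, 1:30]
  path0 <- suppressWarnings(lasso_path_cv(z0, s, colnames(z0), seed = 20))
  base_fit <- stats::glm(y ~ s$age_at_draw + (s$sex == "male"),
                         family = stats::binomial())
  base_auc <- plasmad:::auc_rank(stats::fitted(base_fit), y)
  expect_lt(max(path0$cv_mean, na.rm = TRUE), base_auc + 0.08)
  expect_error(lasso_path_cv(z, s, "absent"), "absent")
})

test_that("frozen models are deterministic, order-invariant and serializable", {
  tc <- tiny_cohort()
  sel <- colnames(tc$z)[1:4]
  m1 <- refit_and_freeze(tc$z, tc$samples, sel, seed = 1)
  # frozen predictions on the training data reproduce the stored scores
  pr <- predict(m1, tc$z, tc$samples)
  expect_equal(unname(pr[m1$train_meta$train_ids]),
               m1$train_meta$train_scores, tolerance = 1e-12)
  # column order of the matrix does not matter
  m2 <- refit_and_freeze(tc$z[, rev(colnames(tc$z))], tc$samples, sel, seed = 1)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
  # empty selection -> covariate-only baseline
  m0 <- refit_and_freeze(tc$z, tc$samples, character(0), seed = 1)
  expect_identical(sort(names(m0$coefficients)), c("(Intercept)", "age", "sexM"))
  # JSON round trip preserves scores
  f <- withr::local_tempfile(fileext = ".json")
  write_frozen_model(m1, f)
  m1b <- read_frozen_model(f)
  expect_equal(predict(m1b, tc$z, tc$samples), pr, tolerance = 1e-12)
})

test_that("undersampled evaluation matches size and composition exactly", {
  set.seed(21)
  y <- c(rep(1, 60), rep(0, 140))
  cell <- factor(c(rep("f", 40), rep("m", 20), rep("f", 50), rep("m", 90)))
  for (i in 1:20) {
    pick <- plasmad:::undersample_matched(y, cell)
    expect_identical(sum(y[pick] == 1), sum(y[pick] == 0))
    expect_identical(table(cell[pick], y[pick])[, "0"],
                     table(cell[pick], y[pick])[, "1"])
    expect_false(anyDuplicated(pick) > 0)
  }

  tc <- tiny_cohort()
  m <- refit_and_freeze(tc$z, tc$samples, colnames(tc$z)[1:3], seed = 1)
  ev <- evaluate_model(m, tc$z, tc$samples, mode = "undersampled", n_iter = 10,
                       seed = 2)
  expect_identical(ev$metric,
                   c("auc", "accuracy", "sensitivity", "specificity", "npv", "ppv"))
  expect_true(all(ev$min <= ev$mean & ev$mean <= ev$max))
  expect_true(all(ev$max <= 1 & ev$min >= 0))
  # permuted labels give chance-level AUC on average
  set.seed(22)
  sh <- tc$samples
  sh$clinical_status <- sample(sh$clinical_status)
  ev0 <- evaluate_model(m, tc$z, sh, mode = "undersampled", n_iter = 50, seed = 3)
  expect_lt(abs(ev0$mean[ev0$metric == "auc"] - 0.5), 0.06)
})

test_that("horizon AUC applies the inclusion rules", {
  base <- structure(list(analytes = character(0),
                         coefficients = c(`(Intercept)` = -7, age = 0.1, sexM = 0),
                         cutoff = 0.5, cutoff_rule = "prob0.5",
                         center = numeric(0), scale = numeric(0),
                         train_meta = list(seed = 1)),
                    class = "frozen_panel_model")
  n <- 40
  s <- make_samples(n, rep("CO", n),
                    age = c(rep(80, 10), rep(60, 30)))  # converters oldest
  z <- matrix(numeric(0), n, 0, dimnames = list(s$sample_id, NULL))
  si <- data.frame(sample_id = s$sample_id,
                   duration = c(rep(4, 10), rep(3, 10), rep(12, 20)),
                   event = c(rep(1L, 10), rep(0L, 30)))
  res <- suppressWarnings(horizon_auc(base, z, s, si, horizons = c(5, 10)))
  # 10 early-censored non-converters are excluded from the 5y horizon
  expect_identical(res$n_pos, c(10L, 10L))
  expect_identical(res$n_neg, c(20L, 20L))
  expect_equal(res$auc, c(1, 1))  # converters are the oldest -> score 1
  expect_warning(horizon_auc(base, z, s, si, horizons = 20), "no positives")
})

test_that("seeded end-to-end training is deterministic and transfers frozen", {
  tc <- tiny_cohort()
  cand <- colnames(tc$z)[1:25]
  t1 <- suppressWarnings(train_panel(tc$z, tc$samples, cand, seed = 30))
  t2 <- suppressWarnings(train_panel(tc$z, tc$samples, cand, seed = 30))
  expect_identical(t1$model$coefficients, t2$model$coefficients)
  expect_identical(t1$model$cutoff, t2$model$cutoff)
  # transfer: scoring a re-normalized external dataset leaves the frozen
  # coefficients untouched
  cf <- sim_config(n_co = 80, n_ad = 60, n_analytes = 60, n_plates = 2,
                   fraction_nonnull = 0.05, effect_size_sd = 0.4,
                   cohort = "EXT", dataset_cluster = "cX", seed = 99)
  ext <- simulate_cohort(cf)
  zx <- zscore_normalize(ext$matrix,
                         stats::setNames(ext$samples$dataset_cluster,
                                         ext$samples$sample_id))
  coef_hash <- digest_coef <- paste(sprintf("%.15g", t1$model$coefficients),
                                    collapse = ",")
  mets <- evaluate_model(t1$model, zx, ext$samples)
  expect_identical(paste(sprintf("%.15g", t1$model$coefficients), collapse = ","),
                   coef_hash)
  expect_true(all(mets[c("auc", "accuracy")] >= 0 & mets[c("auc", "accuracy")] <= 1))
})
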