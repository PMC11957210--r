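# QC cascade: analyte filters, Tukey masking, two-pass call rate,
# per-cluster z-normalization.

test_that("LOD filter removes analytes mostly below detection", {
  vals <- matrix(10, 10, 2, dimnames = list(sprintf("S%02d", 1:10), c("A1", "A2")))
  vals[1:9, 1] <- 0.5  # 90% of A1 below its LOD of 1
  lod <- matrix(c(1, 0.1), 2, 1, dimnames = list(c("A1", "A2"), "P1"))
  pm <- make_pm(vals, lod = lod)
  out <- apply_analyte_filters(pm)
  expect_identical(out$report$analytes_removed$lod, "A1")
  expect_identical(colnames(out$matrix$values), "A2")
})

test_that("scale-factor filter removes deviation > 0.5 from the plate median", {
  vals <- matrix(100, 6, 3, dimnames = list(sprintf("S%d", 1:6), c("A1", "A2", "A3")))
  vals <- vals + matrix(seq(0, 5), 6, 3)  # small spread, CV far below 0.15
  sf <- matrix(c(1.6, 1.0, 0.95), 3, 1, dimnames = list(c("A1", "A2", "A3"), "P1"))
  pm <- make_pm(vals, scale_factor = sf)
  out <- apply_analyte_filters(pm)
  expect_identical(out$report$analytes_removed$scale_factor, "A1")
})

test_that("CV filter: sd/mean of {100,100,100,140} = 20/110 > 0.15", {
  expect_equal(stats::sd(c(100, 100, 100, 140)) / 110, 0.1818, tolerance = 1e-3)
  vals <- cbind(A1 = c(100, 100, 100, 140), A2 = c(100, 101, 102, 103))
  rownames(vals) <- sprintf("S%d", 1:4)
  out <- apply_analyte_filters(make_pm(vals))
  expect_identical(out$report$analytes_removed$cv, "A1")
  # global scope agrees here (single plate)
  out2 <- apply_analyte_filters(make_pm(vals), cv_scope = "global")
  expect_identical(out2$report$analytes_removed$cv, "A1")
})

test_that("analyte filters validate thresholds and refuse to empty the matrix", {
  vals <- cbind(A1 = c(100, 100, 100, 190))
  rownames(vals) <- sprintf("S%d", 1:4)
  expect_error(apply_analyte_filters(make_pm(vals), lod_frac = 0), "lod_frac")
  err <- tryCatch(apply_analyte_filters(make_pm(vals)), error = identity)
  expect_match(conditionMessage(err), "all analytes removed")
  expect_identical(err$report$analytes_removed$cv, "A1")
})

test_that("Tukey fences on log10 values mask the planted outlier only", {
  vals <- cbind(A1 = 10^c(1, 1, 1, 1, 1, 9), A2 = 10^c(2, 2, 2, 2, 2, 2))
  rownames(vals) <- sprintf("S%d", 1:6)
  out <- flag_outliers_iqr(make_pm(vals))
  expect_identical(out$n_masked, 1L)
  expect_true(is.na(out$matrix$values[6, "A1"]))
  expect_true(all(!is.na(out$matrix$values[, "A2"])))  # constant: nothing masked
  # symmetric tight data stays intact, and a second pass masks nothing new
  vals2 <- cbind(A1 = 10^seq(0.9, 1.1, length.out = 12))
  rownames(vals2) <- sprintf("S%02d", 1:12)
  out2 <- flag_outliers_iqr(make_pm(vals2))
  expect_identical(out2$n_masked, 0L)
  expect_identical(flag_outliers_iqr(out$matrix)$n_masked, 0L)
})

test_that("two-pass call-rate filter removes in the documented order", {
  # A1 observed in 60% of samples -> pass 1
  vals <- matrix(1, 10, 4, dimnames = list(sprintf("S%02d", 1:10),
                                           c("A1", "A2", "A3", "A4")))
  vals[1:4, "A1"] <- NA
  out <- call_rate_filter(make_pm(vals))
  expect_identical(out$report$analytes_removed$call_rate_pass1, "A1")
  expect_length(out$report$analytes_removed$call_rate_pass2, 0)

  # A2 sits at 80% only after the pass-1 removal of a bad subject:
  # incoming rate 9/10 = 90% (passes pass 1 and pass 2 thresholds on the
  # incoming matrix), but S10 (call rate 50% < 65%) is removed in pass 1,
  # and A2 drops to 7/9 = 78% < 85% -> removed in pass 2 only.
  vals <- matrix(1, 10, 10, dimnames = list(sprintf("S%02d", 1:10),
                                            sprintf("A%02d", 1:10)))
  vals[10, 1:5] <- NA          # subject S10 at 50%
  vals[c(8, 9), "A06"] <- NA   # A06 at 8/10 on the incoming matrix
  out <- call_rate_filter(make_pm(vals))
  expect_identical(out$report$samples_removed$call_rate_pass1, "S10")
  expect_identical(out$report$analytes_removed$call_rate_pass2, "A06")
  expect_length(out$report$analytes_removed$call_rate_pass1, 0)

  # fully observed matrix passes untouched
  vals3 <- matrix(1, 5, 5, dimnames = list(sprintf("S%d", 1:5), sprintf("A%d", 1:5)))
  out3 <- call_rate_filter(make_pm(vals3))
  expect_identical(out3$matrix$values, vals3)

  # report invariants: disjoint passes, final min call rate >= pass2
  expect_length(intersect(out$report$analytes_removed$call_rate_pass1,
                          out$report$analytes_removed$call_rate_pass2), 0)
  expect_gte(min(out$report$call_rate$after$analyte,
                 out$report$call_rate$after$sample), 0.85)
})

test_that("z-normalization is exact per cluster and strips cluster shifts", {
  set.seed(5)
  vals <- matrix(10^stats::rnorm(200, 3, 0.1), 20, 10,
                 dimnames = list(sprintf("S%02d", 1:20), sprintf("A%02d", 1:10)))
  cl <- rep(c("c1", "c2"), each = 10)
  vals[cl == "c2", ] <- vals[cl == "c2", ] * 7  # multiplicative batch shift
  z <- zscore_normalize(make_pm(vals), cl)
  for (c0 in unique(cl)) {
    expect_true(all(abs(colMeans(z[cl == c0, ])) < 1e-10))
    expect_true(all(abs(apply(z[cl == c0, ], 2, stats::sd) - 1) < 1e-10))
  }
  # the batch shift is gone: cluster means agree to numerical zero
  expect_true(all(abs(colMeans(z[cl == "c1", ]) - colMeans(z[cl == "c2", ])) < 1e-9))
})

test_that("constant analyte within a cluster is dropped with a warning", {
  vals <- cbind(A1 = c(1, 1, 1, 2, 3, 4), A2 = c(1, 2, 3, 4, 5, 6))
  rownames(vals) <- sprintf("S%d", 1:6)
  cl <- rep(c("c1", "c2"), each = 3)
  expect_warning(z <- zscore_normalize(make_pm(vals), cl), "zero within-cluster")
  expect_identical(colnames(z), "A2")
  expect_error(zscore_normalize(make_pm(vals), rep(c("a", "b", "c"), 2)),
               "at least 3")
})

test_that("run_qc: clean cohort passes untouched; one engineered failure per reason", {
  tc <- tiny_cohort()
  cl <- stats::setNames(tc$samples$dataset_cluster, tc$samples$sample_id)
  qc <- run_qc(tc$matrix, cl)
  expect_length(unlist(qc$report$analytes_removed), 0)
  expect_length(unlist(qc$report$samples_removed), 0)

  # engineered failures: LOD (A-first), scale factor, CV, call rate
  pm <- tc$matrix
  a <- colnames(pm$values)
  pm$lod[a[1], ] <- Inf                       # everything below LOD
  pm$scale_factor[a[2], 1] <- pm$scale_factor[a[2], 1] + 0.9
  bad_cv <- seq(1, nrow(pm$values), by = 3)
  pm$values[bad_cv, a[3]] <- pm$values[bad_cv, a[3]] * 2.5
  pm$values[seq(1, floor(0.4 * nrow(pm$values))), a[4]] <- NA
  qc2 <- run_qc(pm, cl)
  expect_identical(qc2$report$analytes_removed$lod, a[1])
  expect_identical(qc2$report$analytes_removed$scale_factor, a[2])
  expect_identical(qc2$report$analytes_removed$cv, a[3])
  expect_identical(qc2$report$analytes_removed$call_rate_pass1, a[4])
  expect_false(any(c(a[1], a[2], a[3], a[4]) %in% colnames(qc2$zscores)))

  # determinism and no alteration of retained raw values
  qc3 <- run_qc(pm, cl)
  expect_identical(qc2$zscores, qc3$zscores)
  kept <- qc2$matrix$values
  orig <- pm$values[rownames(kept), colnames(kept)]
  same <- !is.na(kept)
  expect_identical(kept[same], orig[same])
})
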