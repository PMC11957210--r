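# Sparse predictive panel: stratified train/test split, five-fold
# cross-validated L1-penalized logistic path over the candidate analytes
# (age/sex unpenalized), the "highest lambda retaining 90% of best CV
# performance" rule, an unpenalized logistic refit whose weights, cutoff and
# standardization constants are frozen for transfer, undersampled matched
# evaluation, and conversion-horizon AUCs.

#' Stratified train/test split
#'
#' Allocates `round(train_frac * n)` samples of each stratum to the training
#' set (nearest-integer rounding), deterministically under the seed.
#'
#' @param samples Metadata table.
#' @param train_frac Training fraction (default 0.7).
#' @param stratify_by Column used as the stratum (default `clinical_status`).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample-id vectors.
#' @export
split_train_test <- function(samples, train_frac = 0.7,
                             stratify_by = "clinical_status", seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)")
  strata <- split(samples$sample_id, samples[[stratify_by]])
  set.seed(seed)
  train <- unlist(lapply(strata, function(ids) {
    if (length(ids) < 2) stop("stratum with fewer than 2 samples")
    n_tr <- floor(train_frac * length(ids) + 0.5)
    sample(ids, n_tr)
  }), use.names = FALSE)
  list(train = train, test = setdiff(samples$sample_id, train))
}

# rank-based AUC (probability a random positive scores above a random
# negative; ties count 1/2)
auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Design matrix for panel fitting/scoring. Missing normalized protein
# values are imputed at 0 (the within-cluster mean on the z scale) so that
# sporadic LOD missingness does not discard whole samples; rows with missing
# age or sex are dropped.
panel_design <- function(zmat, samples, analytes) {
  ids <- intersect(rownames(zmat), samples$sample_id)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  z <- zmat[ids, analytes, drop = FALSE]
  z[is.na(z)] <- 0
  x <- cbind(z, age = samples$age_at_draw,
             sexM = as.numeric(samples$sex == "male"))
  y <- as.numeric(samples$clinical_status == "AD")
  keep <- stats::complete.cases(x)
  list(x = x[keep, , drop = FALSE], y = y[keep], ids = ids[keep])
}

#' Cross-validated Lasso path over candidate analytes
#'
#' L1-penalized logistic regression of AD status on the candidate analytes
#' with age and sex as unpenalized covariates, over a descending grid of 100
#' lambda values spanning four orders of magnitude below the smallest lambda
#' that zeroes all penalized coefficients. Folds are stratified by label;
#' analyte predictors are standardized on the training data only and the
#' constants retained. Per-lambda cross-validated mean AUC (or binomial
#' deviance) is recorded together with the selected analyte set.
#'
#' @param zmat Normalized matrix, samples x analytes.
#' @param samples Metadata (CO/AD rows used).
#' @param candidate_analytes Analyte ids to penalize over.
#' @param k_folds Number of CV folds (default 5).
#' @param seed Integer seed (fold assignment).
#' @param metric `"auc"` (default) or `"deviance"`.
#' @return Object of class `lasso_path`: `lambda` (descending), `cv_mean`,
#'   `cv_sd`, `n_selected`, `selected` (list per lambda), the fitted glmnet
#'   object and standardization constants.
#' @export
lasso_path_cv <- function(zmat, samples, candidate_analytes,
                          k_folds = 5, seed = 1L,
                          metric = c("auc", "deviance")) {
  metric <- match.arg(metric)
  if (length(candidate_analytes) < 1) stop("need at least one candidate analyte")
  missing_c <- setdiff(candidate_analytes, colnames(zmat))
  if (length(missing_c)) stop("candidates absent from matrix: ",
                              paste(missing_c, collapse = ", "))
  samples <- samples[samples$clinical_status %in% c("CO", "AD"), , drop = FALSE]
  d <- panel_design(zmat, samples, candidate_analytes)
  if (length(unique(d$y)) < 2) stop("training labels are single-class")

  center <- colMeans(d$x[, candidate_analytes, drop = FALSE])
  scale_ <- apply(d$x[, candidate_analytes, drop = FALSE], 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- d$x
  xs[, candidate_analytes] <- sweep(sweep(xs[, candidate_analytes, drop = FALSE],
                                          2, center), 2, scale_, `/`)

  set.seed(seed)
  foldid <- integer(length(d$y))
  for (cls in unique(d$y)) {
    idx <- which(d$y == cls)
    foldid[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  if (any(tapply(d$y, foldid, function(v) length(unique(v))) < 2))
    stop("a fold contains a single class")

  pf <- c(rep(1, length(candidate_analytes)), 0, 0)  # age/sex unpenalized
  cv <- glmnet::cv.glmnet(xs, d$y, family = "binomial",
                          type.measure = if (metric == "auc") "auc" else "deviance",
                          foldid = foldid, penalty.factor = pf,
                          nlambda = 100, standardize = FALSE)
  beta <- cv$glmnet.fit$beta[candidate_analytes, , drop = FALSE]
  lam <- cv$glmnet.fit$lambda
  sel <- lapply(seq_along(lam), function(j)
    candidate_analytes[which(beta[, j] != 0)])
  cvm <- cv$cvm[match(lam, cv$lambda)]
  cvs <- cv$cvsd[match(lam, cv$lambda)]
  n_sel <- vapply(sel, length, 1L)
  if (any(diff(n_sel) < 0))
    warning("selected-set size not monotone along the path (expected occasionally)")
  structure(list(lambda = lam,
                 cv_mean = if (metric == "auc") cvm else -cvm,
                 cv_sd = cvs, metric = metric,
                 n_selected = n_sel, selected = sel,
                 center = center, scale = scale_,
                 cv_fit = cv, seed = seed),
            class = "lasso_path")
}

#' Select lambda by the 90%-of-best rule
#'
#' Returns the largest lambda whose cross-validated performance retains at
#' least `retention` of the best over the path; ties take the largest
#' lambda. For AUC paths, retention is measured on discrimination above
#' chance (`AUC - 0.5`, i.e. the Gini coefficient) by default: an absolute
#' AUC ratio would treat the chance level 0.5 as retained performance and
#' make 90% reachable by near-trivial models regardless of effect size. The
#' absolute-ratio reading is available via `baseline = "absolute"`. Deviance
#' paths use the negated deviance, so "best" is always the maximum.
#'
#' @param path A [lasso_path_cv()] result.
#' @param retention Retention fraction in (0, 1] (default 0.90).
#' @param baseline `"chance"` (default; retain 90% of `AUC - 0.5`) or
#'   `"absolute"` (retain 90% of the raw metric).
#' @return List with `lambda`, `index`, `selected` analytes at that lambda.
#' @export
select_lambda_90 <- function(path, retention = 0.90,
                             baseline = c("chance", "absolute")) {
  if (retention <= 0 || retention > 1) stop("retention must lie in (0, 1]")
  baseline <- match.arg(baseline)
  perf <- path$cv_mean
  if (identical(path$metric, "auc") && baseline == "chance")
    perf <- perf - 0.5
  ok <- which(!is.na(perf))
  if (!length(ok)) stop("empty path")
  best <- max(perf[ok])
  thr <- if (best >= 0) retention * best else best / retention
  idx <- ok[perf[ok] >= thr - 1e-9 * max(1, abs(thr))]
  i <- idx[which.max(path$lambda[idx])]  # lambda grid is descending
  list(lambda = path$lambda[i], index = i, selected = path$selected[[i]],
       cv_performance = path$cv_mean[i], best_performance = max(path$cv_mean[ok]))
}

#' Refit the selected panel and freeze it
#'
#' Unpenalized logistic refit of AD status on the selected analytes plus age
#' and sex on the training data. The probability cutoff is fixed from the
#' training ROC (Youden's J by default) and, together with the weights and
#' the training standardization constants, frozen: the model is applied to
#' any later dataset without re-estimation. An empty selection yields the
#' age+sex baseline model. Separation falls back to a lightly ridged fit
#' with a warning.
#'
#' @param zmat Normalized training matrix.
#' @param samples Training metadata.
#' @param selected Analyte ids (possibly empty).
#' @param cutoff_rule `"youden"` (default) or `"prob0.5"`.
#' @param seed Stored in the model metadata.
#' @return Object of class `frozen_panel_model`: `analytes`, `coefficients`
#'   (named, incl. `(Intercept)`, `age`, `sexM`), `cutoff`, `center`,
#'   `scale`, `cutoff_rule`, `train_meta`.
#' @export
refit_and_freeze <- function(zmat, samples, selected,
                             cutoff_rule = c("youden", "prob0.5"), seed = 1L) {
  cutoff_rule <- match.arg(cutoff_rule)
  samples <- samples[samples$clinical_status %in% c("CO", "AD"), , drop = FALSE]
  d <- panel_design(zmat, samples, selected)
  center <- scale_ <- stats::setNames(numeric(0), character(0))
  xs <- d$x
  if (length(selected)) {
    center <- colMeans(xs[, selected, drop = FALSE])
    scale_ <- apply(xs[, selected, drop = FALSE], 2, stats::sd)
    scale_[scale_ == 0] <- 1
    xs[, selected] <- sweep(sweep(xs[, selected, drop = FALSE], 2, center),
                            2, scale_, `/`)
  }
  df <- as.data.frame(xs)
  df$.y <- d$y
  fit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15)) {
    warning("separation in logistic refit; falling back to a ridged fit")
    xr <- as.matrix(xs)
    rg <- glmnet::glmnet(xr, d$y, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    cf <- c(`(Intercept)` = as.numeric(rg$a0),
            stats::setNames(as.numeric(rg$beta), rownames(rg$beta)))
  } else {
    cf <- stats::coef(fit)
  }
  scores <- plogis(cbind(1, as.matrix(xs)) %*% cf[c("(Intercept)", colnames(xs))])
  cutoff <- if (cutoff_rule == "prob0.5") 0.5 else {
    thr <- sort(unique(scores))
    j_stat <- vapply(thr, function(t) {
      pred <- scores >= t
      sens <- mean(pred[d$y == 1]); spec <- mean(!pred[d$y == 0])
      sens + spec - 1
    }, 0)
    unname(thr[which.max(j_stat)])
  }
  structure(list(analytes = selected, coefficients = cf,
                 cutoff = as.numeric(cutoff), cutoff_rule = cutoff_rule,
                 center = center, scale = scale_,
                 train_meta = list(seed = seed, n_train = length(d$y),
                                   n_case = sum(d$y),
                                   train_scores = as.numeric(scores),
                                   train_ids = d$ids)),
            class = "frozen_panel_model")
}

#' Score samples with a frozen panel model
#'
#' Applies the stored standardization constants and logistic weights without
#' any re-estimation.
#'
#' @param object A `frozen_panel_model`.
#' @param zmat Normalized matrix for the target dataset.
#' @param samples Target metadata.
#' @param ... Unused.
#' @return Named numeric vector of predicted probabilities.
#' @export
predict.frozen_panel_model <- function(object, zmat, samples, ...) {
  d <- panel_design(zmat, samples, object$analytes)
  xs <- d$x
  if (length(object$analytes))
    xs[, object$analytes] <- sweep(sweep(xs[, object$analytes, drop = FALSE],
                                         2, object$center), 2, object$scale, `/`)
  eta <- cbind(1, as.matrix(xs)) %*%
    object$coefficients[c("(Intercept)", colnames(xs))]
  stats::setNames(as.numeric(plogis(eta)), d$ids)
}

#' @export
print.frozen_panel_model <- function(x, ...) {
  cat(sprintf("frozen_panel_model: %d analyte(s) + age + sex, cutoff %.3f (%s)\n",
              length(x$analytes), x$cutoff, x$cutoff_rule))
  if (length(x$analytes)) cat("  panel:", paste(x$analytes, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a frozen panel model as flat JSON
#'
#' @param model A `frozen_panel_model`.
#' @param path Output path.
#' @export
write_frozen_model <- function(model, path) {
  obj <- list(analytes = model$analytes,
              coefficients = as.list(model$coefficients),
              cutoff = model$cutoff, cutoff_rule = model$cutoff_rule,
              center = as.list(model$center), scale = as.list(model$scale),
              seed = model$train_meta$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frozen_model
#' @export
read_frozen_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(analytes = as.character(obj$analytes),
                 coefficients = unlist(obj$coefficients),
                 cutoff = obj$cutoff, cutoff_rule = obj$cutoff_rule,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 train_meta = list(seed = obj$seed)),
            class = "frozen_panel_model")
}

# One undersampling draw: within each matching cell, sample (without
# replacement) equally many cases and controls -- the minimum of the two cell
# counts -- so the drawn case and control subsets have identical size and
# identical cell composition by construction.
undersample_matched <- function(y, cell) {
  unlist(lapply(levels(cell), function(cl) {
    ca <- which(cell == cl & y == 1); co <- which(cell == cl & y == 0)
    m <- min(length(ca), length(co))
    if (m == 0) return(integer())
    c(sample(ca, m), sample(co, m))
  }))
}

classification_metrics <- function(scores, labels, cutoff) {
  pred <- as.numeric(scores >= cutoff)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  c(auc = auc_rank(scores, labels),
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn) tp / (tp + fn) else NA,
    specificity = if (tn + fp) tn / (tn + fp) else NA,
    npv = if (tn + fn) tn / (tn + fn) else NA,
    ppv = if (tp + fp) tp / (tp + fp) else NA)
}

#' Evaluate a frozen model on a dataset
#'
#' Plain mode computes AUC, accuracy, sensitivity, specificity, NPV and PPV
#' once at the frozen cutoff. Undersampled mode draws, per iteration,
#' equal-size case/control subsets with exactly matched sex (and optionally
#' draw-year cluster) composition without replacement, and reports the
#' mean/min/max of each metric over the iterations.
#'
#' @param model A `frozen_panel_model`.
#' @param zmat Normalized matrix of the evaluation dataset.
#' @param samples Evaluation metadata.
#' @param labels Named binary vector (1 = case) or NULL to use
#'   `clinical_status == "AD"`.
#' @param mode `"plain"` or `"undersampled"`.
#' @param n_iter Iterations for undersampled mode (default 100).
#' @param match_by Matching columns for undersampling (default `"sex"`).
#' @param seed Integer seed for undersampling.
#' @return For plain mode a named metric vector; for undersampled mode a
#'   data.frame with mean/min/max per metric.
#' @export
evaluate_model <- function(model, zmat, samples, labels = NULL,
                           mode = c("plain", "undersampled"),
                           n_iter = 100, match_by = "sex", seed = 1L) {
  mode <- match.arg(mode)
  scores <- predict(model, zmat, samples)
  ids <- names(scores)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  y <- if (is.null(labels)) as.numeric(samples$clinical_status == "AD")
       else as.numeric(labels[ids])
  if (anyNA(y)) stop("labels missing for some scored samples")
  if (mode == "plain")
    return(classification_metrics(scores, y, model$cutoff))

  cell <- interaction(samples[, match_by, drop = FALSE], drop = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(n_iter), function(it) {
    pick <- undersample_matched(y, cell)
    if (length(pick) < 10)
      stop("too few samples to match composition")
    classification_metrics(scores[pick], y[pick], model$cutoff)
  })
  mat <- do.call(rbind, rows)
  data.frame(metric = colnames(mat),
             mean = colMeans(mat), min = apply(mat, 2, min),
             max = apply(mat, 2, max), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Conversion-horizon AUCs of a frozen model
#'
#' For each horizon h (years): positives are converters with event time
#' <= h; negatives are subjects followed at least h years without
#' conversion; non-converters censored before h are excluded. Reports the
#' AUC of the frozen model's baseline scores.
#'
#' @param model A `frozen_panel_model`.
#' @param zmat,samples Dataset to score.
#' @param survival_inputs data.frame `sample_id`, `duration`, `event`.
#' @param horizons Horizons in years (default 5, 10, 15).
#' @return data.frame `horizon`, `auc`, `n_pos`, `n_neg` (`auc` is NA with a
#'   warning when a horizon lacks positives or negatives).
#' @export
horizon_auc <- function(model, zmat, samples, survival_inputs,
                        horizons = c(5, 10, 15)) {
  scores <- predict(model, zmat, samples)
  si <- survival_inputs[match(names(scores), survival_inputs$sample_id), ]
  keep <- !is.na(si$duration)
  scores <- scores[keep]; si <- si[keep, , drop = FALSE]
  out <- lapply(horizons, function(h) {
    pos <- si$event == 1 & si$duration <= h
    neg <- si$duration >= h & !(si$event == 1 & si$duration <= h)
    use <- pos | neg
    if (!any(pos) || !any(neg)) {
      warning("horizon ", h, "y has no positives or no negatives")
      return(data.frame(horizon = h, auc = NA_real_,
                        n_pos = sum(pos), n_neg = sum(neg)))
    }
    data.frame(horizon = h,
               auc = auc_rank(scores[use], as.numeric(pos[use])),
               n_pos = sum(pos), n_neg = sum(neg))
  })
  do.call(rbind, out)
}

#' Train a frozen panel end to end
#'
#' Convenience wrapper: stratified split, CV Lasso path, 90%-of-best lambda,
#' refit and freeze.
#'
#' @param zmat,samples Normalized matrix and metadata.
#' @param candidate_analytes Candidate ids.
#' @param train_frac,retention,k_folds,cutoff_rule,seed Stage parameters.
#' @return List with `model`, `path`, `lambda_sel`, `split`.
#' @export
train_panel <- function(zmat, samples, candidate_analytes,
                        train_frac = 0.7, retention = 0.9, k_folds = 5,
                        cutoff_rule = "youden", seed = 1L) {
  co_ad <- samples[samples$clinical_status %in% c("CO", "AD"), , drop = FALSE]
  split <- split_train_test(co_ad, train_frac, seed = seed)
  tr <- co_ad[co_ad$sample_id %in% split$train, , drop = FALSE]
  path <- lasso_path_cv(zmat, tr, candidate_analytes, k_folds, seed)
  sel <- select_lambda_90(path, retention)
  model <- refit_and_freeze(zmat, tr, sel$selected, cutoff_rule, seed)
  list(model = model, path = path, lambda_sel = sel, split = split)
}
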