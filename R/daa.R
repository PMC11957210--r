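# Three-stage differential abundance: per-analyte OLS of normalized protein
# level on clinical status with age/sex (and cohort) covariates, a
# discovery/replication gate on nominal significance and direction, a
# sample-size-weighted Stouffer meta-analysis, Benjamini-Hochberg FDR over
# the full assayed universe, and tertile odds ratios for effect
# interpretation.

#' Per-analyte linear regression of protein level on AD status
#'
#' For each analyte, fits ordinary least squares of the (z-normalized)
#' protein level on clinical status (CO = 0, AD = 1) plus covariates on
#' complete cases. Positive effects mean higher levels in AD.
#'
#' @param zmat Numeric matrix of normalized protein levels, samples x
#'   analytes (row names are sample ids).
#' @param samples Sample metadata (see [validate_samples()]); only CO and AD
#'   rows are used.
#' @param covariates Character vector among `"age"`, `"sex"`, `"cohort"`.
#' @param min_per_arm Minimum complete cases per arm; analytes below the
#'   floor are skipped (default 10).
#' @return data.frame of class `association_result` with `analyte_id`,
#'   `effect` (SD units), `se`, `p`, `n`, `direction`.
#' @export
fit_analyte_regression <- function(zmat, samples,
                                   covariates = c("age", "sex"),
                                   min_per_arm = 10) {
  samples <- samples[samples$clinical_status %in% c("CO", "AD"), , drop = FALSE]
  ids <- intersect(rownames(zmat), samples$sample_id)
  if (!length(ids)) stop("no CO/AD samples overlap the matrix")
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  zmat <- zmat[ids, , drop = FALSE]
  status <- as.numeric(samples$clinical_status == "AD")

  X <- cbind(intercept = 1, status = status)
  if ("age" %in% covariates) X <- cbind(X, age = samples$age_at_draw)
  if ("sex" %in% covariates) X <- cbind(X, sexM = as.numeric(samples$sex == "male"))
  if ("cohort" %in% covariates && length(unique(samples$cohort)) > 1) {
    X <- cbind(X, stats::model.matrix(~ cohort, data = samples)[, -1, drop = FALSE])
  }
  cc_X <- stats::complete.cases(X)

  res <- lapply(colnames(zmat), function(a) {
    y <- zmat[, a]
    ok <- cc_X & !is.na(y)
    n1 <- sum(status[ok] == 1); n0 <- sum(status[ok] == 0)
    if (n1 < min_per_arm || n0 < min_per_arm) return(NULL)
    Xa <- X[ok, , drop = FALSE]
    qrX <- qr(Xa)
    if (qrX$rank < ncol(Xa)) {
      warning("rank-deficient design for analyte ", a, "; skipped")
      return(NULL)
    }
    fit <- stats::lm.fit(Xa, y[ok])
    df <- sum(ok) - ncol(Xa)
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    eff <- unname(fit$coefficients["status"])
    tval <- eff / se
    data.frame(analyte_id = a, effect = eff, se = se,
               p = 2 * stats::pt(-abs(tval), df), n = sum(ok),
               direction = sign(eff), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    stop("no analyte had enough complete cases per arm")
  class(out) <- c("association_result", class(out))
  rownames(out) <- NULL
  out
}

#' Three-stage selection gate
#'
#' Keeps analytes with nominal discovery significance, nominal replication
#' significance and concordant effect direction across the two stages.
#'
#' @param discovery,replication `association_result` tables sharing analyte
#'   ids.
#' @param alpha Nominal threshold (default 0.05).
#' @return data.frame of gated analytes with per-stage effects/p-values and
#'   a `stage` flag.
#' @export
three_stage_select <- function(discovery, replication, alpha = 0.05) {
  common <- intersect(discovery$analyte_id, replication$analyte_id)
  if (!length(common)) stop("no analyte ids shared between stages")
  d <- discovery[match(common, discovery$analyte_id), ]
  r <- replication[match(common, replication$analyte_id), ]
  keep <- d$p < alpha & r$p < alpha & sign(d$effect) == sign(r$effect) &
    d$effect != 0 & r$effect != 0
  data.frame(analyte_id = common,
             effect_disc = d$effect, p_disc = d$p, n_disc = d$n,
             effect_rep = r$effect, p_rep = r$p, n_rep = r$n,
             selected = keep, stage = ifelse(keep, "meta", "discovery"),
             stringsAsFactors = FALSE)
}

#' Sample-size-weighted Stouffer meta-analysis
#'
#' Combines two stages per analyte with signed z-scores
#' `z_i = sign(effect_i) * qnorm(1 - p_i / 2)` weighted by `sqrt(n_i)`:
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, two-sided
#' `p = 2 pnorm(-|Z|)`. A weighted-Fisher alternative (direction from the
#' sample-size-weighted mean sign) is available for sensitivity.
#'
#' @param discovery,replication `association_result` tables; analytes present
#'   in both stages are combined.
#' @param method `"stouffer"` (default) or `"fisher"`.
#' @return data.frame with `analyte_id`, `z_meta`, `p_meta`, `direction`,
#'   `n_total`.
#' @export
meta_analyze <- function(discovery, replication, method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  common <- intersect(discovery$analyte_id, replication$analyte_id)
  if (!length(common)) stop("no analyte ids shared between stages")
  d <- discovery[match(common, discovery$analyte_id), ]
  r <- replication[match(common, replication$analyte_id), ]
  clamp_p <- function(p) {
    if (any(p <= 0)) warning("p = 0 input clamped to smallest representable")
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
  pd <- clamp_p(d$p); pr <- clamp_p(r$p)
  # upper-tail form stays finite for p below ~1e-16 where 1 - p/2 rounds to 1
  zd <- sign(d$effect) * stats::qnorm(pd / 2, lower.tail = FALSE)
  zr <- sign(r$effect) * stats::qnorm(pr / 2, lower.tail = FALSE)
  if (method == "stouffer") {
    Z <- (sqrt(d$n) * zd + sqrt(r$n) * zr) / sqrt(d$n + r$n)
    p_meta <- pmax(2 * stats::pnorm(-abs(Z)), .Machine$double.xmin)
    dir <- sign(Z)
  } else {
    # weighted Fisher (Lancaster): chi-square with df proportional to n
    df_d <- 2 * d$n / (d$n + r$n) * 2
    df_r <- 2 * r$n / (d$n + r$n) * 2
    stat <- stats::qchisq(pd, df_d, lower.tail = FALSE) +
      stats::qchisq(pr, df_r, lower.tail = FALSE)
    p_meta <- stats::pchisq(stat, df_d + df_r, lower.tail = FALSE)
    dir <- sign(sqrt(d$n) * sign(d$effect) + sqrt(r$n) * sign(r$effect))
    Z <- sign(dir) * stats::qnorm(pmax(p_meta, .Machine$double.xmin) / 2,
                                  lower.tail = FALSE)
  }
  data.frame(analyte_id = common, z_meta = Z, p_meta = p_meta,
             direction = dir, n_total = d$n + r$n, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment over a fixed universe
#'
#' Step-up BH q-values with the universe size `m` fixed externally (e.g. the
#' total number of assayed aptamers), so that a subset of p-values can be
#' adjusted against the full multiplicity burden:
#' `q_(i) = min_(j >= i) min(p_(j) m / j, 1)`, returned in input order.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @param m Universe size, at least `length(pvals)`.
#' @return q-values aligned with `pvals`.
#' @export
bh_adjust <- function(pvals, m = length(pvals)) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (m < length(pvals)) stop("m must be >= number of p-values")
  k <- length(pvals)
  o <- order(pvals)
  q <- pmin(pvals[o] * m / seq_len(k), 1)
  q <- rev(cummin(rev(q)))
  out <- numeric(k)
  out[o] <- q
  out
}

#' Tertile odds ratio for one analyte
#'
#' Compares the highest (3rd) and lowest (1st) tertiles of the analyte's
#' pooled distribution by logistic regression of AD status on the tertile
#' indicator (1st tertile = reference), optionally with covariates. Tertiles
#' are rank-based with stable tie-breaking by sample id. Reports the
#' Wald 95% CI and the transformed OR `max(OR, 1/OR)`.
#'
#' @param zmat Normalized matrix, samples x analytes.
#' @param samples Sample metadata.
#' @param analyte Analyte id.
#' @param covariates Character vector among `"age"`, `"sex"`, `"cohort"`.
#' @param min_per_cell Minimum cases and controls required in each retained
#'   tertile (default 5).
#' @return One-row data.frame with `or_value`, `ci_low`, `ci_high`,
#'   `transformed_or`, tertile counts and a `separation` flag.
#' @export
tertile_odds_ratio <- function(zmat, samples, analyte,
                               covariates = c("age", "sex", "cohort"),
                               min_per_cell = 5) {
  if (!analyte %in% colnames(zmat)) stop("unknown analyte: ", analyte)
  samples <- samples[samples$clinical_status %in% c("CO", "AD"), , drop = FALSE]
  ids <- intersect(rownames(zmat), samples$sample_id)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  x <- zmat[ids, analyte]
  ok <- !is.na(x)
  x <- x[ok]; samples <- samples[ok, , drop = FALSE]; ids <- ids[ok]
  # rank-based tertiles; ties broken by sample id for determinism
  rk <- order(order(x, ids))
  n <- length(x)
  cut1 <- floor(n / 3); cut2 <- n - floor(n / 3)
  tert <- ifelse(rk <= cut1, 1L, ifelse(rk > cut2, 3L, 2L))
  keep <- tert != 2L
  df <- data.frame(ad = as.numeric(samples$clinical_status == "AD"),
                   t3 = as.numeric(tert == 3L),
                   age = samples$age_at_draw,
                   sex = samples$sex,
                   cohort = if (is.null(samples$cohort)) "c1" else samples$cohort,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  counts <- table(factor(df$t3, c(0, 1)), factor(df$ad, c(0, 1)))
  if (any(counts < min_per_cell))
    stop("fewer than ", min_per_cell, " cases or controls in a tertile")
  form <- "ad ~ t3"
  if ("age" %in% covariates) form <- paste(form, "+ age")
  if ("sex" %in% covariates && length(unique(df$sex)) > 1)
    form <- paste(form, "+ sex")
  if ("cohort" %in% covariates && length(unique(df$cohort)) > 1)
    form <- paste(form, "+ cohort")
  fit <- stats::glm(stats::as.formula(form), family = stats::binomial(), data = df)
  co <- summary(fit)$coefficients["t3", ]
  separation <- !fit$converged || abs(co["Estimate"]) > 15
  or <- exp(co["Estimate"])
  ci <- exp(co["Estimate"] + c(-1, 1) * stats::qnorm(0.975) * co["Std. Error"])
  if (separation) ci <- c(0, Inf)
  data.frame(analyte_id = analyte, or_value = unname(or),
             ci_low = ci[1], ci_high = ci[2],
             transformed_or = unname(max(or, 1 / or)),
             n_tertile1 = sum(df$t3 == 0), n_tertile3 = sum(df$t3 == 1),
             separation = separation, stringsAsFactors = FALSE)
}

#' Run the full three-stage differential abundance pipeline
#'
#' Convenience wrapper: per-stage regressions, gate, meta-analysis, and BH
#' adjustment of meta p-values over the full assayed universe.
#'
#' @param z_disc,z_rep Normalized matrices for discovery and replication.
#' @param samples_disc,samples_rep Matching metadata tables.
#' @param m FDR universe size (default: number of analytes in the discovery
#'   matrix).
#' @param alpha Nominal gate threshold.
#' @param fdr Meta-stage FDR threshold for the `significant` flag.
#' @return List with `discovery`, `replication`, `gate`, `meta` tables; the
#'   meta table carries `fdr_q` and `significant` for gated analytes.
#' @export
run_daa <- function(z_disc, samples_disc, z_rep, samples_rep,
                    m = ncol(z_disc), alpha = 0.05, fdr = 0.05) {
  disc <- fit_analyte_regression(z_disc, samples_disc, c("age", "sex"))
  rep_ <- fit_analyte_regression(z_rep, samples_rep, c("age", "sex", "cohort"))
  gate <- three_stage_select(disc, rep_, alpha)
  meta <- meta_analyze(disc, rep_)
  meta <- meta[match(gate$analyte_id, meta$analyte_id), ]
  meta$selected <- gate$selected
  meta$fdr_q <- NA_real_
  if (any(gate$selected))
    meta$fdr_q[gate$selected] <- bh_adjust(meta$p_meta[gate$selected], m)
  meta$significant <- !is.na(meta$fdr_q) & meta$fdr_q < fdr
  list(discovery = disc, replication = rep_, gate = gate, meta = meta)
}
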