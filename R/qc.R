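# Proteomic QC cascade: analyte-level filters (LOD, scale factor, CV),
# Tukey outlier masking on log10 values, two-pass call-rate filtering, and
# per-cluster z-score normalization. Filters only remove or mask -- no
# retained value is altered before normalization.

new_qc_report <- function() {
  list(analytes_removed = list(lod = character(), scale_factor = character(),
                               cv = character(),
                               call_rate_pass1 = character(),
                               call_rate_pass2 = character(),
                               zero_variance = character()),
       samples_removed = list(call_rate_pass1 = character(),
                              call_rate_pass2 = character()),
       outlier_cells_masked = 0L,
       call_rate = list())
}

#' Analyte-level QC filters
#'
#' Removes an analyte when (a) at least `lod_frac` of its measurements fall
#' below the limit of detection, (b) its scale factor deviates from the
#' plate-median scale factor by more than `sf_dev` on any plate, or (c) its
#' coefficient of variation exceeds `cv_max`. The CV reference population is
#' configurable: per plate across all samples on that plate (default; fails
#' if any plate exceeds the threshold) or global.
#'
#' @param pm A [proteomics_matrix()].
#' @param lod_frac Fraction of below-LOD values that disqualifies an analyte
#'   (default 0.85).
#' @param sf_dev Maximum allowed absolute deviation from the per-plate median
#'   scale factor (default 0.5).
#' @param cv_max Maximum allowed coefficient of variation, sd/mean on raw RFU
#'   (default 0.15).
#' @param cv_scope `"plate"` or `"global"`.
#' @return List with the filtered `matrix` and a QC `report`.
#' @export
apply_analyte_filters <- function(pm, lod_frac = 0.85, sf_dev = 0.5,
                                  cv_max = 0.15, cv_scope = c("plate", "global")) {
  cv_scope <- match.arg(cv_scope)
  if (lod_frac <= 0 || lod_frac > 1) stop("lod_frac must lie in (0, 1]")
  if (sf_dev <= 0 || cv_max <= 0) stop("sf_dev and cv_max must be > 0")
  report <- new_qc_report()
  vals <- pm$values
  analytes <- colnames(vals)
  plate <- pm$plate_of_sample

  if (!is.null(pm$lod)) {
    lod_sample <- t(pm$lod[analytes, plate, drop = FALSE])  # samples x analytes
    frac_below <- colMeans(vals < lod_sample, na.rm = TRUE)
    frac_below[is.nan(frac_below)] <- 0
    report$analytes_removed$lod <- analytes[frac_below >= lod_frac]
  }

  if (!is.null(pm$scale_factor)) {
    sf <- pm$scale_factor[analytes, unique(plate), drop = FALSE]
    med <- apply(sf, 2, stats::median, na.rm = TRUE)
    dev <- abs(sweep(sf, 2, med, `-`))
    bad <- apply(dev > sf_dev, 1, any, na.rm = TRUE)
    report$analytes_removed$scale_factor <- analytes[bad]
  }

  cv_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) return(0)
    stats::sd(x) / mean(x)
  }
  if (cv_scope == "plate") {
    cv_bad <- vapply(seq_along(analytes), function(j) {
      any(tapply(vals[, j], plate, cv_of) > cv_max, na.rm = TRUE)
    }, logical(1))
  } else {
    cv_bad <- vapply(seq_along(analytes), function(j) cv_of(vals[, j]) > cv_max,
                     logical(1))
  }
  report$analytes_removed$cv <- analytes[cv_bad]

  drop <- unique(unlist(report$analytes_removed[c("lod", "scale_factor", "cv")]))
  keep <- setdiff(analytes, drop)
  if (!length(keep)) {
    e <- simpleError("all analytes removed by analyte-level filters")
    e$report <- report
    stop(e)
  }
  list(matrix = pm_subset(pm, analytes = keep), report = report)
}

#' Mask expression outliers by Tukey fences on log10 values
#'
#' Per analyte, log10-transformed values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are set to missing. Quartiles use the
#' linear-interpolation convention (`type = 7`) by default. Single pass: the
#' fences are computed once on the incoming data.
#'
#' @param pm A [proteomics_matrix()].
#' @param k Fence multiplier (default 1.5).
#' @param quantile_type Passed to [stats::quantile()].
#' @return List with the masked `matrix` and `n_masked`, the count of cells
#'   set to missing.
#' @export
flag_outliers_iqr <- function(pm, k = 1.5, quantile_type = 7) {
  vals <- pm$values
  lx <- log10(vals)
  n_masked <- 0L
  for (j in seq_len(ncol(vals))) {
    x <- lx[, j]
    if (all(is.na(x))) next
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                         type = quantile_type)
    iqr <- q[2] - q[1]
    out <- !is.na(x) & (x > q[2] + k * iqr | x < q[1] - k * iqr)
    if (any(out)) {
      vals[out, j] <- NA
      n_masked <- n_masked + sum(out)
    }
  }
  pm$values <- vals
  list(matrix = pm, n_masked = n_masked)
}

call_rates <- function(vals) {
  list(analyte = colMeans(!is.na(vals)), sample = rowMeans(!is.na(vals)))
}

#' Two-pass call-rate filter
#'
#' Pass 1 removes analytes and subjects whose call rate (proportion of
#' successful measurements) is below `pass1`, judged simultaneously on the
#' incoming matrix. Call rates are then recomputed on the reduced matrix and
#' pass 2 removes those below `pass2`.
#'
#' @param pm A [proteomics_matrix()].
#' @param pass1,pass2 Call-rate thresholds (defaults 0.65 and 0.85).
#' @return List with the filtered `matrix` and a `report` carrying removed
#'   ids and before/after call rates.
#' @export
call_rate_filter <- function(pm, pass1 = 0.65, pass2 = 0.85) {
  if (!(pass1 > 0 && pass1 <= pass2 && pass2 <= 1))
    stop("need 0 < pass1 <= pass2 <= 1")
  report <- new_qc_report()
  cr0 <- call_rates(pm$values)
  report$call_rate$before <- cr0
  report$analytes_removed$call_rate_pass1 <- names(which(cr0$analyte < pass1))
  report$samples_removed$call_rate_pass1 <- names(which(cr0$sample < pass1))
  keep_a <- setdiff(colnames(pm$values), report$analytes_removed$call_rate_pass1)
  keep_s <- setdiff(rownames(pm$values), report$samples_removed$call_rate_pass1)
  if (!length(keep_a) || !length(keep_s)) {
    e <- simpleError("matrix empty after call-rate pass 1")
    e$report <- report
    stop(e)
  }
  pm <- pm_subset(pm, samples = keep_s, analytes = keep_a)
  cr1 <- call_rates(pm$values)
  report$analytes_removed$call_rate_pass2 <- names(which(cr1$analyte < pass2))
  report$samples_removed$call_rate_pass2 <- names(which(cr1$sample < pass2))
  keep_a <- setdiff(colnames(pm$values), report$analytes_removed$call_rate_pass2)
  keep_s <- setdiff(rownames(pm$values), report$samples_removed$call_rate_pass2)
  if (!length(keep_a) || !length(keep_s)) {
    e <- simpleError("matrix empty after call-rate pass 2")
    e$report <- report
    stop(e)
  }
  pm <- pm_subset(pm, samples = keep_s, analytes = keep_a)
  report$call_rate$after <- call_rates(pm$values)
  list(matrix = pm, report = report)
}

#' Per-cluster z-score normalization
#'
#' Within each dataset cluster (blood-draw-year batch), each analyte's
#' log10-transformed values are centered and scaled to mean 0, sd 1 over
#' non-missing entries. Missing entries are preserved. Analytes with zero
#' within-cluster variance are dropped with a warning.
#'
#' @param pm A [proteomics_matrix()].
#' @param cluster_of_sample Cluster label per sample (named by sample id or
#'   in row order).
#' @param log_transform Normalize on log10 scale (default TRUE).
#' @return Numeric matrix of z-scores (samples x analytes).
#' @export
zscore_normalize <- function(pm, cluster_of_sample, log_transform = TRUE) {
  vals <- if (inherits(pm, "proteomics_matrix")) pm$values else pm
  if (!is.null(names(cluster_of_sample)))
    cluster_of_sample <- cluster_of_sample[rownames(vals)]
  if (length(cluster_of_sample) != nrow(vals))
    stop("cluster_of_sample must cover every sample")
  tab <- table(cluster_of_sample)
  if (any(tab < 3)) stop("each cluster needs at least 3 samples")
  x <- if (log_transform) log10(vals) else vals
  dropped <- character()
  for (cl in names(tab)) {
    rows <- which(cluster_of_sample == cl)
    sub <- x[rows, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    sd_ <- apply(sub, 2, stats::sd, na.rm = TRUE)
    zero <- which(!is.na(sd_) & sd_ == 0)
    dropped <- union(dropped, colnames(x)[zero])
    sd_[sd_ == 0 | is.na(sd_)] <- NA
    x[rows, ] <- sweep(sweep(sub, 2, mu, `-`), 2, sd_, `/`)
  }
  if (length(dropped)) {
    warning("dropping analyte(s) with zero within-cluster variance: ",
            paste(dropped, collapse = ", "))
    x <- x[, setdiff(colnames(x), dropped), drop = FALSE]
  }
  x
}

#' Run the full QC cascade
#'
#' Applies, in order: analyte filters (LOD / scale factor / CV), Tukey
#' outlier masking, the two-pass call-rate filter, and per-cluster z-score
#' normalization.
#'
#' @param pm A [proteomics_matrix()].
#' @param cluster_of_sample Cluster label per sample (for normalization).
#' @param lod_frac,sf_dev,cv_max,cv_scope See [apply_analyte_filters()].
#' @param pass1,pass2 See [call_rate_filter()].
#' @return List with `zscores` (normalized matrix), `matrix` (filtered raw
#'   matrix) and the aggregated `report`.
#' @export
run_qc <- function(pm, cluster_of_sample,
                   lod_frac = 0.85, sf_dev = 0.5, cv_max = 0.15,
                   cv_scope = "plate", pass1 = 0.65, pass2 = 0.85) {
  st1 <- apply_analyte_filters(pm, lod_frac, sf_dev, cv_max, cv_scope)
  st2 <- flag_outliers_iqr(st1$matrix)
  st3 <- call_rate_filter(st2$matrix, pass1, pass2)
  report <- st1$report
  report$outlier_cells_masked <- st2$n_masked
  report$analytes_removed$call_rate_pass1 <- st3$report$analytes_removed$call_rate_pass1
  report$analytes_removed$call_rate_pass2 <- st3$report$analytes_removed$call_rate_pass2
  report$samples_removed <- st3$report$samples_removed
  report$call_rate <- st3$report$call_rate
  cl <- cluster_of_sample
  if (!is.null(names(cl))) cl <- cl[rownames(st3$matrix$values)]
  else cl <- cl[match(rownames(st3$matrix$values), rownames(pm$values))]
  z <- zscore_normalize(st3$matrix, cl)
  report$analytes_removed$zero_variance <-
    setdiff(colnames(st3$matrix$values), colnames(z))
  list(zscores = z, matrix = st3$matrix, report = report)
}
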