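# Gaussian-mixture dichotomization of continuous biomarkers. A two-component
# univariate mixture with unequal variances is fitted by EM on z-scored
# values; the cutoff is the point between the component means where the
# posterior membership probabilities are equal, mapped back to the raw scale
# by inverting the z-transform.

# EM for a k-component univariate Gaussian mixture; k-means initialization.
gmm_em <- function(x, k = 2, max_iter = 1000, tol = 1e-6, seed = 1L) {
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 5)
  ord <- order(km$centers)
  mu <- as.vector(km$centers)[ord]
  sd_ <- vapply(ord, function(c0) {
    s <- stats::sd(x[km$cluster == c0])
    if (is.na(s) || s < 1e-6) stats::sd(x) / k else s
  }, 0)
  w <- (km$size / length(x))[ord]
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(c0) w[c0] * stats::dnorm(x, mu[c0], sd_[c0]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sd_ <- sqrt(colSums(resp * (x - rep(mu, each = length(x)))^2) / nk)
    sd_ <- pmax(sd_, 1e-6)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], sds = sd_[ord],
       loglik = ll, converged = converged, n_iter = it)
}

#' Fit a Gaussian-mixture cutoff for a continuous biomarker
#'
#' Z-scores the values, fits a two-component univariate Gaussian mixture
#' (unequal variances) by EM with k-means initialization, and sets the
#' dichotomization cutoff where the posterior membership probabilities of the
#' two components are equal, between the two component means. The raw-scale
#' cutoff is recovered by inverting the z-transform. A BIC check against 1-
#' and 3-component fits warns when bimodality is questionable; a component
#' weight below 0.01 raises a degenerate flag.
#'
#' @param values Numeric biomarker values (missing dropped).
#' @param positivity_direction `"high_is_positive"` or `"low_is_positive"` --
#'   biomarker metadata, not inferred.
#' @param seed Integer seed for initialization.
#' @param min_n Minimum non-missing values (default 50).
#' @return An object of class `biomarker_cutoff`: component `means`, `sds`,
#'   `weights` (z scale), `cutoff_z`, `cutoff_raw`, `positivity_direction`,
#'   `degenerate` flag.
#' @export
fit_gmm_cutoff <- function(values,
                           positivity_direction = c("high_is_positive",
                                                    "low_is_positive"),
                           seed = 1L, min_n = 50) {
  positivity_direction <- match.arg(positivity_direction)
  x <- values[!is.na(values)]
  if (length(x) < min_n)
    stop("need at least ", min_n, " non-missing values")
  mu_raw <- mean(x); sd_raw <- stats::sd(x)
  if (sd_raw == 0) stop("values are constant")
  z <- (x - mu_raw) / sd_raw

  fit <- gmm_em(z, k = 2, seed = seed)
  if (!fit$converged)
    stop("EM did not converge within the iteration limit")
  degenerate <- any(fit$weights < 0.01) ||
    abs(fit$means[2] - fit$means[1]) < 0.1 * max(fit$sds)
  if (degenerate) warning("degenerate mixture component; cutoff unreliable")

  # posterior-equality point between the component means
  post_diff <- function(t) {
    fit$weights[1] * stats::dnorm(t, fit$means[1], fit$sds[1]) -
      fit$weights[2] * stats::dnorm(t, fit$means[2], fit$sds[2])
  }
  lo <- fit$means[1]; hi <- fit$means[2]
  cutoff_z <- if (hi - lo < 1e-10 || post_diff(lo) * post_diff(hi) > 0) {
    (lo + hi) / 2
  } else {
    stats::uniroot(post_diff, c(lo, hi), tol = 1e-10)$root
  }

  # BIC model check: 1 and 3 components
  bic <- function(ll, n_par) -2 * ll + n_par * log(length(z))
  ll1 <- sum(stats::dnorm(z, mean(z), stats::sd(z) * sqrt((length(z) - 1) / length(z)),
                          log = TRUE))
  bic1 <- bic(ll1, 2)
  fit3 <- tryCatch(gmm_em(z, k = 3, seed = seed), error = function(e) NULL)
  bic2 <- bic(fit$loglik, 5)
  bic3 <- if (!is.null(fit3) && fit3$converged) bic(fit3$loglik, 8) else Inf
  if (bic1 < bic2 || bic3 < bic2)
    warning("BIC prefers a ", if (bic1 < bic2) "1" else "3",
            "-component model; two-component cutoff may be inappropriate")

  structure(list(weights = fit$weights, means = fit$means, sds = fit$sds,
                 cutoff_z = cutoff_z,
                 cutoff_raw = cutoff_z * sd_raw + mu_raw,
                 z_center = mu_raw, z_scale = sd_raw,
                 positivity_direction = positivity_direction,
                 degenerate = degenerate, n = length(x)),
            class = "biomarker_cutoff")
}

#' @export
print.biomarker_cutoff <- function(x, ...) {
  cat(sprintf(paste0("biomarker_cutoff: components N(%.3g, %.3g) w=%.2f / ",
                     "N(%.3g, %.3g) w=%.2f\n  cutoff %.4g (raw), %.4g (z); %s%s\n"),
              x$means[1], x$sds[1], x$weights[1],
              x$means[2], x$sds[2], x$weights[2],
              x$cutoff_raw, x$cutoff_z, x$positivity_direction,
              if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

# dichotomize one biomarker column against its fitted cutoff
biomarker_positive <- function(values, cutoff) {
  pos <- if (cutoff$positivity_direction == "high_is_positive")
    values > cutoff$cutoff_raw else values < cutoff$cutoff_raw
  pos  # NA propagates for missing values
}

#' Assign amyloid/tau biomarker statuses
#'
#' Applies fitted cutoffs to the biomarker columns of a metadata table:
#' A+ when CSF A-beta-42 falls below its cutoff (or the PET composite above
#' its own), T+ when ptau (CSF ptau181 or plasma ptau217) lies above its
#' cutoff. The AT contrast set keeps A+T+ and A-T- samples; discordant
#' profiles are excluded from that contrast. Missing biomarkers yield
#' missing statuses, not errors.
#'
#' @param samples Sample metadata with the biomarker columns referenced by
#'   `cutoffs`.
#' @param cutoffs Named list of [fit_gmm_cutoff()] results; names are
#'   metadata columns (e.g. `csf_abeta42`, `csf_ptau181`).
#' @param amyloid,tau Column names used for the joint AT call.
#' @return `samples` with logical `<column>_positive` columns plus
#'   `at_status` (`"A+T+"`, `"A-T-"`, `"discordant"` or `NA`) and
#'   `at_contrast` (TRUE for rows in the A+T+ vs A-T- contrast).
#' @export
assign_biomarker_status <- function(samples, cutoffs,
                                    amyloid = "csf_abeta42",
                                    tau = "csf_ptau181") {
  for (col in names(cutoffs)) {
    if (!col %in% names(samples)) stop("metadata lacks biomarker column ", col)
    samples[[paste0(col, "_positive")]] <-
      biomarker_positive(samples[[col]], cutoffs[[col]])
  }
  a <- samples[[paste0(amyloid, "_positive")]]
  t_ <- samples[[paste0(tau, "_positive")]]
  if (is.null(a) || is.null(t_))
    stop("cutoffs must include both `", amyloid, "` and `", tau, "`")
  samples$at_status <- ifelse(is.na(a) | is.na(t_), NA_character_,
                              ifelse(a & t_, "A+T+",
                                     ifelse(!a & !t_, "A-T-", "discordant")))
  samples$at_contrast <- !is.na(samples$at_status) &
    samples$at_status %in% c("A+T+", "A-T-")
  samples
}
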