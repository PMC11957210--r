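# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes -- per-plate scale factors, LOD-censored positive
# abundances on a log scale, a fraction of analytes with planted case/control
# shifts in SD units, age/sex nuisance, bimodal biomarkers driven by a latent
# pathology group, exponential conversion times with protein-dependent
# hazards, and linear CDR-SB trajectories with group-dependent slopes.
# It does not emulate assay chemistry, plate spatial effects, or realistic
# protein-protein correlation.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults give a
#' desk-scale cohort (1,000 analytes, 600 controls + 400 cases on 4 plates)
#' that runs in seconds; the full assay scale is reachable by raising
#' `n_analytes`.
#'
#' @param n_co,n_ad Samples per arm (cognitively normal controls / AD cases).
#' @param n_analytes Number of analytes.
#' @param fraction_nonnull Fraction of analytes carrying a planted
#'   case/control shift (0 to 1).
#' @param effect_size_sd Magnitude of planted shifts, in within-group SD
#'   units of the log-scale abundance; signs are drawn at random. A vector
#'   recycles over the planted analytes.
#' @param age_mean,age_sd,age_shift_ad Age-at-draw distribution (years);
#'   cases are shifted by `age_shift_ad`.
#' @param prop_female Proportion of female participants.
#' @param n_plates Number of assay plates (samples assigned round-robin).
#' @param plate_sf_sd SD of log plate scale factors around 1.
#' @param lod_quantile Quantile of the null abundance distribution used as
#'   the per-(analyte, plate) limit of detection; values below it are
#'   censored to missing.
#' @param missing_rate Additional completely-at-random missingness.
#' @param noise_sd Residual SD of log10 abundance. The default 0.05
#'   corresponds to a raw-scale coefficient of variation of about 12%, so a
#'   clean cohort passes the assay CV filter (threshold 0.15) -- planted
#'   effects are expressed in units of this SD, so downstream inference is
#'   invariant to its value.
#' @param biomarkers List of per-biomarker two-component mixture parameters
#'   (`mean_pos`, `mean_neg`, `sd_pos`, `sd_neg`) plus `p_pos_ad`,
#'   `p_pos_co`, the latent-group prevalence per arm.
#' @param hazard_baseline Baseline conversion hazard (events per year) for
#'   controls.
#' @param protein_log_hr Named log hazard ratios per SD of designated
#'   analytes, or an integer: that many planted analytes get log-HR
#'   `log(2)/2`. `0` disables protein-dependent hazards.
#' @param follow_up_range Administrative censoring window (years), uniform.
#' @param cdr_slopes CDR-SB slope means (points/year) by clinical status and
#'   latent group, plus between-subject SD.
#' @param cohort,dataset_cluster Labels stamped onto the metadata.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_co = 600, n_ad = 400, n_analytes = 1000,
                       fraction_nonnull = 0.05, effect_size_sd = 0.4,
                       age_mean = 72, age_sd = 8, age_shift_ad = 3,
                       prop_female = 0.55,
                       n_plates = 4, plate_sf_sd = 0.05,
                       lod_quantile = 0.01, missing_rate = 0.005,
                       noise_sd = 0.05,
                       biomarkers = default_biomarker_mixtures(),
                       hazard_baseline = 0.03, protein_log_hr = 3L,
                       follow_up_range = c(1, 12),
                       cdr_slopes = list(co_neg = 0.09, co_pos = 0.46,
                                         ad_neg = 1.67, ad_pos = 2.02,
                                         sd = 0.25),
                       cohort = "KADRC", dataset_cluster = "clusterA",
                       seed = 1L) {
  if (fraction_nonnull < 0 || fraction_nonnull > 1)
    stop("fraction_nonnull must lie in [0, 1]")
  if (noise_sd <= 0 || age_sd <= 0 || plate_sf_sd < 0)
    stop("all sds must be positive")
  if (lod_quantile < 0 || lod_quantile >= 0.5)
    stop("lod_quantile must lie in [0, 0.5)")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  if (n_plates < 1) stop("need at least one plate")
  for (bm in biomarkers) {
    if (bm$p_pos_ad < 0 || bm$p_pos_ad > 1 || bm$p_pos_co < 0 || bm$p_pos_co > 1)
      stop("latent-group prevalences must lie in [0, 1]")
    if (bm$sd_pos <= 0 || bm$sd_neg <= 0) stop("biomarker sds must be > 0")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Default biomarker mixture parameters
#'
#' Two-component Gaussians on the raw assay scale: CSF A-beta-42 is low in
#' the pathology-positive group, CSF ptau181, amyloid-PET composite SUVR and
#' plasma ptau217 are high. Prevalence of the latent positive group is 0.85
#' among cases and 0.25 among controls (clinical control groups are known to
#' harbour preclinical pathology).
#' @return Named list of mixture parameter lists.
#' @export
default_biomarker_mixtures <- function() {
  shared <- list(p_pos_ad = 0.85, p_pos_co = 0.25)
  list(
    csf_abeta42 = c(list(mean_pos = 550, sd_pos = 120,
                         mean_neg = 1100, sd_neg = 180,
                         direction = "low_is_positive"), shared),
    csf_ptau181 = c(list(mean_pos = 45, sd_pos = 10,
                         mean_neg = 22, sd_neg = 5,
                         direction = "high_is_positive"), shared),
    pet_composite = c(list(mean_pos = 2.4, sd_pos = 0.35,
                           mean_neg = 1.2, sd_neg = 0.18,
                           direction = "high_is_positive"), shared),
    plasma_ptau217 = c(list(mean_pos = 0.60, sd_pos = 0.14,
                            mean_neg = 0.25, sd_neg = 0.07,
                            direction = "high_is_positive"), shared)
  )
}

#' Simulate a cohort with ground truth
#'
#' Generates a [proteomics_matrix()], sample metadata, longitudinal CDR
#' visits and a truth record. Abundances are
#' `10^(baseline + plate effect + status * effect * sd + age/sex nuisance + noise)`,
#' censored to missing below the per-(analyte, plate) LOD. Deterministic
#' under a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return List with `matrix`, `samples`, `cdr`, `truth`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_co + cf$n_ad
  status <- c(rep("CO", cf$n_co), rep("AD", cf$n_ad))
  ids <- sprintf("%s_S%05d", cf$cohort, seq_len(n))
  age <- stats::rnorm(n, cf$age_mean + ifelse(status == "AD", cf$age_shift_ad, 0),
                      cf$age_sd)
  age <- pmax(age, 45)
  sex <- ifelse(stats::runif(n) < cf$prop_female, "female", "male")
  plate <- paste0("P", (seq_len(n) - 1L) %% cf$n_plates + 1L)

  p <- cf$n_analytes
  analytes <- sprintf("seq.%04d", seq_len(p))
  n_nonnull <- round(cf$fraction_nonnull * p)
  planted <- rep(0, p)
  if (n_nonnull > 0) {
    idx <- seq_len(n_nonnull)  # planted analytes are the first block
    eff <- rep_len(cf$effect_size_sd, n_nonnull)
    # a single positive magnitude gets random signs; an explicitly signed
    # vector is used as given (recycled over the planted analytes)
    if (length(cf$effect_size_sd) == 1L && cf$effect_size_sd > 0)
      eff <- eff * sample(c(-1, 1), n_nonnull, replace = TRUE)
    planted[idx] <- eff
  }
  names(planted) <- analytes

  baseline <- stats::runif(p, 2, 4)
  # per-analyte age/sex nuisance, kept small relative to the residual SD so
  # a clean cohort passes the CV filter and planted effects stay in SD units
  beta_age <- stats::rnorm(p, 0, 0.001)
  beta_sex <- stats::rnorm(p, 0, 0.01)
  plates <- paste0("P", seq_len(cf$n_plates))
  log_sf <- matrix(stats::rnorm(p * cf$n_plates, 0, cf$plate_sf_sd),
                   p, cf$n_plates, dimnames = list(analytes, plates))
  sf <- exp(log_sf)

  is_ad <- as.numeric(status == "AD")
  # log10 abundance: samples x analytes
  lm10 <- matrix(stats::rnorm(n * p, 0, cf$noise_sd), n, p)
  lm10 <- sweep(lm10, 2, baseline, `+`)
  lm10 <- lm10 + (age - cf$age_mean) %o% beta_age + (sex == "male") %o% beta_sex
  lm10 <- lm10 + is_ad %o% (planted * cf$noise_sd)
  plate_idx <- match(plate, plates)
  lm10 <- lm10 + t(log_sf * log10(exp(1)))[plate_idx, , drop = FALSE]

  # LOD floor at the configured quantile of each (analyte, plate) null
  # distribution; below-LOD cells become missing.
  lod10 <- outer(baseline, rep(1, cf$n_plates)) +
    log_sf * log10(exp(1)) + stats::qnorm(cf$lod_quantile) * cf$noise_sd
  dimnames(lod10) <- list(analytes, plates)
  vals <- 10^lm10
  dimnames(vals) <- list(ids, analytes)
  lodm <- 10^lod10
  below <- vals < t(lodm)[plate_idx, , drop = FALSE]
  vals[below] <- NA
  if (cf$missing_rate > 0)
    vals[stats::runif(length(vals)) < cf$missing_rate] <- NA

  # latent pathology group and bimodal biomarkers
  p_pos <- ifelse(status == "AD", cf$biomarkers[[1]]$p_pos_ad,
                  cf$biomarkers[[1]]$p_pos_co)
  group <- as.integer(stats::runif(n) < p_pos)
  bm_vals <- lapply(cf$biomarkers, function(bm) {
    ifelse(group == 1L,
           stats::rnorm(n, bm$mean_pos, bm$sd_pos),
           stats::rnorm(n, bm$mean_neg, bm$sd_neg))
  })

  samples <- data.frame(sample_id = ids, age_at_draw = age, sex = sex,
                        cohort = cf$cohort, dataset_cluster = cf$dataset_cluster,
                        clinical_status = status, plate = plate,
                        stringsAsFactors = FALSE)
  for (nm in names(bm_vals)) samples[[nm]] <- bm_vals[[nm]]

  # conversion of controls to symptomatic AD: exponential times with
  # log-hazard linear in designated analytes (z-scale), administrative
  # censoring at a uniformly drawn follow-up
  log_hr <- cf$protein_log_hr
  if (is.numeric(log_hr) && length(log_hr) == 1L && is.null(names(log_hr))) {
    k <- min(as.integer(log_hr), max(n_nonnull, 0L))
    log_hr <- stats::setNames(rep(log(2) / 2, k), analytes[seq_len(k)])
  }
  zmat <- scale(lm10)
  lin <- rep(0, n)
  if (length(log_hr)) {
    j <- match(names(log_hr), analytes)
    if (anyNA(j)) stop("protein_log_hr names not among analyte ids")
    lin <- as.vector(zmat[, j, drop = FALSE] %*% unname(log_hr))
  }
  hazard <- cf$hazard_baseline * exp(lin)
  follow_up <- stats::runif(n, cf$follow_up_range[1], cf$follow_up_range[2])
  t_conv <- stats::rexp(n, rate = pmax(hazard, 1e-12))
  is_co <- status == "CO"
  event <- as.integer(is_co & t_conv <= follow_up)
  time_obs <- ifelse(event == 1L, t_conv, follow_up)

  # CDR-SB trajectories: annual visits, linear decline with group- and
  # status-dependent slope
  sl <- cf$cdr_slopes
  slope_mean <- ifelse(is_co,
                       ifelse(group == 1L, sl$co_pos, sl$co_neg),
                       ifelse(group == 1L, sl$ad_pos, sl$ad_neg))
  true_slope <- pmax(stats::rnorm(n, slope_mean, sl$sd), 0)
  sb0 <- ifelse(is_co, 0, stats::runif(n, 2, 8))
  cdr_list <- vector("list", n)
  for (i in seq_len(n)) {
    t_vis <- c(stats::runif(1, -0.15, 0.15), seq_len(max(1L, floor(follow_up[i]))))
    sb <- pmax(sb0[i] + true_slope[i] * pmax(t_vis, 0) +
                 stats::rnorm(length(t_vis), 0, 0.2), 0)
    if (is_co[i]) {
      glob <- ifelse(event[i] == 1L & t_vis > t_conv[i], 0.5, 0)
      sb[glob == 0] <- pmin(sb[glob == 0], 0.5)
      sb[t_vis <= 0.2] <- 0   # CDR 0 at draw for controls
    } else {
      glob <- ifelse(sb >= 4.5, 1, 0.5)
    }
    cdr_list[[i]] <- data.frame(sample_id = ids[i],
                                visit_age = age[i] + t_vis,
                                years_from_draw = t_vis,
                                cdr_global = glob, cdr_sb = sb,
                                stringsAsFactors = FALSE)
  }
  cdr <- do.call(rbind, cdr_list)

  truth <- list(
    planted_effect = planted,
    latent_group = stats::setNames(group, ids),
    protein_log_hr = log_hr,
    hazard_baseline = cf$hazard_baseline,
    conversion = data.frame(sample_id = ids, hazard = hazard,
                            time = time_obs, event = event,
                            follow_up = follow_up,
                            onset_age = ifelse(event == 1L, age + t_conv, NA),
                            stringsAsFactors = FALSE),
    true_slope = stats::setNames(true_slope, ids),
    biomarker_mixtures = cf$biomarkers,
    config = cf
  )

  list(matrix = proteomics_matrix(vals, stats::setNames(plate, ids),
                                  scale_factor = sf, lod = lodm),
       samples = validate_samples(samples),
       cdr = validate_cdr(cdr),
       truth = truth)
}

#' Oracle (Bayes-optimal) disease score from the generating model
#'
#' Computes, for each sample, the linear log-odds score implied by the
#' generative model: planted effects applied to the normalized protein
#' levels plus the age term induced by the case/control age shift. The AUC
#' of this score on a dataset is a Monte-Carlo estimate of the
#' Bayes-optimal AUC attainable there, the natural yardstick for a fitted
#' panel evaluated on the same samples.
#'
#' @param truth Truth record from [simulate_cohort()].
#' @param zmat Normalized matrix (samples x analytes).
#' @param samples Metadata for the rows to score.
#' @return Named numeric score vector.
#' @export
oracle_score <- function(truth, zmat, samples) {
  cf <- truth$config
  ids <- intersect(rownames(zmat), samples$sample_id)
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  z <- zmat[ids, , drop = FALSE]
  z[is.na(z)] <- 0
  pe <- truth$planted_effect[colnames(z)]
  pe[is.na(pe)] <- 0
  s <- as.vector(z %*% pe) +
    (cf$age_shift_ad / cf$age_sd^2) * samples$age_at_draw
  stats::setNames(s, ids)
}

#' Simulate an external study's summary statistics
#'
#' Produces a per-analyte external result table whose effect signs agree with
#' the internal ground truth with a stated probability; a fixture for
#' cross-study concordance analyses.
#'
#' @param truth Truth record from [simulate_cohort()] (uses `planted_effect`).
#' @param concordance_prob Probability that an external effect sign matches
#'   the internal one.
#' @param noise_sd SD of magnitude noise added to external effects.
#' @param seed Integer seed.
#' @param effect_kind `"mean_difference"` or `"ln_hazard_ratio"` (label
#'   only; the sign convention is shared).
#' @param analytes Optional subset of analyte ids.
#' @return data.frame with `analyte_id`, `effect`, `p`, `effect_kind`.
#' @export
simulate_external_study <- function(truth, concordance_prob = 0.8,
                                    noise_sd = 0.1, seed = 1L,
                                    effect_kind = c("mean_difference",
                                                    "ln_hazard_ratio"),
                                    analytes = NULL) {
  effect_kind <- match.arg(effect_kind)
  if (concordance_prob < 0 || concordance_prob > 1)
    stop("concordance_prob must lie in [0, 1]")
  pe <- truth$planted_effect
  if (!is.null(analytes)) {
    unknown <- setdiff(analytes, names(pe))
    if (length(unknown)) stop("unknown analyte ids: ",
                              paste(unknown, collapse = ", "))
    pe <- pe[analytes]
  }
  set.seed(seed)
  n <- length(pe)
  internal_sign <- ifelse(pe == 0, sample(c(-1, 1), n, replace = TRUE), sign(pe))
  agree <- stats::runif(n) < concordance_prob
  ext_sign <- ifelse(agree, internal_sign, -internal_sign)
  mag <- abs(pe) + abs(stats::rnorm(n, 0, noise_sd)) + 1e-6
  effect <- ext_sign * mag
  se <- pmax(noise_sd, 0.05)
  p <- 2 * stats::pnorm(-abs(effect) / se)
  data.frame(analyte_id = names(pe), effect = effect, p = pmin(pmax(p, 1e-300), 1),
             effect_kind = effect_kind, stringsAsFactors = FALSE)
}
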