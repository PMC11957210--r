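# Progression to symptomatic AD: time-to-event construction for cognitively
# normal participants, Cox proportional-hazards fits (per analyte or for a
# predicted group), Kaplan-Meier summaries, CDR-SB decline slopes and their
# rank-sum comparison. Model fitting is delegated to the survival package
# (Efron tie handling).

#' Build time-to-event inputs for progression analysis
#'
#' Restricts to participants who were cognitively normal (CDR = 0) at blood
#' draw and have at least one later assessment. Duration is the age at AD
#' onset (converters) or at the last CDR visit (non-converters) minus the
#' age at draw; the event flag marks converters. Subjects with non-positive
#' duration (e.g. onset recorded before the draw) are excluded with a
#' warning, never clamped.
#'
#' @param samples Sample metadata (`age_at_draw`, `sex`, ...).
#' @param cdr_visits CDR visit table (see [validate_cdr()]).
#' @param onset_info Optional data.frame `sample_id`, `onset_age` for
#'   converters. When absent, onset is inferred as the midpoint between the
#'   last CDR = 0 visit and the first CDR > 0 visit.
#' @return data.frame with `sample_id`, `duration`, `event`, `age_at_draw`,
#'   `sex`.
#' @export
build_time_to_event <- function(samples, cdr_visits, onset_info = NULL) {
  cdr_visits <- validate_cdr(cdr_visits)
  out <- lapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    age0 <- samples$age_at_draw[i]
    v <- cdr_visits[cdr_visits$sample_id == sid, , drop = FALSE]
    if (!nrow(v)) return(NULL)
    # CN at draw: CDR 0 at the visit closest to the draw
    at_draw <- v[which.min(abs(v$visit_age - age0)), ]
    if (at_draw$cdr_global != 0) return(NULL)
    post <- v[v$visit_age > age0 + 1e-9, , drop = FALSE]
    if (!nrow(post)) return(NULL)
    onset_age <- NA_real_
    if (!is.null(onset_info)) {
      m <- onset_info$onset_age[match(sid, onset_info$sample_id)]
      if (length(m) && !is.na(m)) onset_age <- m
    }
    converted <- any(post$cdr_global > 0)
    if (is.na(onset_age) && converted) {
      first_pos <- min(post$visit_age[post$cdr_global > 0])
      zero_before <- v$visit_age[v$cdr_global == 0 & v$visit_age < first_pos]
      last_zero <- if (length(zero_before)) max(zero_before) else age0
      onset_age <- (last_zero + first_pos) / 2
    }
    event <- as.integer(!is.na(onset_age))
    end_age <- if (event == 1L) onset_age else max(v$visit_age)
    dur <- end_age - age0
    if (dur <= 0) {
      warning("subject ", sid, " excluded: non-positive duration (onset before draw?)")
      return(NULL)
    }
    data.frame(sample_id = sid, duration = dur, event = event,
               age_at_draw = age0, sex = samples$sex[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no eligible cognitively normal subjects")
  rownames(res) <- NULL
  res
}

#' Cox proportional-hazards regression for one exposure
#'
#' Partial-likelihood fit (Efron ties) of duration/event on the exposure plus
#' covariates. Used both per analyte (continuous z-scored level) and for the
#' frozen-panel predicted group (binary indicator).
#'
#' @param inputs data.frame from [build_time_to_event()] with an added
#'   exposure column.
#' @param exposure Name of the exposure column.
#' @param covariates Covariate column names (default age at draw and sex).
#' @param min_events Minimum number of events (default 10).
#' @return List with `ln_hr`, `se`, `p`, `n`, `n_events`, `flagged`
#'   (monotone-likelihood / separation warning).
#' @export
cox_regression <- function(inputs, exposure,
                           covariates = c("age_at_draw", "sex"),
                           min_events = 10) {
  if (!exposure %in% names(inputs)) stop("missing exposure column: ", exposure)
  covariates <- covariates[vapply(covariates, function(cv)
    length(unique(stats::na.omit(inputs[[cv]]))) > 1, logical(1))]
  keep <- stats::complete.cases(inputs[, c("duration", "event", exposure, covariates)])
  d <- inputs[keep, , drop = FALSE]
  if (sum(d$event) < min_events)
    stop("fewer than ", min_events, " events")
  form <- stats::as.formula(paste("survival::Surv(duration, event) ~",
                                  paste(c(exposure, covariates), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w)))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  row <- grep(paste0("^", exposure), rownames(sm$coefficients))[1]
  co <- sm$coefficients[row, ]
  if (abs(co["coef"]) > 15) flagged <- TRUE
  list(ln_hr = unname(co["coef"]), se = unname(co["se(coef)"]),
       p = unname(co["Pr(>|z|)"]), n = nrow(d), n_events = sum(d$event),
       score_test = unname(sm$sctest["test"]),
       score_p = unname(sm$sctest["pvalue"]),
       flagged = flagged, fit = fit)
}

#' Kaplan-Meier survival summary
#'
#' Product-limit estimates with at-risk counts at event times, per group.
#'
#' @param inputs data.frame with `duration`, `event`.
#' @param group Optional grouping vector (recycled/aligned to rows).
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_summary <- function(inputs, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(inputs))
  if (!length(group) || !nrow(inputs)) stop("groups must be non-empty")
  d <- data.frame(duration = inputs$duration, event = inputs$event,
                  group = group)
  fit <- survival::survfit(survival::Surv(duration, event) ~ group, data = d)
  sm <- summary(fit, censored = FALSE)
  grp <- if (is.null(sm$strata)) rep(unique(d$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, survival = sm$surv,
             stringsAsFactors = FALSE)
}

#' CDR sum-of-boxes decline slopes
#'
#' For each subject, the initial record is the CDR visit closest to the blood
#' draw within a +/- `window_days` window (ties broken toward the pre-draw
#' record) and the last record is the latest available visit. The slope is
#' the CDR-SB difference divided by the years spanned. Subjects without an
#' in-window initial record or with no later record are excluded and
#' counted.
#'
#' @param cdr_visits CDR visit table.
#' @param draw_info data.frame `sample_id`, `draw_age` (years).
#' @param window_days Window half-width in days (default 180).
#' @return List with `slopes` (data.frame `sample_id`, `baseline_cdr_sb`,
#'   `years_spanned`, `slope`, `n_visits`) and `n_excluded`.
#' @export
cdr_sb_slope <- function(cdr_visits, draw_info, window_days = 180) {
  cdr_visits <- validate_cdr(cdr_visits)
  window_years <- window_days / 365.25
  n_excluded <- 0L
  out <- lapply(seq_len(nrow(draw_info)), function(i) {
    sid <- draw_info$sample_id[i]
    draw_age <- draw_info$draw_age[i]
    v <- cdr_visits[cdr_visits$sample_id == sid & !is.na(cdr_visits$cdr_sb), ,
                    drop = FALSE]
    if (nrow(v) < 2) { n_excluded <<- n_excluded + 1L; return(NULL) }
    dist <- abs(v$visit_age - draw_age)
    in_win <- which(dist <= window_years + 1e-12)
    if (!length(in_win)) { n_excluded <<- n_excluded + 1L; return(NULL) }
    # nearest wins; ties broken toward the pre-draw record
    cand <- in_win[order(dist[in_win], v$visit_age[in_win])]
    init <- cand[1]
    last <- which.max(v$visit_age)
    yrs <- v$visit_age[last] - v$visit_age[init]
    if (last == init || yrs <= 0) { n_excluded <<- n_excluded + 1L; return(NULL) }
    data.frame(sample_id = sid, baseline_cdr_sb = v$cdr_sb[init],
               years_spanned = yrs,
               slope = (v$cdr_sb[last] - v$cdr_sb[init]) / yrs,
               n_visits = nrow(v), stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, out)
  list(slopes = slopes, n_excluded = n_excluded)
}

#' Compare decline slopes between two groups
#'
#' Two-sided Wilcoxon rank-sum test: exact when the combined sample size is
#' at most 25 and there are no ties, tie-corrected normal approximation
#' otherwise. Reports per-group medians and means.
#'
#' @param slopes Numeric slope values.
#' @param group_labels Two-level grouping vector aligned with `slopes`.
#' @return List with `p`, `medians`, `means`, `n`, `method`.
#' @export
compare_slopes <- function(slopes, group_labels) {
  g <- factor(group_labels)
  if (nlevels(g) != 2) stop("need exactly two groups")
  x <- slopes[g == levels(g)[1]]
  y <- slopes[g == levels(g)[2]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (length(unique(slopes)) == 1) {
    warning("all slope values identical; p = 1")
    p <- 1
    method <- "degenerate"
  } else {
    exact <- (length(x) + length(y)) <= 25 && !anyDuplicated(slopes)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = !exact))
    p <- wt$p.value
    method <- if (exact) "exact" else "normal approximation"
  }
  list(p = p,
       medians = stats::setNames(c(stats::median(x), stats::median(y)), levels(g)),
       means = stats::setNames(c(mean(x), mean(y)), levels(g)),
       n = stats::setNames(c(length(x), length(y)), levels(g)),
       method = method)
}
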