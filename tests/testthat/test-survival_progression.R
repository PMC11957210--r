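# Progression analyses: time-to-event construction, Cox fits vs log-rank,
# Kaplan-Meier estimates, CDR-SB slopes and rank-sum comparisons.

make_cdr <- function(sample_id, ages, globals, sbs = NULL) {
  data.frame(sample_id = sample_id, visit_age = ages, cdr_global = globals,
             cdr_sb = if (is.null(sbs)) globals else sbs,
             stringsAsFactors = FALSE)
}

test_that("time-to-event durations and events follow the rules", {
  s <- make_samples(3, rep("CO", 3), age = c(75, 75, 75))
  cdr <- rbind(
    make_cdr("S01", c(75, 78, 80), c(0, 0, 0)),          # censored at 80
    make_cdr("S02", c(75, 77, 79), c(0, 0, 0.5)),        # converter
    make_cdr("S03", c(75, 78), c(0, 0)))                 # onset before draw
  onset <- data.frame(sample_id = c("S02", "S03"), onset_age = c(78, 74))
  expect_warning(tte <- build_time_to_event(s, cdr, onset), "S03")
  expect_identical(nrow(tte), 2L)
  expect_equal(tte$duration[tte$sample_id == "S01"], 5)
  expect_identical(tte$event[tte$sample_id == "S01"], 0L)
  expect_equal(tte$duration[tte$sample_id == "S02"], 3)
  expect_identical(tte$event[tte$sample_id == "S02"], 1L)

  # without onset info, converters get the midpoint between last CDR=0 and
  # first CDR>0 visits
  tte2 <- build_time_to_event(s[2, , drop = FALSE], cdr[cdr$sample_id == "S02", ])
  expect_equal(tte2$duration, (77 + 79) / 2 - 75)

  # non-CN at draw is excluded entirely
  cdr_ad <- make_cdr("S01", c(75, 78), c(0.5, 1))
  expect_error(build_time_to_event(s[1, , drop = FALSE], cdr_ad), "no eligible")
})

test_that("Cox recovers a planted binary-exposure hazard ratio", {
  set.seed(14)
  n <- 1000
  x <- stats::rbinom(n, 1, 0.5)
  t_ev <- stats::rexp(n, 0.08 * 2^x)
  cens <- stats::runif(n, 0, 8)
  d <- data.frame(sample_id = seq_len(n),
                  duration = pmin(t_ev, cens),
                  event = as.integer(t_ev <= cens),
                  age_at_draw = stats::rnorm(n, 70, 5),
                  sex = sample(c("female", "male"), n, TRUE),
                  exposure = x)
  expect_gt(mean(d$event), 0.2); expect_lt(mean(d$event), 0.45)
  fit <- cox_regression(d, "exposure")
  expect_lt(abs(fit$ln_hr - log(2)), 0.15)
  expect_false(fit$flagged)

  # null exposure: estimate near zero
  d$noise <- stats::rnorm(n)
  fit0 <- cox_regression(d, "noise")
  expect_lt(abs(fit0$ln_hr), 3 * fit0$se)
  expect_error(cox_regression(d[1:20, ], "exposure", min_events = 10), "events")
})

test_that("Cox score test matches the log-rank test without ties/covariates", {
  set.seed(15)
  n <- 60
  g <- rep(0:1, each = n / 2)
  d <- data.frame(duration = stats::rexp(n, 0.1 * 1.8^g) + stats::runif(n, 0, 1e-4),
                  event = 1L, group = g)
  fit <- survival::coxph(survival::Surv(duration, event) ~ group, data = d,
                         ties = "efron")
  lr <- survival::survdiff(survival::Surv(duration, event) ~ group, data = d)
  expect_equal(unname(summary(fit)$sctest["test"]), lr$chisq, tolerance = 1e-6)
})

test_that("Cox estimates are invariant to time-origin shift; sex recode flips sign", {
  set.seed(16)
  n <- 300
  d <- data.frame(duration = stats::rexp(n, 0.1), event = stats::rbinom(n, 1, 0.6),
                  age_at_draw = stats::rnorm(n, 70, 5),
                  sex = sample(c("female", "male"), n, TRUE),
                  exposure = stats::rnorm(n))
  f1 <- cox_regression(d, "exposure")
  d2 <- d; d2$duration <- d2$duration + 5  # common shift: same ranks
  f2 <- cox_regression(d2, "exposure")
  expect_equal(f1$ln_hr, f2$ln_hr, tolerance = 1e-10)
  d3 <- d; d3$sex <- ifelse(d$sex == "male", "a_male", "female")  # flip reference
  f3 <- cox_regression(d3, "exposure")
  expect_equal(f3$ln_hr, f1$ln_hr, tolerance = 1e-6)
  expect_equal(unname(stats::coef(f3$fit)[grep("sex", names(stats::coef(f3$fit)))]),
               -unname(stats::coef(f1$fit)[grep("sex", names(stats::coef(f1$fit)))]),
               tolerance = 1e-6)
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  d <- data.frame(duration = 1:5, event = 1L)
  km <- km_summary(d)
  expect_equal(km$survival, (5 - 1:5) / 5)
  expect_true(all(diff(km$survival) <= 0))
  expect_identical(nrow(km_summary(data.frame(duration = 1:4, event = 0L))), 0L)
  # no-event curve is identically 1 (no event rows in the summary)
  grp <- km_summary(data.frame(duration = c(1, 2, 3, 4), event = c(1, 1, 0, 0)),
                    group = c("a", "a", "b", "b"))
  expect_true(all(grp$group == "a"))
})

test_that("CDR-SB slopes use the windowed initial record", {
  draw <- data.frame(sample_id = c("S01", "S02", "S03"), draw_age = 70)
  cdr <- rbind(
    make_cdr("S01", c(70, 72), c(0, 1), sbs = c(0.5, 2.5)),
    make_cdr("S02", c(70 - 200 / 365.25, 70 + 10 / 365.25, 73),
             c(0, 0, 1), sbs = c(0, 1, 4)),
    make_cdr("S03", 70, 0, sbs = 0))
  out <- cdr_sb_slope(cdr, draw)
  s1 <- out$slopes[out$slopes$sample_id == "S01", ]
  expect_equal(s1$slope, 1)
  # S02: the -200d record is outside the window; +10d wins as initial
  s2 <- out$slopes[out$slopes$sample_id == "S02", ]
  expect_equal(s2$baseline_cdr_sb, 1)
  expect_equal(s2$slope, (4 - 1) / (73 - (70 + 10 / 365.25)))
  expect_identical(out$n_excluded, 1L)  # S03: single visit

  # pre-draw record wins a distance tie
  cdr_tie <- make_cdr("S01", c(70 - 50 / 365.25, 70 + 50 / 365.25, 74),
                      c(0, 0, 1), sbs = c(0, 1, 3))
  tie <- cdr_sb_slope(cdr_tie, draw[1, ])
  expect_equal(tie$slopes$baseline_cdr_sb, 0)
})

test_that("slope comparison: exact enumeration oracle and approximations", {
  # {1,2,3} vs {4,5,6}: 2 of the 20 assignments are as extreme (two-sided)
  cs <- compare_slopes(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(cs$p, 0.1, tolerance = 1e-12)
  expect_identical(cs$method, "exact")

  # enumeration oracle for an arbitrary small case
  x <- c(0.3, 1.1, 2.2, 0.7); y <- c(1.9, 2.8, 3.4)
  obs <- sum(rank(c(x, y))[seq_along(x)])
  combos <- utils::combn(7, 4)
  all_sums <- apply(combos, 2, function(ix) sum(rank(c(x, y))[ix]))
  p_enum <- min(1, 2 * min(mean(all_sums <= obs), mean(all_sums >= obs)))
  cs2 <- compare_slopes(c(x, y), c(rep("a", 4), rep("b", 3)))
  expect_equal(cs2$p, p_enum, tolerance = 1e-10)

  # exact and normal approximation agree within 0.01 near n = 25
  set.seed(18)
  a <- stats::rnorm(12); b <- stats::rnorm(12, 0.5)
  p_exact <- compare_slopes(c(a, b), rep(c("a", "b"), each = 12))$p
  p_norm <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_norm), 0.01)

  expect_warning(cs3 <- compare_slopes(rep(1, 10), rep(c("a", "b"), 5)), "identical")
  expect_equal(cs3$p, 1)
  expect_error(compare_slopes(1:4, rep("a", 4)), "two groups")
})
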