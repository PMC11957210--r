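# Cross-study replication statistics: sign concordance, exact binomial
# enrichment against a 50% null, effect-size correlation on a chosen subset,
# and membership-pattern overlap summaries. The binomial tail is computed
# exactly in log space because the headline p-values sit far in the tail
# (~1e-34 and beyond).

#' Direction concordance between internal and external results
#'
#' Matches analytes present in both tables and counts sign agreement of the
#' effects. External effects of exactly zero carry no sign and are excluded
#' from the evaluable count. For survival-based external studies the effect
#' should be the log hazard ratio, which shares the sign convention.
#'
#' @param internal data.frame with `analyte_id` and `effect` (internal
#'   direction must be nonzero).
#' @param external data.frame with `analyte_id` and `effect`.
#' @return List with `n` (evaluable pairs), `k` (concordant pairs) and the
#'   matched `table`.
#' @export
direction_concordance <- function(internal, external) {
  common <- intersect(internal$analyte_id, external$analyte_id)
  if (!length(common)) stop("no overlapping analyte ids")
  i <- internal[match(common, internal$analyte_id), ]
  e <- external[match(common, external$analyte_id), ]
  evaluable <- i$effect != 0 & e$effect != 0 & !is.na(i$effect) & !is.na(e$effect)
  n_zero <- sum(!evaluable)
  if (n_zero) message(n_zero, " pair(s) excluded (zero or missing effect)")
  tab <- data.frame(analyte_id = common,
                    effect_internal = i$effect, effect_external = e$effect,
                    concordant = sign(i$effect) == sign(e$effect),
                    stringsAsFactors = FALSE)[evaluable, , drop = FALSE]
  list(n = nrow(tab), k = sum(tab$concordant), table = tab)
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# exact log upper tail P(X >= k), X ~ Binomial(n, p), via log-gamma pmf terms
binom_log_upper_tail <- function(k, n, p) {
  if (k <= 0) return(0)
  if (k > n) return(-Inf)
  ks <- k:n
  log_sum_exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p))
}

#' Exact binomial enrichment of sign concordance
#'
#' Fold enrichment `k / (n p0)` and an exact binomial p-value for observing
#' `k` concordant directions out of `n` under a null concordance probability
#' `p0` (0.5 by default: equal chance of either direction). The one-sided
#' p-value is the exact upper tail `P(X >= k)`; the two-sided version at a
#' symmetric null is `2 min(P(X >= k), P(X <= k))` capped at 1. Computed in
#' log space so far-tail values retain full relative accuracy.
#'
#' @param k Observed concordant count.
#' @param n Evaluable pairs.
#' @param p0 Null concordance probability (default 0.5).
#' @param alternative `"greater"` (default, matching the tail description)
#'   or `"two_sided"`.
#' @return List with `fold` and `p`.
#' @export
binomial_enrichment <- function(k, n, p0 = 0.5,
                                alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  upper <- exp(binom_log_upper_tail(k, n, p0))
  if (alternative == "greater") {
    p <- upper
  } else {
    lower <- 1 - exp(binom_log_upper_tail(k + 1, n, p0))
    if (k + 1 > n) lower <- 1
    # at extreme k the complement loses accuracy; recompute lower tail exactly
    if (lower < 1e-10)
      lower <- exp(binom_log_upper_tail(n - k, n, 1 - p0))
    p <- min(1, 2 * min(upper, lower))
  }
  list(fold = k / (n * p0), p = p)
}

#' Effect-size correlation between internal and external results
#'
#' Pearson correlation (and its two-sided p) of matched effects, by default
#' restricted to pairs where the external study reported nominal
#' significance (p < 0.05), matching the convention used when comparing to
#' prior studies.
#'
#' @param internal,external data.frames with `analyte_id`, `effect`;
#'   `external` needs `p` when subsetting.
#' @param subset `"external_nominal"` (default) or `"all"`.
#' @param alpha Nominal threshold for the subset.
#' @return List with `r`, `p`, `n_used`.
#' @export
effect_correlation <- function(internal, external,
                               subset = c("external_nominal", "all"),
                               alpha = 0.05) {
  subset <- match.arg(subset)
  common <- intersect(internal$analyte_id, external$analyte_id)
  i <- internal[match(common, internal$analyte_id), ]
  e <- external[match(common, external$analyte_id), ]
  keep <- !is.na(i$effect) & !is.na(e$effect)
  if (subset == "external_nominal") {
    if (is.null(e$p)) stop("external table lacks a `p` column")
    keep <- keep & !is.na(e$p) & e$p < alpha
  }
  if (sum(keep) < 3) stop("fewer than 3 paired observations after subsetting")
  ct <- stats::cor.test(i$effect[keep], e$effect[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = sum(keep))
}

#' Membership-pattern overlap summary
#'
#' Counts elements of the union of the given sets by their exact membership
#' pattern (the patterns partition the union) -- the tabular backbone of an
#' UpSet-style display.
#'
#' @param named_sets Named list of character vectors.
#' @return data.frame with `pattern` (e.g. `"A&B"`) and `count`.
#' @export
overlap_summary <- function(named_sets) {
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets))))
    stop("sets must be named")
  all_ids <- unique(unlist(named_sets))
  if (!length(all_ids))
    return(data.frame(pattern = character(), count = integer()))
  mem <- vapply(named_sets, function(s) all_ids %in% s, logical(length(all_ids)))
  mem <- matrix(mem, nrow = length(all_ids),
                dimnames = list(all_ids, names(named_sets)))
  pat <- apply(mem, 1, function(r) paste(colnames(mem)[r], collapse = "&"))
  tab <- table(pat)
  data.frame(pattern = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
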