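# Over-representation against user-supplied gene sets (exact hypergeometric
# upper tail) and the aggregated Cauchy (ACAT) combination used to rank
# network modules by their joint enrichment for up- and down-regulated
# signature subsets.

#' Hypergeometric over-representation test
#'
#' For each set, the upper-tail probability `P(X >= k)` of the observed
#' overlap `k` between the hit list and the set, both intersected with the
#' universe, under hypergeometric sampling. Benjamini-Hochberg adjustment is
#' applied across the tested sets.
#'
#' @param hits Character vector of hit identifiers (subset of `universe`).
#' @param sets Named list of character vectors (e.g. from
#'   [read_gene_sets_gmt()]).
#' @param universe Character vector of all testable identifiers.
#' @return data.frame with `set_name`, `universe_size`, `set_size`,
#'   `hit_size`, `overlap`, `fold`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(hits, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- unique(intersect(hits, universe))
  if (!length(hits)) stop("empty hit list (after intersecting with universe)")
  n_u <- length(universe); n_h <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    s <- unique(intersect(sets[[nm]], universe))
    k <- length(intersect(s, hits))
    expected <- length(s) * n_h / n_u
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_h,
                       lower.tail = FALSE)
    data.frame(set_name = nm, universe_size = n_u, set_size = length(s),
               hit_size = n_h, overlap = k,
               fold = if (expected > 0) k / expected else NA_real_,
               p = min(p, 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p, nrow(out))
  out
}

#' Aggregated Cauchy (ACAT) p-value combination
#'
#' `T = sum(w_i tan((0.5 - p_i) pi)) / sum(w_i)` and combined
#' `p = 0.5 - atan(T) / pi`. Inputs at exactly 0 or 1 are clamped to
#' `eps` / `1 - eps` with a warning (the tangent diverges there).
#'
#' @param pvals Numeric p-values in (0, 1).
#' @param weights Positive weights (default equal).
#' @param eps Clamping bound (default 1e-15).
#' @return Combined p-value.
#' @export
acat_combine <- function(pvals, weights = NULL, eps = 1e-15) {
  if (!length(pvals)) stop("empty p-value input")
  if (is.null(weights)) weights <- rep(1, length(pvals))
  if (length(weights) != length(pvals) || any(weights <= 0))
    stop("weights must be positive and match pvals")
  if (any(pvals <= 0 | pvals >= 1)) {
    warning("p-values at 0/1 clamped to (eps, 1 - eps)")
    pvals <- pmin(pmax(pvals, eps), 1 - eps)
  }
  t_stat <- sum(weights * tan((0.5 - pvals) * pi)) / sum(weights)
  min(max(0.5 - atan(t_stat) / pi, 0), 1)
}

#' Rank modules by joint enrichment for up- and down-regulated signatures
#'
#' Per module: hypergeometric enrichment against the up-regulated and
#' down-regulated signature subsets separately, combined by ACAT, ranked by
#' combined p ascending (ties broken by module name for determinism).
#' Modules disjoint from the universe get p = 1 entries.
#'
#' @param modules Named list of protein sets (user-supplied; network
#'   construction is out of scope).
#' @param signature_up,signature_down Up-/down-regulated hit subsets.
#' @param universe All testable identifiers.
#' @return data.frame with `module`, `p_up`, `p_down`, `p_acat`, `rank`.
#' @export
rank_modules <- function(modules, signature_up, signature_down, universe) {
  res_up <- hypergeometric_enrichment(signature_up, modules, universe)
  res_dn <- hypergeometric_enrichment(signature_down, modules, universe)
  p_up <- stats::setNames(res_up$p, res_up$set_name)[names(modules)]
  p_dn <- stats::setNames(res_dn$p, res_dn$set_name)[names(modules)]
  p_acat <- vapply(names(modules), function(m)
    acat_combine(pmin(c(p_up[m], p_dn[m]), 1 - 1e-15)), 0)
  out <- data.frame(module = names(modules), p_up = unname(p_up),
                    p_down = unname(p_dn), p_acat = unname(p_acat),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_acat, out$module), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
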