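# Robust median statistics for small-n microcosm data: Hodges-Lehmann
# shift estimates with exact Mann-Whitney confidence intervals,
# percentile-bootstrap pairwise median comparisons with Benjamini-Hochberg
# adjustment, and Cohen's d effect sizes.

#' Hodges-Lehmann shift estimate with exact confidence interval
#'
#' The estimate is the median of all `nx * ny` pairwise differences
#' `x_i - y_j`. The confidence interval is taken from the order statistics
#' of the sorted pairwise differences at ranks given by the exact
#' Mann-Whitney null quantile, the conservative construction appropriate
#' for the small replicate counts (n = 4) of microcosm experiments.
#'
#' @param x,y numeric vectors of per-microcosm values (each n >= 2).
#' @param conf confidence level (default 0.95).
#' @param labels length-2 character vector naming the two groups.
#' @return A one-row data frame (class `comparison_result`) with columns
#'   `group1`, `group2`, `estimate`, `ci_low`, `ci_high`, `conf`, `method`.
#' @examples
#' hodges_lehmann(c(1, 2), c(0, 1)) # estimate 1 (diffs 0, 1, 1, 2)
#' @export
hodges_lehmann <- function(x, y, conf = 0.95, labels = c("x", "y")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    sg_stop("each group needs at least 2 values", "sg_empty_group")
  }
  diffs <- sort(as.vector(outer(x, y, "-")))
  m <- length(diffs)
  est <- stats::median(diffs)
  alpha <- 1 - conf
  qu <- stats::qwilcox(alpha / 2, length(x), length(y))
  if (qu == 0) qu <- 1
  ql <- m - qu
  res <- data.frame(group1 = labels[1], group2 = labels[2],
                    estimate = est, ci_low = diffs[qu], ci_high = diffs[ql + 1],
                    conf = conf, method = "hodges-lehmann",
                    stringsAsFactors = FALSE)
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Percentile-bootstrap pairwise comparison of group medians
#'
#' For every unordered pair of groups, each group is resampled with
#' replacement `B` times and the bootstrap distribution of the median
#' difference `d* = median(x*) - median(y*)` is formed. The two-sided
#' p-value is `2 * min(phat, 1 - phat)` with
#' `phat = (#\{d* > 0\} + 0.5 * #\{d* = 0\}) / B`, floored at `1/B` so that a
#' finite bootstrap never reports exactly zero. P-values are adjusted
#' across all pairs of the family with [benjamini_hochberg()]. The
#' percentile interval of `d*` is reported alongside. Deterministic given
#' `seed`.
#'
#' @param groups named list of numeric vectors (the comparison family,
#'   typically all treatments of one response x timepoint panel).
#' @param B bootstrap replicates (>= 500; default 2000).
#' @param seed integer seed (required: results are resampling-based).
#' @param conf confidence level for the percentile interval.
#' @return A data frame (class `comparison_result`) with one row per pair:
#'   `group1`, `group2`, `estimate` (observed median difference), `ci_low`,
#'   `ci_high` (percentile bootstrap), `p_raw`, `p_adj`, `method`.
#' @export
bootstrap_median_pairs <- function(groups, B = 2000, seed, conf = 0.95) {
  if (missing(seed)) sg_stop("a seed is required", "sg_seed_required")
  if (B < 500) sg_stop("B must be >= 500", "sg_bootstrap_too_small")
  if (length(groups) < 2) sg_stop("need at least two groups", "sg_empty_group")
  if (is.null(names(groups)) || anyNA(names(groups)) ||
      any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (g in groups) {
    if (length(g) < 2) sg_stop("each group needs at least 2 values",
                               "sg_empty_group")
  }
  set.seed(as.integer(seed))
  # one bootstrap median matrix per group, shared across its pairings
  boot_med <- lapply(groups, function(g) {
    n <- length(g)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    samp <- matrix(g[idx], nrow = B)
    # row medians without apply(): sort each row via matrixized order trick
    row_medians(samp)
  })
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  alpha <- 1 - conf
  rows <- lapply(pairs, function(p) {
    dstar <- boot_med[[p[1]]] - boot_med[[p[2]]]
    phat <- (sum(dstar > 0) + 0.5 * sum(dstar == 0)) / B
    p_raw <- max(2 * min(phat, 1 - phat), 1 / B)
    p_raw <- min(p_raw, 1)
    ci <- stats::quantile(dstar, c(alpha / 2, 1 - alpha / 2),
                          names = FALSE, type = 6)
    data.frame(group1 = p[1], group2 = p[2],
               estimate = stats::median(groups[[p[1]]]) -
                 stats::median(groups[[p[2]]]),
               ci_low = ci[1], ci_high = ci[2],
               p_raw = p_raw, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- benjamini_hochberg(res$p_raw)
  res$method <- "percentile-bootstrap medians"
  class(res) <- c("comparison_result", "data.frame")
  res
}

# median of each row of a numeric matrix, vectorised over rows
row_medians <- function(m) {
  n <- ncol(m)
  srt <- matrix(m[order(row(m), m)], nrow = nrow(m), byrow = TRUE)
  if (n %% 2L == 1L) srt[, (n + 1L) %/% 2L]
  else (srt[, n %/% 2L] + srt[, n %/% 2L + 1L]) / 2
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: with the m raw p-values sorted
#' ascending, `p_adj_(i) = min_(j >= i) m * p_(j) / j`, capped at 1 and
#' mapped back to the input order. Monotone; a singleton is returned
#' unchanged.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    sg_stop("p-values must lie in [0, 1]", "sg_invalid_p")
  }
  m <- length(p)
  o <- order(p)
  scaled <- m * p[o] / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference with the pooled standard deviation
#' `sqrt(((nx-1) sx^2 + (ny-1) sy^2) / (nx + ny - 2))`. A zero pooled sd
#' with unequal means yields `Inf`/`-Inf` with a QC flag (degenerate,
#' infinite effect); with equal means it yields 0.
#'
#' @param x,y numeric vectors (each n >= 2).
#' @return Cohen's d (x relative to y).
#' @examples
#' cohens_d(c(0, 2), c(-1, 1)) # 0.7071
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) sg_stop("each group needs at least 2 values",
                                "sg_empty_group")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  dm <- mean(x) - mean(y)
  if (sp == 0) {
    if (dm == 0) return(0)
    sg_qc_flag("zero pooled sd with unequal means: infinite effect size",
               what = "infinite_effect_size")
    return(sign(dm) * Inf)
  }
  dm / sp
}

#' Compact letter display from pairwise comparisons
#'
#' Assigns significance letters to groups so that two groups share a letter
#' if and only if they were not found significantly different (insert-and-
#' absorb algorithm). Used to annotate per-panel treatment plots.
#'
#' @param comparisons a `comparison_result` data frame with a `p_adj` (or
#'   `p_raw`) column, e.g. from [bootstrap_median_pairs()].
#' @param alpha significance threshold (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
significance_letters <- function(comparisons, alpha = 0.05) {
  stopifnot(is.data.frame(comparisons))
  pcol <- if ("p_adj" %in% names(comparisons)) "p_adj" else "p_raw"
  grps <- unique(c(comparisons$group1, comparisons$group2))
  sets <- list(grps)  # each set = groups allowed to share one letter
  sig <- comparisons[comparisons[[pcol]] < alpha, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      a <- sig$group1[i]; b <- sig$group2[i]
      new_sets <- list()
      for (s in sets) {
        if (all(c(a, b) %in% s)) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else new_sets <- c(new_sets, list(s))
      }
      # absorb: drop sets contained in another
      keep <- vapply(seq_along(new_sets), function(k) {
        !any(vapply(seq_along(new_sets), function(j) {
          j != k && all(new_sets[[k]] %in% new_sets[[j]]) &&
            (length(new_sets[[j]]) > length(new_sets[[k]]) || j < k)
        }, logical(1)))
      }, logical(1))
      sets <- new_sets[keep]
    }
  }
  out <- stats::setNames(rep("", length(grps)), grps)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  # a group significantly different from every other still needs a letter
  empty <- which(out == "")
  if (length(empty)) {
    out[empty] <- letters[length(sets) + seq_along(empty)]
  }
  out
}
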