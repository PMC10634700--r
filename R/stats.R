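#' Mann-Whitney U tests on selected features
#'
#' Two-sided rank-sum test per feature on raw (untransformed) feature
#' values between two region groups. The exact null distribution is used
#' for combined sample sizes up to 20 without ties; otherwise the normal
#' approximation with tie correction (and continuity correction) applies.
#' The test is rank-based, so running it on raw rather than log/min-max
#' transformed values is provably immaterial: both transforms are strictly
#' monotone.
#'
#' @param fm Feature matrix (regions x features).
#' @param groups Group label per row of `fm` (exactly two groups).
#' @param features Feature column names to test (default: all).
#' @return Data frame with `feature`, `p`, and per-group medians.
#' @export
mann_whitney_feature_test <- function(fm, groups, features = colnames(fm)) {
  stopifnot(length(groups) == nrow(fm))
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (!all(table(groups) >= 1)) stop("both groups need at least one region")
  missing <- setdiff(features, colnames(fm))
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
  a <- groups == lev[1]
  res <- lapply(features, function(f) {
    x <- fm[a, f]; y <- fm[!a, f]
    exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
    p <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = exact, correct = TRUE)$p.value
    data.frame(feature = f, p = p,
               median_1 = stats::median(x), median_2 = stats::median(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[3:4] <- paste0("median_", lev)
  out
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false-discovery-rate correction applied per analysis family
#' (one model's top-feature set). Adjusted values are monotone in the
#' sorted order, never below the raw p, and capped at 1.
#'
#' @param p Raw p-values in [0, 1].
#' @param alpha Significance level for the flags.
#' @return Data frame with `p`, `q` and logical `significant` (q < alpha),
#'   in the input order.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = q < alpha)
}
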