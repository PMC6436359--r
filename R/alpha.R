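#' Cronbach's alpha internal consistency
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of the row sums)`
#' for a patients x items score matrix with `k` items. The variance
#' convention (n or n-1 denominator) cancels in the ratio as long as it is
#' applied uniformly; sample variances (`n-1`) are used throughout. Negative
#' values can occur in small samples and are reported unclamped with a
#' warning.
#'
#' @param x numeric matrix or data frame, patients in rows, items in columns;
#'   at least 2 patients and 2 items.
#' @return the alpha coefficient (<= 1).
#' @examples
#' set.seed(1)
#' truth <- rnorm(20)
#' x <- sapply(1:4, function(i) truth + rnorm(20, sd = 0.3))
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_validation("item matrix must be numeric")
  k <- ncol(x)
  n <- nrow(x)
  if (k < 2L) stop_validation("Cronbach's alpha needs at least 2 items")
  if (n < 2L) stop_validation("Cronbach's alpha needs at least 2 patients")
  if (anyNA(x)) stop_validation("item matrix contains missing values")
  v_total <- stats::var(rowSums(x))
  if (!is.finite(v_total) || v_total <= 0)
    stop_validation("total score has zero variance; alpha is undefined")
  v_items <- sum(apply(x, 2L, stats::var))
  alpha <- k / (k - 1) * (1 - v_items / v_total)
  if (alpha < 0)
    warning("negative Cronbach's alpha (", signif(alpha, 4),
            "): items are not positively interrelated in this sample")
  alpha
}

#' Internal consistency of the instrument and its domains
#'
#' Alpha of the full 12-item score matrix and of the three phase domains
#' (oral, pharyngeal, penetration/aspiration) separately.
#'
#' @param records list of `scas_record` objects (>= 2).
#' @param items item table.
#' @return list with `alpha_total` and `alpha_by_domain` (named list).
#' @export
internal_consistency <- function(records, items = scas_items()) {
  m <- item_score_matrix(records, items)
  domains <- split(items$item_id, items$phase)
  list(
    alpha_total = cronbach_alpha(m),
    alpha_by_domain = lapply(
      domains[c("oral", "pharyngeal", "penetration_aspiration")],
      function(ids) cronbach_alpha(m[, ids, drop = FALSE]))
  )
}
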