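#' Weighted kappa for ordinal agreement
#'
#' Chance-corrected agreement between two raters on the same k-level ordinal
#' scale, penalizing disagreements by their distance:
#' `kappa_w = 1 - sum(w * o) / sum(w * e)`, where `o` are observed cell
#' proportions, `e = row margin x column margin` the chance-expected ones,
#' and the disagreement weights are `w_ij = |i - j| / (k - 1)` (linear,
#' default) or its square (quadratic). For k = 2 both weightings reduce to
#' unweighted Cohen's kappa.
#'
#' Standard errors follow the Fleiss–Cohen–Everitt large-sample formulas:
#' `se0` under the null of chance agreement (used for the p-value) and `se`
#' around the point estimate (used for confidence statements and
#' parameter-recovery checks).
#'
#' A table with all its mass in one cell has zero expected disagreement;
#' kappa is then defined as 1 and a degenerate-table warning is issued.
#'
#' @param tab square contingency table of counts (rater A in rows, rater B
#'   in columns, categories in ordinal order), as from [table()].
#' @param weighting `"linear"` or `"quadratic"`.
#' @return list with `kappa`, `weighting`, `se`, `se0`, `z`, `p` (two-sided,
#'   against kappa = 0), and `n`.
#' @examples
#' tab <- table(factor(c(1, 1, 2, 3, 3), levels = 1:3),
#'              factor(c(1, 2, 2, 3, 2), levels = 1:3))
#' weighted_kappa(tab)$kappa
#' @export
weighted_kappa <- function(tab, weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab))
    stop_validation("contingency table must be square (got %d x %d)",
                    nrow(tab), ncol(tab))
  k <- nrow(tab)
  if (k < 2L) stop_validation("need at least 2 categories")
  if (any(tab < 0)) stop_validation("negative counts")
  N <- sum(tab)
  if (N < 1) stop_validation("empty contingency table")

  d <- abs(row(tab) - col(tab)) / (k - 1)
  w <- if (weighting == "linear") d else d^2   # disagreement weights
  p <- tab / N
  pr <- rowSums(p)
  pc <- colSums(p)
  e <- outer(pr, pc)
  Ed <- sum(w * e)
  if (Ed == 0) {
    warning("degenerate table: no expected disagreement; kappa defined as 1")
    return(list(kappa = 1, weighting = weighting, se = 0, se0 = NA_real_,
                z = NA_real_, p = NA_real_, n = N))
  }
  kap <- 1 - sum(w * p) / Ed

  # large-sample variances, in agreement-weight form
  W <- 1 - w
  po <- sum(W * p)
  pe <- sum(W * e)
  wr <- as.vector(W %*% pc)        # E[W | row i]
  wc <- as.vector(pr %*% W)        # E[W | col j]
  var0 <- (sum(e * (W - outer(wr, wc, `+`))^2) - pe^2) / (N * (1 - pe)^2)
  se0 <- sqrt(max(var0, 0))
  varh <- (sum(p * (W * (1 - pe) - outer(wr, wc, `+`) * (1 - po))^2) -
             (po * pe - 2 * pe + po)^2) / (N * (1 - pe)^4)
  se <- sqrt(max(varh, 0))
  z <- if (se0 > 0) kap / se0 else NA_real_
  list(kappa = kap, weighting = weighting, se = se, se0 = se0, z = z,
       p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)), n = N)
}

#' Unweighted Cohen's kappa
#'
#' Identity agreement weights (every disagreement counts fully); the k = 2
#' special case of [weighted_kappa()], provided for per-level analyses.
#'
#' @inheritParams weighted_kappa
#' @return as [weighted_kappa()].
#' @export
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab))
    stop_validation("contingency table must be square")
  if (nrow(tab) == 2L) {
    out <- weighted_kappa(tab, "linear")  # weights coincide for k = 2
    out$weighting <- "unweighted"
    return(out)
  }
  # general k: run weighted_kappa with 0/1 disagreement weights via a
  # collapse-free reimplementation of the same formulas
  k <- nrow(tab)
  N <- sum(tab)
  if (N < 1) stop_validation("empty contingency table")
  p <- tab / N
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  if (pe == 1) {
    warning("degenerate table: no expected disagreement; kappa defined as 1")
    return(list(kappa = 1, weighting = "unweighted", se = 0, se0 = NA_real_,
                z = NA_real_, p = NA_real_, n = N))
  }
  kap <- (po - pe) / (1 - pe)
  W <- diag(k)
  wr <- as.vector(W %*% pc)
  wc <- as.vector(pr %*% W)
  e <- outer(pr, pc)
  var0 <- (sum(e * (W - outer(wr, wc, `+`))^2) - pe^2) / (N * (1 - pe)^2)
  varh <- (sum(p * (W * (1 - pe) - outer(wr, wc, `+`) * (1 - po))^2) -
             (po * pe - 2 * pe + po)^2) / (N * (1 - pe)^4)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kap / se0 else NA_real_
  list(kappa = kap, weighting = "unweighted", se = sqrt(max(varh, 0)),
       se0 = se0, z = z,
       p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)), n = N)
}

#' Per-level (one-vs-rest) kappa
#'
#' Agreement on recognizing one particular severity level: both raters'
#' labels are binarized to "this level" vs "any other level" and unweighted
#' Cohen's kappa is computed on the resulting 2 x 2 table.
#'
#' @param scas_levels,vfss_levels paired label vectors on the same ordinal
#'   scale.
#' @param level the severity level analysed.
#' @param levels the full ordinal label set.
#' @return as [weighted_kappa()], plus the binarized `table`.
#' @export
per_level_kappa <- function(scas_levels, vfss_levels, level,
                            levels = scaspd::vfss_levels()) {
  a <- as.character(scas_levels)
  b <- as.character(vfss_levels)
  if (length(a) != length(b))
    stop_validation("paired label vectors differ in length")
  bad <- setdiff(unique(c(a, b)), levels)
  if (length(bad))
    stop_validation("label(s) not on the ordinal scale: %s",
                    paste(bad, collapse = ", "))
  if (!level %in% levels)
    stop_validation("unknown level '%s'", level)
  if (!level %in% c(a, b))
    stop_validation("level '%s' absent from both raters; kappa undefined",
                    level)
  f <- function(x) factor(ifelse(x == level, level, "other"),
                          levels = c(level, "other"))
  tab <- table(f(a), f(b))
  c(cohen_kappa(tab), list(table = tab))
}
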