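#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC curve of a continuous (or integer) score against
#' a binary truth, with the positivity convention "positive if score >
#' threshold" — so a reported cutoff is the largest score still classified
#' negative, matching the band phrasing of the severity schemes (e.g.
#' "functional >3 <= 19" makes 19 the last negative score of the
#' any-dysphagia task). Thresholds run through all distinct observed scores
#' plus -Inf; the trapezoidal area equals the Mann–Whitney concordance
#' probability with ties counted 1/2.
#'
#' @param scores numeric vector of index-test scores.
#' @param truth binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return object of class `scas_roc`: list with `thresholds` (decreasing,
#'   curve runs from (0,0) to (1,1)), `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, truth) {
  ct <- check_roc_input(scores, truth)
  scores <- ct$scores
  truth <- ct$truth
  ts <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- scores[truth == 1L]
  neg <- scores[truth == 0L]
  tpr <- vapply(ts, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(ts, function(t) mean(neg > t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = ts, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "scas_roc")
}

check_roc_input <- function(scores, truth) {
  scores <- as.numeric(scores)
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    stop_validation("scores and truth differ in length")
  if (anyNA(scores) || anyNA(truth))
    stop_validation("missing values in ROC input")
  if (!all(truth %in% c(0L, 1L)))
    stop_validation("truth must be binary (0/1)")
  if (length(unique(truth)) < 2L)
    stop_validation("both classes must be present to build a ROC curve")
  list(scores = scores, truth = truth)
}

#' @export
print.scas_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Confidence interval for the AUC
#'
#' Either the DeLong variance of the placement values ("structural
#' components") with a normal interval clipped to \[0, 1\], or a seeded
#' percentile bootstrap resampling whole (score, truth) pairs. Bootstrap
#' resamples that lose one class are redrawn; persistent degeneracy (more
#' redraws than `10 * n_boot`) raises an error.
#'
#' @inheritParams roc_curve
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level confidence level.
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed, required for the bootstrap.
#' @return list with `low`, `high`, `method`, and for DeLong the variance
#'   `var`.
#' @export
auc_ci <- function(scores, truth, method = c("delong", "bootstrap"),
                   conf_level = 0.95, n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  ct <- check_roc_input(scores, truth)
  scores <- ct$scores
  truth <- ct$truth
  a2 <- (1 - conf_level) / 2
  if (method == "delong") {
    d <- delong_components(scores, truth)
    z <- stats::qnorm(1 - a2)
    half <- z * sqrt(d$var)
    return(list(low = max(0, d$auc - half), high = min(1, d$auc + half),
                method = "delong", var = d$var))
  }
  if (n_boot < 100) stop_validation("bootstrap needs n_boot >= 100")
  if (is.null(seed)) stop_validation("bootstrap CI requires a seed")
  n <- length(scores)
  boot <- numeric(n_boot)
  with_seed(seed, {
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(truth[idx])) == 2L) break
        redraws <- redraws + 1L
        if (redraws > 10L * n_boot)
          stop_validation("bootstrap degenerate: resamples keep losing a class")
      }
      boot[b] <- roc_curve(scores[idx], truth[idx])$auc
    }
  })
  q <- stats::quantile(boot, c(a2, 1 - a2), names = FALSE)
  list(low = q[1], high = q[2], method = "bootstrap", n_boot = n_boot)
}

# Placement values of the Mann-Whitney kernel and the DeLong variance.
delong_components <- function(scores, truth) {
  x <- scores[truth == 1L]
  y <- scores[truth == 0L]
  m <- length(x)
  n <- length(y)
  M <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(M)
  v01 <- colMeans(M)
  auc <- mean(M)
  var <- (if (m > 1) stats::var(v10) / m else 0) +
         (if (n > 1) stats::var(v01) / n else 0)
  list(auc = auc, var = var, v10 = v10, v01 = v01)
}

#' Youden-optimal cutoff
#'
#' Searches all distinct observed scores as candidate cutoffs (positive if
#' score > cutoff) and maximizes Youden's J = sensitivity + specificity - 1.
#' Ties are broken in favour of higher sensitivity (a screening instrument
#' should not miss dysphagia), then of the lower cutoff. The reported cutoff
#' is therefore the largest score classified negative.
#'
#' @inheritParams roc_curve
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @examples
#' optimal_cutoff(c(1, 2, 3, 10, 12), c(0, 0, 0, 1, 1))
#' @export
optimal_cutoff <- function(scores, truth) {
  ct <- check_roc_input(scores, truth)
  scores <- ct$scores
  truth <- ct$truth
  pos <- scores[truth == 1L]
  neg <- scores[truth == 0L]
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(c) mean(pos > c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg <= c), numeric(1))
  J <- sens + spec - 1
  # mathematically tied J values can differ by machine epsilon; treat
  # near-equal as tied before applying the preference order
  best <- which(J > max(J) - 1e-9)
  best <- best[sens[best] > max(sens[best]) - 1e-9]
  best <- best[1L]  # candidates are sorted: first tie is the lowest cutoff
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden = J[best])
}

#' Confusion-matrix performance at a fixed cutoff
#'
#' @inheritParams roc_curve
#' @param cutoff threshold; positive if score > cutoff.
#' @return list with `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`.
#' @export
performance_at_cutoff <- function(scores, truth, cutoff) {
  ct <- check_roc_input(scores, truth)
  pred <- as.integer(ct$scores > cutoff)
  tp <- sum(pred == 1L & ct$truth == 1L)
  fn <- sum(pred == 0L & ct$truth == 1L)
  tn <- sum(pred == 0L & ct$truth == 0L)
  fp <- sum(pred == 1L & ct$truth == 0L)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
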