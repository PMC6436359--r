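# Independent brute-force oracles used to check the closed-form
# implementations. Each one recomputes its statistic from first principles
# (explicit loops, textbook ANOVA fits, covariance matrices) and never calls
# the package's own code path.

# Weighted kappa by explicit double sums over all cells.
oracle_weighted_kappa <- function(tab, weighting = "linear") {
  k <- nrow(tab)
  N <- sum(tab)
  pr <- rowSums(tab) / N
  pc <- colSums(tab) / N
  num <- den <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      d <- abs(i - j) / (k - 1)
      w <- if (weighting == "linear") d else d^2
      num <- num + w * tab[i, j] / N
      den <- den + w * pr[i] * pc[j]
    }
  }
  1 - num / den
}

# Cronbach's alpha from the full covariance matrix.
oracle_alpha <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# ICC mean squares from an explicit two-way ANOVA fit.
oracle_icc_ms <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- stats::anova(stats::lm(y ~ subj + rater, d))[["Mean Sq"]]
  list(MSR = ms[1], MSC = ms[2], MSE = ms[3],
       MSW = (ms[2] * (k - 1) + ms[3] * (n - 1) * (k - 1)) / (n * (k - 1)))
}

oracle_icc <- function(x, model = "twoway_random_absolute", unit = "single") {
  n <- nrow(x)
  k <- ncol(x)
  ms <- oracle_icc_ms(x)
  with(ms, switch(paste(model, unit),
    "twoway_random_absolute single" =
      (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE)),
    "twoway_random_absolute average" =
      (MSR - MSE) / (MSR + (MSC - MSE) / n),
    "twoway_mixed_consistency single" =
      (MSR - MSE) / (MSR + (k - 1) * MSE),
    "twoway_mixed_consistency average" = (MSR - MSE) / MSR,
    "oneway single" = (MSR - MSW) / (MSR + (k - 1) * MSW),
    "oneway average" = (MSR - MSW) / MSR))
}

# AUC as the Mann-Whitney concordance probability by pair enumeration.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# DeLong variance from naive placement-value loops.
oracle_delong_var <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  v10 <- sapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)))
  v01 <- sapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)))
  stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
}

# Youden-optimal cutoff by exhaustive search (positive if score > cutoff).
oracle_cutoff <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  best <- NULL
  for (c in sort(unique(scores))) {
    se <- mean(pos > c)
    sp <- mean(neg <= c)
    j <- se + sp - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && se > best$se + 1e-12))
      best <- list(cutoff = c, se = se, sp = sp, j = j)
  }
  best
}

# 2x2 unweighted kappa closed form.
oracle_kappa_2x2 <- function(a, b, c, d) {
  2 * (a * d - b * c) / ((a + b) * (b + d) + (a + c) * (c + d))
}

# Random small instances under the calling test's RNG stream.
random_kappa_table <- function() {
  k <- sample(2:5, 1)
  tab <- matrix(stats::rpois(k * k, lambda = sample(1:8, 1)) +
                  diag(sample(0:5, 1), k), k, k)
  # guarantee mass off the diagonal in both directions (non-degenerate)
  tab[1, 2] <- tab[1, 2] + 1L
  tab[2, 1] <- tab[2, 1] + 1L
  tab
}

all_ones_grid <- function() {
  matrix(1L, 12, 3,
         dimnames = list(scas_items()$item_id,
                         c("liquid", "paste", "solid")))
}

zero_grid <- function() {
  matrix(0L, 12, 3,
         dimnames = list(scas_items()$item_id,
                         c("liquid", "paste", "solid")))
}
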