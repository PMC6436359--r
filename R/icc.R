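#' Intraclass correlation coefficient from variance components
#'
#' Computes the ICC of a patients x raters table from the two-way ANOVA
#' mean squares, in the three common forms:
#'
#' * `"twoway_random_absolute"` — two-way random effects, absolute
#'   agreement, ICC(2,1)/ICC(2,k). The default: raters are a random sample
#'   and systematic rater differences count as disagreement. This is the
#'   usual SPSS choice for method-comparison studies and the form used when
#'   comparing an index test's severity rating against a gold standard.
#' * `"twoway_mixed_consistency"` — two-way mixed effects, consistency,
#'   ICC(3,1)/ICC(3,k); rater offsets are ignored.
#' * `"oneway"` — one-way random effects, ICC(1,1)/ICC(1,k).
#'
#' Confidence intervals and the p-value against ICC = 0 come from the exact
#' F distributions of the mean-square ratios (Shrout & Fleiss / McGraw &
#' Wong); the absolute-agreement single-measures interval uses the
#' Satterthwaite approximation for its denominator degrees of freedom.
#'
#' @param ratings numeric matrix/data frame, patients in rows, raters in
#'   columns (>= 2 each). For severity agreement the ordinal labels are
#'   encoded as ranks first (see [severity_rank()]).
#' @param model ICC model, see above.
#' @param unit `"single"` (default) for the reliability of one rating,
#'   `"average"` for the mean of the k ratings.
#' @param conf_level confidence level of the interval.
#' @return list with elements `icc`, `ci` (length-2), `p`, `model`, `unit`,
#'   and the mean squares `ms` used.
#' @examples
#' r <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 2, 4, 4, 5, 7))
#' icc(r)$icc
#' @export
icc <- function(ratings,
                model = c("twoway_random_absolute", "twoway_mixed_consistency",
                          "oneway"),
                unit = c("single", "average"),
                conf_level = 0.95) {
  model <- match.arg(model)
  unit <- match.arg(unit)
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stop_validation("ratings must be numeric")
  if (anyNA(x)) stop_validation("ratings contain missing values")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L)
    stop_validation("ICC needs at least 2 patients and 2 raters")
  if (stats::var(as.vector(x)) == 0)
    stop_validation("all ratings identical; ICC is undefined")

  grand <- mean(x)
  rm <- rowMeans(x)
  cm <- colMeans(x)
  SSR <- k * sum((rm - grand)^2)              # between patients
  SSC <- n * sum((cm - grand)^2)              # between raters
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC                      # residual (two-way)
  SSW <- SST - SSR                            # within patients (one-way)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  MSW <- SSW / (n * (k - 1))
  a2 <- (1 - conf_level) / 2

  if (model == "oneway") {
    Fv <- MSR / MSW
    df1 <- n - 1
    df2 <- n * (k - 1)
    FL <- Fv / stats::qf(1 - a2, df1, df2)
    FU <- Fv * stats::qf(1 - a2, df2, df1)
    if (unit == "single") {
      est <- (MSR - MSW) / (MSR + (k - 1) * MSW)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    } else {
      est <- (MSR - MSW) / MSR
      ci <- c(1 - 1 / FL, 1 - 1 / FU)
    }
  } else if (model == "twoway_mixed_consistency") {
    Fv <- MSR / MSE
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    FL <- Fv / stats::qf(1 - a2, df1, df2)
    FU <- Fv * stats::qf(1 - a2, df2, df1)
    if (unit == "single") {
      est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    } else {
      est <- (MSR - MSE) / MSR
      ci <- c(1 - 1 / FL, 1 - 1 / FU)
    }
  } else { # twoway_random_absolute
    Fv <- MSR / MSE
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    single <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
    # Satterthwaite df for the ICC(2,1) interval
    Fj <- MSC / MSE
    vn <- (k - 1) * (n - 1) *
      (k * single * Fj + n * (1 + (k - 1) * single) - k * single)^2
    vd <- (n - 1) * k^2 * single^2 * Fj^2 +
      (n * (1 + (k - 1) * single) - k * single)^2
    v <- vn / vd
    FLs <- stats::qf(1 - a2, n - 1, v)
    FUs <- stats::qf(1 - a2, v, n - 1)
    lower <- n * (MSR - FLs * MSE) /
      (FLs * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FUs * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FUs * MSR)
    if (unit == "single") {
      est <- single
      ci <- c(lower, upper)
    } else {
      est <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
      sb <- function(r) r * k / (1 + (k - 1) * r)  # Spearman-Brown step-up
      ci <- c(sb(lower), sb(upper))
    }
  }
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(icc = est, ci = sort(pmin(pmax(ci, -1), 1)), p = unname(p),
       model = model, unit = unit,
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW))
}
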