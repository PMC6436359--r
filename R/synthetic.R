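#' Specify a synthetic paired cohort
#'
#' The generator draws a latent ("true") severity level per patient, builds
#' a SCAS-PD record whose total score falls inside the corresponding band,
#' and draws the VFSS label from a confusion kernel applied to the true
#' level — emulating a validation cohort with a controlled severity mix and
#' index-test/gold-standard concordance.
#'
#' The default severity distribution follows the reported cohort of 31
#' patients with clinical severity counts 7/5/6/6/4 (normal through severe),
#' renormalized to sum to one. When no explicit kernel is given it is built
#' from the scalar `concordance` c as `K = c * I + (1 - c) * U`, where every
#' row of `U` equals `severity_probs`; the implied population linear (or
#' quadratic) weighted kappa between the index test and the gold standard is
#' then exactly c, which makes parameter-recovery checks analytic.
#'
#' @param n cohort size (>= 2).
#' @param severity_probs probability vector over the five severity levels.
#' @param concordance scalar in \[0, 1\]; ignored when `confusion_kernel`
#'   is supplied.
#' @param confusion_kernel optional 5 x 5 row-stochastic matrix,
#'   `P(VFSS level | true level)`.
#' @param coherent if `TRUE` (default), profile sampling favours grids where
#'   penetration/aspiration signs only occur in offerings that also show a
#'   pharyngeal sign.
#' @param seed integer seed; the generated cohort is a pure function of the
#'   spec (including this seed).
#' @return a `scas_cohort_spec` list.
#' @export
cohort_spec <- function(n = 31,
                        severity_probs = c(normal = 7, functional = 5,
                                           mild = 6, moderate = 6,
                                           severe = 4) / 28,
                        concordance = 0.8,
                        confusion_kernel = NULL,
                        coherent = TRUE,
                        seed = 1L) {
  if (n < 2) stop_validation("cohort size must be >= 2")
  severity_probs <- as.numeric(severity_probs)
  if (length(severity_probs) != 5L || any(severity_probs < 0) ||
      abs(sum(severity_probs) - 1) > 1e-8)
    stop_validation("severity_probs must be 5 non-negative values summing to 1")
  if (is.null(confusion_kernel)) {
    if (is.na(concordance) || concordance < 0 || concordance > 1)
      stop_validation("concordance must lie in [0, 1]")
    confusion_kernel <- concordance * diag(5) +
      (1 - concordance) * matrix(severity_probs, 5, 5, byrow = TRUE)
  } else {
    confusion_kernel <- as.matrix(confusion_kernel)
    if (!all(dim(confusion_kernel) == c(5L, 5L)) ||
        any(confusion_kernel < 0) ||
        any(abs(rowSums(confusion_kernel) - 1) > 1e-8))
      stop_validation("confusion_kernel must be 5 x 5 row-stochastic")
    concordance <- NA_real_
  }
  dimnames(confusion_kernel) <- list(vfss_levels(), vfss_levels())
  names(severity_probs) <- vfss_levels()
  structure(list(n = as.integer(n), severity_probs = severity_probs,
                 concordance = concordance,
                 confusion_kernel = confusion_kernel,
                 coherent = isTRUE(coherent), seed = as.integer(seed)),
            class = "scas_cohort_spec")
}

# An offering is coherent when any PA sign in it co-occurs with at least one
# pharyngeal sign in the same offering.
is_coherent_grid <- function(grid, items) {
  pa <- items$item_id[items$phase == "penetration_aspiration"]
  ph <- items$item_id[items$phase == "pharyngeal"]
  all(colSums(grid[pa, , drop = FALSE]) == 0 |
        colSums(grid[ph, , drop = FALSE]) > 0)
}

# Deterministic exact-total grid: walk the 36 cells in decreasing weight
# order (pharyngeal before PA within ties, for coherence) and set a flag
# whenever it still fits. With cell weights {1 x 6, 2 x 9, 10 x 9, 15 x 6,
# 20 x 3, 30 x 3} this greedy walk hits every integer total in 0..354
# exactly: whenever a large denomination runs out the remainder is at most
# 24, which the 2- and 1-point cells cover contiguously.
greedy_grid <- function(target, items = scas_items()) {
  stopifnot(target == round(target), target >= 0, target <= sum(3 * items$weight))
  offs <- offering_ids()
  cells <- expand.grid(item = items$item_id, offering = offs,
                       stringsAsFactors = FALSE)
  cells$weight <- items$weight[match(cells$item, items$item_id)]
  phase_rank <- c(pharyngeal = 0L, penetration_aspiration = 1L, oral = 2L)
  cells$phase <- items$phase[match(cells$item, items$item_id)]
  ord <- order(-cells$weight, phase_rank[cells$phase])
  grid <- matrix(0L, nrow(items), 3L, dimnames = list(items$item_id, offs))
  acc <- 0
  for (r in ord) {
    w <- cells$weight[r]
    if (acc + w <= target) {
      grid[cells$item[r], cells$offering[r]] <- 1L
      acc <- acc + w
    }
  }
  stopifnot(acc == target)
  grid
}

#' Sample an assessment record inside a target severity band
#'
#' Rejection sampling: a target total is drawn uniformly from the band's
#' attainable integer scores, each of the 36 flags is drawn Bernoulli with
#' probability target/354 (so the expected total equals the target), and the
#' grid is kept if its score classifies into the band (and, when `coherent`,
#' respects the pharyngeal/PA coherence preference). After `max_attempts`
#' rejections a deterministic greedy construction of the band's median
#' attainable total guarantees termination; the fallback may relax the
#' coherence preference.
#'
#' @param target_band severity label of `scheme`.
#' @param scheme a [scas_scheme()].
#' @param coherent see [cohort_spec()].
#' @param patient_id identifier of the returned record.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param items item table.
#' @param max_attempts rejection budget before the deterministic fallback.
#' @return a `scas_record` whose total classifies into `target_band`.
#' @export
sample_profile <- function(target_band, scheme = scas_scheme("preliminary"),
                           coherent = TRUE, patient_id = "synthetic",
                           seed = NULL, items = scas_items(),
                           max_attempts = 1000L) {
  if (!is.null(seed)) {
    return(with_seed(seed, sample_profile(target_band, scheme, coherent,
                                          patient_id, NULL, items,
                                          max_attempts)))
  }
  i <- match(target_band, scheme$levels)
  if (is.na(i)) stop_validation("band '%s' not in scheme '%s'",
                                target_band, scheme$name)
  max_total <- sum(3 * items$weight)
  lo <- scheme$lower[i]
  hi <- min(scheme$upper[i], max_total)
  interior <- seq.int(max(floor(lo) + 1, 0), floor(hi))
  if (!length(interior))
    stop_validation("band '%s' contains no attainable integer score",
                    target_band)
  offs <- offering_ids()
  for (a in seq_len(max_attempts)) {
    target <- if (length(interior) == 1L) interior else sample(interior, 1L)
    grid <- matrix(stats::rbinom(3L * nrow(items), 1L, target / max_total),
                   nrow(items), 3L, dimnames = list(items$item_id, offs))
    total <- sum(items$weight * rowSums(grid))
    if (total > lo && total <= scheme$upper[i] &&
        (!coherent || is_coherent_grid(grid, items)))
      return(assessment_record(patient_id, grid, items = items))
  }
  target <- interior[ceiling(length(interior) / 2)]
  assessment_record(patient_id, greedy_grid(target, items), items = items)
}

#' Generate a synthetic paired cohort
#'
#' Draws true severity levels from `spec$severity_probs`, builds one
#' SCAS-PD record per patient inside the band of its true level (so the
#' index test classifies every patient at the true level by construction)
#' and draws the VFSS label from the confusion kernel's row of the true
#' level. The result is a pure function of the spec: the same spec gives a
#' bit-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @param scheme scheme whose bands the profiles are sampled in; the default
#'   five-band preliminary scheme matches the five VFSS levels one-to-one.
#'   Under a scheme with fewer bands, deeper levels collapse into its last
#'   band.
#' @param items item table.
#' @return object of class `scas_cohort_sim`: list with `cohort` (a
#'   [paired_cohort()]), `true_levels` and `spec`.
#' @examples
#' sim <- generate_cohort(cohort_spec(n = 10, concordance = 1, seed = 7))
#' table(classify_severity(sim$cohort$totals, scas_scheme("preliminary")),
#'       sim$cohort$vfss)
#' @export
generate_cohort <- function(spec, scheme = scas_scheme("preliminary"),
                            items = scas_items()) {
  stopifnot(inherits(spec, "scas_cohort_spec"))
  lv <- vfss_levels()
  with_seed(spec$seed, {
    true <- sample(lv, spec$n, replace = TRUE, prob = spec$severity_probs)
    band <- scheme$levels[pmin(severity_rank(true, lv),
                               length(scheme$levels) - 1L) + 1L]
    ids <- sprintf("P%04d", seq_len(spec$n))
    records <- vector("list", spec$n)
    vf <- character(spec$n)
    for (i in seq_len(spec$n)) {
      records[[i]] <- sample_profile(band[i], scheme, spec$coherent,
                                     patient_id = ids[i], items = items)
      vf[i] <- sample(lv, 1L, prob = spec$confusion_kernel[true[i], ])
    }
    structure(list(cohort = paired_cohort(ids, records = records, vfss = vf,
                                          items = items),
                   true_levels = true, spec = spec),
              class = "scas_cohort_sim")
  })
}

#' @export
print.scas_cohort_sim <- function(x, ...) {
  cat(sprintf("Synthetic paired cohort (n = %d, seed %d%s)\n",
              x$spec$n, x$spec$seed,
              if (!is.na(x$spec$concordance))
                sprintf(", concordance %.2f", x$spec$concordance) else ""))
  print(x$cohort)
  invisible(x)
}
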