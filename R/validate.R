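#' Assemble a paired index-test / gold-standard cohort
#'
#' One row per patient: the SCAS-PD assessment (a full record, or a
#' precomputed total score) paired with the ordinal VFSS severity label.
#'
#' @param patient_ids unique identifiers, length n >= 2.
#' @param records optional list of `scas_record` objects.
#' @param totals optional numeric totals; derived from `records` when absent.
#' @param vfss VFSS severity labels, one of [vfss_levels()].
#' @param items item table used to score `records`.
#' @return object of class `scas_cohort`.
#' @export
paired_cohort <- function(patient_ids, records = NULL, totals = NULL, vfss,
                          items = scas_items()) {
  patient_ids <- as.character(patient_ids)
  n <- length(patient_ids)
  if (n < 2L) stop_validation("a paired cohort needs at least 2 patients")
  if (anyDuplicated(patient_ids))
    stop_validation("patient identifiers must be unique")
  vfss <- as.character(vfss)
  if (length(vfss) != n)
    stop_validation("vfss labels and patient_ids differ in length")
  bad <- setdiff(unique(vfss), vfss_levels())
  if (length(bad))
    stop_validation("unknown VFSS level(s): %s", paste(bad, collapse = ", "))
  if (is.null(records) && is.null(totals))
    stop_validation("provide records or totals")
  if (!is.null(records)) {
    if (length(records) != n)
      stop_validation("records and patient_ids differ in length")
    derived <- vapply(records, function(r) score_assessment(r, items)$total,
                      numeric(1))
    if (is.null(totals)) totals <- derived
    else if (!isTRUE(all.equal(as.numeric(totals), derived)))
      stop_validation("supplied totals disagree with scored records")
  }
  totals <- as.numeric(totals)
  if (length(totals) != n)
    stop_validation("totals and patient_ids differ in length")
  if (any(totals < 0 | totals > 354))
    stop_validation("total scores must lie in [0, 354]")
  structure(list(patient_ids = patient_ids, records = records,
                 totals = totals, vfss = vfss, n = n),
            class = "scas_cohort")
}

#' @export
print.scas_cohort <- function(x, ...) {
  cat(sprintf("Paired cohort: %d patients%s, VFSS levels: %s\n", x$n,
              if (is.null(x$records)) " (totals only)" else "",
              paste(names(table(factor(x$vfss, vfss_levels()))),
                    table(factor(x$vfss, vfss_levels())),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Configuration of a validation run
#'
#' @param kappa_weighting `"linear"` (default) or `"quadratic"`.
#' @param icc_model,icc_unit see [icc()].
#' @param ci_method AUC interval method, `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param conf_level confidence level used throughout.
#' @param seed integer seed; required when any stochastic method (bootstrap)
#'   is selected.
#' @return a `scas_config` list.
#' @export
validation_config <- function(kappa_weighting = c("linear", "quadratic"),
                              icc_model = c("twoway_random_absolute",
                                            "twoway_mixed_consistency",
                                            "oneway"),
                              icc_unit = c("single", "average"),
                              ci_method = c("delong", "bootstrap"),
                              n_boot = 2000, conf_level = 0.95, seed = NULL) {
  ci_method <- match.arg(ci_method)
  if (ci_method == "bootstrap" && is.null(seed))
    stop_validation("bootstrap CIs require a seed")
  structure(list(kappa_weighting = match.arg(kappa_weighting),
                 icc_model = match.arg(icc_model),
                 icc_unit = match.arg(icc_unit),
                 ci_method = ci_method, n_boot = n_boot,
                 conf_level = conf_level, seed = seed),
            class = "scas_config")
}

# Map the 5-level VFSS scale onto a scheme's bands: levels beyond the last
# band collapse into it (the revised scheme merges moderate and severe into
# moderate_severe, rank 3).
collapse_to_scheme <- function(level, scheme) {
  r <- severity_rank(level, vfss_levels())
  scheme$levels[pmin(r, length(scheme$levels) - 1L) + 1L]
}

#' Cross-tabulate index-test and gold-standard severity
#'
#' @param cohort a [paired_cohort()].
#' @param scheme severity scheme applied to the SCAS-PD totals; VFSS levels
#'   beyond the scheme's last band are collapsed into it so the table is
#'   square on the scheme's ordinal scale.
#' @return contingency table (SCAS-PD rows, VFSS columns).
#' @export
contingency_table <- function(cohort, scheme = scas_scheme("revised")) {
  stopifnot(inherits(cohort, "scas_cohort"))
  scas <- as.character(classify_severity(cohort$totals, scheme))
  vf <- collapse_to_scheme(cohort$vfss, scheme)
  table(`SCAS-PD` = factor(scas, scheme$levels),
        VFSS = factor(vf, scheme$levels))
}

#' Run the full validation battery on a paired cohort
#'
#' Scores and classifies every patient, then computes the statistics an
#' instrument-validation study reports against its gold standard:
#'
#' * agreement — ICC of the ordinally encoded severity ratings, weighted
#'   kappa of the severity cross-table, and one-vs-rest kappa per level
#'   (levels absent from the cohort are reported as not estimable);
#' * internal consistency — Cronbach's alpha of the 12 per-item scores and
#'   of each phase domain (requires full records);
#' * diagnostic accuracy — for each reference dichotomization of the VFSS
#'   (at least functional, at least mild i.e. any dysphagia, at least
#'   moderate): the empirical ROC of the total score, its AUC with a
#'   confidence interval, and the Youden-optimal cutoff with sensitivity
#'   and specificity.
#'
#' @param cohort a [paired_cohort()].
#' @param scheme severity scheme for classification and agreement.
#' @param config a [validation_config()].
#' @param items item table.
#' @return object of class `scas_validation`.
#' @export
validate_cohort <- function(cohort, scheme = scas_scheme("revised"),
                            config = validation_config(),
                            items = scas_items()) {
  stopifnot(inherits(cohort, "scas_cohort"), inherits(config, "scas_config"))
  totals <- cohort$totals
  scas_lv <- as.character(classify_severity(totals, scheme))
  vf_coll <- collapse_to_scheme(cohort$vfss, scheme)

  tab <- contingency_table(cohort, scheme)
  wk <- weighted_kappa(tab, config$kappa_weighting)

  ratings <- cbind(scas = severity_rank(scas_lv, scheme$levels),
                   vfss = severity_rank(vf_coll, scheme$levels))
  ic <- icc(ratings, model = config$icc_model, unit = config$icc_unit,
            conf_level = config$conf_level)

  per_level <- lapply(scheme$levels, function(lv) {
    if (!lv %in% c(scas_lv, vf_coll))
      return(list(kappa = NA_real_, p = NA_real_, estimable = FALSE))
    pk <- per_level_kappa(scas_lv, vf_coll, lv, scheme$levels)
    list(kappa = pk$kappa, p = pk$p, estimable = TRUE)
  })
  names(per_level) <- scheme$levels

  consistency <- if (!is.null(cohort$records))
    internal_consistency(cohort$records, items) else NULL

  dichot <- c(functional = "functional", mild = "mild", moderate = "moderate")
  roc <- lapply(dichot, function(thr) {
    truth <- dichotomize(cohort$vfss, thr, vfss_levels())
    if (length(unique(truth)) < 2L)
      return(list(estimable = FALSE))
    rc <- roc_curve(totals, truth)
    ci <- auc_ci(totals, truth, method = config$ci_method,
                 conf_level = config$conf_level, n_boot = config$n_boot,
                 seed = config$seed)
    oc <- optimal_cutoff(totals, truth)
    list(estimable = TRUE, threshold_level = thr, curve = rc,
         auc = rc$auc, auc_ci = c(ci$low, ci$high),
         cutoff = oc$cutoff, sensitivity = oc$sensitivity,
         specificity = oc$specificity, youden = oc$youden)
  })
  names(roc) <- c("ge_functional", "ge_mild", "ge_moderate")

  structure(list(
    n = cohort$n,
    scheme = scheme$name,
    config = unclass(config),
    patients = data.frame(patient_id = cohort$patient_ids, total = totals,
                          scas_severity = scas_lv,
                          scas_rank = severity_rank(scas_lv, scheme$levels),
                          vfss = cohort$vfss,
                          stringsAsFactors = FALSE),
    crosstab = tab,
    agreement = list(icc = ic$icc, icc_ci = ic$ci, icc_p = ic$p,
                     icc_model = ic$model, icc_unit = ic$unit,
                     weighted_kappa = wk$kappa, kappa_weighting = wk$weighting,
                     kappa_se = wk$se, kappa_p = wk$p,
                     per_level_kappa = per_level),
    consistency = consistency,
    roc = roc
  ), class = "scas_validation")
}

#' @export
print.scas_validation <- function(x, ...) {
  cat(sprintf("SCAS-PD validation report (n = %d, scheme '%s')\n", x$n, x$scheme))
  cat(sprintf("  ICC (%s, %s): %.3f [%.3f, %.3f], p = %.3g\n",
              x$agreement$icc_model, x$agreement$icc_unit, x$agreement$icc,
              x$agreement$icc_ci[1], x$agreement$icc_ci[2], x$agreement$icc_p))
  cat(sprintf("  Weighted kappa (%s): %.3f, p = %.3g\n",
              x$agreement$kappa_weighting, x$agreement$weighted_kappa,
              x$agreement$kappa_p))
  if (!is.null(x$consistency))
    cat(sprintf("  Cronbach's alpha: total %.3f (oral %.3f, pharyngeal %.3f, PA %.3f)\n",
                x$consistency$alpha_total,
                x$consistency$alpha_by_domain$oral,
                x$consistency$alpha_by_domain$pharyngeal,
                x$consistency$alpha_by_domain$penetration_aspiration))
  for (nm in names(x$roc)) {
    r <- x$roc[[nm]]
    if (isTRUE(r$estimable))
      cat(sprintf("  %s: cutoff %g, AUC %.3f [%.3f, %.3f], Se %.1f%%, Sp %.1f%%\n",
                  nm, r$cutoff, r$auc, r$auc_ci[1], r$auc_ci[2],
                  100 * r$sensitivity, 100 * r$specificity))
    else cat(sprintf("  %s: not estimable (one class absent)\n", nm))
  }
  invisible(x)
}
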