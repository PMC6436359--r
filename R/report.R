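# Rendering of validation reports. All numeric output is serialized at 6
# significant digits so repeated runs diff cleanly.

signif6 <- function(x) {
  if (is.list(x)) return(lapply(x, signif6))
  if (is.double(x)) return(signif(x, 6))
  x
}

as_report_list <- function(report) {
  stopifnot(inherits(report, "scas_validation"))
  x <- unclass(report)
  x$package_version <- as.character(utils::packageVersion("scaspd"))
  x$crosstab <- as.data.frame(report$crosstab, stringsAsFactors = FALSE)
  names(x$crosstab) <- c("scas", "vfss", "count")
  x$patients <- as.list(report$patients)
  x$roc <- lapply(report$roc, function(r) {
    if (!isTRUE(r$estimable)) return(list(estimable = FALSE))
    r$curve <- list(thresholds = ifelse(is.finite(r$curve$thresholds),
                                        r$curve$thresholds, NA_real_),
                    fpr = r$curve$fpr, tpr = r$curve$tpr)
    r
  })
  signif6(x)
}

#' Write a validation report
#'
#' JSON mirrors the full `scas_validation` structure (agreement, internal
#' consistency, per-dichotomization ROC results, per-patient
#' classifications, cross-table). Markdown renders the agreement and
#' diagnostic-accuracy tables in the layout instrument-validation studies
#' print. Output is deterministic: identical reports give byte-identical
#' files.
#'
#' @param report a [validate_cohort()] result.
#' @param path output file.
#' @param format `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("output directory does not exist: %s", dir)
  if (format == "json") {
    jsonlite::write_json(as_report_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  } else {
    con <- file(path, open = "wb")  # binary: fixed newlines on any platform
    on.exit(close(con))
    writeLines(report_markdown(report), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()`: the parsed report as a list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_io("report file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

fmt <- function(x, pct = FALSE) {
  if (is.na(x)) return("--")
  if (pct) sprintf("%.1f", 100 * x) else format(signif(x, 6))
}

#' Render a validation report as markdown lines
#'
#' @param report a `scas_validation` object.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "scas_validation"))
  ag <- report$agreement
  lines <- c(
    "# SCAS-PD validation report",
    "",
    sprintf("- patients: %d", report$n),
    sprintf("- severity scheme: %s", report$scheme),
    sprintf("- kappa weighting: %s; ICC model: %s (%s); AUC CI: %s",
            report$config$kappa_weighting, report$config$icc_model,
            report$config$icc_unit, report$config$ci_method),
    sprintf("- package version: %s",
            as.character(utils::packageVersion("scaspd"))),
    "",
    "## Agreement with the gold standard",
    "",
    "| statistic | estimate | 95% CI | p |",
    "|---|---|---|---|",
    sprintf("| ICC | %s | %s-%s | %s |", fmt(ag$icc), fmt(ag$icc_ci[1]),
            fmt(ag$icc_ci[2]), fmt(ag$icc_p)),
    sprintf("| weighted kappa (%s) | %s | -- | %s |", ag$kappa_weighting,
            fmt(ag$weighted_kappa), fmt(ag$kappa_p)),
    "",
    "### Kappa by severity level (one-vs-rest)",
    "",
    "| level | kappa | p |",
    "|---|---|---|",
    vapply(names(ag$per_level_kappa), function(lv) {
      pk <- ag$per_level_kappa[[lv]]
      if (!isTRUE(pk$estimable))
        sprintf("| %s | not estimable | -- |", lv)
      else sprintf("| %s | %s | %s |", lv, fmt(pk$kappa), fmt(pk$p))
    }, character(1))
  )
  if (!is.null(report$consistency)) {
    cs <- report$consistency
    lines <- c(lines, "",
      "## Internal consistency (Cronbach's alpha)",
      "",
      "| scale | alpha |",
      "|---|---|",
      sprintf("| total (12 items) | %s |", fmt(cs$alpha_total)),
      sprintf("| oral phase | %s |", fmt(cs$alpha_by_domain$oral)),
      sprintf("| pharyngeal phase | %s |", fmt(cs$alpha_by_domain$pharyngeal)),
      sprintf("| penetration/aspiration | %s |",
              fmt(cs$alpha_by_domain$penetration_aspiration)))
  }
  labels <- c(ge_functional = "at least functional",
              ge_mild = "any dysphagia (at least mild)",
              ge_moderate = "at least moderate")
  rows <- vapply(names(report$roc), function(nm) {
    r <- report$roc[[nm]]
    if (!isTRUE(r$estimable))
      return(sprintf("| %s | not estimable | -- | -- | -- |", labels[[nm]]))
    sprintf("| %s | %s | %s (%s-%s) | %s | %s |", labels[[nm]],
            fmt(r$cutoff), fmt(r$auc), fmt(r$auc_ci[1]), fmt(r$auc_ci[2]),
            fmt(r$sensitivity, pct = TRUE), fmt(r$specificity, pct = TRUE))
  }, character(1))
  c(lines, "",
    "## Diagnostic accuracy of the total score",
    "",
    "| dichotomization | cutoff (points) | AUC (95% CI) | sensitivity (%) | specificity (%) |",
    "|---|---|---|---|---|",
    rows)
}
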