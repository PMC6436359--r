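#' The canonical SCAS-PD item table
#'
#' The twelve scored signs of altered swallowing, grouped by phase: four oral
#' signs, three pharyngeal signs and five signs of laryngotracheal
#' penetration/aspiration. Each sign scores `weight` points every time it is
#' observed during one food offering; with three offerings per assessment the
#' maximum contribution of a sign is `max_total = 3 * weight`, the phase maxima
#' are 18 / 66 / 270 points and the instrument total ranges 0–354.
#'
#' @return A data frame with columns `item_id`, `label`, `phase`
#'   (`"oral"`, `"pharyngeal"` or `"penetration_aspiration"`),
#'   `weight` (points per offering) and `max_total`.
#' @examples
#' items <- scas_items()
#' tapply(items$max_total, items$phase, sum)  # 270 / 18 / 66
#' @export
scas_items <- function() {
  items <- data.frame(
    item_id = c("lip_closure", "labial_discharge", "oral_transit", "residue",
                "multiple_deglutition", "larynx_elevation",
                "cervical_auscultation",
                "throat_clearing", "cough", "voice_quality", "choking",
                "breathing"),
    label = c("Altered lip closure", "Labial discharge",
              "Prolonged oral transit time", "Residue",
              "Multiple deglutition", "Reduced larynx elevation",
              "Altered cervical auscultation",
              "Throat clearing", "Cough", "Change in voice quality",
              "Choking", "Alteration in breathing"),
    phase = rep(c("oral", "pharyngeal", "penetration_aspiration"),
                times = c(4L, 3L, 5L)),
    weight = c(1, 1, 2, 2, 2, 10, 10, 10, 15, 15, 20, 30),
    stringsAsFactors = FALSE
  )
  items$max_total <- 3 * items$weight
  items
}

# Accepted spellings for item identifiers. "prehension_of_food" is the
# narrative name of the first oral sign; the item table uses the tabular name
# "altered lip closure" for the same sign.
.item_aliases <- c(
  prehension_of_food   = "lip_closure",
  altered_lip_closure  = "lip_closure",
  prolonged_oral_transit_time = "oral_transit",
  oral_transit_time    = "oral_transit",
  reduced_larynx_elevation = "larynx_elevation",
  altered_cervical_auscultation = "cervical_auscultation",
  change_voice_quality = "voice_quality",
  change_in_voice_quality = "voice_quality",
  alteration_in_breathing = "breathing",
  respiratory_impairment  = "breathing"
)

#' Normalize item identifiers, resolving known aliases
#'
#' @param x character vector of item identifiers.
#' @param items item table, as from [scas_items()].
#' @return canonical item identifiers; unknown identifiers raise a
#'   validation error naming them.
#' @export
normalize_item_id <- function(x, items = scas_items()) {
  x <- tolower(trimws(as.character(x)))
  hit <- .item_aliases[x]
  x[!is.na(hit)] <- hit[!is.na(hit)]
  bad <- setdiff(unique(x), items$item_id)
  if (length(bad)) {
    stop_validation("unknown item identifier(s): %s",
                    paste(bad, collapse = ", "))
  }
  x
}

#' The three food offerings of an assessment
#'
#' Each assessment administers three consistencies in fixed order: 20 ml of
#' thin liquid (water), 10 ml of paste (thickened liquid, pudding
#' consistency) and one unit of solid (a salt cracker). Every sign is scored
#' once per offering.
#'
#' @return data frame with columns `offering_id` and `description`.
#' @export
scas_offerings <- function() {
  data.frame(
    offering_id = c("liquid", "paste", "solid"),
    description = c("20 ml thin liquid (water)",
                    "10 ml paste (thickened liquid, pudding consistency)",
                    "one unit of solid (salt cracker)"),
    stringsAsFactors = FALSE
  )
}

offering_ids <- function() c("liquid", "paste", "solid")

#' Construct a severity stratification scheme
#'
#' A scheme is an ordered list of severity bands tiling the 0–354 score
#' range. Band upper bounds are inclusive and lower bounds exclusive, so a
#' score equal to a printed cutoff belongs to the band below it
#' (e.g. "functional >3 <= 19" contains 19).
#'
#' @param name scheme name.
#' @param levels ordered severity labels, least to most severe.
#' @param upper inclusive upper bound of each band; strictly increasing,
#'   the last must be 354 and the first must be >= 0 so the bands tile the
#'   whole score range.
#' @return an object of class `scas_scheme`.
#' @seealso [scas_scheme()] for the two canonical schemes.
#' @export
severity_scheme <- function(name, levels, upper) {
  levels <- as.character(levels)
  upper <- as.numeric(upper)
  if (length(levels) < 2L || length(levels) != length(upper))
    stop_validation("a scheme needs >= 2 bands, one upper bound per band")
  if (anyDuplicated(levels))
    stop_validation("severity labels must be unique")
  if (any(diff(upper) <= 0))
    stop_validation("band upper bounds must be strictly increasing")
  if (upper[1] < 0 || upper[length(upper)] != 354)
    stop_validation("bands must tile [0, 354]: first upper bound >= 0, last = 354")
  structure(
    list(name = name, levels = levels,
         lower = c(-Inf, upper[-length(upper)]), upper = upper),
    class = "scas_scheme"
  )
}

#' Canonical SCAS-PD severity schemes
#'
#' Two stratifications of the 0–354 total score ship with the instrument:
#'
#' * `"preliminary"`: normal <=2, functional >2 <=15, mild >15 <=35,
#'   moderate >35 <=60, severe >60 — the five-band scheme used when the
#'   instrument was first drafted.
#' * `"revised"`: normal <=3, functional >3 <=19, mild >19 <=35,
#'   moderate_severe >35 — the four-band scheme after ROC-based cutoff
#'   revision against videofluoroscopy; a total above 35 points flags a high
#'   risk of laryngotracheal aspiration.
#'
#' @param name `"revised"` (default) or `"preliminary"`.
#' @return a `scas_scheme` object.
#' @examples
#' classify_severity(c(0, 19, 20, 36), scas_scheme("revised"))
#' @export
scas_scheme <- function(name = c("revised", "preliminary")) {
  name <- match.arg(name)
  switch(name,
    preliminary = severity_scheme(
      "preliminary",
      c("normal", "functional", "mild", "moderate", "severe"),
      c(2, 15, 35, 60, 354)),
    revised = severity_scheme(
      "revised",
      c("normal", "functional", "mild", "moderate_severe"),
      c(3, 19, 35, 354))
  )
}

#' @export
print.scas_scheme <- function(x, ...) {
  cat(sprintf("SCAS-PD severity scheme '%s'\n", x$name))
  lo <- ifelse(is.finite(x$lower), sprintf(">%g", x$lower), "")
  cat(sprintf("  %-15s %s<=%g\n", x$levels, lo, x$upper), sep = "")
  invisible(x)
}

#' Severity levels of the videofluoroscopy (VFSS) rating scale
#'
#' The gold-standard examination is rated on five ordinal levels: within
#' normal pattern, functional (spontaneous compensation), mild (discrete)
#' dysphagia, moderate dysphagia and severe (intense) dysphagia.
#'
#' @return ordered character vector of level tokens.
#' @export
vfss_levels <- function() {
  c("normal", "functional", "mild", "moderate", "severe")
}

#' Classify a total score into a severity band
#'
#' @param total numeric vector of total scores, each in \[0, 354\].
#' @param scheme a [scas_scheme()].
#' @return factor of severity labels with the scheme's levels. Boundary
#'   scores belong to the lower band (upper bounds are inclusive).
#' @examples
#' classify_severity(19, scas_scheme("revised"))   # functional
#' classify_severity(61, scas_scheme("preliminary"))  # severe
#' @export
classify_severity <- function(total, scheme = scas_scheme("revised")) {
  stopifnot(inherits(scheme, "scas_scheme"))
  total <- as.numeric(total)
  if (any(!is.finite(total)) || any(total < 0) || any(total > 354))
    stop_validation("total score outside the instrument range [0, 354]")
  idx <- findInterval(total, scheme$upper, left.open = TRUE) + 1L
  factor(scheme$levels[idx], levels = scheme$levels)
}

#' Ordinal rank of severity labels
#'
#' @param level character or factor of severity labels.
#' @param levels the ordered label set (defaults to [vfss_levels()]).
#' @return integer ranks starting at 0 for the least severe level.
#' @export
severity_rank <- function(level, levels = vfss_levels()) {
  r <- match(as.character(level), levels)
  if (anyNA(r))
    stop_validation("label(s) not on the given ordinal scale: %s",
                    paste(unique(level[is.na(r)]), collapse = ", "))
  r - 1L
}

#' Dichotomize an ordinal severity label at a threshold level
#'
#' Used to build the reference dichotomizations of the validation battery:
#' at least functional, at least mild ("any dysphagia") and at least
#' moderate. The threshold is inclusive.
#'
#' @param level character/factor of severity labels.
#' @param threshold_level single label of the same ordinal scale.
#' @param levels the ordered label set shared by both arguments.
#' @return integer vector, 1 where `level >= threshold_level`, else 0.
#' @examples
#' dichotomize(c("normal", "severe", "functional"), "functional")
#' @export
dichotomize <- function(level, threshold_level, levels = vfss_levels()) {
  r <- severity_rank(level, levels)
  t <- severity_rank(threshold_level, levels)
  if (length(t) != 1L)
    stop_validation("threshold_level must be a single label")
  as.integer(r >= t)
}

#' Write / read a versioned instrument definition
#'
#' The full instrument configuration — item weights, offerings and the two
#' canonical severity schemes — serializes to JSON so alternative weightings
#' can be loaded and passed to the scoring functions.
#'
#' @param path file path of the JSON configuration.
#' @param items item table (see [scas_items()]).
#' @param schemes named list of [scas_scheme()] objects.
#' @param version configuration version string.
#' @return `write_instrument()` returns `path` invisibly; `read_instrument()`
#'   a list with elements `version`, `items`, `offerings`, `schemes`.
#' @export
write_instrument <- function(path, items = scas_items(),
                             schemes = list(preliminary = scas_scheme("preliminary"),
                                            revised = scas_scheme("revised")),
                             version = "1.0") {
  cfg <- list(
    version = version,
    offerings = scas_offerings(),
    items = items,
    schemes = lapply(schemes, function(s)
      list(name = s$name, levels = s$levels, upper = s$upper))
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  if (!file.exists(path)) stop_io("instrument file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (col in c("item_id", "label", "phase")) {
    if (is.null(cfg$items[[col]]))
      stop_validation("instrument file misses item column '%s'", col)
  }
  cfg$items$weight <- as.numeric(cfg$items$weight)
  cfg$items$max_total <- 3 * cfg$items$weight
  cfg$schemes <- lapply(cfg$schemes, function(s)
    severity_scheme(s$name, s$levels, s$upper))
  cfg
}
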