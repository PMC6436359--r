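#' Build an observation grid
#'
#' The raw data of one assessment: a binary flag per (item, offering) cell
#' recording whether the sign was observed during that offering. A sign is
#' scored at most once per offering, so flags are 0/1; repeated events within
#' one offering do not accumulate points.
#'
#' @param x a 12 x 3 matrix (rows = items, columns = offerings) of 0/1 flags,
#'   or a long data frame with columns `item_id`, `offering_id`, `observed`.
#'   Row and column names (or the long-form identifier columns) are matched
#'   against the item table, resolving known aliases.
#' @param items item table, as from [scas_items()].
#' @return integer matrix with `items$item_id` rows and
#'   `liquid`/`paste`/`solid` columns.
#' @export
observation_grid <- function(x, items = scas_items()) {
  offs <- offering_ids()
  if (is.data.frame(x)) {
    need <- c("item_id", "offering_id", "observed")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop_validation("long-form grid misses column(s): %s",
                      paste(miss, collapse = ", "))
    x$item_id <- normalize_item_id(x$item_id, items)
    bad_off <- setdiff(unique(as.character(x$offering_id)), offs)
    if (length(bad_off))
      stop_validation("unknown offering(s): %s", paste(bad_off, collapse = ", "))
    dup <- duplicated(x[c("item_id", "offering_id")])
    if (any(dup))
      stop_validation("duplicate (item, offering) entries at row(s): %s",
                      paste(which(dup), collapse = ", "))
    m <- matrix(NA_integer_, nrow(items), 3L,
                dimnames = list(items$item_id, offs))
    m[cbind(x$item_id, as.character(x$offering_id))] <- as.integer(x$observed)
  } else {
    m <- as.matrix(x)
    if (!is.null(rownames(m))) {
      rn <- normalize_item_id(rownames(m), items)
      if (anyDuplicated(rn)) stop_validation("duplicate item rows in grid")
      rownames(m) <- rn
      m <- m[items$item_id[items$item_id %in% rn], , drop = FALSE]
    } else if (nrow(m) == nrow(items)) {
      rownames(m) <- items$item_id
    } else {
      stop_validation("grid must have item row names or one row per item")
    }
    if (is.null(colnames(m)) && ncol(m) == 3L) colnames(m) <- offs
    bad_off <- setdiff(colnames(m), offs)
    if (length(bad_off))
      stop_validation("unknown offering(s): %s", paste(bad_off, collapse = ", "))
    storage.mode(m) <- "integer"
  }
  full <- matrix(NA_integer_, nrow(items), 3L,
                 dimnames = list(items$item_id, offs))
  full[rownames(m), colnames(m)] <- m
  miss <- which(is.na(full), arr.ind = TRUE)
  if (nrow(miss)) {
    pairs <- paste0("(", rownames(full)[miss[, 1]], ", ",
                    offs[miss[, 2]], ")")
    stop_validation("incomplete grid; missing entries: %s",
                    paste(pairs, collapse = ", "))
  }
  if (!all(full %in% c(0L, 1L)))
    stop_validation("occurrence flags must be 0 or 1")
  full
}

#' Assemble one patient's assessment record
#'
#' @param patient_id non-empty identifier.
#' @param grid observation grid (anything [observation_grid()] accepts).
#' @param metadata optional named list of descriptors (age, Hoehn & Yahr
#'   stage, ...) carried through unchanged.
#' @param imputed_offerings offerings that could not be administered and were
#'   scored at the maximum (see [impute_offering()]).
#' @param items item table.
#' @return an object of class `scas_record`.
#' @export
assessment_record <- function(patient_id, grid, metadata = list(),
                              imputed_offerings = character(),
                              items = scas_items()) {
  patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L || is.na(patient_id) || !nzchar(patient_id))
    stop_validation("patient_id must be a single non-empty string")
  grid <- observation_grid(grid, items)
  imputed_offerings <- as.character(imputed_offerings)
  bad <- setdiff(imputed_offerings, offering_ids())
  if (length(bad))
    stop_validation("unknown imputed offering(s): %s", paste(bad, collapse = ", "))
  structure(list(patient_id = patient_id, grid = grid,
                 metadata = metadata,
                 imputed_offerings = imputed_offerings),
            class = "scas_record")
}

#' Impute an offering that could not be administered
#'
#' When a patient cannot ingest one consistency (e.g. solid food in severe
#' dysphagia), the offering is scored at its maximum: every sign flag for
#' that offering is set to 1 and the record is marked as imputed.
#'
#' @param record a `scas_record`.
#' @param offering one of `"liquid"`, `"paste"`, `"solid"`.
#' @return the modified record.
#' @export
impute_offering <- function(record, offering) {
  stopifnot(inherits(record, "scas_record"))
  offering <- match.arg(offering, offering_ids())
  record$grid[, offering] <- 1L
  record$imputed_offerings <- union(record$imputed_offerings, offering)
  record
}

#' @export
print.scas_record <- function(x, ...) {
  cat(sprintf("SCAS-PD record for patient '%s' (%d signs flagged%s)\n",
              x$patient_id, sum(x$grid),
              if (length(x$imputed_offerings))
                paste0("; imputed: ", paste(x$imputed_offerings, collapse = ", "))
              else ""))
  invisible(x)
}

#' Score one food offering
#'
#' Sums the item weights of the signs observed during a single offering.
#' With the canonical weights the per-offering score is bounded by 118
#' points (all twelve signs present).
#'
#' @param grid an observation grid or `scas_record`.
#' @param offering one of `"liquid"`, `"paste"`, `"solid"`.
#' @param items item table.
#' @return the offering score in points.
#' @examples
#' g <- matrix(0, 12, 3, dimnames = list(scas_items()$item_id, c("liquid", "paste", "solid")))
#' g["choking", "liquid"] <- 1
#' score_offering(g, "liquid")  # 20
#' @export
score_offering <- function(grid, offering, items = scas_items()) {
  if (inherits(grid, "scas_record")) grid <- grid$grid
  grid <- observation_grid(grid, items)
  offering <- match.arg(offering, offering_ids())
  sum(items$weight * grid[items$item_id, offering])
}

#' Score a full assessment
#'
#' Computes the oral, pharyngeal and penetration/aspiration subscores (each
#' the sum of its items' weights over the three offerings) and the total.
#' Canonical maxima are 18, 66, 270 and 354 points.
#'
#' @param record a `scas_record`, or an observation grid.
#' @param items item table.
#' @return object of class `scas_score`: list with elements `oral`,
#'   `pharyngeal`, `penetration_aspiration`, `total`.
#' @export
score_assessment <- function(record, items = scas_items()) {
  grid <- if (inherits(record, "scas_record")) record$grid else record
  grid <- observation_grid(grid, items)
  per_item <- items$weight * rowSums(grid[items$item_id, , drop = FALSE])
  ph <- vapply(split(per_item, items$phase), sum, numeric(1))
  out <- list(
    oral = unname(ph["oral"]),
    pharyngeal = unname(ph["pharyngeal"]),
    penetration_aspiration = unname(ph["penetration_aspiration"])
  )
  out$total <- out$oral + out$pharyngeal + out$penetration_aspiration
  structure(out, class = "scas_score")
}

#' @export
print.scas_score <- function(x, ...) {
  cat(sprintf(
    "SCAS-PD score: total %g (oral %g, pharyngeal %g, penetration/aspiration %g)\n",
    x$total, x$oral, x$pharyngeal, x$penetration_aspiration))
  invisible(x)
}

#' Per-item score matrix of a set of records
#'
#' One row per patient, one column per item; each entry is the item's weight
#' times the number of offerings in which the sign was observed. This is the
#' matrix internal-consistency (Cronbach's alpha) analyses run on, totalling
#' to the instrument score across the twelve columns.
#'
#' @param records list of `scas_record` objects.
#' @param items item table.
#' @return numeric matrix, patients x items.
#' @export
item_score_matrix <- function(records, items = scas_items()) {
  stopifnot(length(records) >= 1L)
  m <- t(vapply(records, function(r) {
    stopifnot(inherits(r, "scas_record"))
    items$weight * rowSums(r$grid[items$item_id, , drop = FALSE])
  }, numeric(nrow(items))))
  dimnames(m) <- list(vapply(records, `[[`, "", "patient_id"), items$item_id)
  m
}
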