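# Readers and writers. CSV dialect: comma-separated, UTF-8, header required,
# decimal point. Severity labels travel as lowercase tokens, always next to
# an integer rank column so downstream sorting never depends on locale.

wide_cols <- function(items = scas_items()) {
  as.vector(outer(items$item_id, offering_ids(), paste, sep = "__"))
}

#' Read assessment records
#'
#' Three on-disk encodings are supported:
#' * `long_csv` — columns `patient_id, item_id, offering_id, observed` (0/1),
#'   36 rows per patient;
#' * `wide_csv` — one row per patient: `patient_id` plus 36 columns named
#'   `<item_id>__<offering_id>`;
#' * `json` — array of objects `{patient_id, grid, metadata,
#'   imputed_offerings}` with `grid` mapping item to per-offering flags.
#'
#' `format = "auto"` picks by file extension and header. Item aliases are
#' resolved; non-binary flags, duplicate (patient, item, offering) entries
#' and incomplete grids raise validation errors naming the offending rows.
#'
#' @param path input file.
#' @param format `"auto"`, `"long_csv"`, `"wide_csv"` or `"json"`.
#' @param items item table.
#' @return list of `scas_record` objects (empty for a header-only file).
#' @export
read_records <- function(path, format = c("auto", "long_csv", "wide_csv",
                                          "json"),
                         items = scas_items()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("input file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
    else {
      header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
      if ("item_id" %in% header) "long_csv" else "wide_csv"
    }
  }
  switch(format,
    long_csv = read_records_long(path, items),
    wide_csv = read_records_wide(path, items),
    json = read_records_json(path, items))
}

read_records_long <- function(path, items) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "item_id", "offering_id", "observed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_validation("long CSV misses column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(df)) return(list())
  bad <- which(!(df$observed %in% c(0, 1)))
  if (length(bad))
    stop_validation("non-binary 'observed' values at row(s): %s",
                    paste(bad + 1L, collapse = ", "))  # +1: header line
  df$item_id <- normalize_item_id(df$item_id, items)
  dup <- which(duplicated(df[c("patient_id", "item_id", "offering_id")]))
  if (length(dup))
    stop_validation("duplicate (patient, item, offering) at row(s): %s",
                    paste(dup + 1L, collapse = ", "))
  lapply(split(df, factor(df$patient_id, unique(df$patient_id))),
         function(d) assessment_record(d$patient_id[1],
                                       d[c("item_id", "offering_id", "observed")],
                                       items = items))
}

read_records_wide <- function(path, items) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% names(df))
    stop_validation("wide CSV misses column 'patient_id'")
  if (!nrow(df)) return(list())
  cols <- wide_cols(items)
  # resolve aliases in column names
  parts <- strsplit(setdiff(names(df), "patient_id"), "__", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) == 2L) {
      cn <- paste(normalize_item_id(parts[[i]][1], items), parts[[i]][2],
                  sep = "__")
      names(df)[names(df) == setdiff(names(df), "patient_id")[i]] <- cn
    }
  }
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_validation("wide CSV misses column(s): %s", paste(miss, collapse = ", "))
  dup <- which(duplicated(df$patient_id))
  if (length(dup))
    stop_validation("duplicate patient_id at row(s): %s",
                    paste(dup + 1L, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    flags <- as.numeric(df[i, cols])
    if (!all(flags %in% c(0, 1)))
      stop_validation("non-binary flags at row %d", i + 1L)
    grid <- matrix(as.integer(flags), nrow(items), 3L,
                   dimnames = list(items$item_id, offering_ids()))
    assessment_record(df$patient_id[i], grid, items = items)
  })
}

read_records_json <- function(path, items) {
  recs <- jsonlite::read_json(path)
  lapply(recs, function(r) {
    if (is.null(r$patient_id) || is.null(r$grid))
      stop_validation("JSON record needs 'patient_id' and 'grid'")
    ids <- normalize_item_id(names(r$grid), items)
    grid <- matrix(0L, nrow(items), 3L,
                   dimnames = list(items$item_id, offering_ids()))
    for (i in seq_along(r$grid)) {
      g <- r$grid[[i]]
      grid[ids[i], names(g)] <- as.integer(unlist(g))
    }
    assessment_record(r$patient_id, grid,
                      metadata = if (is.null(r$metadata)) list() else r$metadata,
                      imputed_offerings = as.character(unlist(r$imputed_offerings)),
                      items = items)
  })
}

#' Write assessment records
#'
#' @param records list of `scas_record` objects.
#' @param path output file.
#' @param format `"long_csv"`, `"wide_csv"` or `"json"` (JSON keeps metadata
#'   and imputed-offering flags; the CSV forms carry the grids only).
#' @param items item table.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path,
                          format = c("long_csv", "wide_csv", "json"),
                          items = scas_items()) {
  format <- match.arg(format)
  if (format == "long_csv") {
    df <- do.call(rbind, lapply(records, function(r) {
      data.frame(patient_id = r$patient_id,
                 item_id = rep(items$item_id, 3L),
                 offering_id = rep(offering_ids(), each = nrow(items)),
                 observed = as.integer(r$grid[items$item_id, ]),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df))
      df <- data.frame(patient_id = character(), item_id = character(),
                       offering_id = character(), observed = integer())
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "wide_csv") {
    df <- do.call(rbind, lapply(records, function(r)
      c(list(patient_id = r$patient_id),
        stats::setNames(as.list(as.integer(r$grid[items$item_id, ])),
                        wide_cols(items)))))
    df <- as.data.frame(df)
    df[] <- lapply(df, unlist)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    out <- lapply(records, function(r) {
      grid <- lapply(stats::setNames(items$item_id, items$item_id),
                     function(it) as.list(r$grid[it, ]))
      list(patient_id = r$patient_id, grid = grid,
           metadata = r$metadata, imputed_offerings = r$imputed_offerings)
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read / write VFSS severity labels
#'
#' CSV with columns `patient_id, vfss` (lowercase level tokens); an optional
#' `vfss_rank` column is written for locale-safe sorting and ignored on
#' read.
#'
#' @param path CSV file.
#' @return `read_vfss()`: data frame with `patient_id` and `vfss`.
#' @export
read_vfss <- function(path) {
  if (!file.exists(path)) stop_io("VFSS label file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("patient_id", "vfss"), names(df))
  if (length(miss))
    stop_validation("VFSS CSV misses column(s): %s", paste(miss, collapse = ", "))
  df$vfss <- tolower(trimws(df$vfss))
  bad <- which(!df$vfss %in% vfss_levels())
  if (length(bad))
    stop_validation("unknown VFSS level(s) at row(s): %s",
                    paste(bad + 1L, collapse = ", "))
  df[c("patient_id", "vfss")]
}

#' @rdname read_vfss
#' @param labels data frame with `patient_id` and `vfss`, or a named
#'   character vector of levels.
#' @export
write_vfss <- function(labels, path) {
  if (!is.data.frame(labels))
    labels <- data.frame(patient_id = names(labels),
                         vfss = as.character(labels),
                         stringsAsFactors = FALSE)
  labels$vfss_rank <- severity_rank(labels$vfss, vfss_levels())
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
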