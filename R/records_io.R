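# Patient-level visit records: reading, validation, writing.
#
# A visit record has five ordered timestamps -- arrival, triage, first early
# warning score (EWS), last EWS, departure -- of which only arrival and
# departure are mandatory, plus optional clinical attributes.

.ts_fields <- c("arrival", "triage_time", "first_ews_time",
                "last_ews_time", "departure")
.optional_ts <- c("triage_time", "first_ews_time", "last_ews_time")
.patient_cols <- c("visit_id", "arrival", "departure", "triage_time",
                   "first_ews_time", "last_ews_time", "age", "sex",
                   "triage_score", "trauma", "diagnosis")

#' Read and validate patient-level ED visit records
#'
#' Reads a CSV of one row per visit, parses timestamps, and enforces the
#' record invariants. Records whose arrival or departure is missing or
#' unparseable, or with departure before arrival, are dropped and itemised
#' in the validation report. Optional timestamps that are unparseable or
#' fall outside `[arrival, departure]` are blanked to missing (the record is
#' kept). Surrogate-timestamp order violations (e.g. triage after first EWS)
#' are flagged but non-fatal: such records are excluded later only from
#' queues whose bounds they violate.
#'
#' @param path CSV file, comma-separated, UTF-8, header row required.
#' @param column_map Named character vector mapping canonical field names
#'   (`arrival`, `departure`, `triage_time`, `first_ews_time`,
#'   `last_ews_time`, `visit_id`, `age`, `sex`, `triage_score`, `trauma`,
#'   `diagnosis`) to column names in the file. `NULL` means columns already
#'   use the canonical names. Must cover at least `arrival` and `departure`.
#' @param timestamp_format `strptime()` format, default `"%Y-%m-%d %H:%M"`.
#' @return List with `records` (data.frame of accepted records, canonical
#'   columns) and `report` (an `ed_validation_report`:
#'   `n_read = n_accepted + n_dropped`, plus a `violations` data.frame of
#'   `(visit_id, kind)` covering drops and non-fatal flags).
#' @export
read_patients <- function(path, column_map = NULL,
                          timestamp_format = "%Y-%m-%d %H:%M") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src))
      stop("column_map names columns absent from file: ",
           paste(missing_src, collapse = ", "))
    for (canon in names(column_map)) names(raw)[names(raw) == column_map[[canon]]] <- canon
  }
  if (!all(c("arrival", "departure") %in% names(raw)))
    stop("mandatory columns 'arrival' and 'departure' not found ",
         "(use column_map to map them)")
  validate_patients(raw, timestamp_format = timestamp_format)
}

#' Validate a data.frame of visit records
#'
#' The validation core behind [read_patients()]; usable directly on an
#' in-memory data.frame (e.g. simulator output re-checked after editing).
#'
#' @inheritParams read_patients
#' @param df Data.frame with at least `arrival` and `departure` columns.
#' @return Same shape as [read_patients()].
#' @export
validate_patients <- function(df, timestamp_format = "%Y-%m-%d %H:%M") {
  n_read <- nrow(df)
  if (!"visit_id" %in% names(df))
    df$visit_id <- sprintf("row%06d", seq_len(max(n_read, 0L)))
  df$visit_id <- as.character(df$visit_id)

  blank <- function(proto) rep(proto, nrow(df))
  for (f in .ts_fields) {
    if (!f %in% names(df)) df[[f]] <- blank(NA_character_)
    df[[f]] <- parse_ts(df[[f]], timestamp_format)
  }
  df$age <- if ("age" %in% names(df)) suppressWarnings(as.numeric(df$age)) else blank(NA_real_)
  df$age[!is.na(df$age) & df$age < 0] <- NA_real_
  df$sex <- if ("sex" %in% names(df)) as.character(df$sex) else blank(NA_character_)
  df$sex[!df$sex %in% c("F", "M")] <- NA_character_
  ts_raw <- if ("triage_score" %in% names(df)) suppressWarnings(as.integer(df$triage_score)) else blank(NA_integer_)
  ts_raw[!is.na(ts_raw) & (ts_raw < 1L | ts_raw > 5L)] <- NA_integer_
  df$triage_score <- ts_raw
  df$trauma <- if ("trauma" %in% names(df)) {
    tolower(as.character(df$trauma)) %in% c("true", "t", "1", "yes")
  } else blank(FALSE)
  df$diagnosis <- if ("diagnosis" %in% names(df)) as.character(df$diagnosis) else blank(NA_character_)
  df$diagnosis[!nzchar(df$diagnosis) | is.na(df$diagnosis)] <- NA_character_

  violations <- list()
  note <- function(ids, kind) {
    if (length(ids)) violations[[length(violations) + 1L]] <<-
        data.frame(visit_id = ids, kind = kind, stringsAsFactors = FALSE)
  }

  bad_arr <- is.na(df$arrival)
  bad_dep <- is.na(df$departure)
  note(df$visit_id[bad_arr], "unparseable arrival")
  note(df$visit_id[bad_dep & !bad_arr], "unparseable departure")
  neg <- !bad_arr & !bad_dep & df$departure < df$arrival
  note(df$visit_id[neg], "negative stay")
  drop <- bad_arr | bad_dep | neg

  kept <- df[!drop, , drop = FALSE]
  # optional timestamps outside [arrival, departure] are blanked, non-fatal
  for (f in .optional_ts) {
    out <- !is.na(kept[[f]]) &
      (kept[[f]] < kept$arrival | kept[[f]] > kept$departure)
    note(kept$visit_id[out], paste(f, "outside stay"))
    kept[[f]][out] <- NA
  }
  # idealised order violation among surrogate timestamps: flag, keep
  ord_bad <- rep(FALSE, nrow(kept))
  pairs <- list(c("triage_time", "first_ews_time"),
                c("first_ews_time", "last_ews_time"))
  for (p in pairs) {
    both <- !is.na(kept[[p[1]]]) & !is.na(kept[[p[2]]])
    ord_bad <- ord_bad | (both & kept[[p[1]]] > kept[[p[2]]])
  }
  note(kept$visit_id[ord_bad], "surrogate order violation")

  kept <- kept[, .patient_cols, drop = FALSE]
  rownames(kept) <- NULL
  viol <- if (length(violations)) do.call(rbind, violations) else
    data.frame(visit_id = character(), kind = character(),
               stringsAsFactors = FALSE)
  report <- structure(
    list(n_read = n_read, n_accepted = nrow(kept),
         n_dropped = n_read - nrow(kept), violations = viol),
    class = "ed_validation_report")
  list(records = kept, report = report)
}

#' @export
print.ed_validation_report <- function(x, ...) {
  cat(sprintf("ED visit validation: %d read, %d accepted, %d dropped\n",
              x$n_read, x$n_accepted, x$n_dropped))
  if (nrow(x$violations)) {
    tab <- table(x$violations$kind)
    for (k in names(tab)) cat(sprintf("  %-28s %d\n", k, tab[[k]]))
  }
  invisible(x)
}

#' Write visit records to CSV
#'
#' Inverse of [read_patients()]: timestamps are formatted to the minute so a
#' write/read round trip reproduces the records field-for-field.
#'
#' @param records Data.frame of validated visit records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(records, path) {
  out <- records
  for (f in .ts_fields) out[[f]] <- format_ts(out[[f]])
  out$trauma <- ifelse(out$trauma, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
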