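#' @useDynLib dgrnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rpois rexp plogis sd
#'   setNames t.test wilcox.test dist
#' @importFrom utils read.table write.table head
NULL

EHR_COLUMNS <- c("patient_id", "code", "category", "time", "age", "sex",
                 "race", "label", "criterion_date")
CODE_CATEGORIES <- c("diagnosis", "drug", "lab", "other")

#' Construct a patient record
#'
#' A patient record holds one patient's timed, ordered medical events
#' together with demographics, the binary outcome label and the criterion
#' date from which hold-off windows are applied.  Event times are day
#' offsets from the patient's first recorded event; events are kept sorted
#' by time with ties broken by code string so sequences are deterministic.
#'
#' @param patient_id Character scalar.
#' @param events `data.frame` with columns `code`, `category`, `time`.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param race Character scalar.
#' @param label Outcome, 0 or 1.
#' @param criterion_date Day offset of the outcome-confirmation marker.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, events, age, sex, race, label,
                           criterion_date) {
  stopifnot(is.character(patient_id), nzchar(patient_id))
  if (!all(c("code", "category", "time") %in% names(events)))
    stop("events must have columns code, category, time")
  if (any(events$time < 0)) stop("event times must be non-negative")
  bad <- setdiff(unique(events$category), CODE_CATEGORIES)
  if (length(bad))
    stop("unknown code category: ", paste(bad, collapse = ", "))
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  ord <- order(events$time, events$code)
  events <- events[ord, c("code", "category", "time"), drop = FALSE]
  rownames(events) <- NULL
  structure(list(patient_id = patient_id, events = events,
                 age = as.numeric(age), sex = sex, race = race,
                 label = as.integer(label),
                 criterion_date = as.numeric(criterion_date)),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %d events, %s/%s age %g, label %d>\n",
              x$patient_id, nrow(x$events), x$sex, x$race, x$age, x$label))
  invisible(x)
}

#' Read an EHR event table
#'
#' Reads a long-format event table (one row per patient/event) from
#' delimited text (comma or tab, header row mandatory) or JSON lines, and
#' assembles one [patient_record] per distinct `patient_id`.  Events are
#' sorted by time with ties broken by code string ascending; duplicate
#' (patient, code, time) rows are kept.
#'
#' @param path File path.
#' @param format `"auto"` (sniff from extension/content), `"csv"`, `"tsv"`
#'   or `"jsonl"`.
#' @return List of [patient_record] objects, ordered by first appearance.
#' @export
read_ehr_table <- function(path, format = c("auto", "csv", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path)) "jsonl"
              else if (grepl("\\.tsv$", path)) "tsv" else "csv"
  }
  if (format == "jsonl") {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- read.table(path, header = TRUE, sep = sep,
                     colClasses = "character", check.names = FALSE,
                     quote = "\"", comment.char = "", encoding = "UTF-8")
  }
  ehr_records_from_df(df)
}

# shared assembly used by both the reader and the simulator
ehr_records_from_df <- function(df) {
  missing_cols <- setdiff(EHR_COLUMNS, names(df))
  if (length(missing_cols))
    stop("EHR table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tm <- suppressWarnings(as.numeric(df$time))
  if (anyNA(tm)) {
    bad <- which(is.na(tm))[1]
    stop(sprintf("non-numeric time %s at data row %d",
                 dQuote(df$time[bad]), bad))
  }
  df$time <- tm
  ids <- unique(df$patient_id)
  lapply(ids, function(id) {
    rows <- df[df$patient_id == id, , drop = FALSE]
    patient_record(
      patient_id = id,
      events = data.frame(code = as.character(rows$code),
                          category = as.character(rows$category),
                          time = rows$time, stringsAsFactors = FALSE),
      age = as.numeric(rows$age[1]), sex = as.character(rows$sex[1]),
      race = as.character(rows$race[1]),
      label = as.integer(rows$label[1]),
      criterion_date = as.numeric(rows$criterion_date[1]))
  })
}

records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(p) {
    if (nrow(p$events) == 0) return(NULL)
    data.frame(patient_id = p$patient_id, code = p$events$code,
               category = p$events$category, time = p$events$time,
               age = p$age, sex = p$sex, race = p$race, label = p$label,
               criterion_date = p$criterion_date,
               stringsAsFactors = FALSE)
  }))
}

#' Write an EHR event table
#'
#' Inverse of [read_ehr_table()]; the round trip is lossless on
#' (patient_id, code, time, label, demographics).
#'
#' @param records List of [patient_record] or an [ehr_cohort].
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"jsonl"`.
#' @export
write_ehr_table <- function(records, path, format = c("csv", "tsv", "jsonl")) {
  format <- match.arg(format)
  if (inherits(records, "ehr_cohort")) records <- records$patients
  df <- records_to_df(records)
  if (format == "jsonl") {
    con <- file(path, "w"); on.exit(close(con))
    jsonlite::stream_out(df, con, verbose = FALSE)
  } else {
    write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Remove rare medical codes
#'
#' Drops every code whose total number of event occurrences across all
#' records is below `min_count` (the cohorts in the motivating study drop
#' codes appearing fewer than 10 times).  Patients left with zero events
#' are dropped and reported.
#'
#' @param records List of [patient_record].
#' @param min_count Minimum total occurrence count for a code to survive.
#' @return List with elements `records` (filtered), `removed_codes`
#'   (character vector) and `dropped_patients` (ids emptied by the filter).
#' @export
filter_rare_codes <- function(records, min_count = 10) {
  stopifnot(min_count >= 1)
  counts <- table(unlist(lapply(records, function(p) p$events$code)))
  removed <- names(counts)[counts < min_count]
  dropped <- character()
  out <- list()
  for (p in records) {
    keep <- !(p$events$code %in% removed)
    if (!any(keep)) { dropped <- c(dropped, p$patient_id); next }
    p$events <- p$events[keep, , drop = FALSE]
    rownames(p$events) <- NULL
    out[[length(out) + 1L]] <- p
  }
  list(records = out, removed_codes = removed, dropped_patients = dropped)
}

#' Assemble a matched case-control cohort with a hold-off window
#'
#' Cases are patients whose history contains any of `case_codes`; the first
#' occurrence of such a code sets the case's criterion date.  Each case is
#' matched without replacement to `controls_per_case` case-free patients of
#' identical sex and the same integer age (within `age_tolerance` years);
#' control criterion dates are copied verbatim from their case.  All events
#' later than `criterion_date - holdoff_days` are then truncated away, so
#' prediction is genuinely prospective.  Cases lacking enough matching
#' controls, and patients emptied by truncation, are dropped with a warning.
#'
#' @param records List of [patient_record].
#' @param case_codes Character vector of outcome-defining codes.
#' @param holdoff_days Width of the prediction hold-off window in days.
#' @param controls_per_case Matched controls per case (default 3).
#' @param age_tolerance Allowed age difference in integer years (default 0,
#'   the strictest reading of same-age matching).
#' @param seed Integer seed shuffling the control candidate order.
#' @return An `ehr_cohort`: list with `patients`, `vocabulary` (data.frame
#'   of code/category), `holdoff_days` and a `provenance` list of counts.
#' @export
build_cohort <- function(records, case_codes, holdoff_days,
                         controls_per_case = 3, age_tolerance = 0,
                         seed = 1) {
  stopifnot(holdoff_days >= 0, controls_per_case >= 1)
  is_case <- vapply(records, function(p) any(p$events$code %in% case_codes),
                    logical(1))
  cases <- records[is_case]
  pool <- records[!is_case]
  set.seed(as.integer(seed))
  pool <- pool[sample.int(length(pool))]
  used <- rep(FALSE, length(pool))
  pool_age <- vapply(pool, function(p) floor(p$age), numeric(1))
  pool_sex <- vapply(pool, function(p) p$sex, character(1))

  patients <- list()
  n_cases <- 0L; n_controls <- 0L
  for (cs in cases) {
    idx <- which(!used & pool_sex == cs$sex &
                 abs(pool_age - floor(cs$age)) <= age_tolerance)
    if (length(idx) < controls_per_case) {
      warning(sprintf("case %s dropped: only %d matching controls available",
                      cs$patient_id, length(idx)))
      next
    }
    chosen <- idx[seq_len(controls_per_case)]
    crit <- min(cs$events$time[cs$events$code %in% case_codes])
    cs$criterion_date <- crit
    cs$label <- 1L
    kept_case <- truncate_holdoff(cs, holdoff_days)
    if (is.null(kept_case)) {
      warning(sprintf("case %s dropped: no events before the hold-off window",
                      cs$patient_id))
      next
    }
    ctrls <- list()
    for (j in chosen) {
      ct <- pool[[j]]
      ct$criterion_date <- crit
      ct$label <- 0L
      ct <- truncate_holdoff(ct, holdoff_days)
      if (!is.null(ct)) ctrls[[length(ctrls) + 1L]] <- ct
    }
    if (length(ctrls) < controls_per_case) {
      warning(sprintf("case %s dropped: control(s) emptied by hold-off",
                      cs$patient_id))
      next
    }
    used[chosen] <- TRUE
    patients[[length(patients) + 1L]] <- kept_case
    patients <- c(patients, ctrls)
    n_cases <- n_cases + 1L
    n_controls <- n_controls + controls_per_case
  }
  if (length(patients) == 0) stop("empty cohort: no case could be matched")
  new_cohort(patients, holdoff_days, n_cases, n_controls)
}

truncate_holdoff <- function(p, holdoff_days) {
  keep <- p$events$time <= p$criterion_date - holdoff_days
  if (!any(keep)) return(NULL)
  p$events <- p$events[keep, , drop = FALSE]
  rownames(p$events) <- NULL
  p
}

new_cohort <- function(patients, holdoff_days, n_cases = NULL,
                       n_controls = NULL) {
  labels <- vapply(patients, function(p) p$label, integer(1))
  if (is.null(n_cases)) n_cases <- sum(labels == 1L)
  if (is.null(n_controls)) n_controls <- sum(labels == 0L)
  ev <- do.call(rbind, lapply(patients, function(p)
    p$events[, c("code", "category")]))
  vocab <- unique(ev)
  vocab <- vocab[order(vocab$code), , drop = FALSE]
  rownames(vocab) <- NULL
  lens <- vapply(patients, function(p) nrow(p$events), numeric(1))
  visits <- vapply(patients, function(p) length(unique(p$events$time)),
                   numeric(1))
  structure(list(
    patients = patients, vocabulary = vocab, holdoff_days = holdoff_days,
    provenance = list(
      cases = n_cases, controls = n_controls,
      events = sum(lens), unique_events = nrow(vocab),
      mean_record_length = mean(lens),
      mean_events_per_visit = sum(lens) / sum(visits))),
    class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf(paste0("<ehr_cohort: %d cases + %d controls, %d events",
                     " (%d unique), hold-off %g days>\n"),
              pv$cases, pv$controls, pv$events, pv$unique_events,
              x$holdoff_days))
  cat(sprintf("  mean record length %.2f, mean events/visit %.2f\n",
              pv$mean_record_length, pv$mean_events_per_visit))
  invisible(x)
}

#' Export a cohort with a provenance sidecar
#'
#' Writes the event table plus a `<path>.provenance.json` sidecar holding
#' the cohort counts (cases, controls, events, unique events, mean record
#' length, mean events per visit).
#'
#' @inheritParams write_ehr_table
#' @param cohort An `ehr_cohort`.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "tsv", "jsonl")) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  write_ehr_table(cohort$patients, path, format)
  side <- paste0(path, ".provenance.json")
  jsonlite::write_json(c(cohort$provenance,
                         list(holdoff_days = cohort$holdoff_days)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flatten a patient's events to (code index, time) pairs
#'
#' Maps each event code to its index in `vocabulary` (a character vector of
#' codes), preserving the deterministic time-then-code sort order.
#'
#' @param patient A [patient_record].
#' @param vocabulary Character vector; position defines the code index.
#' @return List with `codes` (integer indices, 1-based), `times` (numeric)
#'   and `usable` (FALSE when the patient has no events).
#' @export
flatten_events <- function(patient, vocabulary) {
  ev <- patient$events
  if (nrow(ev) == 0)
    return(list(codes = integer(0), times = numeric(0), usable = FALSE))
  idx <- match(ev$code, vocabulary)
  if (anyNA(idx))
    stop("code not in vocabulary: ",
         paste(unique(ev$code[is.na(idx)]), collapse = ", "))
  list(codes = as.integer(idx), times = as.numeric(ev$time), usable = TRUE)
}
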