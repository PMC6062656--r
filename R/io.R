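# CSV column contracts. All tables are comma-separated UTF-8 with a mandatory
# header row; timestamps are ISO-8601 without timezone (local ward time);
# empty cells are missing values.
OBS_COLUMNS <- c("admission_id", "timestamp", "hr", "rr", "sbp", "dbp",
                 "temp", "spo2", "avpu", "on_oxygen")
ADM_COLUMNS <- c("admission_id", "admit_time", "discharge_time", "age",
                 "specialty", "discharged_alive")
EVENT_COLUMNS <- c("admission_id", "event_type", "timestamp")

#' Read an observation-set table from CSV
#'
#' Columns: `admission_id`, `timestamp` (ISO-8601), `hr`, `rr`, `sbp`, `dbp`,
#' `temp`, `spo2` (numeric), `avpu` (`A`/`V`/`P`/`U`), `on_oxygen`
#' (`true`/`false`/`1`/`0`); empty cells are missing. Rows with unparseable
#' fields (a bad timestamp, an AVPU level outside the four, an SpO2 above
#' 100%) are not silently dropped: they are removed from the returned table
#' and collected into a `malformed` attribute naming the row, the field and
#' the offending value. Missing mandatory columns are an error.
#'
#' @param path CSV file path.
#' @return data.frame of typed observation rows, with attribute `"malformed"`
#'   (a data.frame `row`/`field`/`value`, zero rows when everything parsed).
#' @seealso [malformed_rows()], [write_observations()]
#' @export
read_observations <- function(path) {
  raw <- data.table::fread(path, colClasses = "character", na.strings = "",
                           data.table = FALSE)
  missing_cols <- setdiff(OBS_COLUMNS, names(raw))
  if (length(missing_cols) > 0L)
    stop("read_observations: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- data.frame(row = integer(0), field = character(0),
                    value = character(0), stringsAsFactors = FALSE)
  note_bad <- function(rows, field, values) {
    if (length(rows) > 0L)
      bad <<- rbind(bad, data.frame(row = rows, field = field,
                                    value = as.character(values),
                                    stringsAsFactors = FALSE))
  }
  out <- data.frame(admission_id = raw$admission_id, stringsAsFactors = FALSE)
  ts <- suppressWarnings(parse_timestamp(raw$timestamp))
  note_bad(which(is.na(ts) & !is.na(raw$timestamp)), "timestamp",
           raw$timestamp[is.na(ts) & !is.na(raw$timestamp)])
  note_bad(which(is.na(raw$timestamp)), "timestamp", NA)
  out$timestamp <- ts
  for (v in c("hr", "rr", "sbp", "dbp", "temp", "spo2")) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    badi <- which(is.na(x) & !is.na(raw[[v]]))
    note_bad(badi, v, raw[[v]][badi])
    if (v == "spo2") {
      oob <- which(!is.na(x) & (x < 0 | x > 100))
      note_bad(oob, v, x[oob])
      x[oob] <- NA_real_
    }
    out[[v]] <- x
  }
  av <- toupper(trimws(raw$avpu))
  badav <- which(!is.na(av) & !av %in% AVPU_LEVELS)
  note_bad(badav, "avpu", raw$avpu[badav])
  av[badav] <- NA_character_
  out$avpu <- av
  ox <- tolower(trimws(raw$on_oxygen))
  oxv <- rep(NA, nrow(raw))
  oxv[ox %in% c("true", "t", "1", "yes")] <- TRUE
  oxv[ox %in% c("false", "f", "0", "no")] <- FALSE
  badox <- which(!is.na(ox) & is.na(oxv))
  note_bad(badox, "on_oxygen", raw$on_oxygen[badox])
  out$on_oxygen <- oxv
  keep <- setdiff(seq_len(nrow(out)), unique(bad$row))
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "malformed") <- bad[order(bad$row), , drop = FALSE]
  res
}

#' Malformed-row report of a [read_observations()] result
#' @param x the data.frame returned by [read_observations()].
#' @return data.frame with columns `row`, `field`, `value`.
#' @export
malformed_rows <- function(x) {
  attr(x, "malformed") %||%
    data.frame(row = integer(0), field = character(0), value = character(0))
}

#' Write an observation-set table to CSV
#'
#' Inverse of [read_observations()]: the write-read round trip is lossless,
#' including missingness.
#'
#' @param observations data.frame of observation sets.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  df <- observations[, intersect(c(OBS_COLUMNS, "imputed"), names(observations)),
                     drop = FALSE]
  df$timestamp <- format_timestamp(parse_timestamp(df$timestamp))
  df$on_oxygen <- ifelse(is.na(df$on_oxygen), NA_character_,
                         ifelse(df$on_oxygen, "true", "false"))
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}

#' Read an admissions table from CSV
#'
#' Columns: `admission_id`, `admit_time`, `discharge_time` (ISO-8601), `age`
#' (years), `specialty`, `discharged_alive` (`true`/`false`).
#'
#' @param path CSV file path.
#' @return typed data.frame.
#' @export
read_admissions <- function(path) {
  df <- data.table::fread(path, colClasses = "character", na.strings = "",
                          data.table = FALSE)
  missing_cols <- setdiff(ADM_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("read_admissions: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df$admit_time <- parse_timestamp(df$admit_time)
  df$discharge_time <- parse_timestamp(df$discharge_time)
  df$age <- as.numeric(df$age)
  df$discharged_alive <- tolower(df$discharged_alive) %in% c("true", "t", "1", "yes")
  df
}

#' Write an admissions table to CSV
#' @param admissions data.frame of admissions.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(admissions, path) {
  df <- admissions[, ADM_COLUMNS, drop = FALSE]
  df$admit_time <- format_timestamp(parse_timestamp(df$admit_time))
  df$discharge_time <- format_timestamp(parse_timestamp(df$discharge_time))
  df$discharged_alive <- ifelse(df$discharged_alive, "true", "false")
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}

#' Read a clinical-events table from CSV
#'
#' Columns: `admission_id`, `event_type` (`death`, `cardiac_arrest`,
#' `unanticipated_icu`), `timestamp` (ISO-8601).
#'
#' @param path CSV file path.
#' @return typed data.frame.
#' @export
read_events <- function(path) {
  df <- data.table::fread(path, colClasses = "character", na.strings = "",
                          data.table = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("read_events: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$event_type %in% EVENT_TYPES))
    stop("read_events: unknown event type(s): ",
         paste(setdiff(unique(df$event_type), EVENT_TYPES), collapse = ", "))
  df$timestamp <- parse_timestamp(df$timestamp)
  df
}

#' Write a clinical-events table to CSV
#' @param events data.frame of events.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- events[, EVENT_COLUMNS, drop = FALSE]
  df$timestamp <- format_timestamp(parse_timestamp(df$timestamp))
  data.table::fwrite(df, path, na = "", quote = FALSE)
  invisible(path)
}

#' Write an EWS definition to a JSON config file
#'
#' One document per scoring system: name, oxygen increment, AVPU map, and the
#' per-variable band list (score, lower, upper; infinite bounds serialized as
#' `null`). The write-read round trip reproduces the definition exactly.
#'
#' @param definition an [ews_definition()].
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_ews_definition <- function(definition, path) {
  stopifnot(inherits(definition, "ews_definition"))
  doc <- list(
    name = definition$name,
    note = definition$note,
    oxygen_increment = definition$oxygen_increment,
    avpu_map = as.list(definition$avpu_map),
    variables = lapply(names(definition$tables), function(v) {
      bt <- definition$tables[[v]]
      list(variable = v,
           resolution = bt$resolution,
           admissible = lapply(bt$admissible,
                               function(x) if (is.finite(x)) x else NULL),
           bands = lapply(seq_len(nrow(bt$bands)), function(i)
             list(score = bt$bands$score[i],
                  lower = if (is.finite(bt$bands$lower[i])) bt$bands$lower[i],
                  upper = if (is.finite(bt$bands$upper[i])) bt$bands$upper[i])))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an EWS definition from a JSON config file
#'
#' Re-validates everything through the [band_table()] and [ews_definition()]
#' constructors, so a config with overlapping or gapped bands is rejected
#' with an error naming the variable.
#'
#' @param path path written by [write_ews_definition()] (or hand-authored in
#'   the same schema).
#' @return an [ews_definition()].
#' @export
read_ews_definition <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$name) || is.null(doc$variables) || is.null(doc$avpu_map))
    stop("read_ews_definition: config must define name, avpu_map and variables")
  tables <- list()
  for (vdoc in doc$variables) {
    v <- vdoc$variable
    if (is.null(v)) stop("read_ews_definition: a variable entry lacks 'variable'")
    bands <- vdoc$bands
    lowers <- vapply(bands, function(b) b$lower %||% -Inf, numeric(1))
    uppers <- vapply(bands, function(b) b$upper %||% Inf, numeric(1))
    scores <- vapply(bands, function(b) as.integer(b$score), integer(1))
    adm <- if (!is.null(vdoc$admissible))
      c(vdoc$admissible[[1]] %||% -Inf, vdoc$admissible[[2]] %||% Inf)
    tables[[v]] <- band_table(v, scores, lowers, uppers,
                              resolution = vdoc$resolution %||% 1,
                              admissible = adm)
  }
  avpu <- vapply(doc$avpu_map, as.integer, integer(1))
  ews_definition(name = doc$name, tables = tables, avpu_map = avpu,
                 oxygen_increment = doc$oxygen_increment %||% 0L,
                 note = doc$note %||% "")
}

#' Write centile specifications to a JSON config file
#' @param specs named list of [centile_spec()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centile_specs <- function(specs, path) {
  doc <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "centile_spec"))
    list(variable = sp$variable,
         resolution = sp$resolution,
         lower = as.list(sp$lower),
         upper = if (!is.null(sp$upper)) as.list(sp$upper))
  })
  jsonlite::write_json(unname(doc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read centile specifications from a JSON config file
#' @param path path written by [write_centile_specs()].
#' @return named list of [centile_spec()]s.
#' @export
read_centile_specs <- function(path) {
  doc <- jsonlite::read_json(path)
  specs <- lapply(doc, function(d) {
    centile_spec(d$variable,
                 lower = unlist(d$lower),
                 upper = if (!is.null(d$upper)) unlist(d$upper),
                 resolution = d$resolution %||% 1)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "variable")
  specs
}
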