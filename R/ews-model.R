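#' Score-band table for one vital sign
#'
#' A `band_table` is the per-variable half of a band-based early warning
#' score: an ordered set of contiguous value ranges ("bands"), each carrying
#' an integer sub-score in \{0, 1, 2, 3\}. Bands are stored with their
#' *printed* inclusive endpoints at the variable's charting resolution
#' (integers for most vitals, 0.1 degC for temperature), e.g. a band printed
#' "43-49" means 43 <= x <= 49. Internally the partition is half-open on a
#' grid shifted by half the resolution, so a non-integer reading such as a
#' heart rate of 104.5 falls in the band *above* the one ending at 104 rather
#' than being rejected.
#'
#' Invariants enforced at construction: bands tile the admissible range with
#' no gaps or overlaps (each band's lower bound is the previous band's upper
#' bound plus one resolution step); exactly one band scores 0; and sub-scores
#' are non-increasing up to the score-0 band then non-decreasing after it,
#' so moving away from the normal range never lowers the sub-score.
#'
#' @param variable variable name; one of `"hr"`, `"rr"`, `"sbp"`, `"temp"`,
#'   `"spo2"` for the shipped systems, but any name is accepted.
#' @param scores integer vector of sub-scores, one per band, ordered by band
#'   position (lowest values first).
#' @param lowers,uppers numeric vectors of printed inclusive band endpoints;
#'   `lowers[1]` may be `-Inf` and `uppers[length(uppers)]` may be `Inf`.
#' @param resolution charting resolution of the variable (default 1; use 0.1
#'   for temperature).
#' @param admissible length-2 numeric giving the physically admissible range
#'   of the variable; values outside it are scoring errors, not scores.
#'   Defaults to `c(0, 100)` for SpO2 and unrestricted otherwise.
#' @return an object of class `band_table`.
#' @seealso [sub_score()], [ews_definition()]
#' @export
band_table <- function(variable, scores, lowers, uppers,
                       resolution = if (identical(variable, "temp")) 0.1 else 1,
                       admissible = NULL) {
  stopifnot(is.character(variable), length(variable) == 1L, nzchar(variable))
  k <- length(scores)
  if (k < 2L || length(lowers) != k || length(uppers) != k)
    stop("band table for '", variable, "': scores, lowers and uppers must have equal length >= 2")
  scores <- as.integer(scores)
  if (anyNA(scores) || !all(scores %in% 0:3))
    stop("band table for '", variable, "': scores must be integers in 0..3")
  if (sum(scores == 0L) != 1L)
    stop("band table for '", variable, "': exactly one band must score 0")
  if (anyNA(lowers) || anyNA(uppers))
    stop("band table for '", variable, "': band endpoints must not be NA")
  if (any(lowers > uppers))
    stop("band table for '", variable, "': every band needs lower <= upper")
  # contiguity: next band starts one resolution step above this band's end
  gaps <- lowers[-1L] - (uppers[-k] + resolution)
  if (any(abs(gaps) > resolution * 1e-6)) {
    bad <- which(abs(gaps) > resolution * 1e-6)[1L]
    stop(sprintf(
      "band table for '%s': bands %d (ends %s) and %d (starts %s) %s",
      variable, bad, format(uppers[bad]), bad + 1L, format(lowers[bad + 1L]),
      if (gaps[bad] > 0) "leave a gap" else "overlap"))
  }
  i0 <- which(scores == 0L)
  if (is.unsorted(rev(scores[seq_len(i0)])) || is.unsorted(scores[i0:k]))
    stop("band table for '", variable,
         "': scores must not decrease moving away from the score-0 band")
  if (is.null(admissible))
    admissible <- if (identical(variable, "spo2")) c(0, 100) else c(-Inf, Inf)
  stopifnot(length(admissible) == 2L, admissible[1] < admissible[2])
  structure(
    list(variable = variable,
         resolution = resolution,
         bands = data.frame(score = scores, lower = lowers, upper = uppers),
         # half-open internal cut points: band i ends at uppers[i] + res/2
         cuts = uppers[-k] + resolution / 2,
         admissible = as.numeric(admissible)),
    class = "band_table")
}

#' Sub-score of a vital-sign value under a band table
#'
#' Locates each value in the band partition and returns that band's score.
#' The partition is half-open at internal boundaries shifted by half the
#' charting resolution, so printed inclusive endpoints behave as printed for
#' on-grid values while non-integer monitor readings are still scored.
#'
#' Missing values are an error by design: imputation is an upstream,
#' preprocessing concern (see [impute_observations()]), and a silent default
#' here could hide a pipeline bug.
#'
#' @param value numeric vector of values in the variable's units.
#' @param table a [band_table()].
#' @return integer vector of sub-scores in 0..3.
#' @export
sub_score <- function(value, table) {
  stopifnot(inherits(table, "band_table"))
  if (length(value) == 0L) return(integer(0))
  if (anyNA(value))
    stop("sub_score('", table$variable,
         "'): missing value; impute or drop the observation upstream")
  if (any(!is.finite(value)))
    stop("sub_score('", table$variable, "'): values must be finite")
  out <- value < table$admissible[1] | value > table$admissible[2]
  if (any(out))
    stop(sprintf("sub_score('%s'): value %s outside admissible range [%s, %s]",
                 table$variable, format(value[out][1L]),
                 format(table$admissible[1]), format(table$admissible[2])))
  table$bands$score[findInterval(value, table$cuts) + 1L]
}

#' A complete band-based early warning score definition
#'
#' Bundles per-variable [band_table()]s with the AVPU consciousness-level
#' sub-score map and the supplemental-oxygen increment into one scoring
#' system. The aggregate score of an observation set is the sum of the
#' per-variable sub-scores, the AVPU sub-score, and the oxygen increment when
#' the patient is on any supplemental oxygen. Diastolic blood pressure is
#' recorded in observation sets but never scored.
#'
#' @param name human-readable system name.
#' @param tables named list of [band_table()]s, keyed by variable.
#' @param avpu_map named integer vector with entries for all of `A`, `V`,
#'   `P`, `U`. Both centile-based systems and NEWS use A -> 0, V/P/U -> 3.
#' @param oxygen_increment non-negative integer added when `on_oxygen` is
#'   `TRUE` (2 for systems that score supplemental oxygen, 0 otherwise).
#' @param note free-text provenance note.
#' @return an object of class `ews_definition`.
#' @seealso [cews_manual()], [cews_continuous()], [news_definition()],
#'   [aggregate_score()], [derive_ews()]
#' @export
ews_definition <- function(name, tables, avpu_map, oxygen_increment = 0L,
                           note = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(tables) || length(tables) == 0L || is.null(names(tables)) ||
      any(!nzchar(names(tables))))
    stop("'tables' must be a non-empty named list of band tables")
  for (v in names(tables)) {
    if (!inherits(tables[[v]], "band_table"))
      stop("tables[['", v, "']] is not a band_table")
    if (!identical(tables[[v]]$variable, v))
      stop("tables[['", v, "']] is a table for variable '",
           tables[[v]]$variable, "'")
  }
  avpu_map <- avpu_map[AVPU_LEVELS]
  if (anyNA(avpu_map) || !identical(names(avpu_map), AVPU_LEVELS))
    stop("avpu_map must define integer sub-scores for all of A, V, P, U")
  avpu_map <- vapply(avpu_map, as.integer, integer(1))
  oxygen_increment <- as.integer(oxygen_increment)
  stopifnot(length(oxygen_increment) == 1L, !is.na(oxygen_increment),
            oxygen_increment >= 0L)
  structure(list(name = name, tables = tables, avpu_map = avpu_map,
                 oxygen_increment = oxygen_increment, note = note),
            class = "ews_definition")
}

#' AVPU sub-score
#'
#' @param level character vector of AVPU levels (`"A"`, `"V"`, `"P"`, `"U"`).
#' @param definition an [ews_definition()].
#' @return integer vector of sub-scores.
#' @export
avpu_sub_score <- function(level, definition) {
  stopifnot(inherits(definition, "ews_definition"))
  level <- as.character(level)
  if (anyNA(level) || !all(level %in% AVPU_LEVELS))
    stop("avpu_sub_score: AVPU level must be one of A, V, P, U (got ",
         paste(unique(level[!level %in% AVPU_LEVELS | is.na(level)]),
               collapse = ", "), ")")
  unname(definition$avpu_map[level])
}

#' Aggregate early warning scores for a table of observation sets
#'
#' Vectorised scoring: each row of `observations` must provide a non-missing
#' value for every variable in `definition$tables`, plus `avpu`, plus
#' `on_oxygen` when the definition carries a positive oxygen increment.
#' Missingness must have been resolved upstream (see
#' [preprocess_observations()]); a missing required value is an error naming
#' the variable.
#'
#' @param observations data.frame with one row per observation set; columns
#'   named as in [read_observations()] (`hr`, `rr`, `sbp`, `temp`, `spo2`,
#'   `avpu`, `on_oxygen`, ...).
#' @param definition an [ews_definition()].
#' @return integer vector of aggregate scores, one per row.
#' @seealso [aggregate_score()] for a single observation set.
#' @export
score_observations <- function(observations, definition) {
  stopifnot(is.data.frame(observations), inherits(definition, "ews_definition"))
  n <- nrow(observations)
  total <- integer(n)
  needed <- c(names(definition$tables), "avpu",
              if (definition$oxygen_increment > 0L) "on_oxygen")
  for (v in needed) {
    if (!v %in% names(observations))
      stop("score_observations: required column '", v, "' is absent")
    if (anyNA(observations[[v]]))
      stop("score_observations: missing values in required variable '", v,
           "'; run preprocessing/imputation first")
  }
  for (v in names(definition$tables))
    total <- total + sub_score(observations[[v]], definition$tables[[v]])
  total <- total + avpu_sub_score(observations$avpu, definition)
  if (definition$oxygen_increment > 0L)
    total <- total + definition$oxygen_increment *
      as.integer(as.logical(observations$on_oxygen))
  total
}

#' Aggregate early warning score of one observation set
#'
#' @param obs a list or one-row data.frame with the fields required by the
#'   definition (see [score_observations()]).
#' @inheritParams score_observations
#' @return a single integer aggregate score.
#' @export
aggregate_score <- function(obs, definition) {
  if (is.data.frame(obs)) {
    stopifnot(nrow(obs) == 1L)
    df <- obs
  } else {
    obs <- obs[!vapply(obs, is.null, logical(1))]
    df <- as.data.frame(obs, stringsAsFactors = FALSE)
  }
  score_observations(df, definition)
}

#' Printed range strings for a band table
#'
#' Formats each band the way track-and-trigger charts print them:
#' `"<= 42"`, `"43-49"`, `">= 128"`, or a single value for one-point bands.
#'
#' @param table a [band_table()].
#' @return character vector, one printed range per band.
#' @export
format_bands <- function(table) {
  stopifnot(inherits(table, "band_table"))
  b <- table$bands
  mapply(function(lo, hi) {
    if (is.infinite(lo) && is.infinite(hi)) "any"
    else if (is.infinite(lo)) paste0("<= ", format(hi))
    else if (is.infinite(hi)) paste0(">= ", format(lo))
    else if (lo == hi) format(lo)
    else paste0(format(lo), "-", format(hi))
  }, b$lower, b$upper)
}

#' @export
print.band_table <- function(x, ...) {
  cat(sprintf("Band table: %s (resolution %s)\n",
              VITAL_LABELS[x$variable] %||% x$variable,
              format(x$resolution)))
  df <- data.frame(range = format_bands(x), score = x$bands$score)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.ews_definition <- function(x, ...) {
  cat(sprintf("EWS definition: %s\n", x$name))
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  for (v in names(x$tables)) {
    bt <- x$tables[[v]]
    cat(sprintf("  %-28s %s\n", VITAL_LABELS[v] %||% v,
                paste(sprintf("%s:%d", format_bands(bt), bt$bands$score),
                      collapse = "  ")))
  }
  cat(sprintf("  %-28s %s\n", "AVPU",
              paste(sprintf("%s:%d", names(x$avpu_map), x$avpu_map),
                    collapse = "  ")))
  cat(sprintf("  %-28s +%d if on supplemental oxygen\n", "Oxygen",
              x$oxygen_increment))
  invisible(x)
}
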