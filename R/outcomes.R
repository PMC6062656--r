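EVENT_TYPES <- c("death", "cardiac_arrest", "unanticipated_icu")

# deterministic priority for simultaneous events; only matters for
# individual-outcome analyses, never for the composite label
EVENT_PRIORITY <- c(death = 1L, cardiac_arrest = 2L, unanticipated_icu = 3L)

#' First adverse event of an admission
#'
#' Returns the earliest event; when several events share the earliest
#' timestamp, the tie is broken by the fixed priority death > cardiac arrest
#' > unanticipated ICU admission so the result is deterministic.
#'
#' @param events data.frame with columns `admission_id`, `event_type`
#'   (`"death"`, `"cardiac_arrest"`, `"unanticipated_icu"`), `timestamp`,
#'   all rows belonging to one admission.
#' @return a one-row data.frame, or `NULL` when there are no events.
#' @export
first_event <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  if (length(unique(events$admission_id)) != 1L)
    stop("first_event: events must belong to a single admission")
  if (!all(events$event_type %in% EVENT_TYPES))
    stop("first_event: unknown event type(s): ",
         paste(setdiff(unique(events$event_type), EVENT_TYPES), collapse = ", "))
  ts <- parse_timestamp(events$timestamp)
  ord <- order(ts, EVENT_PRIORITY[events$event_type])
  out <- events[ord[1L], , drop = FALSE]
  out$timestamp <- ts[ord[1L]]
  rownames(out) <- NULL
  out
}

# first event per admission for a whole events table; returns a data.frame
# keyed by admission_id (zero rows if no events)
first_events_by_admission <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(admission_id = character(0), event_type = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC")))
  ev <- data.table::as.data.table(events)
  ev[, timestamp := parse_timestamp(timestamp)]
  if (!all(ev$event_type %in% EVENT_TYPES))
    stop("unknown event type(s): ",
         paste(setdiff(unique(ev$event_type), EVENT_TYPES), collapse = ", "))
  ev[, prio := EVENT_PRIORITY[event_type]]
  data.table::setorder(ev, admission_id, timestamp, prio)
  out <- ev[, .SD[1L], by = admission_id][, prio := NULL]
  as.data.frame(out)
}

#' Label observation sets with the composite outcome within a horizon
#'
#' For each admission the composite outcome is the *first* occurrence of
#' cardiac arrest, unanticipated ICU admission, or death; later events are
#' ignored. Observation sets at or after the first event are excluded from
#' the labeled data. A retained observation is labeled positive when the
#' first event falls inside the half-open window `(t_obs, t_obs + horizon]`
#' (an event at exactly `t_obs + horizon` hours counts; an event at exactly
#' `t_obs` excludes the observation, since the observation is not strictly
#' before it). Admissions without events contribute all-negative labels.
#'
#' For individual-outcome analyses pass `outcome_type`: exclusion is still
#' governed by the first event of *any* type, but only first events of the
#' requested type produce positive labels (an admission whose first event is
#' death contributes no positives to the cardiac-arrest analysis).
#'
#' @param observations data.frame of (preprocessed) observation sets with
#'   `admission_id` and `timestamp`.
#' @param events data.frame of clinical events (see [first_event()]).
#' @param horizon horizon T in hours (e.g. 12, 24, 48); must be positive.
#' @param outcome_type optional single event type restricting which first
#'   events count as positives; `NULL` (default) gives the composite outcome.
#' @return list with `labeled` (the retained observations plus columns
#'   `label` (logical) and `hours_to_event` (NA when the admission has no
#'   event)) and `n_excluded` (observations at or after the first event).
#' @export
label_observations <- function(observations, events, horizon,
                               outcome_type = NULL) {
  stopifnot(is.data.frame(observations))
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0)
    stop("label_observations: horizon must be a positive number of hours")
  if (!is.null(outcome_type))
    stopifnot(outcome_type %in% EVENT_TYPES)
  fe <- first_events_by_admission(events)
  obs <- as.data.frame(observations)
  obs$timestamp <- parse_timestamp(obs$timestamp)
  idx <- match(obs$admission_id, fe$admission_id)
  t_event <- fe$timestamp[idx]           # NA for event-free admissions
  type_event <- fe$event_type[idx]
  dt_hours <- hours_between(obs$timestamp, t_event)
  exclude <- !is.na(dt_hours) & dt_hours <= 0
  label <- !is.na(dt_hours) & dt_hours > 0 & dt_hours <= horizon
  if (!is.null(outcome_type))
    label <- label & !is.na(type_event) & type_event == outcome_type
  labeled <- obs[!exclude, , drop = FALSE]
  labeled$label <- label[!exclude]
  labeled$hours_to_event <- dt_hours[!exclude]
  rownames(labeled) <- NULL
  list(labeled = labeled, n_excluded = sum(exclude))
}
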