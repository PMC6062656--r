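#' Default physiological plausibility ranges
#'
#' Permissive per-variable admissible ranges used to drop observation values
#' that can only be data-entry errors (a temperature of 3.6 degC, an SpO2 of
#' 150%). These are deliberately wide: they are not reference ranges, only a
#' guard against implausible charting. All are configurable.
#'
#' @return named list of `c(min, max)` vectors for `hr` (10-300 beats/min),
#'   `rr` (1-80 breaths/min), `sbp` (30-300 mmHg), `temp` (25-45 degC) and
#'   `spo2` (10-100 %).
#' @export
default_plausibility_ranges <- function() {
  list(hr = c(10, 300), rr = c(1, 80), sbp = c(30, 300),
       temp = c(25, 45), spo2 = c(10, 100))
}

#' Apply admission-level inclusion rules
#'
#' Filters an admissions table by the four cohort rules, applied
#' sequentially: (1) adults only (age at least `min_age` years); (2) the
#' admitting specialty is not palliative medicine; (3) patients discharged
#' alive before midnight at the end of the admission calendar day are
#' excluded (a discharge at 00:30 the next day is included); (4) the
#' admission has at least one *complete* observation set (all scored
#' measurements present, AVPU and the oxygen flag included).
#'
#' @param admissions data.frame with columns `admission_id`, `age`,
#'   `specialty`, `admit_time`, `discharge_time`, `discharged_alive`.
#' @param observations data.frame of observation sets (see
#'   [read_observations()]) used for rule 4.
#' @param min_age minimum age in years (default 16).
#' @param excluded_specialties character vector of specialties excluded at
#'   admission (default `"palliative medicine"`, matched case-insensitively).
#' @return a list of class `admission_filter` with `included_ids`,
#'   `n_input`, `n_included`, and `exclusions` (named counts per rule, each
#'   admission counted once against the first rule it fails).
#' @export
filter_admissions <- function(admissions, observations, min_age = 16,
                              excluded_specialties = "palliative medicine") {
  required <- c("admission_id", "age", "specialty", "admit_time",
                "discharge_time", "discharged_alive")
  missing_cols <- setdiff(required, names(admissions))
  if (length(missing_cols) > 0L)
    stop("filter_admissions: admissions table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  adm <- as.data.frame(admissions)
  adm$admit_time <- parse_timestamp(adm$admit_time)
  adm$discharge_time <- parse_timestamp(adm$discharge_time)
  if (anyNA(adm$age) || anyNA(adm$admit_time) || anyNA(adm$discharge_time) ||
      anyNA(adm$discharged_alive))
    stop("filter_admissions: admissions table has missing required fields")

  underage <- adm$age < min_age
  palliative <- !underage &
    tolower(trimws(adm$specialty)) %in% tolower(excluded_specialties)
  # "before midnight on the day of admission": same local calendar day
  same_day <- as.Date(adm$discharge_time, tz = "UTC") <=
    as.Date(adm$admit_time, tz = "UTC")
  same_day_alive <- !underage & !palliative & same_day &
    as.logical(adm$discharged_alive)

  complete_ids <- complete_obs_admissions(observations)
  no_complete <- !underage & !palliative & !same_day_alive &
    !(adm$admission_id %in% complete_ids)

  included <- !(underage | palliative | same_day_alive | no_complete)
  structure(list(
    included_ids = adm$admission_id[included],
    n_input = nrow(adm),
    n_included = sum(included),
    exclusions = c(underage = sum(underage),
                   palliative_specialty = sum(palliative),
                   same_day_alive_discharge = sum(same_day_alive),
                   no_complete_observation = sum(no_complete))),
    class = "admission_filter")
}

# admission ids owning at least one observation set with every scored
# measurement present (five vitals + AVPU + oxygen flag)
complete_obs_admissions <- function(observations) {
  fields <- c(VITAL_VARS, "avpu", "on_oxygen")
  miss <- setdiff(fields, names(observations))
  if (length(miss) > 0L)
    stop("observations table lacks column(s): ", paste(miss, collapse = ", "))
  complete <- !Reduce(`|`, lapply(observations[fields], is.na))
  unique(observations$admission_id[complete])
}

#' @export
print.admission_filter <- function(x, ...) {
  cat(sprintf("Admission filter: %d of %d admissions included\n",
              x$n_included, x$n_input))
  for (r in names(x$exclusions))
    cat(sprintf("  excluded (%s): %d\n", r, x$exclusions[[r]]))
  invisible(x)
}

#' Validate observation sets against missingness and plausibility rules
#'
#' Returns a per-row verdict: an observation set is dropped when more than
#' `max_missing` of its scored measurements are absent, or when any present
#' value falls outside its plausibility range. By default AVPU and the
#' supplemental-oxygen flag count towards the missing-measurement tally
#' alongside the five continuous vitals (switchable, since "measurement" is
#' not crisply defined in routine charting); diastolic pressure never counts,
#' as it is recorded but never scored.
#'
#' @param observations data.frame of observation sets.
#' @param ranges plausibility ranges, as [default_plausibility_ranges()].
#' @param max_missing maximum tolerated number of missing measurements
#'   (default 2).
#' @param count_avpu_oxygen should AVPU and `on_oxygen` count as
#'   measurements in the missingness tally? Default `TRUE`.
#' @return character vector, one of `"keep"`, `"too_many_missing"`,
#'   `"implausible"` per row.
#' @export
validate_observations <- function(observations,
                                  ranges = default_plausibility_ranges(),
                                  max_missing = 2L,
                                  count_avpu_oxygen = TRUE) {
  stopifnot(is.data.frame(observations))
  missing_rng <- setdiff(VITAL_VARS, names(ranges))
  if (length(missing_rng) > 0L)
    stop("validate_observations: no plausibility range for: ",
         paste(missing_rng, collapse = ", "))
  fields <- c(VITAL_VARS, if (count_avpu_oxygen) c("avpu", "on_oxygen"))
  n_missing <- Reduce(`+`, lapply(observations[fields],
                                  function(x) as.integer(is.na(x))))
  implausible <- rep(FALSE, nrow(observations))
  for (v in VITAL_VARS) {
    x <- observations[[v]]
    implausible <- implausible |
      (!is.na(x) & (x < ranges[[v]][1] | x > ranges[[v]][2]))
  }
  verdict <- rep("keep", nrow(observations))
  verdict[implausible] <- "implausible"
  verdict[n_missing > max_missing] <- "too_many_missing"
  verdict
}

#' Population means of the scored vital signs
#'
#' Computes the per-variable mean over a development observation table, for
#' use as imputation values. When the same development data also drive
#' threshold derivation, each mean falls inside its variable's score-0 band,
#' which is exactly what makes mean imputation score-neutral.
#'
#' @param observations data.frame of development observation sets.
#' @return a named list of class `population_means` with the five vital-sign
#'   means plus the categorical imputation values `avpu = "A"` (the modal
#'   level by a wide margin) and `on_oxygen = FALSE`.
#' @export
population_means <- function(observations) {
  stopifnot(is.data.frame(observations), nrow(observations) > 0L)
  m <- lapply(VITAL_VARS, function(v) mean(observations[[v]], na.rm = TRUE))
  names(m) <- VITAL_VARS
  if (anyNA(unlist(m)))
    stop("population_means: a variable has no non-missing values")
  structure(c(m, list(avpu = "A", on_oxygen = FALSE)),
            class = "population_means")
}

#' Mean-impute missing measurements in validated observation sets
#'
#' Replaces each missing scored measurement by its development-population
#' mean ([population_means()]); missing AVPU becomes `"A"` and a missing
#' oxygen flag becomes `FALSE` (the modal values, the categorical analogue of
#' mean imputation). Non-missing values are untouched. The names of imputed
#' variables are recorded per row in an `imputed` column
#' (semicolon-separated, empty when nothing was imputed).
#'
#' @param observations data.frame of observation sets that passed
#'   [validate_observations()].
#' @param means a [population_means()] object (or compatible named list).
#' @return the completed data.frame with an `imputed` column.
#' @export
impute_observations <- function(observations, means) {
  stopifnot(is.data.frame(observations))
  fields <- c(VITAL_VARS, "avpu", "on_oxygen")
  obs <- as.data.frame(observations)
  flags <- rep("", nrow(obs))
  for (v in fields) {
    miss <- is.na(obs[[v]])
    if (!any(miss)) next
    if (is.null(means[[v]]))
      stop("impute_observations: no imputation value for missing variable '",
           v, "'")
    obs[[v]][miss] <- means[[v]]
    flags[miss] <- ifelse(nzchar(flags[miss]),
                          paste(flags[miss], v, sep = ";"), v)
  }
  obs$imputed <- flags
  obs
}

#' Validate, drop and impute in one pass
#'
#' Convenience wrapper: applies [validate_observations()], drops rows with a
#' non-keep verdict, and mean-imputes the remainder. If `means` is omitted
#' they are computed from the kept rows themselves (appropriate for a
#' development dataset; pass development means explicitly when preprocessing
#' a validation dataset).
#'
#' @inheritParams validate_observations
#' @param means optional [population_means()]; computed from the kept rows
#'   when `NULL`.
#' @return list with `observations` (cleaned, imputed), `means` (the means
#'   used), and `report` (named drop counts).
#' @export
preprocess_observations <- function(observations,
                                    ranges = default_plausibility_ranges(),
                                    means = NULL,
                                    max_missing = 2L,
                                    count_avpu_oxygen = TRUE) {
  verdict <- validate_observations(observations, ranges, max_missing,
                                   count_avpu_oxygen)
  kept <- observations[verdict == "keep", , drop = FALSE]
  if (nrow(kept) == 0L) stop("preprocess_observations: no observation sets survive validation")
  if (is.null(means)) means <- population_means(kept)
  list(observations = impute_observations(kept, means),
       means = means,
       report = c(kept = sum(verdict == "keep"),
                  too_many_missing = sum(verdict == "too_many_missing"),
                  implausible = sum(verdict == "implausible")))
}
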