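#' Marginal distribution with an exact quantile function
#'
#' The generator only uses distribution families whose CDFs are available in
#' closed form and whose quantile functions are therefore exact (directly for
#' `"uniform"` and `"truncnorm"`, by monotone bisection of the closed-form
#' CDF to ~1e-12 for `"mixnorm"`), so that every derived threshold can be
#' checked against the generator's own truth. Families:
#' \describe{
#'   \item{truncnorm}{`mean`, `sd`, `lower`, `upper`.}
#'   \item{uniform}{`min`, `max`.}
#'   \item{mixnorm}{two-component normal mixture truncated to
#'     `[lower, upper]`: `mean1`, `sd1`, `mean2`, `sd2`, `w1` (weight of the
#'     first component). Used for vitals whose bulk is tight but whose tails
#'     are heavy, like manually charted respiratory rate.}
#' }
#'
#' @param family `"truncnorm"`, `"uniform"` or `"mixnorm"`.
#' @param ... family parameters (see above).
#' @return object of class `marginal_dist` with `family`, `params`,
#'   `quantile(p)` and `sample(n)` functions.
#' @export
marginal_dist <- function(family = c("truncnorm", "uniform", "mixnorm"), ...) {
  family <- match.arg(family)
  params <- list(...)
  if (family == "truncnorm") {
    stopifnot(all(c("mean", "sd", "lower", "upper") %in% names(params)),
              params$sd > 0, params$lower < params$upper)
    fa <- stats::pnorm((params$lower - params$mean) / params$sd)
    fb <- stats::pnorm((params$upper - params$mean) / params$sd)
    qfun <- function(p) {
      stopifnot(all(p >= 0 & p <= 1))
      params$mean + params$sd * stats::qnorm(fa + p * (fb - fa))
    }
  } else if (family == "uniform") {
    stopifnot(all(c("min", "max") %in% names(params)),
              params$min < params$max)
    qfun <- function(p) {
      stopifnot(all(p >= 0 & p <= 1))
      params$min + p * (params$max - params$min)
    }
  } else {
    stopifnot(all(c("mean1", "sd1", "mean2", "sd2", "w1", "lower", "upper") %in%
                    names(params)),
              params$sd1 > 0, params$sd2 > 0,
              params$w1 >= 0, params$w1 <= 1,
              params$lower < params$upper)
    cdf_raw <- function(x)
      params$w1 * stats::pnorm((x - params$mean1) / params$sd1) +
      (1 - params$w1) * stats::pnorm((x - params$mean2) / params$sd2)
    fa <- cdf_raw(params$lower); fb <- cdf_raw(params$upper)
    qfun <- function(p) {
      stopifnot(all(p >= 0 & p <= 1))
      target <- fa + p * (fb - fa)
      lo <- rep(params$lower, length(p)); hi <- rep(params$upper, length(p))
      for (i in 1:60) {            # bisection: exact CDF, monotone, ~1e-12
        mid <- (lo + hi) / 2
        below <- cdf_raw(mid) < target
        lo[below] <- mid[below]; hi[!below] <- mid[!below]
      }
      (lo + hi) / 2
    }
  }
  structure(list(family = family, params = params, quantile = qfun,
                 sample = function(n) qfun(stats::runif(n))),
            class = "marginal_dist")
}

#' Default vital-sign marginals of the synthetic ward cohort
#'
#' Simple parametric families matched to the development-cohort summary
#' statistics of manually charted ward observations (medians/IQRs roughly:
#' heart rate 82 (71-93) beats/min, respiratory rate 17 (16-18) breaths/min,
#' systolic pressure 123 (110-138) mmHg, temperature 36.3 (36.0-36.7) degC,
#' SpO2 97 (95-98) %). Truncated normals are used except for respiratory
#' rate, whose charted distribution pairs a very tight bulk (IQR of 2
#' breaths/min) with heavy tails reaching the high twenties: a two-component
#' normal mixture reproduces both. The SpO2 marginal is truncated at 100%,
#' which gives its one-sided, left-skewed shape. These are summary-statistic
#' matches, not density replicas of real charted data; the severity shift of
#' [generate_cohort()] additionally moves whole-cohort medians slightly
#' towards the deteriorating tails.
#'
#' @return named list of [marginal_dist()] objects for the five vitals.
#' @export
default_marginals <- function() {
  list(
    hr = marginal_dist("truncnorm", mean = 82, sd = 16.3, lower = 25, upper = 220),
    rr = marginal_dist("mixnorm", mean1 = 17, sd1 = 1.3, mean2 = 17, sd2 = 6,
                       w1 = 0.8, lower = 4, upper = 60),
    sbp = marginal_dist("truncnorm", mean = 124, sd = 20.8, lower = 40, upper = 260),
    temp = marginal_dist("truncnorm", mean = 36.35, sd = 0.52, lower = 30, upper = 43),
    spo2 = marginal_dist("truncnorm", mean = 97.5, sd = 2.5, lower = 70, upper = 100))
}

#' Configuration of the synthetic ward cohort generator
#'
#' All knobs of [generate_cohort()] with defaults emulating the published
#' development/validation cohorts' stated world: marginals matched to the
#' charted vital-sign summary statistics, a composite-outcome prevalence of
#' about 7% of admissions, AVPU overwhelmingly "Alert" (98.2%), supplemental
#' oxygen on 17.8% of observation sets, and observation sets charted roughly
#' every 6 hours.
#'
#' The latent structure: each admission carries a severity `s ~ Exp(1)`.
#' Event probability is `plogis(alpha + hazard_slope * s)` with `alpha`
#' calibrated so the expected prevalence matches `prevalence`. Vital signs
#' are shifted towards their abnormal tails in Gaussian-copula space by
#' `effect_size * s * w(t)`, where the proximity weight `w(t)` rises from
#' `proximity_weight_floor` towards 1 as the observation approaches the
#' event time (time constant `proximity_tau_hours`); with
#' `effect_size = 0` vitals are independent of severity and any EWS is
#' uninformative by construction. Shift directions are fixed at the
#' clinically deteriorating tails (heart/respiratory rate up, systolic
#' pressure and SpO2 down, temperature direction random per admission).
#'
#' @param n_admissions number of admissions.
#' @param seed integer RNG seed; everything the generator draws depends on it.
#' @param marginals named list of [marginal_dist()]s (see
#'   [default_marginals()]).
#' @param obs_min,obs_pois_mean observations per admission:
#'   `obs_min + rpois(obs_pois_mean)`.
#' @param obs_interval_hours nominal charting interval.
#' @param avpu_probs baseline AVPU level probabilities (named, sums to 1).
#' @param oxygen_rate baseline supplemental-oxygen probability.
#' @param missing_rate per-variable missingness probability for the five
#'   continuous vitals; AVPU and the oxygen flag go missing at a quarter of
#'   this rate.
#' @param implausible_rate probability an observation set carries one
#'   injected physiologically-implausible value.
#' @param effect_size severity-to-vitals effect size delta (>= 0).
#' @param hazard_slope slope of severity in the event logit.
#' @param prevalence target fraction of admissions with a composite event.
#' @param proximity_tau_hours time constant of pre-event deterioration.
#' @param proximity_weight_floor baseline proximity weight for observations
#'   far from any event (and for event-free admissions).
#' @param underage_rate,palliative_rate,same_day_rate injection rates of
#'   admissions that the cohort filters should exclude (younger than 16,
#'   palliative-medicine specialty, same-day live discharge).
#' @param second_event_rate probability an event admission has a second,
#'   later event (exercises first-event censoring).
#' @param post_event_obs_rate probability the last observation of an event
#'   admission is charted after the event (exercises post-event exclusion).
#' @param event_type_probs named probabilities of the *first* event type.
#' @param rr_heaping if `TRUE`, respiratory-rate readings are heaped onto
#'   even values with probability 0.5, mimicking manual-charting digit
#'   preference (default off).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_admissions = 1000L,
                          seed = 1L,
                          marginals = default_marginals(),
                          obs_min = 4L,
                          obs_pois_mean = 8,
                          obs_interval_hours = 6,
                          avpu_probs = c(A = 0.982, V = 0.015, P = 0.002, U = 0.001),
                          oxygen_rate = 0.178,
                          missing_rate = 0.02,
                          implausible_rate = 0.002,
                          effect_size = 1.0,
                          hazard_slope = 2.0,
                          prevalence = 0.07,
                          proximity_tau_hours = 18,
                          proximity_weight_floor = 0.3,
                          underage_rate = 0.01,
                          palliative_rate = 0.005,
                          same_day_rate = 0.03,
                          second_event_rate = 0.25,
                          post_event_obs_rate = 0.3,
                          event_type_probs = c(death = 0.75,
                                               unanticipated_icu = 0.20,
                                               cardiac_arrest = 0.05),
                          rr_heaping = FALSE) {
  rates <- c(oxygen_rate, missing_rate, implausible_rate, underage_rate,
             palliative_rate, same_day_rate, second_event_rate,
             post_event_obs_rate)
  if (any(rates < 0 | rates > 1)) stop("cohort_config: rates must lie in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1)
    stop("cohort_config: prevalence must lie strictly inside (0, 1)")
  if (effect_size < 0) stop("cohort_config: effect_size must be >= 0")
  stopifnot(n_admissions >= 1, obs_min >= 1, obs_interval_hours > 0,
            proximity_tau_hours > 0,
            proximity_weight_floor >= 0, proximity_weight_floor <= 1)
  if (!setequal(names(avpu_probs), AVPU_LEVELS) ||
      abs(sum(avpu_probs) - 1) > 1e-8)
    stop("cohort_config: avpu_probs must cover A, V, P, U and sum to 1")
  if (!setequal(names(event_type_probs), EVENT_TYPES) ||
      abs(sum(event_type_probs) - 1) > 1e-8)
    stop("cohort_config: event_type_probs must cover the three event types and sum to 1")
  for (v in VITAL_VARS)
    if (!inherits(marginals[[v]], "marginal_dist"))
      stop("cohort_config: marginals must contain a marginal_dist for '", v, "'")
  structure(as.list(environment()), class = "cohort_config")
}

#' Draw an i.i.d. sample from one configured marginal
#'
#' Feeds threshold-derivation recovery tests: the returned quantile function
#' is the exact truth the derived thresholds are compared against. Values
#' are *not* rounded to charting resolution here; [generate_cohort()] does
#' that for its observation tables.
#'
#' @param variable one of the configured vitals.
#' @param n sample size (>= 1).
#' @param config a [cohort_config()].
#' @param seed RNG seed (defaults to the config's).
#' @return list with `samples` (length n) and `quantile` (function of p).
#' @export
generate_marginal_sample <- function(variable, n, config = cohort_config(),
                                     seed = config$seed) {
  if (!variable %in% names(config$marginals))
    stop("generate_marginal_sample: unknown variable '", variable, "'")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("generate_marginal_sample: n must be >= 1")
  m <- config$marginals[[variable]]
  set.seed(as.integer(seed))
  list(samples = m$sample(as.integer(n)), quantile = m$quantile,
       family = m$family)
}

# charting resolution used when writing vitals into observation tables
charting_resolution <- c(hr = 1, rr = 1, sbp = 1, temp = 0.1, spo2 = 1)

# deteriorating-tail direction of each vital in Gaussian-copula space
SHIFT_DIRECTION <- c(hr = 1, rr = 1, sbp = -1, spo2 = -1)  # temp: per admission

#' Generate a synthetic ward cohort
#'
#' Produces the three tables every other module consumes -- admissions,
#' timed vital-sign observation sets, and clinical events -- plus a truth
#' object sufficient to compute any marginal centile analytically and to
#' audit the event generation. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `admissions`, `observations`, `events` (data.frames in
#'   the package's CSV column conventions) and `truth` (list: per-variable
#'   quantile functions, per-admission severity, event calibration intercept
#'   `alpha`, realized prevalence, and the event record).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  set.seed(as.integer(cf$seed))
  n <- as.integer(cf$n_admissions)
  adm_id <- sprintf("adm%06d", seq_len(n))

  severity <- stats::rexp(n)
  age <- round(marginal_dist("truncnorm", mean = 61, sd = 17,
                             lower = 16, upper = 100)$sample(n))
  specialty <- sample(c("general medicine", "general surgery"), n,
                      replace = TRUE, prob = c(0.6, 0.4))

  # admissions the cohort filters are meant to exclude
  underage <- stats::runif(n) < cf$underage_rate
  age[underage] <- sample(8:15, sum(underage), replace = TRUE)
  palliative <- !underage & stats::runif(n) < cf$palliative_rate
  specialty[palliative] <- "palliative medicine"
  same_day <- !underage & !palliative & stats::runif(n) < cf$same_day_rate
  injected <- underage | palliative | same_day

  # event calibration on the eligible subset so the *overall* expected
  # prevalence hits the target; infeasible targets error out
  eligible <- !injected
  target_elig <- cf$prevalence * n / sum(eligible)
  if (target_elig >= 1)
    stop("generate_cohort: infeasible config - target prevalence cannot be reached")
  mean_prev <- function(a) mean(stats::plogis(a + cf$hazard_slope * severity[eligible]))
  alpha <- stats::uniroot(function(a) mean_prev(a) - target_elig,
                          lower = -40, upper = 10, tol = 1e-10)$root
  has_event <- eligible &
    stats::rbinom(n, 1L, stats::plogis(alpha + cf$hazard_slope * severity)) == 1L

  n_obs <- cf$obs_min + stats::rpois(n, cf$obs_pois_mean)
  n_obs[same_day] <- 2L
  admit_day <- as.POSIXct("2014-03-24 00:00:00", tz = "UTC") +
    86400 * floor(stats::runif(n, 0, 550))
  admit_time <- admit_day + 3600 * stats::runif(n, 7, 20)
  admit_time[same_day] <- admit_day[same_day] + 3600 * 9

  # event time anchored to a late observation; sometimes one observation is
  # charted after the event to exercise post-event exclusion downstream
  anchor <- pmax(n_obs - stats::rbinom(n, 1L, cf$post_event_obs_rate), 2L)
  t_event_off <- (anchor - 1) * cf$obs_interval_hours + stats::runif(n, 2, 12)

  # ---- observation-level quantities ----
  N <- sum(n_obs)
  adm <- rep(seq_len(n), n_obs)
  k <- sequence(n_obs)
  obs_off <- (k - 1) * cf$obs_interval_hours +
    stats::runif(N, 0, cf$obs_interval_hours / 3)
  w <- rep(cf$proximity_weight_floor, N)
  ev_rows <- has_event[adm]
  dtte <- pmax(t_event_off[adm] - obs_off, 0)
  w[ev_rows] <- cf$proximity_weight_floor +
    (1 - cf$proximity_weight_floor) * exp(-dtte[ev_rows] / cf$proximity_tau_hours)
  shift <- cf$effect_size * severity[adm] * w

  temp_dir <- sample(c(-1, 1), n, replace = TRUE)
  vital <- list()
  for (v in VITAL_VARS) {
    dir_v <- if (v == "temp") temp_dir[adm] else SHIFT_DIRECTION[[v]]
    u <- stats::runif(N)
    p <- stats::pnorm(stats::qnorm(u) + dir_v * shift)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    x <- cf$marginals[[v]]$quantile(p)
    if (v == "rr" && cf$rr_heaping) {
      heap <- stats::runif(N) < 0.5
      x[heap] <- 2 * round(x[heap] / 2)
    }
    vital[[v]] <- round_to(x, charting_resolution[[v]])
  }

  p_na_base <- 1 - cf$avpu_probs[["A"]]
  p_na <- stats::plogis(stats::qlogis(p_na_base) + shift)
  avpu <- rep("A", N)
  nonalert <- stats::runif(N) < p_na
  if (any(nonalert)) {
    vpu <- cf$avpu_probs[c("V", "P", "U")]
    avpu[nonalert] <- sample(c("V", "P", "U"), sum(nonalert), replace = TRUE,
                             prob = vpu / sum(vpu))
  }
  on_oxygen <- stats::runif(N) <
    stats::plogis(stats::qlogis(cf$oxygen_rate) + 0.7 * shift)

  # missingness and implausible-value injection (what preprocessing removes)
  for (v in VITAL_VARS)
    vital[[v]][stats::runif(N) < cf$missing_rate] <- NA_real_
  avpu[stats::runif(N) < cf$missing_rate / 4] <- NA_character_
  on_oxygen[stats::runif(N) < cf$missing_rate / 4] <- NA
  implausible_vals <- c(hr = 350, rr = 90, sbp = 350, temp = 49.5, spo2 = 5)
  bad <- which(stats::runif(N) < cf$implausible_rate)
  if (length(bad) > 0L) {
    bad_var <- sample(VITAL_VARS, length(bad), replace = TRUE)
    for (v in VITAL_VARS) {
      rows <- bad[bad_var == v]
      if (length(rows)) vital[[v]][rows] <- implausible_vals[[v]]
    }
  }

  observations <- data.frame(
    admission_id = adm_id[adm],
    timestamp = admit_time[adm] + 3600 * obs_off,
    hr = vital$hr, rr = vital$rr, sbp = vital$sbp,
    dbp = round(vital$sbp * 0.62 + stats::rnorm(N, 0, 6)),
    temp = vital$temp, spo2 = pmin(vital$spo2, 100),
    avpu = avpu, on_oxygen = on_oxygen,
    stringsAsFactors = FALSE)

  # ---- events ----
  ev_idx <- which(has_event)
  ev_type <- sample(names(cf$event_type_probs), length(ev_idx), replace = TRUE,
                    prob = cf$event_type_probs)
  ev_time <- admit_time[ev_idx] + 3600 * t_event_off[ev_idx]
  second <- stats::runif(length(ev_idx)) < cf$second_event_rate &
    ev_type != "death"
  ev2_type <- rep("death", length(ev_idx))  # deterioration cascades end in death
  ev2_time <- ev_time + 3600 * stats::runif(length(ev_idx), 1, 24)
  events <- data.frame(
    admission_id = c(adm_id[ev_idx], adm_id[ev_idx][second]),
    event_type = c(ev_type, ev2_type[second]),
    timestamp = c(ev_time, ev2_time[second]),
    stringsAsFactors = FALSE)
  events <- events[order(events$admission_id, events$timestamp), , drop = FALSE]
  rownames(events) <- NULL

  # ---- discharge ----
  last_obs <- admit_time + 3600 * ((n_obs - 1) * cf$obs_interval_hours +
                                     cf$obs_interval_hours / 3)
  discharge <- last_obs + 3600 * stats::runif(n, 4, 48)
  discharged_alive <- rep(TRUE, n)
  final_death <- vapply(split(events$timestamp[events$event_type == "death"],
                              events$admission_id[events$event_type == "death"]),
                        max, numeric(1))
  if (length(final_death) > 0L) {
    di <- match(names(final_death), adm_id)
    discharge[di] <- as.POSIXct(final_death, tz = "UTC",
                                origin = "1970-01-01")
    discharged_alive[di] <- FALSE
  }
  # events must precede discharge for non-death admissions too
  ev_last <- vapply(split(as.numeric(events$timestamp), events$admission_id),
                    max, numeric(1))
  if (length(ev_last) > 0L) {
    di <- match(names(ev_last), adm_id)
    discharge[di] <- pmax(discharge[di],
                          as.POSIXct(ev_last, tz = "UTC", origin = "1970-01-01") +
                            3600)
    discharge[di][!discharged_alive[di]] <-
      as.POSIXct(ev_last[!discharged_alive[di]], tz = "UTC", origin = "1970-01-01")
  }
  discharge[same_day] <- admit_day[same_day] + 3600 * 20

  admissions <- data.frame(
    admission_id = adm_id,
    admit_time = admit_time,
    discharge_time = discharge,
    age = age,
    specialty = specialty,
    discharged_alive = discharged_alive,
    stringsAsFactors = FALSE)

  truth <- list(
    quantiles = lapply(cf$marginals, `[[`, "quantile"),
    severity = stats::setNames(severity, adm_id),
    alpha = alpha,
    event_admissions = adm_id[has_event],
    realized_prevalence = mean(has_event),
    injected = list(underage = adm_id[underage],
                    palliative = adm_id[palliative],
                    same_day = adm_id[same_day]),
    seed = cf$seed)

  list(admissions = admissions, observations = observations,
       events = events, truth = truth)
}
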