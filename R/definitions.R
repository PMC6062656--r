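#' Manual centile-based early warning score (mCEWS)
#'
#' The centile-based EWS whose thresholds were derived from the distribution
#' of *manually charted* ward vital signs: sub-score thresholds sit at the
#' 1st/5th/10th and 90th/95th/99th centiles of each vital sign (20th/10th/2nd
#' for the one-sided SpO2 distribution; 10th/1st and 90th/99th only for
#' temperature, which has no score-2 bands).
#'
#' One transcription note: the published manual respiratory-rate row prints
#' overlapping score-2/score-1 cells ("8-11" then "11-12"). Centile bands are
#' half-open at their thresholds (a value *below* the 5th-centile threshold
#' scores 2, at or above it scores 1), so RR = 11 receives score 1 and the
#' score-2 band is stored as 8-10.
#'
#' @param oxygen if `TRUE` (default) the definition carries the additional
#'   score of 2 for any supplemental oxygen support; `FALSE` gives the plain
#'   vital-sign-only variant.
#' @return an [ews_definition()].
#' @export
cews_manual <- function(oxygen = TRUE) {
  ews_definition(
    name = if (oxygen) "Manual CEWS (+O2)" else "Manual CEWS",
    tables = list(
      hr = band_table("hr", c(3, 2, 1, 0, 1, 2, 3),
                      c(-Inf, 43, 50, 54, 105, 113, 128),
                      c(42, 49, 53, 104, 112, 127, Inf)),
      rr = band_table("rr", c(3, 2, 1, 0, 1, 2, 3),
                      c(-Inf, 8, 11, 13, 22, 24, 29),
                      c(7, 10, 12, 21, 23, 28, Inf)),
      temp = band_table("temp", c(3, 1, 0, 1, 3),
                        c(-Inf, 35.5, 36.0, 37.4, 38.4),
                        c(35.4, 35.9, 37.3, 38.3, Inf)),
      sbp = band_table("sbp", c(3, 2, 1, 0, 1, 2, 3),
                       c(-Inf, 84, 91, 101, 158, 168, 185),
                       c(83, 90, 100, 157, 167, 184, Inf)),
      spo2 = band_table("spo2", c(3, 2, 1, 0),
                        c(-Inf, 85, 91, 94),
                        c(84, 90, 93, Inf))),
    avpu_map = c(A = 0L, V = 3L, P = 3L, U = 3L),
    oxygen_increment = if (oxygen) 2L else 0L,
    note = "Centile thresholds from manually charted ward observations.")
}

#' Continuous centile-based early warning score (cCEWS)
#'
#' The original centile-based EWS, with thresholds derived from
#' *continuously acquired* bedside-monitor vital signs. Same centile scheme
#' as [cews_manual()]; the threshold values differ because the monitor-data
#' distributions differ (most visibly in the upper respiratory-rate tail).
#' Ships without an oxygen increment, matching how it was defined.
#'
#' @return an [ews_definition()].
#' @export
cews_continuous <- function() {
  ews_definition(
    name = "Continuous CEWS",
    tables = list(
      hr = band_table("hr", c(3, 2, 1, 0, 1, 2, 3),
                      c(-Inf, 51, 59, 64, 105, 113, 128),
                      c(50, 58, 63, 104, 112, 127, Inf)),
      rr = band_table("rr", c(3, 2, 1, 0, 1, 2, 3),
                      c(-Inf, 8, 11, 14, 26, 29, 34),
                      c(7, 10, 13, 25, 28, 33, Inf)),
      temp = band_table("temp", c(3, 1, 0, 1, 3),
                        c(-Inf, 35.5, 36.0, 37.4, 38.4),
                        c(35.4, 35.9, 37.3, 38.3, Inf)),
      sbp = band_table("sbp", c(3, 2, 1, 0, 1, 2, 3),
                       c(-Inf, 86, 97, 102, 155, 165, 185),
                       c(85, 96, 101, 154, 164, 184, Inf)),
      spo2 = band_table("spo2", c(3, 2, 1, 0),
                        c(-Inf, 85, 91, 94),
                        c(84, 90, 93, Inf))),
    avpu_map = c(A = 0L, V = 3L, P = 3L, U = 3L),
    oxygen_increment = 0L,
    note = "Centile thresholds from continuously monitored vital signs.")
}

#' National Early Warning Score (NEWS)
#'
#' The UK Royal College of Physicians National Early Warning Score (2012),
#' shipped as the supervised comparator configuration. Its band boundaries
#' are a transcription of the published chart, not a derivation; any
#' correctness question about it is a transcription question.
#'
#' @return an [ews_definition()].
#' @export
news_definition <- function() {
  ews_definition(
    name = "NEWS",
    tables = list(
      hr = band_table("hr", c(3, 1, 0, 1, 2, 3),
                      c(-Inf, 41, 51, 91, 111, 131),
                      c(40, 50, 90, 110, 130, Inf)),
      rr = band_table("rr", c(3, 1, 0, 2, 3),
                      c(-Inf, 9, 12, 21, 25),
                      c(8, 11, 20, 24, Inf)),
      temp = band_table("temp", c(3, 1, 0, 1, 2),
                        c(-Inf, 35.1, 36.1, 38.1, 39.1),
                        c(35.0, 36.0, 38.0, 39.0, Inf)),
      sbp = band_table("sbp", c(3, 2, 1, 0, 3),
                       c(-Inf, 91, 101, 111, 220),
                       c(90, 100, 110, 219, Inf)),
      spo2 = band_table("spo2", c(3, 2, 1, 0),
                        c(-Inf, 92, 94, 96),
                        c(91, 93, 95, Inf))),
    avpu_map = c(A = 0L, V = 3L, P = 3L, U = 3L),
    oxygen_increment = 2L,
    note = "RCP National Early Warning Score (2012) chart transcription.")
}
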