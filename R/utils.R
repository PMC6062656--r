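
# data.table is used via :: only; this flag keeps its [ dispatch working here
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to a fixed resolution, half away from zero
#'
#' Rounds `x` to the nearest multiple of `resolution`, with exact halves
#' rounded away from zero (so 0.5 -> 1, -0.5 -> -1, unlike [base::round()]'s
#' banker's rounding). Used when converting inverted centiles to printable
#' thresholds at a variable's charting resolution (integers for most vitals,
#' 0.1 degC for temperature).
#'
#' @param x numeric vector.
#' @param resolution positive grid step.
#' @return numeric vector on the resolution grid.
#' @export
round_to <- function(x, resolution = 1) {
  stopifnot(is.numeric(x), length(resolution) == 1L, resolution > 0)
  # small epsilon guards against 36.049999999 / 0.1 landing just below a half
  r <- sign(x) * floor(abs(x) / resolution + 0.5 + 1e-9) * resolution
  round(r, 10L)
}

# Parse ISO-8601-ish timestamps ("2014-03-24T10:30:00" or with a space) as
# timezone-naive local ward time, represented internally as UTC. Unparseable
# strings yield NA (callers decide whether that is malformed) rather than the
# error base R raises for non-standard formats.
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  s <- sub("T", " ", as.character(x))
  out <- as.POSIXct(rep(NA_character_, length(s)), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(s[todo], tz = "UTC", format = fmt)
  }
  out
}

format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

hours_between <- function(from, to) as.numeric(difftime(to, from, units = "hours"))

# canonical scored continuous variables, in charting order
VITAL_VARS <- c("hr", "rr", "sbp", "temp", "spo2")

VITAL_LABELS <- c(hr = "Heart rate (beats/min)",
                  rr = "Respiratory rate (breaths/min)",
                  sbp = "Systolic blood pressure (mmHg)",
                  temp = "Temperature (degC)",
                  spo2 = "SpO2 (%)")

AVPU_LEVELS <- c("A", "V", "P", "U")

# Short polynomial fingerprint of a string, logged by CLI commands so a run's
# configuration can be matched to its outputs. Not cryptographic.
config_fingerprint <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
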