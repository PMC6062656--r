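# Independent brute-force oracles. These deliberately reimplement the
# contracts with naive loops so they share no code path with the package.

# interval-membership sub-score: bands given as printed inclusive endpoints
# at `resolution`; internally half-open on the grid shifted by res/2
oracle_sub_score <- function(x, scores, lowers, uppers, resolution = 1) {
  hits <- integer(0)
  for (i in seq_along(scores)) {
    lo <- if (is.infinite(lowers[i])) -Inf else lowers[i] - resolution / 2
    hi <- if (is.infinite(uppers[i])) Inf else uppers[i] + resolution / 2
    if (x >= lo && x < hi) hits <- c(hits, i)
  }
  stopifnot(length(hits) == 1L)
  as.integer(scores[hits])
}

# O(n^2) Mann-Whitney concordance with mid-rank tie handling
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
  total / (length(pos) * length(neg))
}

# direct average-precision summation over descending score cutoffs
oracle_average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  cutoffs <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  ap <- 0
  prev_recall <- 0
  for (ct in cutoffs) {
    sel <- scores >= ct
    recall <- sum(labels & sel) / n_pos
    precision <- sum(labels & sel) / sum(sel)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# exact Gaussian-mixture CDF by double loop (tiny n only)
oracle_mixture_cdf <- function(x, samples, h) {
  vapply(x, function(xi) {
    s <- 0
    for (si in samples) s <- s + pnorm((xi - si) / h)
    s / length(samples)
  }, numeric(1))
}

# a complete, in-range observation set at the development medians
median_obs <- function(...) {
  obs <- list(hr = 82, rr = 17, sbp = 123, temp = 36.3, spo2 = 97,
              avpu = "A", on_oxygen = FALSE)
  utils::modifyList(obs, list(...))
}

# random complete observation table spanning all bands
random_obs_table <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    admission_id = sprintf("a%03d", sample.int(max(2L, n %/% 5L), n, replace = TRUE)),
    timestamp = as.POSIXct("2015-01-01", tz = "UTC") + 3600 * seq_len(n),
    hr = sample(20:220, n, replace = TRUE),
    rr = sample(2:60, n, replace = TRUE),
    sbp = sample(50:260, n, replace = TRUE),
    dbp = sample(30:140, n, replace = TRUE),
    temp = round(runif(n, 33, 41), 1),
    spo2 = sample(60:100, n, replace = TRUE),
    avpu = sample(c("A", "V", "P", "U"), n, replace = TRUE,
                  prob = c(0.9, 0.05, 0.03, 0.02)),
    on_oxygen = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# printed band-table content transcribed from the published chart, used to
# check the shipped definitions cell by cell
published_bands <- function() {
  list(
    manual = list(
      hr = list(scores = c(3, 2, 1, 0, 1, 2, 3),
                lowers = c(-Inf, 43, 50, 54, 105, 113, 128),
                uppers = c(42, 49, 53, 104, 112, 127, Inf)),
      # printed score-2 cell "8-11" overlaps the score-1 cell "11-12";
      # under the half-open centile convention RR = 11 scores 1, so the
      # score-2 band is 8-10
      rr = list(scores = c(3, 2, 1, 0, 1, 2, 3),
                lowers = c(-Inf, 8, 11, 13, 22, 24, 29),
                uppers = c(7, 10, 12, 21, 23, 28, Inf)),
      temp = list(scores = c(3, 1, 0, 1, 3),
                  lowers = c(-Inf, 35.5, 36.0, 37.4, 38.4),
                  uppers = c(35.4, 35.9, 37.3, 38.3, Inf)),
      sbp = list(scores = c(3, 2, 1, 0, 1, 2, 3),
                 lowers = c(-Inf, 84, 91, 101, 158, 168, 185),
                 uppers = c(83, 90, 100, 157, 167, 184, Inf)),
      spo2 = list(scores = c(3, 2, 1, 0),
                  lowers = c(-Inf, 85, 91, 94),
                  uppers = c(84, 90, 93, Inf))),
    continuous = list(
      hr = list(scores = c(3, 2, 1, 0, 1, 2, 3),
                lowers = c(-Inf, 51, 59, 64, 105, 113, 128),
                uppers = c(50, 58, 63, 104, 112, 127, Inf)),
      rr = list(scores = c(3, 2, 1, 0, 1, 2, 3),
                lowers = c(-Inf, 8, 11, 14, 26, 29, 34),
                uppers = c(7, 10, 13, 25, 28, 33, Inf)),
      temp = list(scores = c(3, 1, 0, 1, 3),
                  lowers = c(-Inf, 35.5, 36.0, 37.4, 38.4),
                  uppers = c(35.4, 35.9, 37.3, 38.3, Inf)),
      sbp = list(scores = c(3, 2, 1, 0, 1, 2, 3),
                 lowers = c(-Inf, 86, 97, 102, 155, 165, 185),
                 uppers = c(85, 96, 101, 154, 164, 184, Inf)),
      spo2 = list(scores = c(3, 2, 1, 0),
                  lowers = c(-Inf, 85, 91, 94),
                  uppers = c(84, 90, 93, Inf))))
}
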