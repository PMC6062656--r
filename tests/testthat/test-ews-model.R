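test_that("shipped CEWS definitions reproduce every published band cell", {
  pub <- published_bands()
  defs <- list(manual = cews_manual(), continuous = cews_continuous())
  for (sys in names(pub)) {
    for (v in names(pub[[sys]])) {
      got <- defs[[sys]]$tables[[v]]$bands
      want <- pub[[sys]][[v]]
      expect_equal(got$score, want$scores,
                   info = sprintf("%s %s scores", sys, v))
      expect_equal(got$lower, want$lowers,
                   info = sprintf("%s %s lowers", sys, v))
      expect_equal(got$upper, want$uppers,
                   info = sprintf("%s %s uppers", sys, v))
    }
    expect_equal(unname(defs[[sys]]$avpu_map), c(0L, 3L, 3L, 3L))
  }
  expect_equal(cews_manual()$oxygen_increment, 2L)
  expect_equal(cews_manual(oxygen = FALSE)$oxygen_increment, 0L)
  expect_equal(cews_continuous()$oxygen_increment, 0L)
})

test_that("sub_score matches the published worked values", {
  m <- cews_manual()
  expect_identical(sub_score(128, m$tables$hr), 3L)
  expect_identical(sub_score(17, m$tables$rr), 0L)
  # overlap cell in the published manual RR row: half-open rule gives 11 -> 1
  expect_identical(sub_score(11, m$tables$rr), 1L)
  expect_identical(sub_score(12, m$tables$rr), 1L)
  expect_identical(sub_score(13, m$tables$rr), 0L)
  # any value strictly inside the score-0 band scores 0
  for (x in c(60, 80, 100)) expect_identical(sub_score(x, m$tables$hr), 0L)
  # non-integer monitor readings use the half-open internal representation
  expect_identical(sub_score(104.5, m$tables$hr), 1L)
  expect_identical(sub_score(104.4, m$tables$hr), 0L)
  expect_identical(sub_score(42.6, m$tables$hr), 2L)
})

test_that("sub_score rejects missing and physically inadmissible values", {
  m <- cews_manual()
  expect_error(sub_score(NA_real_, m$tables$hr), "missing")
  expect_error(sub_score(Inf, m$tables$rr), "finite")
  expect_error(sub_score(150, m$tables$spo2), "admissible")
  expect_error(sub_score(-3, m$tables$spo2), "admissible")
  expect_identical(sub_score(100, m$tables$spo2), 0L)
})

test_that("every admissible value receives exactly one sub-score (partition scan)", {
  for (defn in list(cews_manual(), cews_continuous(), news_definition())) {
    for (v in names(defn$tables)) {
      bt <- defn$tables[[v]]
      grid <- switch(v,
                     temp = seq(25, 45, by = 0.1),
                     spo2 = seq(0, 100, by = 1),
                     seq(0, 250, by = 1))
      expected <- vapply(grid, oracle_sub_score, integer(1),
                         scores = bt$bands$score, lowers = bt$bands$lower,
                         uppers = bt$bands$upper, resolution = bt$resolution)
      expect_identical(sub_score(grid, bt), expected,
                       info = sprintf("%s / %s", defn$name, v))
    }
  }
})

test_that("sub-scores never decrease moving away from the score-0 band", {
  for (defn in list(cews_manual(), cews_continuous(), news_definition())) {
    for (v in names(defn$tables)) {
      bt <- defn$tables[[v]]
      b0 <- bt$bands[bt$bands$score == 0L, ]
      lo <- max(bt$admissible[1], min(bt$bands$lower[is.finite(bt$bands$lower)]) - 10)
      hi <- min(bt$admissible[2], max(bt$bands$upper[is.finite(bt$bands$upper)]) + 10)
      down <- sub_score(seq(b0$lower, lo, by = -bt$resolution), bt)
      up <- sub_score(seq(min(b0$upper, hi), hi, by = bt$resolution), bt)
      expect_false(is.unsorted(down), info = sprintf("%s %s down", defn$name, v))
      expect_false(is.unsorted(up), info = sprintf("%s %s up", defn$name, v))
    }
  }
})

test_that("avpu sub-scores follow the chart and reject unknown levels", {
  m <- cews_manual()
  expect_identical(avpu_sub_score(c("A", "V", "P", "U"), m), c(0L, 3L, 3L, 3L))
  expect_error(avpu_sub_score("X", m), "AVPU")
  expect_error(avpu_sub_score(NA_character_, m), "AVPU")
})

test_that("aggregate score is additive and handles the oxygen increment", {
  m <- cews_manual()
  expect_identical(aggregate_score(median_obs(), m), 0L)
  expect_identical(aggregate_score(median_obs(on_oxygen = TRUE), m), 2L)
  # all-extreme observation: sum of independently computed sub-scores
  ext <- median_obs(hr = 128, rr = 29, sbp = 185, temp = 38.4, spo2 = 84,
                    avpu = "U", on_oxygen = TRUE)
  expect_identical(aggregate_score(ext, m), 3L + 3L + 3L + 3L + 3L + 3L + 2L)

  # additivity on a random table, against per-variable oracle sums
  tab <- random_obs_table(200)
  got <- score_observations(tab, m)
  want <- integer(nrow(tab))
  for (v in names(m$tables)) {
    bt <- m$tables[[v]]
    want <- want + vapply(tab[[v]], oracle_sub_score, integer(1),
                          scores = bt$bands$score, lowers = bt$bands$lower,
                          uppers = bt$bands$upper, resolution = bt$resolution)
  }
  want <- want + ifelse(tab$avpu == "A", 0L, 3L) + 2L * tab$on_oxygen
  expect_identical(got, want)
})

test_that("aggregate score errors name the missing variable", {
  m <- cews_manual()
  obs <- median_obs(); obs$rr <- NULL
  expect_error(aggregate_score(obs, m), "rr")
  obs2 <- as.data.frame(median_obs()); obs2$sbp <- NA_real_
  expect_error(aggregate_score(obs2, m), "sbp")
  # on_oxygen only required when the system scores oxygen
  obs3 <- median_obs(); obs3$on_oxygen <- NULL
  expect_error(aggregate_score(obs3, m), "on_oxygen")
  expect_identical(aggregate_score(obs3, cews_manual(oxygen = FALSE)), 0L)
})

test_that("band_table constructor enforces the structural invariants", {
  expect_error(band_table("hr", c(3, 0), c(-Inf, 45), c(50, Inf)), "overlap")
  expect_error(band_table("hr", c(3, 0), c(-Inf, 60), c(50, Inf)), "gap")
  expect_error(band_table("hr", c(3, 1), c(-Inf, 51), c(50, Inf)), "score 0")
  expect_error(band_table("hr", c(0, 0), c(-Inf, 51), c(50, Inf)), "score 0")
  expect_error(band_table("hr", c(1, 0, 2, 1), c(-Inf, 40, 60, 80),
                          c(39, 59, 79, Inf)), "decrease")
  expect_error(band_table("hr", c(3, 0, 5), c(-Inf, 40, 60), c(39, 59, Inf)),
               "0..3", fixed = TRUE)
})

test_that("NEWS transcription scores its published chart boundaries", {
  n <- news_definition()
  expect_identical(sub_score(c(8, 9, 12, 20, 21, 24, 25), n$tables$rr),
                   c(3L, 1L, 0L, 0L, 2L, 2L, 3L))
  expect_identical(sub_score(c(91, 92, 94, 96), n$tables$spo2),
                   c(3L, 2L, 1L, 0L))
  expect_identical(sub_score(c(35.0, 35.1, 36.1, 38.1, 39.1), n$tables$temp),
                   c(3L, 1L, 0L, 1L, 2L))
  expect_identical(sub_score(c(90, 91, 101, 111, 219, 220), n$tables$sbp),
                   c(3L, 2L, 1L, 0L, 0L, 3L))
  expect_identical(sub_score(c(40, 41, 51, 91, 111, 131), n$tables$hr),
                   c(3L, 1L, 0L, 1L, 2L, 3L))
})
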