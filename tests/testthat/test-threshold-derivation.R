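test_that("kde_bandwidth evaluates the normal-approximation rule exactly", {
  expect_equal(kde_bandwidth(sigma = 1, n = 1), 1.06)
  expect_equal(kde_bandwidth(sigma = 2, n = 32), 1.06)  # 32^(-1/5) = 1/2
  expect_equal(kde_bandwidth(sigma = 10, n = 100000),
               1.06 * 10 * 100000^(-0.2), tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(500, sd = 3)
  expect_equal(kde_bandwidth(x), 1.06 * sd(x) * 500^(-1 / 5), tolerance = 1e-12)
  # n-1 vs n denominator is switchable and documented
  expect_equal(kde_bandwidth(x, sd_denominator = "n"),
               1.06 * sd(x) * sqrt(499 / 500) * 500^(-1 / 5), tolerance = 1e-12)
})

test_that("kde_bandwidth scales as n^(-1/5): h(n) / h(32 n) = 2", {
  for (n in c(10, 1000, 12345))
    expect_equal(kde_bandwidth(sigma = 1.7, n = n) /
                   kde_bandwidth(sigma = 1.7, n = 32 * n), 2, tolerance = 1e-12)
})

test_that("kde_bandwidth rejects degenerate input", {
  expect_error(kde_bandwidth(rep(5, 10)), "positive")
  expect_error(kde_bandwidth(numeric(0)), "at least one")
  expect_error(kde_bandwidth(3), "single sample")
  expect_error(kde_bandwidth(c(1, NA, 2)), "finite")
})

test_that("smoothed_cdf equals the brute-force Gaussian-mixture CDF", {
  set.seed(11)
  x <- rnorm(200, 50, 8)
  d <- smoothed_cdf(x, method = "exact")
  idx <- seq(1, length(d$grid), by = 37)
  expect_equal(d$cdf[idx], oracle_mixture_cdf(d$grid[idx], x, d$bandwidth),
               tolerance = 1e-12)
})

test_that("binned evaluation agrees with exact evaluation", {
  set.seed(12)
  x <- c(rnorm(4000, 80, 15), rnorm(2000, 110, 8))  # bimodal
  de <- smoothed_cdf(x, method = "exact")
  db <- smoothed_cdf(x, method = "binned")
  expect_lt(max(abs(de$cdf - db$cdf)), 1e-6)
})

test_that("smoothed_cdf is a valid CDF with resolved tails", {
  set.seed(13)
  for (x in list(runif(500, 0, 10), rexp(3000))) {
    d <- smoothed_cdf(x)
    expect_false(is.unsorted(d$cdf))
    expect_true(all(d$cdf >= 0 & d$cdf <= 1))
    expect_lte(d$cdf[1], 1e-4)
    expect_gte(d$cdf[length(d$cdf)], 0.9999)
  }
  # symmetry: P at the centre of a symmetric sample is 1/2
  xs <- c(1, 2, 4, 6, 7)  # symmetric about 4
  d <- smoothed_cdf(xs, bandwidth = 0.8, method = "exact")
  expect_equal(approx(d$grid, d$cdf, xout = 4)$y, 0.5, tolerance = 1e-6)
})

test_that("smoothed_cdf recovers normal quantiles within smoothing bias", {
  set.seed(14)
  x <- rnorm(1e5)
  d <- smoothed_cdf(x)
  p_at <- approx(d$grid, d$cdf, xout = 1.2816)$y
  expect_equal(p_at, 0.90, tolerance = 0.01)
})

test_that("smoothed_cdf input validation", {
  expect_error(smoothed_cdf(5), "at least two")
  expect_error(smoothed_cdf(c(1, 2, NaN)), "finite")
  expect_error(smoothed_cdf(c(1, 2, 3), bandwidth = 0), "positive")
})

test_that("invert_centile is a monotone right-inverse of the CDF", {
  set.seed(15)
  x <- rgamma(5000, 3, 0.5)
  d <- smoothed_cdf(x)
  ps <- c(0.01, 0.02, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 0.99)
  qs <- invert_centile(d, ps)
  expect_false(is.unsorted(qs))
  # round trip through linear interpolation of the stored CDF
  back <- approx(d$grid, d$cdf, xout = qs)$y
  expect_equal(back, ps, tolerance = 1e-9)
  # median of a symmetric sample is its centre
  xs <- c(10, 11, 13, 15, 16)
  ds <- smoothed_cdf(xs, bandwidth = 1, method = "exact")
  expect_equal(invert_centile(ds, 0.5), 13, tolerance = 1e-3)
  expect_error(invert_centile(d, 0), "inside")
  expect_error(invert_centile(d, 1), "inside")
})

test_that("uniform draws give ~exact analytic centiles through the pipeline", {
  set.seed(16)
  x <- runif(2e5, 0, 100)
  d <- smoothed_cdf(x)
  expect_equal(invert_centile(d, 0.10), 10, tolerance = 0.25)
  bt <- derive_band_table(x, centile_spec("hr"))
  th <- attr(bt, "thresholds")
  expect_true(all(abs(th$value - c(1, 5, 10, 90, 95, 99)) <= 1))
})

test_that("one-sided specs produce no upper bands", {
  ms <- generate_marginal_sample("spo2", 20000, cohort_config(seed = 17))
  sp <- centile_spec("spo2", lower = c("3" = 0.02, "2" = 0.10, "1" = 0.20),
                     upper = NULL)
  bt <- derive_band_table(ms$samples, sp)
  b <- bt$bands
  expect_identical(b$score, c(3L, 2L, 1L, 0L))
  expect_identical(b$upper[nrow(b)], Inf)  # score-0 band extends upwards
})

test_that("rounded-threshold collisions are an error naming the centiles", {
  set.seed(18)
  x <- rnorm(5000, 50, 0.3)  # centiles closer together than the resolution
  expect_error(derive_band_table(x, centile_spec("hr")), "collide")
  expect_error(derive_band_table(x, centile_spec("hr")), "%")
})

test_that("derivation is deterministic and recovers generator quantiles", {
  cfg <- cohort_config(seed = 5)
  for (v in c("rr", "hr", "temp")) {
    ms <- generate_marginal_sample(v, 3e4, cfg)
    spec <- default_centile_specs()[[v]]
    bt1 <- derive_band_table(ms$samples, spec)
    bt2 <- derive_band_table(ms$samples, spec)
    expect_identical(bt1, bt2)
    th <- attr(bt1, "thresholds")
    truth <- round_to(ms$quantile(th$centile), spec$resolution)
    expect_true(all(abs(th$value - truth) <= spec$resolution + 1e-9),
                info = v)
  }
})

test_that("derive_ews assembles a full definition from an observation table", {
  set.seed(19)
  co <- generate_cohort(cohort_config(n_admissions = 800, seed = 19,
                                      missing_rate = 0, implausible_rate = 0))
  defn <- derive_ews(co$observations, name = "test CEWS")
  expect_s3_class(defn, "ews_definition")
  expect_setequal(names(defn$tables), c("hr", "rr", "sbp", "temp", "spo2"))
  expect_identical(unname(defn$avpu_map), c(0L, 3L, 3L, 3L))
  expect_identical(defn$oxygen_increment, 2L)
  # deterministic: bit-identical on re-derivation
  expect_identical(defn, derive_ews(co$observations, name = "test CEWS"))
  expect_error(derive_ews(co$observations[0, ]), "empty")
  # temperature table has no score-2 bands
  expect_false(2L %in% defn$tables$temp$bands$score)
})

test_that("centile_spec validates ordering and range", {
  expect_error(centile_spec("hr", lower = c("3" = 0.05, "2" = 0.01, "1" = 0.10)),
               "increasing")
  expect_error(centile_spec("hr", lower = c("1" = 0.01, "2" = 0.05, "3" = 0.10)),
               "decreasing")
  expect_error(centile_spec("hr", lower = c("3" = 0)), "\\(0, 1\\)")
  expect_error(centile_spec("hr", lower = c("3" = 0.5),
                            upper = c("3" = 0.4)), "below upper")
})
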