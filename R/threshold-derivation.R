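#' Gaussian-kernel bandwidth by the normal-approximation rule
#'
#' Computes `h = 1.06 * sigma_hat * n^(-1/5)`, the normal-reference
#' ("rule-of-thumb") bandwidth for a Gaussian kernel density estimate, where
#' `sigma_hat` is the standard deviation of the `n` samples. Either pass the
#' samples, or pass `sigma` and `n` directly to evaluate the formula itself.
#'
#' `sigma_hat` uses the sample (n-1 denominator) standard deviation by
#' default; set `sd_denominator = "n"` for the population form. The two are
#' indistinguishable at the sample sizes threshold derivation is meant for.
#'
#' @param samples numeric vector of observations (ignored when `sigma` and
#'   `n` are given).
#' @param sigma,n optional explicit standard deviation and sample count.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @return bandwidth in the units of the samples.
#' @export
kde_bandwidth <- function(samples = NULL, sigma = NULL, n = NULL,
                          sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (is.null(sigma)) {
    if (is.null(samples) || length(samples) < 1L)
      stop("kde_bandwidth: need at least one sample (or explicit sigma and n)")
    if (any(!is.finite(samples)))
      stop("kde_bandwidth: samples must be finite")
    n <- length(samples)
    if (n == 1L)
      stop("kde_bandwidth: sigma is undefined for a single sample; pass sigma explicitly")
    sigma <- stats::sd(samples)
    if (sd_denominator == "n") sigma <- sigma * sqrt((n - 1) / n)
  } else {
    if (is.null(n)) stop("kde_bandwidth: n must be given with sigma")
    stopifnot(length(sigma) == 1L, length(n) == 1L, is.finite(sigma), n >= 1)
  }
  if (is.na(sigma) || sigma <= 0)
    stop("kde_bandwidth: standard deviation must be positive (constant sample?)")
  1.06 * sigma * n^(-1 / 5)
}

#' Kernel-smoothed cumulative distribution of a vital-sign sample
#'
#' Estimates the CDF as an equal-weight mixture of Gaussian kernels centred
#' at the observations: `P(x) = (1/n) * sum_i pnorm((x - x_i) / h)`. The
#' estimate is evaluated on a regular grid extending `4h` beyond the sample
#' range, so the tail mass outside the grid is negligible and all centiles of
#' interest are strictly inside it.
#'
#' Two evaluation paths give the same result: `"exact"` sums the mixture
#' directly (O(n * grid) work, used for small n), and `"binned"` first
#' linear-bins the samples onto the evaluation grid and then evaluates the
#' mixture by FFT convolution (used for large n; binning error is
#' O((grid step / h)^2) and the grid step is far below `h` for any realistic
#' sample). `"auto"` switches on sample size.
#'
#' @param samples numeric vector, n >= 2, finite.
#' @param bandwidth kernel bandwidth; defaults to [kde_bandwidth()] of the
#'   samples.
#' @param grid_n number of grid points (default 4096).
#' @param method `"auto"`, `"exact"` or `"binned"`.
#' @return an object of class `smoothed_cdf` with fields `grid`, `cdf`,
#'   `n`, `sigma`, `bandwidth`, `method`.
#' @export
smoothed_cdf <- function(samples, bandwidth = NULL, grid_n = 4096L,
                         method = c("auto", "exact", "binned")) {
  method <- match.arg(method)
  n <- length(samples)
  if (n < 2L) stop("smoothed_cdf: need at least two samples")
  if (any(!is.finite(samples))) stop("smoothed_cdf: samples must be finite")
  stopifnot(grid_n >= 16L)
  h <- bandwidth %||% kde_bandwidth(samples)
  if (!is.finite(h) || h <= 0) stop("smoothed_cdf: bandwidth must be positive")
  grid <- seq(min(samples) - 4 * h, max(samples) + 4 * h, length.out = grid_n)
  if (method == "auto") method <- if (n <= 8192L) "exact" else "binned"
  P <- if (method == "exact") cdf_mixture_exact(samples, grid, h)
       else cdf_mixture_binned(samples, grid, h)
  # guard against convolution round-off: clamp and enforce monotonicity
  P <- cummax(pmin(pmax(P, 0), 1))
  structure(list(grid = grid, cdf = P, n = n, sigma = stats::sd(samples),
                 bandwidth = h, method = method),
            class = "smoothed_cdf")
}

# direct mixture CDF, chunked over grid points to bound memory
cdf_mixture_exact <- function(samples, grid, h) {
  m <- length(grid)
  chunk <- max(1L, floor(2^24 / length(samples)))
  P <- numeric(m)
  i <- 1L
  while (i <= m) {
    j <- min(m, i + chunk - 1L)
    P[i:j] <- colMeans(stats::pnorm(outer(samples, grid[i:j], function(x, g) (g - x) / h)))
    i <- j + 1L
  }
  P
}

# linear-bin the samples onto the evaluation grid, then convolve the bin
# weights with the kernel CDF sampled on grid offsets:
#   P_j = sum_b w_b * Phi((g_j - g_b) / h)
cdf_mixture_binned <- function(samples, grid, h) {
  m <- length(grid)
  delta <- grid[2L] - grid[1L]
  pos <- (samples - grid[1L]) / delta          # fractional grid coordinate
  lo <- pmin(pmax(floor(pos), 0), m - 2L)
  frac <- pos - lo
  w <- numeric(m)
  agg <- rowsum(c(1 - frac, frac), group = c(lo + 1L, lo + 2L))
  w[as.integer(rownames(agg))] <- agg / length(samples)
  kern <- stats::pnorm((-(m - 1L):(m - 1L)) * delta / h)
  z <- stats::convolve(w, rev(kern), type = "open")
  z[m:(2L * m - 1L)]
}

#' @export
print.smoothed_cdf <- function(x, ...) {
  cat(sprintf(
    "Kernel-smoothed CDF: n = %d, sigma = %.4g, h = %.4g (%s evaluation, %d grid points on [%.4g, %.4g])\n",
    x$n, x$sigma, x$bandwidth, x$method, length(x$grid), x$grid[1L],
    x$grid[length(x$grid)]))
  invisible(x)
}

#' Invert a smoothed CDF at a probability
#'
#' Returns the smallest grid value whose CDF reaches `p`, refined by linear
#' interpolation between the straddling grid points. Monotone in `p`.
#'
#' @param dist a [smoothed_cdf()].
#' @param p probabilities strictly inside (0, 1); vectorised.
#' @return numeric vector of (unrounded) threshold values.
#' @export
invert_centile <- function(dist, p) {
  stopifnot(inherits(dist, "smoothed_cdf"))
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("invert_centile: p must lie strictly inside (0, 1)")
  P <- dist$cdf
  g <- dist$grid
  vapply(p, function(pi) {
    j <- findInterval(pi, P, left.open = TRUE)  # largest j with P[j] < pi
    if (j == 0L) return(g[1L])
    if (j >= length(P)) return(g[length(P)])    # p beyond resolved tail mass
    g[j] + (pi - P[j]) / (P[j + 1L] - P[j]) * (g[j + 1L] - g[j])
  }, numeric(1))
}

#' Centile-to-score specification for one vital sign
#'
#' Declares which centiles of a vital sign's smoothed distribution become
#' sub-score thresholds, on which side(s), and at what charting resolution.
#' The default two-sided scheme puts thresholds at the 10th/5th/1st centiles
#' (scores 1/2/3 below them) and the 90th/95th/99th centiles (scores 1/2/3 at
#' or above them). SpO2 is one-sided (20th/10th/2nd, no upper bands);
#' temperature uses 10th/1st and 90th/99th only (no score-2 bands) at 0.1
#' degC resolution.
#'
#' `lower` and `upper` are named numeric vectors mapping score (the name) to
#' centile probability. Lower centiles must increase as scores fall towards
#' 0; upper centiles must increase as scores rise.
#'
#' @param variable variable name.
#' @param lower named numeric vector of lower-tail centiles, names are the
#'   scores, e.g. `c("3" = 0.01, "2" = 0.05, "1" = 0.10)`; the value at a
#'   score's centile is the first value that *escapes* that score (so values
#'   below the 0.01 threshold score 3).
#' @param upper named numeric vector of upper-tail centiles, e.g.
#'   `c("1" = 0.90, "2" = 0.95, "3" = 0.99)`; `NULL` for one-sided variables.
#' @param resolution charting resolution used to round thresholds.
#' @return an object of class `centile_spec`.
#' @export
centile_spec <- function(variable,
                         lower = c("3" = 0.01, "2" = 0.05, "1" = 0.10),
                         upper = c("1" = 0.90, "2" = 0.95, "3" = 0.99),
                         resolution = if (identical(variable, "temp")) 0.1 else 1) {
  stopifnot(is.character(variable), length(variable) == 1L)
  check_side <- function(side, nm, ascending_scores) {
    if (is.null(side)) return(NULL)
    if (is.null(names(side)) || anyNA(suppressWarnings(as.integer(names(side)))))
      stop("centile_spec('", variable, "'): ", nm, " centiles must be named by score")
    if (any(side <= 0) || any(side >= 1))
      stop("centile_spec('", variable, "'): centiles must lie in (0, 1)")
    if (is.unsorted(side, strictly = TRUE))
      stop("centile_spec('", variable, "'): ", nm, " centiles must be strictly increasing")
    sc <- as.integer(names(side))
    if (!all(sc %in% 1:3))
      stop("centile_spec('", variable, "'): scores must be in 1..3")
    ok <- if (ascending_scores) !is.unsorted(sc, strictly = TRUE)
          else !is.unsorted(rev(sc), strictly = TRUE)
    if (!ok)
      stop("centile_spec('", variable, "'): ", nm,
           " scores must be strictly ", if (ascending_scores) "increasing" else "decreasing",
           " with the centile")
    side
  }
  lower <- check_side(lower, "lower", ascending_scores = FALSE)
  if (is.null(lower)) stop("centile_spec('", variable, "'): lower centiles are required")
  upper <- check_side(upper, "upper", ascending_scores = TRUE)
  if (!is.null(upper) && max(lower) >= min(upper))
    stop("centile_spec('", variable, "'): lower centiles must all lie below upper centiles")
  stopifnot(resolution > 0)
  structure(list(variable = variable, lower = lower, upper = upper,
                 sidedness = if (is.null(upper)) "lower_only" else "two_sided",
                 resolution = resolution),
            class = "centile_spec")
}

#' Default centile specifications for the five scored vital signs
#'
#' @return named list of [centile_spec()]s for `hr`, `rr`, `sbp`, `temp`
#'   (10th/1st and 90th/99th only, resolution 0.1), and `spo2` (one-sided
#'   20th/10th/2nd).
#' @export
default_centile_specs <- function() {
  list(
    hr = centile_spec("hr"),
    rr = centile_spec("rr"),
    sbp = centile_spec("sbp"),
    temp = centile_spec("temp",
                        lower = c("3" = 0.01, "1" = 0.10),
                        upper = c("1" = 0.90, "3" = 0.99)),
    spo2 = centile_spec("spo2",
                        lower = c("3" = 0.02, "2" = 0.10, "1" = 0.20),
                        upper = NULL))
}

#' Derive a score-band table from raw samples
#'
#' Runs the full unsupervised derivation for one vital sign: fit the
#' kernel-smoothed CDF ([smoothed_cdf()] with the [kde_bandwidth()] rule),
#' invert it at the specified centiles, round each threshold to the charting
#' resolution (half away from zero), and assemble contiguous score bands
#' under the half-open boundary convention of [band_table()]: values below a
#' threshold keep the more extreme score, values at or above it move towards
#' the score-0 band (and symmetrically on the upper side, where values at or
#' above a threshold take the more extreme score).
#'
#' If rounding makes two thresholds collide (non-strictly-ordered), the
#' derivation fails listing the colliding centiles rather than silently
#' producing an empty band.
#'
#' @param samples numeric vector of raw development values for the variable.
#' @param spec a [centile_spec()].
#' @param ... passed to [smoothed_cdf()] (e.g. `grid_n`, `method`).
#' @return a [band_table()] with attribute `"thresholds"`: a data.frame of
#'   side, centile, score, raw (unrounded) and rounded threshold values.
#' @export
derive_band_table <- function(samples, spec, ...) {
  stopifnot(inherits(spec, "centile_spec"))
  if (length(samples) < 10L)
    stop("derive_band_table('", spec$variable, "'): too few samples")
  d <- smoothed_cdf(samples, ...)
  res <- spec$resolution
  side <- c(rep("lower", length(spec$lower)), rep("upper", length(spec$upper)))
  ps <- c(unname(spec$lower), unname(spec$upper))
  scores <- as.integer(c(names(spec$lower), names(spec$upper)))
  raw <- invert_centile(d, ps)
  val <- round_to(raw, res)
  collide <- which(diff(val) < res - res * 1e-6)
  if (length(collide) > 0L)
    stop(sprintf(
      "derive_band_table('%s'): rounded thresholds collide at centiles %s (values %s)",
      spec$variable,
      paste(sprintf("%g%%/%g%%", 100 * ps[collide], 100 * ps[collide + 1L]),
            collapse = ", "),
      paste(sprintf("%s/%s", format(val[collide]), format(val[collide + 1L])),
            collapse = ", ")))
  nl <- length(spec$lower)
  lv <- val[seq_len(nl)]
  uv <- val[side == "upper"]
  # bands, low to high: below the first lower threshold, between consecutive
  # lower thresholds, the score-0 band, between upper thresholds, above the
  # last upper threshold
  lowers <- c(-Inf, lv, uv)
  uppers <- c(lv - res, if (length(uv)) c(uv - res, Inf) else Inf)
  bscores <- c(scores[1L], scores[seq_len(nl)][-1L], 0L,
               if (length(uv)) scores[side == "upper"])
  bt <- band_table(spec$variable, bscores, lowers, uppers, resolution = res)
  attr(bt, "thresholds") <- data.frame(side = side, centile = ps,
                                       score = scores, raw = raw,
                                       value = val)
  attr(bt, "cdf_summary") <- list(n = d$n, sigma = d$sigma,
                                  bandwidth = d$bandwidth)
  bt
}

#' Derive a complete centile-based EWS definition from an observation table
#'
#' Applies [derive_band_table()] per scored vital sign (missing values are
#' dropped per variable) and attaches the fixed AVPU map (A -> 0, V/P/U -> 3)
#' and the requested oxygen increment. Derivation is deterministic: deriving
#' twice from the same data gives identical definitions.
#'
#' @param observations data.frame of preprocessed observation sets.
#' @param specs named list of [centile_spec()]s (default
#'   [default_centile_specs()]); one per scored variable.
#' @param oxygen_increment integer oxygen increment of the resulting system.
#' @param name name of the resulting system.
#' @param ... passed to [derive_band_table()].
#' @return an [ews_definition()].
#' @export
derive_ews <- function(observations, specs = default_centile_specs(),
                       oxygen_increment = 2L, name = "derived CEWS", ...) {
  stopifnot(is.data.frame(observations))
  if (nrow(observations) == 0L) stop("derive_ews: empty observation table")
  tables <- lapply(specs, function(sp) {
    if (!sp$variable %in% names(observations))
      stop("derive_ews: observation table has no column '", sp$variable, "'")
    x <- observations[[sp$variable]]
    derive_band_table(x[!is.na(x)], sp, ...)
  })
  names(tables) <- vapply(specs, `[[`, character(1), "variable")
  ews_definition(name = name, tables = tables,
                 avpu_map = c(A = 0L, V = 3L, P = 3L, U = 3L),
                 oxygen_increment = oxygen_increment,
                 note = sprintf("Derived from %d observation sets.",
                                nrow(observations)))
}
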