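embed_series <- function(series, m, J) {
  N <- length(series)
  M <- N - (m - 1L) * J
  if (M < 2L) stop("series too short for this embedding")
  X <- matrix(0, M, m)
  for (k in seq_len(m)) X[, k] <- series[(1:M) + (k - 1L) * J]
  X
}

ami_binned <- function(x, y, nb) {
  N <- length(x)
  bx <- ceiling(rank(x, ties.method = "first") * nb / N)
  by <- ceiling(rank(y, ties.method = "first") * nb / N)
  joint <- tabulate((bx - 1L) * nb + by, nbins = nb * nb) / N
  px <- tabulate(bx, nbins = nb) / N
  py <- tabulate(by, nbins = nb) / N
  pij <- joint[joint > 0]
  outer_p <- as.numeric(outer(py, px))[joint > 0]
  sum(pij * log(pij / outer_p))
}

#' Embedding delay from average mutual information
#'
#' Returns the first significant local minimum of the average mutual
#' information (AMI) of the series against its lagged copy, computed on
#' equiprobable bins. "Significant" means the minimum lies at least 20%
#' below the lag-1 AMI, which guards against the binning jitter of
#' strongly deterministic signals. A memoryless series (lag-1 AMI already
#' at the large-lag floor) returns 1 immediately. When the AMI shows no
#' significant interior minimum -- a clean sinusoid is the canonical case
#' -- the estimator falls back to the autocorrelation: its first zero
#' crossing (a quarter period for a sinusoid), or failing that its first
#' 1/e crossing. The result is invariant to affine rescaling of the
#' series.
#'
#' @param series numeric vector, length >= 200.
#' @param max_lag largest lag examined.
#' @param n_bins bins for the AMI histogram (default scales with length).
#' @return Integer lag >= 1.
#' @examples
#' \donttest{
#' estimate_delay(sin(2 * pi * (1:1000) / 40))  # quarter period: 10
#' }
#' @export
estimate_delay <- function(series, max_lag = NULL,
                           n_bins = NULL) {
  series <- as.numeric(series)
  N <- length(series)
  if (N < 200) stop("need at least 200 samples to estimate the delay")
  if (sd(series) == 0) stop("constant series has no temporal structure")
  if (is.null(max_lag)) max_lag <- min(floor(N / 4), 200L)
  if (is.null(n_bins)) n_bins <- max(8L, min(32L, floor(sqrt(N / 5))))
  ami <- vapply(0:max_lag, function(l) {
    if (l == 0) ami_binned(series, series, n_bins)
    else ami_binned(series[1:(N - l)], series[(1 + l):N], n_bins)
  }, numeric(1))
  floor_level <- median(ami[max(2, max_lag - round(max_lag / 4)):
                              (max_lag + 1)])
  rise <- ami[1] - floor_level
  if (ami[2] - floor_level < 0.05 * rise) return(1L)   # memoryless series
  for (l in 1:(max_lag - 1)) {
    a <- ami[l + 1]
    deep <- a < 0.8 * ami[2]
    if (a < ami[l] && a <= ami[l + 2] && deep) return(l) # first deep minimum
    if (deep && a - floor_level < 0.05 * (ami[2] - floor_level)) return(l)
  }
  ac <- acf(series, lag.max = max_lag, plot = FALSE)$acf[-1]
  zero <- which(ac <= 0)
  if (length(zero)) return(as.integer(zero[1]))
  efold <- which(ac < exp(-1))
  if (length(efold)) return(as.integer(efold[1]))
  stop("no AMI minimum and no autocorrelation decay found")
}

#' Embedding dimension by false nearest neighbours
#'
#' Smallest embedding dimension at which the fraction of false nearest
#' neighbours (neighbours whose separation grows by more than `rtol` when
#' the embedding is extended by one coordinate, or beyond `atol` standard
#' deviations) drops below `fnn_tol`. Capped at `max_dim`. A strictly
#' monotone series is flagged as non-stationary with a warning.
#'
#' @param series numeric vector, length >= 500.
#' @param lag embedding lag in samples (e.g. from [estimate_delay()]).
#' @param max_dim cap on the dimension (default 10).
#' @param rtol,atol Kennel false-neighbour thresholds.
#' @param fnn_tol acceptable false-neighbour fraction (default 1%).
#' @return Integer dimension >= 1, with attribute `fnn_fractions`.
#' @export
estimate_dimension <- function(series, lag, max_dim = 10L, rtol = 10,
                               atol = 2, fnn_tol = 0.01) {
  series <- as.numeric(series)
  N <- length(series)
  if (N < 500) stop("need at least 500 samples to estimate the dimension")
  d <- diff(series)
  if (all(d > 0) || all(d < 0))
    warning("series is strictly monotone; embedding assumes stationarity")
  sigma <- sd(series)
  fracs <- numeric(0)
  for (m in seq_len(max_dim)) {
    M <- N - m * lag               # rows usable in both m and m+1 dims
    if (M < 50) break
    X <- embed_series(series, m, lag)[1:M, , drop = FALSE]
    nxt <- series[(1:M) + m * lag]
    nn <- nearest_neighbors(X, exclude = lag)
    ok <- !is.na(nn$idx) & is.finite(nn$dist)
    if (!any(ok)) break
    # exact recurrences (zero distance) are judged by the extension alone
    den <- pmax(nn$dist[ok], 1e-12 * sigma)
    gap <- abs(nxt[ok] - nxt[nn$idx[ok]])
    ratio <- gap / den
    dm1 <- sqrt(nn$dist[ok]^2 + gap^2)
    false_nn <- (ratio > rtol) | (dm1 / sigma > atol)
    fr <- mean(false_nn)
    if (!is.finite(fr)) break
    fracs <- c(fracs, fr)
    if (fr < fnn_tol) return(structure(m, fnn_fractions = fracs))
  }
  structure(as.integer(length(fracs)), fnn_fractions = fracs)
}

# blockwise nearest-neighbour search with a temporal exclusion window
nearest_neighbors <- function(X, exclude = 0L, block = 512L) {
  M <- nrow(X)
  sq <- rowSums(X^2)
  best_d2 <- rep(Inf, M)
  best_j <- rep(NA_integer_, M)
  for (start in seq(1L, M, by = block)) {
    cols <- start:min(start + block - 1L, M)
    D2 <- outer(sq, rep(1, length(cols))) +
      matrix(sq[cols], M, length(cols), byrow = TRUE) -
      2 * (X %*% t(X[cols, , drop = FALSE]))
    ii <- rep(1:M, length(cols))
    jj <- rep(cols, each = M)
    D2[abs(ii - jj) <= exclude] <- Inf
    cmin <- apply(D2, 1, which.min)
    dmin <- D2[cbind(1:M, cmin)]
    upd <- dmin < best_d2
    best_d2[upd] <- dmin[upd]
    best_j[upd] <- cols[cmin[upd]]
  }
  list(idx = best_j, dist = sqrt(pmax(best_d2, 0)))
}

#' Embedding parameters
#'
#' @param delay_steps lag J in samples (>= 1).
#' @param dimension embedding dimension m (>= 2 for flows).
#' @param mean_period_steps mean orbital period in samples, used as the
#'   temporal exclusion window for neighbour searches.
#' @return Object of class `embedding_params`.
#' @export
embedding_params <- function(delay_steps, dimension, mean_period_steps = 1L) {
  stopifnot(delay_steps >= 1, dimension >= 1, mean_period_steps >= 1)
  structure(list(delay_steps = as.integer(delay_steps),
                 dimension = as.integer(dimension),
                 mean_period_steps = as.integer(mean_period_steps)),
            class = "embedding_params")
}

#' Mean orbital period in samples
#'
#' Reciprocal of the power-spectrum peak frequency (periodogram with a 10%
#' taper), capped at a tenth of the series length. Used as the temporal
#' neighbour-exclusion window of the divergence method.
#'
#' @param series numeric vector.
#' @return Integer number of samples (>= 1).
#' @export
mean_period_steps <- function(series) {
  sp <- spec.pgram(as.numeric(series), taper = 0.1, detrend = TRUE,
                   plot = FALSE)
  f <- sp$freq[which.max(sp$spec)]
  p <- round(1 / f)
  max(1L, min(as.integer(p), floor(length(series) / 10)))
}

#' Largest Lyapunov exponent by the Rosenstein method
#'
#' Estimates the largest Lyapunov exponent of a uniformly sampled scalar
#' series: delay-embed the series, pair each point with its nearest
#' neighbour whose temporal separation exceeds the mean period (so the
#' pair lies on different orbits), track the log distance of each pair
#' over a horizon, average over pairs, and fit a line to the initial
#' (pre-plateau) region of the mean log-divergence curve. The slope,
#' divided by the sampling period, is the exponent.
#'
#' @param series numeric vector (>= 1000 samples recommended).
#' @param embedding an [embedding_params()], or `NULL` to estimate the lag
#'   (mutual information), dimension (false nearest neighbours) and mean
#'   period (spectral peak) from the series.
#' @param sample_period time between samples.
#' @param fit_range integer vector `c(start, end)` of horizon steps for
#'   the linear fit. `NULL` selects the steepest sustained linear segment:
#'   among sliding windows one mean period long (at least 5 steps) lying
#'   before the point where the curve has completed 80% of its rise, the
#'   window with the largest least-squares slope is fitted. Averaging over
#'   a whole orbital period cancels the scalloping of the divergence
#'   curve, and the 80% guard keeps the fit off the saturation plateau.
#' @param horizon number of steps to track pair divergence; default
#'   `min(6 * mean period, M/4)`.
#' @param zero_band classification band: exponents within `zero_band` of 0
#'   count as periodic/quasiperiodic.
#' @return An `lle_estimate`: list with `lambda1`, `fit_range_steps`,
#'   `r_squared`, `classification`, `low_confidence`, `embedding`, and
#'   `curve` (a `divergence_curve` with `horizon_steps`,
#'   `mean_log_divergence`, `n_pairs`).
#' @examples
#' \donttest{
#' x <- generate_fixture("logistic_map", 2000, seed = 7)
#' rosenstein_lle(x, sample_period = 1)$lambda1   # about log(2)
#' }
#' @export
rosenstein_lle <- function(series, embedding = NULL, sample_period = 1,
                           fit_range = NULL, horizon = NULL,
                           zero_band = 0.02) {
  series <- as.numeric(series)
  N <- length(series)
  if (N < 200) stop("series too short for a divergence estimate")
  if (is.null(embedding)) {
    J <- estimate_delay(series)
    m <- estimate_dimension(series, J)
    mp <- mean_period_steps(series)
    embedding <- embedding_params(J, max(2L, as.integer(m)), mp)
  }
  stopifnot(inherits(embedding, "embedding_params"))
  J <- embedding$delay_steps
  m <- embedding$dimension
  mp <- embedding$mean_period_steps
  if ((m - 1L) * J >= N / 2) stop("embedding window exceeds half the series")
  X <- embed_series(series, m, J)
  M <- nrow(X)
  nn <- nearest_neighbors(X, exclude = mp)
  if (all(is.na(nn$idx))) stop("no valid neighbour pairs found")
  if (is.null(horizon)) horizon <- max(10L, min(6L * mp, floor(M / 4)))
  horizon <- min(horizon, M - 1L)
  steps <- 0:horizon
  mean_log <- rep(NA_real_, horizon + 1L)
  npairs <- integer(horizon + 1L)
  i_all <- seq_len(M)
  for (k in steps) {
    ok <- which(!is.na(nn$idx) & (i_all + k) <= M & (nn$idx + k) <= M)
    if (!length(ok)) break
    dd <- sqrt(rowSums((X[ok + k, , drop = FALSE] -
                        X[nn$idx[ok] + k, , drop = FALSE])^2))
    pos <- dd > 0
    if (!any(pos)) next
    mean_log[k + 1L] <- mean(log(dd[pos]))
    npairs[k + 1L] <- sum(pos)
  }
  valid <- which(!is.na(mean_log))
  curve <- structure(list(horizon_steps = steps[valid],
                          mean_log_divergence = mean_log[valid],
                          n_pairs = min(npairs[valid])),
                     class = "divergence_curve")
  y <- mean_log[valid]
  kv <- steps[valid]
  if (is.null(fit_range)) {
    wlen <- max(5L, mp)
    rise <- y - y[1]
    k80 <- kv[which(rise >= 0.8 * max(rise))[1]]
    if (is.na(k80)) k80 <- kv[length(kv)]
    best_s <- NA_integer_; best_slope <- -Inf
    s_max <- length(kv) - wlen
    if (s_max >= 1L) {
      for (s in 1:s_max) {
        if (kv[s + wlen] > k80 && is.finite(best_slope)) break
        kkw <- kv[s:(s + wlen)]
        yw <- y[s:(s + wlen)]
        sl <- sum((kkw - mean(kkw)) * (yw - mean(yw))) /
          sum((kkw - mean(kkw))^2)
        if (sl > best_slope) { best_slope <- sl; best_s <- s }
      }
    }
    if (is.na(best_s)) fit_range <- c(kv[1], kv[length(kv)])
    else fit_range <- c(kv[best_s], kv[best_s + wlen])
  }
  sel <- valid[steps[valid] >= fit_range[1] & steps[valid] <= fit_range[2]]
  if (length(sel) < 3) stop("fit range contains fewer than 3 points")
  kk <- steps[sel]
  fit <- lm(mean_log[sel] ~ kk)
  lambda1 <- unname(coef(fit)[2]) / sample_period
  r2 <- summary(fit)$r.squared
  structure(list(lambda1 = lambda1,
                 fit_range_steps = as.integer(fit_range),
                 r_squared = r2,
                 classification = classify_by_lle(lambda1, zero_band),
                 low_confidence = r2 < 0.5,
                 embedding = embedding,
                 sample_period = sample_period,
                 curve = curve),
            class = "lle_estimate")
}

#' @export
print.lle_estimate <- function(x, ...) {
  cat(sprintf(
    "<lle_estimate> lambda1 = %.4f /time (%s), fit steps [%d, %d], r^2 = %.3f%s\n",
    x$lambda1, x$classification, x$fit_range_steps[1], x$fit_range_steps[2],
    x$r_squared, if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Classify an attractor by the sign of its largest Lyapunov exponent
#'
#' Positive exponent: chaotic motion; within the zero band: limit cycle or
#' quasiperiodic motion; negative: fixed-point attractor.
#'
#' @param lambda1 largest Lyapunov exponent (inverse time units).
#' @param zero_band half-width of the band treated as zero (> 0).
#' @return One of `"chaotic"`, `"limit_cycle_or_quasiperiodic"`,
#'   `"fixed_point"`.
#' @examples
#' classify_by_lle(0.0995)
#' @export
classify_by_lle <- function(lambda1, zero_band = 0.02) {
  if (zero_band <= 0) stop("`zero_band` must be positive")
  if (is.na(lambda1)) return(NA_character_)
  if (lambda1 > zero_band) "chaotic"
  else if (lambda1 < -zero_band) "fixed_point"
  else "limit_cycle_or_quasiperiodic"
}

#' Largest Lyapunov exponent against the commensurate order
#'
#' Simulates the fractional Rossler system at each order, discards the
#' transient, samples the x coordinate at `sample_period`, and estimates
#' the largest Lyapunov exponent per cell. Cells whose post-transient
#' motion has collapsed to a fixed point are labelled directly (the
#' divergence method needs an extended attractor). Failures are recorded
#' per cell, not raised. Isolated positive cells inside an otherwise
#' periodic band are annotated as period-window candidates.
#'
#' @param params a [rossler_params()] (its `alpha` is overridden per cell).
#' @param alpha_values orders in (0, 1].
#' @param t_end,transient,h integration horizon, discarded head, and step.
#' @param sample_period spacing of the analyzed series (a multiple of `h`).
#' @param embedding optional fixed [embedding_params()] reused across
#'   cells (default: estimated per cell).
#' @param init initial state.
#' @param zero_band classification band for the exponent.
#' @return `data.frame` with columns `alpha`, `lambda1`, `r_squared`,
#'   `classification`, `period_window_candidate`, `status`; the
#'   per-cell `lle_estimate` objects are in `attr(, "estimates")`.
#' @export
lle_vs_order <- function(params, alpha_values, t_end = 300, transient = 100,
                         h = 0.01, sample_period = 0.1, embedding = NULL,
                         init = c(1, 1, 1), zero_band = 0.02) {
  stopifnot(inherits(params, "rossler_params"))
  every <- round(sample_period / h)
  if (abs(every * h - sample_period) > 1e-12)
    stop("`sample_period` must be a multiple of `h`")
  grid <- time_grid(round(t_end / h), h)
  estimates <- vector("list", length(alpha_values))
  rows <- lapply(seq_along(alpha_values), function(i) {
    a <- alpha_values[i]
    row <- data.frame(alpha = a, lambda1 = NA_real_, r_squared = NA_real_,
                      classification = NA_character_,
                      period_window_candidate = FALSE, status = "ok")
    tr <- tryCatch(solve_fde(rossler_system(
      rossler_params(params$a, params$b, params$c, alpha = a)), init, grid),
      error = function(e) e)
    if (inherits(tr, "error")) { row$status <- conditionMessage(tr); return(row) }
    if (tr$status != "ok") { row$status <- tr$status; return(row) }
    keep <- tr$times > transient
    x <- tr$states[keep, 1][seq(1, sum(keep), by = every)]
    # a collapsed or peakless (monotonically relaxing) series is a
    # fixed-point attractor; the divergence method needs an extended orbit
    if (diff(range(x)) < 1e-6 ||
        length(find_peaks(x, min_prominence = 1e-9)) == 0L) {
      row$classification <- "fixed_point"
      return(row)
    }
    est <- tryCatch(
      rosenstein_lle(x, embedding = embedding,
                     sample_period = sample_period, zero_band = zero_band),
      error = function(e) e)
    if (inherits(est, "error")) { row$status <- conditionMessage(est); return(row) }
    estimates[[i]] <<- est
    row$lambda1 <- est$lambda1
    row$r_squared <- est$r_squared
    row$classification <- est$classification
    row
  })
  out <- do.call(rbind, rows)
  # isolated chaotic cell between periodic neighbours: periodic-window candidate
  ch <- out$classification == "chaotic" & !is.na(out$classification)
  if (nrow(out) >= 3) {
    for (i in 2:(nrow(out) - 1))
      if (isTRUE(ch[i]) && !isTRUE(ch[i - 1]) && !isTRUE(ch[i + 1]))
        out$period_window_candidate[i] <- TRUE
  }
  attr(out, "estimates") <- estimates
  out
}

#' Non-chaotic probability under a uniform order prior
#'
#' Treats the commensurate order as uniformly distributed on (0, 1],
#' locates the chaos-onset critical order from an exponent-vs-order scan
#' (the smallest order classified chaotic), optionally refines the onset
#' by one bisection between the bracketing grid points, and returns the
#' measure of the non-chaotic order set -- the probability that a system
#' with a randomly drawn order behaves non-chaotically.
#'
#' @param scan `data.frame` from [lle_vs_order()] (columns `alpha` and
#'   `classification`, optionally `lambda1`).
#' @param zero_band if `lambda1` is present, classification is re-derived
#'   as `lambda1 > zero_band` (cells with `NA` exponent count as
#'   non-chaotic only when explicitly classified `fixed_point`).
#' @param classify_fun optional `function(alpha) -> logical` (TRUE =
#'   chaotic) used for the single bisection refinement between the last
#'   non-chaotic and first chaotic grid points.
#' @return Probability (numeric scalar) with attributes `alpha_c`
#'   (estimated critical order) and `chaotic_measure`
#'   (`1 - probability`).
#' @export
nonchaotic_probability <- function(scan, zero_band = 0.02,
                                   classify_fun = NULL) {
  stopifnot(is.data.frame(scan), "alpha" %in% names(scan))
  scan <- scan[order(scan$alpha), ]
  if ("lambda1" %in% names(scan)) {
    chaotic <- !is.na(scan$lambda1) & scan$lambda1 > zero_band
  } else {
    chaotic <- scan$classification == "chaotic" & !is.na(scan$classification)
  }
  if (!any(chaotic)) {
    warning("no chaotic cell in the scan; non-chaotic measure is 1")
    return(structure(1.0, alpha_c = NA_real_, chaotic_measure = 0.0))
  }
  hi <- min(scan$alpha[chaotic])
  below <- scan$alpha < hi & !chaotic
  if (!any(below)) {
    warning("every scanned order is chaotic down to the grid floor")
    p <- min(scan$alpha)
    return(structure(p, alpha_c = p, chaotic_measure = 1 - p))
  }
  lo <- max(scan$alpha[below])
  if (!is.null(classify_fun)) {
    mid <- (lo + hi) / 2
    if (isTRUE(classify_fun(mid))) hi <- mid else lo <- mid
  }
  alpha_c <- (lo + hi) / 2
  structure(alpha_c, alpha_c = alpha_c, chaotic_measure = 1 - alpha_c)
}
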