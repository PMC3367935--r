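#' Steady state of the one-variable Goodwin model
#'
#' The unique non-negative root of \eqn{1/(1 + x^n) = k_2 x}: the
#' intersection of the strictly decreasing synthesis rate with the strictly
#' increasing degradation rate. Found by bracketing root search and
#' polished by Newton steps to residual below `1e-12`. The steady state is
#' shared by the delayed and fractional variants (delay and order do not
#' move the fixed point, only its stability).
#'
#' @param params a [goodwin_params()].
#' @return The steady-state concentration (scalar), with attribute
#'   `residual`.
#' @examples
#' goodwin_fixed_point(goodwin_params(n = 1, k2 = 1))  # (sqrt(5) - 1) / 2
#' @export
goodwin_fixed_point <- function(params) {
  stopifnot(inherits(params, "goodwin_params"))
  g <- function(x) 1 / (1 + x^params$n) - params$k2 * x
  upper <- 1 / params$k2 + 1
  x <- uniroot(g, c(0, upper), tol = 1e-14)$root
  for (i in 1:8) { # Newton polish
    gp <- -params$n * x^(params$n - 1) / (1 + x^params$n)^2 - params$k2
    step <- g(x) / gp
    if (!is.finite(step)) break
    x <- x - step
    if (abs(g(x)) < 1e-13) break
  }
  structure(x, residual = g(x))
}

goodwin3_fixed_point <- function(n, k2) {
  # x3 solves k2^3 * x (1 + x^n) = 1; x2 = k2 x3, x1 = k2 x2
  g <- function(x) k2^3 * x * (1 + x^n) - 1
  upper <- max(2, (1 / k2^3)^(1 / (n + 1)) * 2 + 2)
  x3 <- uniroot(g, c(0, upper), tol = 1e-14)$root
  c(k2^2 * x3, k2 * x3, x3)
}

#' Linear stability of the symmetric three-variable Goodwin loop
#'
#' Fixed point and Jacobian eigenvalues of the symmetric chain
#' \eqn{x_1' = 1/(1+x_3^n) - k_2 x_1}, \eqn{x_2' = x_1 - k_2 x_2},
#' \eqn{x_3' = x_2 - k_2 x_3}. The loop is stable iff all eigenvalues of
#' the Jacobian at the fixed point have negative real part; the
#' characteristic equation is \eqn{(\lambda + k_2)^3 = -c} with loop gain
#' \eqn{c = n x_3^{n-1}/(1 + x_3^n)^2}, so instability requires
#' \eqn{c > 8 k_2^3} (the secant condition for three identical stages).
#'
#' @param n Hill coefficient.
#' @param k2 common degradation rate.
#' @return A `stability_report`: list with `fixed_point`, `eigenvalues`,
#'   `stable`, `loop_gain_ratio` (the gain \eqn{c/k_2^3}; 8 at the Hopf
#'   boundary).
#' @examples
#' goodwin3_stability(n = 9, k2 = 0.5)
#' @export
goodwin3_stability <- function(n, k2) {
  if (n < 1 || k2 <= 0) stop("need n >= 1 and k2 > 0")
  fp <- goodwin3_fixed_point(n, k2)
  x3 <- fp[3]
  cgain <- n * x3^(n - 1) / (1 + x3^n)^2
  J <- rbind(c(-k2, 0, -cgain),
             c(1, -k2, 0),
             c(0, 1, -k2))
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(fixed_point = fp, eigenvalues = ev,
                 stable = all(Re(ev) < 0),
                 loop_gain_ratio = cgain / k2^3),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s; max Re(eigenvalue) = %.3g; gain ratio %.4g\n",
              if (x$stable) "stable" else "unstable",
              max(Re(x$eigenvalues)), x$loop_gain_ratio))
  invisible(x)
}

#' Critical Hill coefficient of the symmetric three-variable Goodwin loop
#'
#' The infimum Hill coefficient at which the fixed point of the symmetric
#' loop can lose linear stability for some choice of the common rate
#' constant. For three identical first-order stages the secant condition
#' gives instability iff the normalized loop gain \eqn{n\,u/(1+u)} (with
#' \eqn{u = x_3^{*n}}) exceeds \eqn{\sec^3(\pi/3) = 8}; since
#' \eqn{u/(1+u) < 1} approaches 1 as the degradation rate shrinks, the
#' infimum over rates is exactly 8. Computed generically by bisection on
#' `n` with a Jacobian eigenvalue test minimized over a rate grid, which
#' extends to asymmetric rates later; the closed-form secant value is the
#' cross-check.
#'
#' @param symmetric_rates must be `TRUE` (the asymmetric case is out of
#'   scope).
#' @param tol bisection tolerance on `n`.
#' @param k2_grid rate constants over which instability is sought (the
#'   supremum over rates is approached as `k2` shrinks).
#' @return The critical Hill coefficient (numeric scalar).
#' @examples
#' goodwin3_critical_hill()
#' @export
goodwin3_critical_hill <- function(symmetric_rates = TRUE, tol = 1e-8,
                                   k2_grid = 10^seq(0, -5, by = -1)) {
  if (!isTRUE(symmetric_rates))
    stop("asymmetric-rate critical Hill surfaces are not implemented")
  unstable_for_some_rate <- function(n) {
    for (k2 in k2_grid) {
      if (!goodwin3_stability(n, k2)$stable) return(TRUE)
    }
    FALSE
  }
  lo <- 1; hi <- 16
  if (!unstable_for_some_rate(hi)) stop("no instability found up to n = 16")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (unstable_for_some_rate(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (min_prominence > 0 && length(idx)) {
    tr <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
    keep <- vapply(idx, function(i) {
      lo <- tr[tr < i]; hi <- tr[tr > i]
      base <- max(c(if (length(lo)) x[max(lo)], if (length(hi)) x[min(hi)],
                    -Inf))
      if (!is.finite(base)) base <- min(x)
      (x[i] - base) > min_prominence
    }, logical(1))
    idx <- idx[keep]
  }
  idx
}

#' Classify a trajectory's long-run behavior
#'
#' Discards the initial `transient_fraction` of the samples, detects local
#' maxima of the chosen observable, and labels the post-transient motion:
#' \describe{
#'   \item{`fixed_point`}{post-transient range below `tolerance` (or a
#'     peakless trajectory whose tail has settled);}
#'   \item{`sustained_oscillation`}{at least `min_peaks` peaks whose
#'     amplitude trend (least-squares slope of peak height against peak
#'     time) is not decaying, i.e. `>= -slope_tol` per time unit;}
#'   \item{`damped_oscillation`}{oscillatory but with decaying peaks;}
#'   \item{`irregular`}{erratic peak spacing (coefficient of variation of
#'     inter-peak intervals above `cv_threshold`) or a non-settling
#'     peakless trajectory.}
#' }
#'
#' @param traj an `fde_trajectory` (errors if flagged as blown up), or a
#'   numeric vector with `times` supplied.
#' @param transient_fraction fraction of samples discarded as transient.
#' @param tolerance absolute range below which the motion counts as at a
#'   fixed point.
#' @param observable column index of the observable.
#' @param min_peaks peaks required for a sustained label.
#' @param slope_tol amplitude-trend slope tolerance (per time unit).
#' @param cv_threshold inter-peak-interval CV above which motion is
#'   irregular.
#' @param times sample times when `traj` is a plain vector.
#' @return A `trajectory_class`: list with `label`, `amplitude_trend`,
#'   `peak_count`.
#' @examples
#' t <- seq(0, 120, by = 0.05)
#' classify_trajectory(exp(-0.05 * t) * sin(t), times = t)$label
#' @export
classify_trajectory <- function(traj, transient_fraction = 0.5,
                                tolerance = 1e-3, observable = 1L,
                                min_peaks = 5L, slope_tol = 1e-4,
                                cv_threshold = 0.4, times = NULL) {
  if (inherits(traj, "fde_trajectory")) {
    if (traj$status != "ok")
      stop("trajectory is flagged '", traj$status, "'; cannot classify")
    x <- traj$states[, observable]
    tt <- traj$times
  } else {
    x <- as.numeric(traj)
    tt <- if (is.null(times)) seq_along(x) else times
  }
  n <- length(x)
  i0 <- max(1L, floor(n * transient_fraction) + 1L)
  x <- x[i0:n]; tt <- tt[i0:n]
  out <- function(label, trend = 0, count = 0L)
    structure(list(label = label, amplitude_trend = trend,
                   peak_count = as.integer(count)),
              class = "trajectory_class")
  rng <- diff(range(x))
  if (rng < tolerance) return(out("fixed_point"))
  pk <- find_peaks(x, min_prominence = tolerance / 4)
  if (length(pk) < 2) {
    # peakless: settling (tail nearly still relative to the whole window)
    # counts as heading to a fixed point, otherwise the motion is erratic
    tail_n <- max(2L, floor(length(x) * 0.2))
    tail_rng <- diff(range(x[(length(x) - tail_n + 1L):length(x)]))
    if (tail_rng < max(tolerance, 0.1 * rng)) return(out("fixed_point"))
    return(out("irregular", count = length(pk)))
  }
  heights <- x[pk]; ptimes <- tt[pk]
  gaps <- diff(ptimes)
  cv <- if (length(gaps) >= 2) sd(gaps) / mean(gaps) else 0
  trend <- unname(coef(lm(heights ~ ptimes))[2])
  if (cv > cv_threshold) return(out("irregular", trend, length(pk)))
  if (length(pk) >= min_peaks && trend >= -slope_tol)
    return(out("sustained_oscillation", trend, length(pk)))
  out("damped_oscillation", trend, length(pk))
}

#' @export
print.trajectory_class <- function(x, ...) {
  cat(sprintf("<trajectory_class> %s (%d peaks, amplitude trend %.3g)\n",
              x$label, x$peak_count, x$amplitude_trend))
  invisible(x)
}

default_goodwin_grid <- function(t_end = 500, h = 0.01) {
  time_grid(round(t_end / h), h)
}

#' Sweep the transcriptional delay of the Goodwin oscillator
#'
#' Solves the fractional delay Goodwin oscillator at each delay in
#' `tau_values` (constant history at the initial value) and classifies the
#' post-transient motion. At orders near 1 and default `(n, k2)` the
#' classification moves monotonically from fixed/damped at small delay to
#' sustained oscillation at large delay.
#'
#' @param params a [goodwin_params()] (its `tau` field is overridden).
#' @param tau_values positive delays, sorted increasing.
#' @param t_end,h integration horizon and step.
#' @param init history/initial value.
#' @param ... passed to [classify_trajectory()].
#' @return `data.frame` with columns `tau`, `label`, `peak_count`,
#'   `amplitude_trend`, `status`.
#' @examples
#' \donttest{
#' delay_sweep(goodwin_params(alpha = 1), c(1, 25), t_end = 200)
#' }
#' @export
delay_sweep <- function(params, tau_values, t_end = 500, h = 0.01,
                        init = 0.1, ...) {
  stopifnot(inherits(params, "goodwin_params"))
  if (any(tau_values <= 0) || is.unsorted(tau_values))
    stop("`tau_values` must be positive and sorted")
  rows <- lapply(tau_values, function(tau) {
    p <- goodwin_params(params$n, params$k2, tau, params$alpha)
    res <- tryCatch({
      tr <- solve_fdde(fractional_delay_goodwin(p), history_spec(init),
                       default_goodwin_grid(t_end, h))
      cl <- classify_trajectory(tr, ...)
      data.frame(tau = tau, label = cl$label, peak_count = cl$peak_count,
                 amplitude_trend = cl$amplitude_trend, status = tr$status)
    }, error = function(e)
      data.frame(tau = tau, label = NA_character_, peak_count = NA_integer_,
                 amplitude_trend = NA_real_, status = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}

#' Sweep the Caputo order of the Goodwin oscillator
#'
#' Solves the fractional delay Goodwin oscillator at each order in
#' `alpha_values` with fixed `(n, k2, tau)` and classifies the
#' post-transient motion. Reducing the order (weakening the
#' transcriptional memory) stabilizes the loop: where order 0.9 sustains a
#' limit cycle, order 0.7 relaxes to the fixed point.
#'
#' @param params a [goodwin_params()] (its `alpha` field is overridden).
#' @param alpha_values orders in (0, 1].
#' @inheritParams delay_sweep
#' @return `data.frame` with columns `alpha`, `label`, `peak_count`,
#'   `amplitude_trend`, `status`.
#' @export
order_sweep <- function(params, alpha_values, t_end = 500, h = 0.01,
                        init = 0.1, ...) {
  stopifnot(inherits(params, "goodwin_params"))
  rows <- lapply(alpha_values, function(alpha) {
    p <- goodwin_params(params$n, params$k2, params$tau, alpha)
    res <- tryCatch({
      tr <- solve_fdde(fractional_delay_goodwin(p), history_spec(init),
                       default_goodwin_grid(t_end, h))
      cl <- classify_trajectory(tr, ...)
      data.frame(alpha = alpha, label = cl$label, peak_count = cl$peak_count,
                 amplitude_trend = cl$amplitude_trend, status = tr$status)
    }, error = function(e)
      data.frame(alpha = alpha, label = NA_character_,
                 peak_count = NA_integer_, amplitude_trend = NA_real_,
                 status = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}

cluster_maxima <- function(vals, merge_tol) {
  if (!length(vals)) return(numeric(0))
  v <- sort(vals)
  splits <- which(diff(v) > merge_tol)
  starts <- c(1L, splits + 1L)
  ends <- c(splits, length(v))
  vapply(seq_along(starts),
         function(i) mean(v[starts[i]:ends[i]]), numeric(1))
}

#' Bifurcation scan against the fractional order
#'
#' For each order, integrates the system produced by `spec_factory(alpha)`,
#' discards the transient, and collects the distinct post-transient local
#' maxima of the chosen observable (parabolically refined, then merged
#' within `merge_tol`). One cluster indicates period-one motion, two
#' period-two, three period-three; many distinct maxima indicate a chaotic
#' candidate. Blown-up cells are recorded as missing.
#'
#' @param spec_factory function `alpha -> fde_system`.
#' @param alpha_values strictly increasing orders in (0, 1].
#' @param observable coordinate index whose maxima are collected.
#' @param transient_fraction fraction of the run discarded.
#' @param t_end,h integration horizon and step (defaults sized for the
#'   Rossler timescale).
#' @param init initial state passed to the solver.
#' @param merge_tol maxima closer than this merge into one cluster.
#' @return A `bifurcation_scan`: list with `alpha_values`,
#'   `maxima_per_alpha` (list of cluster centers; `NULL` for failed
#'   cells), `n_clusters`, `raw_maxima`.
#' @examples
#' \donttest{
#' bs <- bifurcation_scan(
#'   function(a) rossler_system(rossler_params(alpha = a)),
#'   c(0.90, 1.0), init = c(1, 1, 1), t_end = 300)
#' bs$n_clusters
#' }
#' @export
bifurcation_scan <- function(spec_factory, alpha_values, observable = 1L,
                             transient_fraction = 0.5, t_end = 1000,
                             h = 0.01, init = c(1, 1, 1),
                             merge_tol = 1e-3) {
  if (is.unsorted(alpha_values, strictly = TRUE))
    stop("`alpha_values` must be strictly increasing")
  vapply(alpha_values, check_alpha, numeric(1))
  grid <- time_grid(round(t_end / h), h)
  res <- lapply(alpha_values, function(a) {
    sys <- spec_factory(a)
    tr <- solve_fde(sys, init, grid)
    if (tr$status != "ok") return(NULL)
    x <- tr$states[, observable]
    n <- length(x)
    i0 <- max(1L, floor(n * transient_fraction) + 1L)
    x <- x[i0:n]
    pk <- find_peaks(x, min_prominence = merge_tol)
    if (!length(pk)) return(list(raw = numeric(0)))
    # parabolic refinement of the peak value reduces grid-sampling jitter
    vals <- vapply(pk, function(i) {
      if (i <= 1L || i >= length(x)) return(x[i])
      y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
      den <- y1 - 2 * y2 + y3
      if (den == 0) return(y2)
      y2 - (y3 - y1)^2 / (8 * den)
    }, numeric(1))
    list(raw = vals)
  })
  maxima <- lapply(res, function(r)
    if (is.null(r)) NULL else cluster_maxima(r$raw, merge_tol))
  structure(list(alpha_values = alpha_values,
                 maxima_per_alpha = maxima,
                 n_clusters = vapply(maxima, function(m)
                   if (is.null(m)) NA_integer_ else length(m), integer(1)),
                 raw_maxima = lapply(res, function(r)
                   if (is.null(r)) NULL else r$raw),
                 transient_fraction = transient_fraction),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat("<bifurcation_scan>\n")
  print(data.frame(alpha = x$alpha_values, clusters = x$n_clusters))
  invisible(x)
}

#' @export
plot.bifurcation_scan <- function(x, ...) {
  a <- rep(x$alpha_values, vapply(x$raw_maxima, length, integer(1)))
  v <- unlist(x$raw_maxima)
  graphics::plot(a, v, pch = ".", xlab = "order alpha",
                 ylab = "post-transient local maxima", ...)
  invisible(x)
}

#' @rdname bifurcation_scan
#' @param x a `bifurcation_scan`.
#' @return `as.data.frame`: long-format `data.frame` with columns `alpha`,
#'   `maximum_value`.
#' @export
as.data.frame.bifurcation_scan <- function(x, ...) {
  data.frame(alpha = rep(x$alpha_values,
                         vapply(x$raw_maxima, length, integer(1))),
             maximum_value = unlist(x$raw_maxima))
}
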