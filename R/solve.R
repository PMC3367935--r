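#' Commensurate fractional (delay) differential equation system
#'
#' Describes a system \eqn{D^\alpha y = f(t, y, y(t-\tau))} where
#' \eqn{D^\alpha} is the left-sided Caputo derivative of common
#' (commensurate) order `alpha` in every coordinate and `tau >= 0` is a
#' single fixed delay (0 for none).
#'
#' @param dimension number of state variables (>= 1).
#' @param rhs either a function `f(t, y, ylag, params)` returning the
#'   state-increment vector (`ylag` is `NULL` for undelayed systems), or
#'   the name of a compiled built-in right-hand side: `"rossler"`
#'   (params `a`, `b`, `c`) or `"goodwin_delay"` (params `n`, `k2`).
#' @param alpha commensurate Caputo order in (0, 1].
#' @param delay fixed delay `tau >= 0` in time units.
#' @param params named list of parameters passed to `rhs`.
#' @param labels optional coordinate names.
#' @return Object of class `fde_system`.
#' @examples
#' sys <- fde_system(1, function(t, y, ylag, p) -y, alpha = 0.7)
#' @export
fde_system <- function(dimension, rhs, alpha, delay = 0, params = list(),
                       labels = NULL) {
  if (dimension < 1 || dimension != round(dimension))
    stop("`dimension` must be a positive integer")
  alpha <- check_alpha(alpha)
  if (!is.numeric(delay) || length(delay) != 1L || delay < 0)
    stop("`delay` must be a single number >= 0")
  builtin <- 0L
  if (is.character(rhs)) {
    builtin <- switch(rhs, rossler = 1L, goodwin_delay = 2L,
                      stop("unknown built-in rhs: ", rhs))
    rhs_name <- rhs
    rhs <- NULL
  } else {
    stopifnot(is.function(rhs))
    rhs_name <- "custom"
  }
  if (is.null(labels)) labels <- c("x", "y", "z", paste0("x", 4:9))[seq_len(dimension)]
  structure(list(dimension = as.integer(dimension), rhs = rhs,
                 rhs_name = rhs_name, builtin = builtin,
                 alpha = alpha, delay = as.numeric(delay),
                 params = params, labels = labels),
            class = "fde_system")
}

#' @export
print.fde_system <- function(x, ...) {
  cat(sprintf("<fde_system> dim %d, order alpha = %g, delay tau = %g, rhs '%s'\n",
              x$dimension, x$alpha, x$delay, x$rhs_name))
  invisible(x)
}

#' Initial history for a delayed system
#'
#' History segment on `[-tau, 0]` supplying the delayed argument before the
#' computed trajectory reaches back that far. The default used throughout
#' the package is a constant history equal to the initial value (the
#' simulation-diagram convention of assigning the initial value with a step
#' input).
#'
#' @param constant state vector held constant on `[-tau, 0]`, or
#' @param fn function of `t` in `[-tau, 0]` returning the state vector.
#' @return Object of class `history_spec`.
#' @examples
#' history_spec(constant = 0.5)
#' @export
history_spec <- function(constant = NULL, fn = NULL) {
  if (is.null(constant) == is.null(fn))
    stop("supply exactly one of `constant` or `fn`")
  if (!is.null(fn)) stopifnot(is.function(fn))
  structure(list(mode = if (is.null(fn)) "constant" else "function",
                 constant = if (is.null(constant)) numeric(0) else as.numeric(constant),
                 fn = fn),
            class = "history_spec")
}

new_trajectory <- function(times, states, labels, method, system, status,
                           partial = FALSE) {
  colnames(states) <- labels[seq_len(ncol(states))]
  structure(list(times = times, states = states, labels = labels,
                 method = method, alpha = system$alpha,
                 delay = system$delay, h = times[2] - times[1],
                 params = system$params, rhs_name = system$rhs_name,
                 status = status, partial = partial),
            class = "fde_trajectory")
}

#' @export
print.fde_trajectory <- function(x, ...) {
  cat(sprintf("<fde_trajectory> '%s', alpha = %g, %d points, h = %g, status: %s\n",
              x$rhs_name, x$alpha, length(x$times), x$h, x$status))
  invisible(x)
}

#' @export
as.data.frame.fde_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
plot.fde_trajectory <- function(x, observable = 1L, ...) {
  graphics::plot(x$times, x$states[, observable], type = "l",
                 xlab = "t", ylab = x$labels[observable], ...)
  invisible(x)
}

rhs_eval_r <- function(system, t, y, ylag) {
  if (system$builtin == 1L) {
    p <- system$params
    c(-y[2] - y[3], y[1] + p$a * y[2], p$b + y[3] * (y[1] - p$c))
  } else if (system$builtin == 2L) {
    p <- system$params
    xd <- if (is.null(ylag)) y[1] else ylag[1]
    xd <- max(xd, 0)
    1 / (1 + xd^p$n) - p$k2 * y[1]
  } else {
    system$rhs(t, y, ylag, system$params)
  }
}

builtin_num_params <- function(system) {
  if (system$builtin == 1L) {
    p <- system$params
    as.numeric(c(p$a, p$b, p$c))
  } else if (system$builtin == 2L) {
    p <- system$params
    as.numeric(c(p$n, p$k2))
  } else numeric(0)
}

solve_abm <- function(system, init, grid, history, blowup) {
  tau <- system$delay
  hist_is_fun <- FALSE
  hist_fun <- function(t) numeric(0)
  hist_const <- numeric(0)
  if (tau > 0) {
    if (history$mode == "function") {
      hist_is_fun <- TRUE
      hist_fun <- history$fn
    } else {
      hist_const <- rep_len(history$constant, system$dimension)
    }
  }
  rhs_fun <- if (is.null(system$rhs)) function(...) numeric(0) else system$rhs
  res <- .abm_solve_cpp(system$builtin, rhs_fun, system$params,
                        builtin_num_params(system), system$alpha, grid$h,
                        grid$n_steps, as.numeric(init), tau,
                        hist_is_fun, hist_fun, hist_const, blowup)
  times <- grid$t0 + (0:res$last_index) * grid$h
  new_trajectory(times, res$states, system$labels, "abm", system,
                 res$status, partial = res$status != "ok")
}

solve_oustaloup <- function(system, init, grid, history, blowup,
                            oust_band = c(1e-3, 1e3), oust_cells = 5,
                            desolve_method = "lsoda") {
  d <- system$dimension
  # D^alpha x = f  <=>  x' = v,  V(s) = s^(1-alpha) F(s):  the fractional
  # integrator is a pure integrator behind a band-limited differentiator of
  # order 1 - alpha (Oustaloup cells + appended low-pass).
  flt <- oustaloup_filter(1 - system$alpha, oust_band[1], oust_band[2],
                          oust_cells)
  sec <- oustaloup_sections(flt)
  nsec <- sec$n
  tau <- system$delay
  idxW <- d + seq_len(nsec * d)
  idxv <- d + nsec * d + seq_len(d)
  deriv <- function(t, state, parms) {
    x <- state[1:d]
    W <- matrix(state[idxW], nsec, d)
    v <- state[idxv]
    ylag <- NULL
    if (tau > 0) {
      ylag <- if (t <= tau) {
        if (history$mode == "function") history$fn(t - tau)
        else rep_len(history$constant, d)
      } else deSolve::lagvalue(t - tau, 1:d)
    }
    u <- rhs_eval_r(system, t, x, ylag)
    ch <- oustaloup_chain_deriv(sec, W, v, u)
    list(c(v, as.numeric(ch$dW), ch$dv))
  }
  state0 <- c(as.numeric(init), rep(0, nsec * d), rep(0, d))
  times <- grid_times(grid)
  out <- tryCatch({
    if (tau > 0)
      deSolve::dede(y = state0, times = times, func = deriv, parms = NULL,
                    method = desolve_method)
    else
      deSolve::ode(y = state0, times = times, func = deriv, parms = NULL,
                   method = desolve_method)
  }, error = function(e) NULL)
  if (is.null(out)) {
    states <- matrix(as.numeric(init), nrow = 1)
    return(new_trajectory(times[1:2], rbind(states, states), system$labels,
                          "oustaloup", system, "blowup", partial = TRUE))
  }
  states <- unname(as.matrix(out[, 1 + (1:d), drop = FALSE]))
  bad <- !is.finite(states) | abs(states) > blowup
  if (any(bad)) {
    k <- min(which(apply(bad, 1, any))) - 1L
    k <- max(k, 1L)
    return(new_trajectory(times[1:k], states[1:k, , drop = FALSE],
                          system$labels, "oustaloup", system, "blowup",
                          partial = TRUE))
  }
  new_trajectory(times[seq_len(nrow(states))], states, system$labels,
                 "oustaloup", system, "ok")
}

#' Integrate a commensurate fractional system
#'
#' Solves \eqn{D^\alpha y = f(t, y)} from `y(0) = init` on a uniform grid.
#' The reference scheme (`method = "abm"`) is the fractional
#' Adams-Bashforth-Moulton predictor-corrector, a direct time-domain
#' discretization of the Caputo memory integral (compiled; cost grows
#' quadratically with the number of steps because the whole past enters
#' every step). The alternative (`method = "oustaloup"`) realizes the
#' fractional integrator as a band-limited Oustaloup filter chain with an
#' appended low-pass, integrated as an ordinary state-space system by
#' \pkg{deSolve}; it reproduces the block-diagram simulation route and
#' serves as an independent cross-check of the reference scheme.
#'
#' If any state exceeds `blowup` in magnitude (or becomes non-finite) the
#' solver stops and returns the partial trajectory with
#' `status = "blowup"`; instability is a detectable outcome, not a crash.
#'
#' @param system an [fde_system()] with `delay == 0`.
#' @param init initial state vector.
#' @param grid a [time_grid()].
#' @param method `"abm"` (reference) or `"oustaloup"`.
#' @param blowup magnitude threshold for declaring divergence.
#' @param ... further arguments to the Oustaloup route
#'   (`oust_band`, `oust_cells`, `desolve_method`).
#' @return An `fde_trajectory`.
#' @examples
#' sys <- fde_system(1, function(t, y, ylag, p) -y, alpha = 0.7)
#' tr <- solve_fde(sys, 1, time_grid(500, 0.01))
#' # matches the Mittag-Leffler relaxation E_alpha(-t^alpha)
#' max(abs(tr$states[, 1] - mittag_leffler(0.7, -tr$times^0.7)))
#' @export
solve_fde <- function(system, init, grid, method = c("abm", "oustaloup"),
                      blowup = 1e8, ...) {
  method <- match.arg(method)
  stopifnot(inherits(system, "fde_system"), inherits(grid, "time_grid"))
  if (system$delay > 0)
    stop("system has a delay; use solve_fdde() with a history")
  if (length(init) != system$dimension)
    stop("`init` must have length ", system$dimension)
  if (method == "abm") solve_abm(system, init, grid, NULL, blowup)
  else solve_oustaloup(system, init, grid, NULL, blowup, ...)
}

#' Integrate a commensurate fractional delay system
#'
#' Solves \eqn{D^\alpha y = f(t, y, y(t - \tau))} with the delayed argument
#' taken from `history` for `t <= tau` and from linear interpolation of the
#' computed trajectory thereafter. The Caputo memory integral itself always
#' starts at `t = 0` (left-sided operator); the delay enters only through
#' the right-hand side.
#'
#' @param system an [fde_system()] with `delay > 0` (and
#'   `delay >= grid$h`; a delay below the step size is unresolvable).
#' @param history a [history_spec()], or a numeric vector shorthand for a
#'   constant history.
#' @inheritParams solve_fde
#' @return An `fde_trajectory`. The initial state is the history value at
#'   `t = 0`.
#' @examples
#' p <- goodwin_params(n = 10, k2 = 0.1, tau = 20, alpha = 0.9)
#' sys <- fractional_delay_goodwin(p)
#' tr <- solve_fdde(sys, history_spec(constant = 0.1), time_grid(2000, 0.05))
#' @export
solve_fdde <- function(system, history, grid, method = c("abm", "oustaloup"),
                       blowup = 1e8, ...) {
  method <- match.arg(method)
  stopifnot(inherits(system, "fde_system"), inherits(grid, "time_grid"))
  if (system$delay <= 0)
    stop("system has no delay; use solve_fde()")
  if (system$delay < grid$h)
    stop("delay tau = ", system$delay, " is smaller than the step h = ",
         grid$h, "; refine the grid")
  if (is.numeric(history)) history <- history_spec(constant = history)
  stopifnot(inherits(history, "history_spec"))
  init <- if (history$mode == "function") history$fn(0)
          else rep_len(history$constant, system$dimension)
  if (length(init) != system$dimension)
    stop("history value must have length ", system$dimension)
  if (method == "abm") solve_abm(system, init, grid, history, blowup)
  else solve_oustaloup(system, init, grid, history, blowup, ...)
}
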