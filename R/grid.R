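#' Uniform time grid
#'
#' Discretization grid used by all operators and solvers. Grids start at
#' `t0 = 0`: the memory operators are left-sided, anchored at the initial
#' time, so every computation shares the same causal origin.
#'
#' @param n_steps number of steps (grid has `n_steps + 1` points).
#' @param h step size (> 0), in the model's dimensionless time unit.
#' @param t0 initial time; fixed at 0.
#' @return An object of class `time_grid` with fields `t0`, `h`, `n_steps`.
#' @examples
#' g <- time_grid(100, 0.01)
#' head(grid_times(g))
#' @export
time_grid <- function(n_steps, h, t0 = 0) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("`h` must be a single positive number")
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != round(n_steps))
    stop("`n_steps` must be a positive integer")
  if (!identical(as.numeric(t0), 0))
    stop("grids are anchored at t0 = 0 (left-sided operators)")
  structure(list(t0 = 0, h = as.numeric(h), n_steps = as.integer(n_steps)),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid a `time_grid`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + (0:grid$n_steps) * grid$h
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d steps of h = %g on [0, %g]\n",
              x$n_steps, x$h, x$n_steps * x$h))
  invisible(x)
}

#' Function sampled on a uniform grid
#'
#' @param grid a [time_grid()].
#' @param values numeric vector, one value per grid point
#'   (length `n_steps + 1`).
#' @return An object of class `sampled_fn`.
#' @examples
#' g <- time_grid(10, 0.1)
#' sampled_fn(g, sin(grid_times(g)))
#' @export
sampled_fn <- function(grid, values) {
  stopifnot(inherits(grid, "time_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_steps + 1L)
    stop("`values` must have length n_steps + 1 = ", grid$n_steps + 1L)
  structure(list(grid = grid, values = values), class = "sampled_fn")
}

#' @export
print.sampled_fn <- function(x, ...) {
  cat(sprintf("<sampled_fn> %d points, h = %g\n",
              length(x$values), x$grid$h))
  invisible(x)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("the derivative order `alpha` must satisfy 0 < alpha <= 1")
  as.numeric(alpha)
}

as_sampled <- function(f, grid) {
  if (inherits(f, "sampled_fn")) return(f)
  if (is.null(grid)) stop("supply a `time_grid` when `f` is a plain vector")
  sampled_fn(grid, f)
}
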