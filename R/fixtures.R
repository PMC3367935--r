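#' Deterministic test-series generators
#'
#' Generates the canonical fixture series used to validate the analysis
#' layer without external data. All randomness flows from `seed`, so an
#' identical spec yields a bit-identical series.
#'
#' Kinds:
#' \describe{
#'   \item{`logistic_map`}{iterates \eqn{x_{k+1} = r x_k (1 - x_k)}
#'     (default `r = 4`, the fully chaotic map with Lyapunov exponent
#'     `log 2`); `x0` defaults to a seed-derived point in (0.05, 0.95).}
#'   \item{`sinusoid`}{`amplitude * sin(2 pi t / period + phase)` sampled
#'     at integer `t`.}
#'   \item{`damped_sinusoid`}{the sinusoid times `exp(-decay * t)`.}
#'   \item{`white_noise`}{i.i.d. normal draws with `sd`.}
#'   \item{`canned_trajectory`}{a short integer-order benchmark Rossler
#'     trajectory (x coordinate), deterministic.}
#' }
#'
#' @param kind one of the kinds above.
#' @param length number of samples.
#' @param parameters named list of kind-specific overrides (`r`, `x0`,
#'   `amplitude`, `period`, `phase`, `decay`, `sd`, `sample_period`).
#' @param seed integer seed.
#' @return Numeric series of the requested length.
#' @examples
#' generate_fixture("logistic_map", 5, list(x0 = 0.2))
#' @export
generate_fixture <- function(kind, length, parameters = list(), seed = 1L) {
  p <- function(name, default)
    if (!is.null(parameters[[name]])) parameters[[name]] else default
  n <- as.integer(length)
  stopifnot(n >= 1)
  switch(kind,
    logistic_map = {
      r <- p("r", 4)
      x0 <- p("x0", {
        set.seed(seed); runif(1, 0.05, 0.95)
      })
      x <- numeric(n)
      x[1] <- x0
      for (k in seq_len(n - 1)) x[k + 1] <- r * x[k] * (1 - x[k])
      x
    },
    sinusoid = {
      t <- seq_len(n) - 1
      p("amplitude", 1) * sin(2 * pi * t / p("period", 50) + p("phase", 0))
    },
    damped_sinusoid = {
      t <- seq_len(n) - 1
      p("amplitude", 1) * exp(-p("decay", 0.01) * t) *
        sin(2 * pi * t / p("period", 50) + p("phase", 0))
    },
    white_noise = {
      set.seed(seed)
      stats::rnorm(n, sd = p("sd", 1))
    },
    canned_trajectory = {
      sp <- p("sample_period", 0.1)
      h <- 0.01
      tr <- solve_fde(rossler_system(rossler_params()), c(1, 1, 1),
                      time_grid(ceiling(n * sp / h), h))
      tr$states[seq(1, by = round(sp / h), length.out = n), 1]
    },
    stop("unknown fixture kind: ", kind)
  )
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV has a header `t,x[,y,z,...]`, one row per grid point, written
#' with 17 significant digits so a round trip reproduces the value columns
#' bit for bit. `write_trajectory` also writes `<path>.json` with the
#' solver metadata (method, order, step, parameters, status) unless
#' `sidecar = FALSE`.
#'
#' @param traj an `fde_trajectory`.
#' @param path output CSV path.
#' @param sidecar write the JSON metadata sidecar.
#' @return `write_trajectory`: the path, invisibly. `read_trajectory`: a
#'   `data.frame` with column `t` and the state columns (metadata from the
#'   sidecar, if present, in `attr(, "meta")`).
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "fde_trajectory"))
  df <- as.data.frame(traj)
  header <- paste(colnames(df), collapse = ",")
  body <- do.call(paste, c(lapply(df, function(col) sprintf("%.17g", col)),
                           sep = ","))
  writeLines(c(header, body), path)
  if (sidecar) {
    meta <- list(method = traj$method, alpha = traj$alpha, h = traj$h,
                 delay = traj$delay, params = traj$params,
                 rhs = traj$rhs_name, status = traj$status,
                 n_points = length(traj$times))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(df, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  df
}

#' Read a scalar series from CSV
#'
#' Accepts a single-column file or a `t,x` file (any additional columns
#' are ignored; the first non-time column is returned).
#'
#' @param path CSV path.
#' @return Numeric series with attribute `sample_period` when a uniform
#'   time column is present.
#' @export
read_series <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) == 1L) return(as.numeric(df[[1]]))
  tcol <- which(tolower(names(df)) %in% c("t", "time"))[1]
  if (is.na(tcol)) return(as.numeric(df[[1]]))
  x <- as.numeric(df[[setdiff(seq_along(df), tcol)[1]]])
  dt <- diff(as.numeric(df[[tcol]]))
  if (length(dt) && diff(range(dt)) < 1e-9 * max(abs(dt)))
    attr(x, "sample_period") <- dt[1]
  x
}
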