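# First-order co-transcriptional self-cleavage kinetics:
# F_t = F_inf * (1 - exp(-k * t)), with t in minutes and k (k_obs) in 1/min.

#' Product fraction of the first-order cleavage model
#'
#' @param k first-order rate constant, 1/min (> 0).
#' @param F_inf endpoint product fraction, in [0, 1.05].
#' @param t time(s), minutes (>= 0).
#' @return F_inf * (1 - exp(-k t)), vectorized over `t`.
#' @export
predict_fraction <- function(k, F_inf, t) {
  if (any(k <= 0)) abort("rate constant k must be positive")
  if (any(t < 0)) abort("time must be non-negative")
  if (F_inf < 0 || F_inf > 1.05) abort("F_inf must be in [0, 1.05]")
  F_inf * (1 - exp(-k * t))
}

#' Invert the cleavage model for the rate constant
#'
#' Solves F_t = F_inf (1 - exp(-k t)) for k: k = -ln(1 - F_t/F_inf) / t.
#'
#' @param F_t observed product fraction, with 0 < F_t < F_inf.
#' @param F_inf endpoint fraction.
#' @param t time, minutes (> 0).
#' @return Rate constant k, 1/min.
#' @export
invert_rate <- function(F_t, F_inf, t) {
  if (any(t <= 0)) abort("time must be positive")
  if (any(F_t <= 0) || any(F_t >= F_inf)) {
    abort("F_t must satisfy 0 < F_t < F_inf")
  }
  -log(1 - F_t / F_inf) / t
}

#' Construct and validate a cleavage time course
#'
#' @param times minutes, strictly increasing, >= 0.
#' @param fractions product fractions in [0, 1], same length.
#' @return A tibble with columns `time_min` and `fraction`.
#' @export
time_course <- function(times, fractions) {
  times <- as.numeric(times); fractions <- as.numeric(fractions)
  if (length(times) != length(fractions)) {
    abort("times and fractions must have the same length")
  }
  if (any(times < 0) || any(diff(times) <= 0)) {
    abort("times must be non-negative and strictly increasing")
  }
  if (any(fractions < 0 | fractions > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  tibble(time_min = times, fraction = fractions)
}

#' Simulate a noisy cleavage time course
#'
#' Model values with additive Gaussian noise, clipped to [0, 1]; identical
#' seeds give identical data.
#'
#' @param k,F_inf model parameters.
#' @param times sampling times, minutes.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed optional RNG seed.
#' @return A time-course tibble.
#' @export
simulate_time_course <- function(k, F_inf, times, noise_sd = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- predict_fraction(k, F_inf, times)
  if (noise_sd > 0) f <- f + stats::rnorm(length(times), 0, noise_sd)
  time_course(times, pmin(1, pmax(0, f)))
}

# profiled residual sum of squares: for fixed k the optimal F_inf is the
# closed-form linear least-squares solution through the origin
profile_rss <- function(k, t, f, f_max = 1.05) {
  g <- 1 - exp(-k * t)
  denom <- sum(g^2)
  F_inf <- if (denom > 0) min(f_max, max(0, sum(f * g) / denom)) else 0
  list(F_inf = F_inf, rss = sum((f - F_inf * g)^2))
}

#' Fit the first-order cleavage model to a time course
#'
#' Minimizes the residual sum of squares of F_t = F_inf (1 - exp(-k t)) by
#' profiled 1-D minimization: for fixed k the optimal F_inf is closed-form,
#' so the search reduces to golden-section minimization over log k, bracketed
#' by a coarse log-spaced grid. F_inf is allowed up to 1.05 to absorb small
#' gel-quantification overshoot; fitted values above 1 are flagged with a
#' warning.
#'
#' @param tc a time-course tibble (or anything [time_course()] accepts via
#'   columns `time_min`, `fraction`); at least 3 points, not all zero.
#' @param k_bounds search interval for k, 1/min.
#' @param rel_tol convergence tolerance on k (|dk|/k).
#' @return An object of class `kinetic_fit`: list with `F_inf`, `k_obs`,
#'   `rss`, `converged`, `n`, and the data.
#' @export
fit_time_course <- function(tc, k_bounds = c(1e-5, 10), rel_tol = 1e-6) {
  tc <- time_course(tc$time_min, tc$fraction)
  t <- tc$time_min; f <- tc$fraction
  pos <- t > 0
  if (sum(pos) < 3L) abort("need at least 3 positive-time points to fit")
  if (all(f == 0)) abort("degenerate data: all fractions are zero")
  t <- t[pos]; f <- f[pos]
  obj <- function(logk) profile_rss(exp(logk), t, f)$rss
  lo <- log(k_bounds[1]); hi <- log(k_bounds[2])
  # bracket the minimum on a coarse grid (the profiled RSS can have local
  # structure for poorly informative data)
  grid <- seq(lo, hi, length.out = 80L)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  a <- grid[max(1L, i - 1L)]
  b <- grid[min(length(grid), i + 1L)]
  # golden-section on log k
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  converged <- FALSE
  for (iter in seq_len(200L)) {
    if (f1 > f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- obj(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- obj(x1)
    }
    if (abs(b - a) < rel_tol) { converged <- TRUE; break }
  }
  logk <- (a + b) / 2
  k <- exp(logk)
  sol <- profile_rss(k, t, f)
  at_bound <- k <= k_bounds[1] * 1.01 || k >= k_bounds[2] * 0.99
  if (sol$F_inf > 1) warn("fitted F_inf exceeds 1 (gel overshoot?)")
  structure(
    list(F_inf = sol$F_inf, k_obs = k, rss = sol$rss,
         converged = converged && !at_bound, n = length(t), data = tc),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> F_inf = %.4f, k_obs = %.4g 1/min (t1/2 = %.3g min)\n",
    x$F_inf, x$k_obs, log(2) / x$k_obs))
  cat(sprintf("  n = %d points, rss = %.3g, converged: %s\n",
              x$n, x$rss, x$converged))
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x a `kinetic_fit`.
#' @param ... unused.
#' @return One row per parameter (`F_inf`, `k_obs`) with estimates.
#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = c("F_inf", "k_obs"),
         estimate = c(x$F_inf, x$k_obs),
         unit = c("fraction", "1/min"))
}

#' Glance at a kinetic fit
#'
#' @param x a `kinetic_fit`.
#' @param ... unused.
#' @return One-row tibble with fit summaries.
#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble(F_inf = x$F_inf, k_obs = x$k_obs, half_life_min = log(2) / x$k_obs,
         rss = x$rss, n = x$n, converged = x$converged)
}

#' Plot a kinetic fit
#'
#' Observed product fractions with the fitted first-order curve.
#'
#' @param object a `kinetic_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, ...) {
  tmax <- max(object$data$time_min)
  curve <- tibble(
    time_min = seq(0, tmax, length.out = 200L),
    fraction = predict_fraction(object$k_obs, object$F_inf,
                                seq(0, tmax, length.out = 200L)))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_min, y = .data$fraction)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "time (min)", y = "product fraction",
      title = sprintf("F_inf = %.3f, k_obs = %.3g 1/min",
                      object$F_inf, object$k_obs)) +
    ggplot2::ylim(0, 1)
}

#' Read / write cleavage time courses as TSV
#'
#' Two columns: `time_min`, `fraction`.
#'
#' @param path file path.
#' @return `read_time_course` returns a time-course tibble.
#' @export
read_time_course <- function(path) {
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      time_min = readr::col_double(), fraction = readr::col_double())),
    error = function(e) abort(sprintf("malformed time-course TSV '%s': %s",
                                      path, conditionMessage(e))))
  if (!all(c("time_min", "fraction") %in% names(df))) {
    abort("time-course TSV needs columns time_min and fraction")
  }
  bad <- which(is.na(df$time_min) | is.na(df$fraction))
  if (length(bad)) {
    abort(sprintf("non-numeric time-course value at data line %d", bad[1]))
  }
  time_course(df$time_min, df$fraction)
}

#' @rdname read_time_course
#' @param tc a time-course tibble.
#' @export
write_time_course <- function(tc, path) {
  readr::write_tsv(time_course(tc$time_min, tc$fraction), path)
  invisible(path)
}
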