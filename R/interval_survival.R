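# Interval-censored log-normal survival analysis
#
# The first analytical approach: maximum likelihood on exact plus
# interval-censored durations under a log-normal law, applied to per-centimetre
# sojourn times and to cumulative admission-to-level durations, with percentile
# and staircase outputs.

#' Reaching-time intervals for one woman
#'
#' For each dilatation level from the admission level through 10 cm (no 9-cm
#' state; 8 to 10 cm is one transition), brackets the unobserved time the
#' level was reached: the lower bound is the last exam time with a smaller
#' dilatation, the upper bound the first exam time at or above the level. The
#' admission level is taken as reached exactly at the admission exam (time 0),
#' and the 10-cm time is exact (full dilatation is recorded). Times are hours
#' since admission.
#'
#' @param record one woman's exam rows (long format, time-sorted).
#' @return tibble with columns `d` (level), `lower`, `upper`, `exact`.
#' @export
reaching_intervals <- function(record) {
  stopifnot(nrow(record) >= 2)
  times <- record$exam_time_h
  dil <- record$dilatation_cm
  if (is.unsorted(times)) stop("exam times must be nondecreasing")
  if (any(diff(dil) < 0)) {
    stop("record rejected: exam dilatations regress (outlier) for woman ",
         record$woman_id[1])
  }
  t_full <- record$full_dilatation_time_h[1]
  if (is.na(t_full)) stop("record lacks a full-dilatation time")
  adm <- dil[1]
  levels <- .dilatation_levels[.dilatation_levels >= adm]
  out <- lapply(levels, function(d) {
    if (d == adm) return(c(0, 0))
    if (d == 10L) return(c(t_full, t_full))
    lo <- max(times[dil < d])
    above <- times[dil >= d]
    up <- if (length(above)) min(above) else t_full
    c(lo, up)
  })
  out <- do.call(rbind, out)
  tibble::tibble(
    d = levels, lower = out[, 1], upper = out[, 2],
    exact = out[, 1] == out[, 2]
  )
}

#' Interval-censored sojourn data for one transition
#'
#' For every woman admitted at or below `from` (and thus observed over the
#' transition), combines the reaching-time brackets of the two levels into
#' conservative sojourn bounds: `lower = max(0, lower(to) - upper(from))`,
#' `upper = upper(to) - lower(from)`; the datum is exact when both reaching
#' times are exact.
#'
#' @param cohort long cohort tibble (included records).
#' @param from,to dilatation levels; `to` must be the successor of `from` in
#'   the 2,3,...,8,10 sequence.
#' @return tibble with `woman_id`, `lower`, `upper`, `exact`.
#' @export
sojourn_data <- function(cohort, from, to) {
  idx <- match(from, .sojourn_transitions$from)
  if (is.na(idx) || .sojourn_transitions$to[idx] != to) {
    stop("transition must be one of 2→3, ..., 7→8, 8→10")
  }
  recs <- split(cohort, cohort$woman_id)
  rows <- lapply(recs, function(r) {
    if (r$dilatation_cm[1] > from) return(NULL)
    ri <- reaching_intervals(r)
    a <- ri[ri$d == from, ]
    b <- ri[ri$d == to, ]
    tibble::tibble(
      woman_id = r$woman_id[1],
      lower = max(0, b$lower - a$upper),
      upper = b$upper - a$lower,
      exact = a$exact && b$exact
    )
  })
  dplyr::bind_rows(rows)
}

# negative log-likelihood of (mu, log sigma) for exact + interval data
.lognormal_nll <- function(par, t_exact, lo, up) {
  mu <- par[1]
  sigma <- exp(par[2])
  ll <- 0
  if (length(t_exact)) {
    ll <- ll + sum(dlnorm(t_exact, mu, sigma, log = TRUE))
  }
  if (length(lo)) {
    zl <- ifelse(lo <= 0, -Inf, (log(lo) - mu) / sigma)
    zu <- ifelse(is.finite(up), (log(up) - mu) / sigma, Inf)
    ll <- ll + sum(.log_pnorm_diff(zl, zu))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit a log-normal distribution to exact and interval-censored durations
#'
#' Maximises the combined likelihood: log-normal density terms for exact
#' observations and normal-CDF difference terms for interval-censored ones
#' (a lower bound of zero is handled as left-censoring, an infinite upper
#' bound as right-censoring). Optimisation is over `(mu, log sigma)` with
#' multistart from interval-midpoint moments.
#'
#' @param data tibble with `lower`, `upper`, `exact` (exact rows carry the
#'   duration in both bounds).
#' @param min_n minimum number of informative observations (default 10).
#' @return object of class `lognormal_fit`: `mu`, `sigma` (log-hours scale),
#'   `loglik`, `n_exact`, `n_interval`, `converged`.
#' @export
fit_lognormal <- function(data, min_n = 10) {
  stopifnot(all(c("lower", "upper", "exact") %in% names(data)))
  stopifnot(all(data$lower <= data$upper + 1e-12))
  informative <- data$exact | data$lower > 0 | is.finite(data$upper)
  data <- data[informative, ]
  if (nrow(data) < min_n) {
    stop("fewer than ", min_n, " informative observations")
  }
  t_exact <- data$lower[data$exact]
  if (any(t_exact <= 0)) stop("exact durations must be positive")
  lo <- data$lower[!data$exact]
  up <- data$upper[!data$exact]
  if (length(t_exact) && length(unique(t_exact)) == 1 && !length(lo)) {
    stop("degenerate data: all exact values equal (sigma -> 0)")
  }

  mid <- c(t_exact, ifelse(is.finite(up), pmax((lo + up) / 2, 1e-6),
                           1.5 * pmax(lo, 1e-3)))
  m0 <- mean(log(mid))
  s0 <- max(sd(log(mid)), 0.2)
  if (!is.finite(s0)) s0 <- 0.5
  starts <- list(c(m0, log(s0)), c(m0 + 0.5, log(1.5 * s0)),
                 c(m0 - 0.5, log(0.75 * s0)))
  best <- NULL
  for (st in starts) {
    fit <- optim(st, .lognormal_nll, t_exact = t_exact, lo = lo, up = up,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 2000))
    fit <- optim(fit$par, .lognormal_nll, t_exact = t_exact, lo = lo, up = up,
                 method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 500))
    if (is.null(best) || fit$value < best$value - 1e-8) best <- fit
  }
  structure(list(
    mu = best$par[1],
    sigma = exp(best$par[2]),
    loglik = -best$value,
    n_exact = length(t_exact),
    n_interval = length(lo),
    converged = best$convergence == 0 && best$value < 1e9
  ), class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  q <- lognormal_percentiles(x)
  cat(sprintf(
    "log-normal fit: mu = %.4f, sigma = %.4f (n exact %d, interval %d)\n",
    x$mu, x$sigma, x$n_exact, x$n_interval))
  cat(sprintf("  median %.2f h (p5 %.2f, p95 %.2f); loglik %.2f%s\n",
              q[["0.5"]], q[["0.05"]], q[["0.95"]], x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Percentiles of a fitted log-normal duration law
#'
#' @param fit a `lognormal_fit`.
#' @param probs probabilities in (0, 1).
#' @return named vector of hours, `exp(mu + sigma * z_p)`.
#' @export
lognormal_percentiles <- function(fit, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(fit, "lognormal_fit"))
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
  if (!fit$converged) warning("percentiles from a non-converged fit")
  setNames(exp(fit$mu + fit$sigma * qnorm(probs)), probs)
}

#' Sojourn duration table (survival approach)
#'
#' Fits the interval-censored log-normal model to every per-centimetre
#' transition and reports the requested percentiles, mirroring the published
#' sojourn-time table layout.
#'
#' @param cohort included long cohort (a single parity stratum, typically).
#' @param transitions data frame of `from`/`to` levels (default 3 to 4 cm
#'   through 8 to 10 cm).
#' @param probs percentile probabilities.
#' @param min_n minimum informative observations per fit; smaller strata are
#'   omitted with a warning.
#' @return tibble with `from`, `to`, `p5`, `p50`, `p95` (or the requested
#'   probs), and `n`.
#' @export
sojourn_duration_table <- function(cohort,
                                   transitions = .sojourn_transitions[-1, ],
                                   probs = c(0.05, 0.5, 0.95),
                                   min_n = 10) {
  rows <- lapply(seq_len(nrow(transitions)), function(i) {
    from <- transitions$from[i]
    to <- transitions$to[i]
    dat <- sojourn_data(cohort, from, to)
    if (is.null(dat) || nrow(dat) < min_n) {
      warning(sprintf("transition %d→%d omitted: n < %d", from, to, min_n))
      return(NULL)
    }
    fit <- fit_lognormal(dat, min_n = min_n)
    q <- lognormal_percentiles(fit, probs)
    out <- tibble::tibble(from = from, to = to, n = nrow(dat))
    out[paste0("p", probs * 100)] <- as.list(q)
    out
  })
  dplyr::bind_rows(rows)
}

#' Cumulative duration table (survival approach)
#'
#' For each admission dilatation level and each higher target level, fits the
#' interval-censored log-normal model to the admission-to-target durations
#' (admission exam at time 0, exact) of the women admitted at that level, and
#' reports percentiles -- the cumulative analogue of the sojourn table.
#'
#' @param cohort included long cohort (one parity stratum, typically).
#' @param admission_levels admission dilatations to tabulate (default 3--6 cm).
#' @param probs percentile probabilities.
#' @param min_n minimum informative observations; smaller strata are omitted
#'   with a warning.
#' @return tibble with `admission`, `to`, percentile columns and `n`.
#' @export
cumulative_duration_table <- function(cohort, admission_levels = 3:6,
                                      probs = c(0.05, 0.5, 0.95),
                                      min_n = 10) {
  ws <- cohort |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(adm = dplyr::first(.data$dilatation_cm), .groups = "drop")
  rows <- list()
  for (a in admission_levels) {
    ids <- ws$woman_id[ws$adm == a]
    if (!length(ids)) next
    sub <- dplyr::filter(cohort, .data$woman_id %in% ids)
    recs <- split(sub, sub$woman_id)
    ris <- lapply(recs, reaching_intervals)
    targets <- .dilatation_levels[.dilatation_levels > a]
    for (d in targets) {
      dat <- dplyr::bind_rows(lapply(ris, function(ri) ri[ri$d == d, ]))
      dat <- tibble::tibble(lower = dat$lower, upper = dat$upper,
                            exact = dat$exact)
      if (nrow(dat) < min_n) {
        warning(sprintf("admission %d to %d cm omitted: n < %d", a, d, min_n))
        next
      }
      fit <- fit_lognormal(dat, min_n = min_n)
      q <- lognormal_percentiles(fit, probs)
      out <- tibble::tibble(admission = a, to = d, n = nrow(dat))
      out[paste0("p", probs * 100)] <- as.list(q)
      rows[[length(rows) + 1]] <- out
    }
  }
  dplyr::bind_rows(rows)
}

#' Staircase series of cumulative-duration percentiles
#'
#' Extracts, for one admission level, the chosen percentile of the cumulative
#' duration to each successive dilatation level, as plotted in the
#' slowest-yet-normal staircase figures.
#'
#' @param table a cumulative duration table from
#'   [cumulative_duration_table()] (or the Markov analogue).
#' @param admission_level admission dilatation.
#' @param prob percentile (default 0.95).
#' @return tibble with `level` and `hours`, nondecreasing in `level`.
#' @export
staircase_series <- function(table, admission_level, prob = 0.95) {
  col <- paste0("p", prob * 100)
  if (!col %in% names(table)) stop("table lacks a ", col, " column")
  rows <- table[table$admission == admission_level, ]
  if (!nrow(rows)) stop("no rows for admission level ", admission_level)
  rows <- rows[order(rows$to), ]
  out <- tibble::tibble(level = rows$to, hours = rows[[col]])
  if (is.unsorted(out$hours)) {
    warning("staircase is not monotone; check stratum sizes")
  }
  out
}
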