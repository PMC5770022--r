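# Progressive continuous-time multistate Markov model on panel-observed
# cervical dilatation.
#
# State space: 2, 3, 4, 5, 6, 7, 8, 10 cm and an absorbing delivery state D.
# The chain is progressive and unidirectional: each non-absorbing state r has
# one free intensity q_r to its successor, so Q is upper bidiagonal. Panel
# snapshots contribute ln P(dt)[r, s] with P(t) = expm(tQ); exactly-timed
# entries (full dilatation, delivery) contribute density terms ln [P(dt) Q]_{r,s}.

#' The labour state space
#'
#' @return a list with `labels` (`"2"` ... `"8"`, `"10"`, `"D"`), `values`
#'   (numeric dilatation, `NA` for delivery), `n_states`, and the index of the
#'   absorbing state.
#' @export
labour_statespace <- function() {
  list(
    labels = c("2", "3", "4", "5", "6", "7", "8", "10", "D"),
    values = c(2, 3, 4, 5, 6, 7, 8, 10, NA),
    n_states = 9L,
    absorbing = 9L
  )
}

#' Build the transition intensity matrix Q
#'
#' @param rates vector of 8 intensities (per hour) for the transitions
#'   2->3, ..., 8->10, 10->D; `NA` marks a non-identifiable rate (treated as
#'   zero when exponentiating).
#' @return a 9 x 9 matrix with rows summing to zero, only the next-state
#'   off-diagonal entry nonzero, and an all-zero absorbing row.
#' @export
build_intensity_matrix <- function(rates) {
  ss <- labour_statespace()
  stopifnot(length(rates) == ss$n_states - 1L)
  if (any(!is.na(rates) & rates < 0)) stop("intensities must be >= 0")
  Q <- matrix(0, ss$n_states, ss$n_states,
              dimnames = list(ss$labels, ss$labels))
  for (r in seq_len(ss$n_states - 1L)) {
    q <- rates[r]
    if (is.na(q)) next
    Q[r, r + 1L] <- q
    Q[r, r] <- -q
  }
  Q
}

# extract successor rates from a valid progressive Q (NA rows allowed for
# non-identifiable intensities)
.rates_from_Q <- function(Q) {
  n <- nrow(Q)
  na_rows <- apply(is.na(Q), 1L, any)
  Q[na_rows, ] <- 0
  off <- Q
  diag(off) <- 0
  if (any(off < -1e-12)) stop("off-diagonal intensities must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rows of Q must sum to zero")
  bad <- which(off != 0, arr.ind = TRUE)
  if (any(bad[, 2] != bad[, 1] + 1L)) {
    stop("Q must be progressive: only next-state transitions allowed")
  }
  if (any(Q[n, ] != 0)) stop("absorbing row of Q must be zero")
  rates <- Q[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]
  rates[na_rows[-n]] <- NA_real_
  rates
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' Solves the Kolmogorov forward equations of the time-homogeneous chain by
#' the matrix exponential of Q scaled by the time interval.
#'
#' @param Q intensity matrix.
#' @param t nonnegative time interval (hours).
#' @return a row-stochastic matrix with entries in `[0, 1]`.
#' @export
transition_probability <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  Qn <- Q
  Qn[is.na(Qn)] <- 0
  P <- as.matrix(Matrix::expm(Qn * t))
  dimnames(P) <- dimnames(Q)
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

# closed-form occupancy probability P(t)[r, s] for the bidiagonal chain
# (hypoexponential): rates q over states, vectorised over t.
# Falls back to expm when rates within the span nearly collide.
.p_occupancy <- function(rates, r, s, t, Q = NULL) {
  rates <- c(rates, 0)  # the absorbing state has exit rate zero
  if (s < r) return(rep(0, length(t)))
  if (s == r) return(exp(-rates[r] * t))
  qs <- rates[r:s]
  gaps <- abs(outer(qs, qs, "-"))
  diag(gaps) <- Inf
  if (min(gaps) < 1e-7 * max(qs, 1e-12)) {
    if (is.null(Q)) Q <- build_intensity_matrix(rates)
    return(vapply(t, function(ti) transition_probability(Q, ti)[r, s], 0))
  }
  num <- prod(qs[-length(qs)])
  acc <- rep(0, length(t))
  for (k in seq_along(qs)) {
    denom <- prod(qs[-k] - qs[k])
    acc <- acc + exp(-qs[k] * t) / denom
  }
  pmax(num * acc, 0)
}

#' Panel observations from a cohort
#'
#' Converts included labour records into panel series: the admission exam and
#' subsequent exams are snapshots of the occupied state; the full-dilatation
#' time is an exactly-timed entry into state 10; the delivery time (when
#' present) an exactly-timed entry into the absorbing state D.
#'
#' @param cohort included long cohort tibble.
#' @return tibble with `woman_id`, `time_h`, `state` (index into the state
#'   space), `exact` (exactly-timed entry vs panel snapshot).
#' @export
panels_from_cohort <- function(cohort) {
  ss <- labour_statespace()
  first_stage <- dplyr::filter(cohort, .data$dilatation_cm < 10L)
  idx <- match(as.character(first_stage$dilatation_cm), ss$labels)
  if (any(is.na(idx))) {
    stop("dilatations outside the modelled state space: ",
         paste(unique(first_stage$dilatation_cm[is.na(idx)]), collapse = ", "))
  }
  panel <- tibble::tibble(
    woman_id = first_stage$woman_id,
    time_h = first_stage$exam_time_h,
    state = idx,
    exact = FALSE
  )
  per_woman <- cohort |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(
      full = dplyr::first(.data$full_dilatation_time_h),
      delivery = if ("delivery_time_h" %in% names(cohort))
        dplyr::first(.data$delivery_time_h) else NA_real_,
      .groups = "drop"
    )
  anchors <- dplyr::bind_rows(
    tibble::tibble(woman_id = per_woman$woman_id, time_h = per_woman$full,
                   state = match("10", ss$labels), exact = TRUE),
    tibble::tibble(woman_id = per_woman$woman_id, time_h = per_woman$delivery,
                   state = ss$absorbing, exact = TRUE)
  )
  anchors <- anchors[!is.na(anchors$time_h), ]
  out <- dplyr::bind_rows(panel, anchors)
  out[order(out$woman_id, out$time_h, out$state), ]
}

#' Log-likelihood of panel data under a progressive chain
#'
#' Sums, over consecutive observation pairs within each woman, the log
#' transition probability `ln P(dt)[r, s]` for panel snapshots and the exact
#' entry-time density `ln [P(dt) Q]_{r, s}` for exactly-timed transitions
#' (full dilatation, delivery). An observed move to a lower state yields
#' `-Inf` with a diagnostic attribute.
#'
#' @param Q intensity matrix (progressive).
#' @param panels tibble from [panels_from_cohort()].
#' @return the log-likelihood (scalar). Attribute `"violations"` lists
#'   impossible pairs when the value is `-Inf`.
#' @export
panel_log_likelihood <- function(Q, panels) {
  if (!nrow(panels)) return(0)
  rates <- .rates_from_Q(Q)
  o <- panels[order(panels$woman_id, panels$time_h), ]
  same <- o$woman_id[-1] == o$woman_id[-nrow(o)]
  pairs <- tibble::tibble(
    r = o$state[-nrow(o)][same],
    s = o$state[-1][same],
    dt = (o$time_h[-1] - o$time_h[-nrow(o)])[same],
    exact = o$exact[-1][same],
    woman_id = o$woman_id[-1][same]
  )
  if (!nrow(pairs)) return(0)
  if (any(pairs$s < pairs$r)) {
    bad <- pairs[pairs$s < pairs$r, ]
    out <- -Inf
    attr(out, "violations") <- bad
    return(out)
  }
  ll <- 0
  key <- paste(pairs$r, pairs$s, pairs$exact)
  for (grp in split(seq_len(nrow(pairs)), key)) {
    r <- pairs$r[grp[1]]
    s <- pairs$s[grp[1]]
    dt <- pairs$dt[grp]
    if (pairs$exact[grp[1]]) {
      # density of entering s exactly dt after being seen in r
      p <- .p_occupancy(rates, r, s - 1L, dt, Q) * rates[s - 1L]
    } else {
      p <- .p_occupancy(rates, r, s, dt, Q)
    }
    if (any(p <= 0)) return(-Inf)
    ll <- ll + sum(log(p))
  }
  ll
}

#' Fit transition intensities to panel data
#'
#' Maximises the panel log-likelihood over the log intensities of the
#' progressive chain. Rates whose transitions are never spanned by any
#' observation pair are flagged non-identifiable (`NA`). Standard errors come
#' from the numerical Hessian at the optimum.
#'
#' @param panels tibble from [panels_from_cohort()].
#' @param init optional initial rates (length 8); default 0.7/h.
#' @return object of class `markov_fit`: `Q`, `rates`, `se_rates`, `loglik`,
#'   `converged`, `identifiable`.
#' @export
fit_intensities <- function(panels, init = NULL) {
  ss <- labour_statespace()
  n_rates <- ss$n_states - 1L
  o <- panels[order(panels$woman_id, panels$time_h), ]
  same <- o$woman_id[-1] == o$woman_id[-nrow(o)]
  r <- o$state[-nrow(o)][same]
  s <- o$state[-1][same]
  ex <- o$exact[-1][same]
  span_hi <- ifelse(ex, pmax(s - 1L, r), s)
  identifiable <- vapply(seq_len(n_rates), function(k) {
    any(r <= k & k <= span_hi)
  }, TRUE)
  if (!any(identifiable)) stop("no transition information in the panels")
  if (is.null(init)) init <- rep(0.7, n_rates)
  theta0 <- log(init[identifiable])

  nll <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(1e10)
    rates <- rep(NA_real_, n_rates)
    rates[identifiable] <- exp(theta)
    Q <- build_intensity_matrix(rates)
    Q[is.na(Q)] <- 0
    rates[!identifiable] <- 0
    ll <- panel_log_likelihood(Q, panels)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- optim(theta0, nll, method = "BFGS",
               control = list(reltol = 1e-12, maxit = 500))
  if (fit$convergence != 0) {
    fit2 <- optim(fit$par, nll, method = "Nelder-Mead",
                  control = list(reltol = 1e-12, maxit = 5000))
    if (fit2$value < fit$value) fit <- fit2
  }
  hess <- stats::optimHess(fit$par, nll)
  se_log <- rep(NA_real_, sum(identifiable))
  vc <- try(solve(hess), silent = TRUE)
  if (!inherits(vc, "try-error")) {
    d <- diag(vc)
    se_log[d > 0] <- sqrt(d[d > 0])
  }
  rates <- rep(NA_real_, n_rates)
  rates[identifiable] <- exp(fit$par)
  se <- rep(NA_real_, n_rates)
  se[identifiable] <- rates[identifiable] * se_log
  names(rates) <- names(se) <-
    paste0(ss$labels[-ss$n_states], "->", ss$labels[-1])
  structure(list(
    Q = build_intensity_matrix(rates),
    rates = rates,
    se_rates = se,
    loglik = -fit$value,
    converged = fit$convergence == 0 && fit$value < 1e9,
    identifiable = identifiable
  ), class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("progressive multistate Markov fit (intensities per hour)\n")
  print(round(rbind(rate = x$rates, se = x$se_rates), 4))
  cat(sprintf("loglik %.2f%s\n", x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Simulate dilatation trajectories on a fixed grid
#'
#' Draws an admission state for each woman and advances the chain on a fixed
#' time grid using the one-step transition matrix `P(step)`, recording the
#' entry time into each state until 10 cm is reached (states skipped within
#' one tick inherit the tick's entry time, so their sojourn is zero).
#'
#' @param Q intensity matrix (fitted or constructed).
#' @param admission_distribution named probability vector over admission
#'   state labels (e.g. `c("2" = .26, "3" = .11, ...)`).
#' @param n number of women.
#' @param step grid step in hours (default 5 minutes).
#' @param horizon maximum simulated time in hours; women not absorbed by then
#'   keep `NA` entries, with a warning.
#' @param seed optional integer seed.
#' @return object of class `markov_trajectories`: list with `entry` (n x 8
#'   matrix of entry times into states 2 ... 10), `admission_state` (labels),
#'   `step`, `horizon`.
#' @export
simulate_markov_cohort <- function(Q, admission_distribution, n,
                                   step = 1 / 12, horizon = 72, seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (step <= 0) stop("step must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  ss <- labour_statespace()
  target <- match("10", ss$labels)
  P <- transition_probability(Q, step)
  cum <- t(apply(P, 1L, cumsum))

  adm_labels <- names(admission_distribution)
  stopifnot(all(adm_labels %in% ss$labels[seq_len(target)]))
  adm_idx <- match(
    sample(adm_labels, n, replace = TRUE, prob = admission_distribution),
    ss$labels
  )
  entry <- matrix(NA_real_, n, target,
                  dimnames = list(NULL, ss$labels[seq_len(target)]))
  entry[cbind(seq_len(n), adm_idx)] <- 0

  state <- adm_idx
  tick <- 0L
  max_ticks <- ceiling(horizon / step)
  while (any(state < target) && tick < max_ticks) {
    tick <- tick + 1L
    active <- which(state < target)
    u <- runif(length(active))
    cur <- state[active]
    nxt <- cur
    for (rs in unique(cur)) {
      sel <- cur == rs
      nxt[sel] <- findInterval(u[sel], cum[rs, ], left.open = TRUE) + 1L
    }
    moved <- nxt > cur
    if (any(moved)) {
      mi <- active[moved]
      cm <- cur[moved]
      # a tick may carry a woman through 10 cm into D; record up to 10 cm
      nm <- pmin(nxt[moved], target)
      single <- nm == cm + 1L
      if (any(single)) {
        entry[cbind(mi[single], nm[single])] <- tick * step
      }
      for (j in which(!single)) {
        entry[mi[j], (cm[j] + 1L):nm[j]] <- tick * step
      }
      state[mi] <- nm
    }
  }
  if (any(state < target)) {
    warning(sum(state < target),
            " trajectories did not reach 10 cm by the horizon")
  }
  structure(list(
    entry = entry,
    admission_state = ss$labels[adm_idx],
    step = step,
    horizon = horizon
  ), class = "markov_trajectories")
}

#' Empirical sojourn-time percentiles from simulated trajectories
#'
#' Per transition, the empirical percentiles of the time spent in the
#' originating state, among women admitted at or below it. Values are
#' reported at grid resolution (one step is the smallest positive value; a
#' state skipped within a tick contributes a zero sojourn).
#'
#' @param traj a `markov_trajectories` object.
#' @param probs percentile probabilities.
#' @return tibble with `from`, `to`, percentile columns, `n`.
#' @export
markov_sojourn_table <- function(traj, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(traj, "markov_trajectories"))
  entry <- traj$entry
  labels <- colnames(entry)
  adm <- match(traj$admission_state, labels)
  rows <- list()
  for (r in seq_len(ncol(entry) - 1L)) {
    ok <- adm <= r & !is.na(entry[, r]) & !is.na(entry[, r + 1L])
    if (!any(ok)) next
    soj <- entry[ok, r + 1L] - entry[ok, r]
    q <- quantile(soj, probs, type = 1, names = FALSE)
    out <- tibble::tibble(from = as.integer(labels[r]),
                          to = as.integer(labels[r + 1L]), n = sum(ok))
    out[paste0("p", probs * 100)] <- as.list(q)
    rows[[length(rows) + 1]] <- out
  }
  dplyr::bind_rows(rows)
}

#' Empirical cumulative first-passage percentiles from trajectories
#'
#' Per admission state and higher target level, the empirical percentiles of
#' the first-passage time from admission (time 0) to the target.
#'
#' @param traj a `markov_trajectories` object.
#' @param probs percentile probabilities.
#' @return tibble with `admission`, `to`, percentile columns, `n`.
#' @export
markov_cumulative_table <- function(traj, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(inherits(traj, "markov_trajectories"))
  entry <- traj$entry
  labels <- colnames(entry)
  adm <- match(traj$admission_state, labels)
  rows <- list()
  for (a in sort(unique(adm))) {
    sel <- adm == a
    for (d in (a + 1L):ncol(entry)) {
      if (d > ncol(entry)) next
      fp <- entry[sel, d]
      fp <- fp[!is.na(fp)]
      if (!length(fp)) next
      q <- quantile(fp, probs, type = 1, names = FALSE)
      out <- tibble::tibble(admission = as.integer(labels[a]),
                            to = as.integer(labels[d]), n = length(fp))
      out[paste0("p", probs * 100)] <- as.list(q)
      rows[[length(rows) + 1]] <- out
    }
  }
  dplyr::bind_rows(rows)
}

#' Analytic sojourn quantiles of the fitted chain
#'
#' Cross-check for the simulation-based table: under the time-homogeneous
#' chain, the sojourn in state r is exponential with rate `q_r`, so the
#' p-quantile is `-ln(1 - p) / q_r`.
#'
#' @param Q intensity matrix.
#' @param probs percentile probabilities.
#' @return tibble with `from`, `to` and one column per probability.
#' @export
exponential_sojourn_quantiles <- function(Q, probs = c(0.05, 0.5, 0.95)) {
  ss <- labour_statespace()
  rates <- .rates_from_Q(Q)
  out <- tibble::tibble(
    from = ss$labels[-ss$n_states],
    to = ss$labels[-1]
  )
  for (p in probs) out[[paste0("p", p * 100)]] <- -log(1 - p) / rates
  out
}

#' Reverse-time average labour curve from trajectories
#'
#' Anchors every trajectory at full dilatation (time 0) and, for each number
#' of hours tau before it, averages the occupied dilatation over the
#' trajectories whose admission-to-10 cm duration is at least tau. The curve
#' ends exactly at 10 cm at tau = 0 and is nonincreasing in tau.
#'
#' @param traj a `markov_trajectories` object; all trajectories must have
#'   reached 10 cm (others are dropped with a warning).
#' @param tau_grid hours before full dilatation (default: 0 to the 98th
#'   percentile of durations, step 0.1 h).
#' @return tibble with `hours_before_full`, `mean_dilatation`, `n`.
#' @export
average_curve_markov <- function(traj, tau_grid = NULL) {
  stopifnot(inherits(traj, "markov_trajectories"))
  entry <- traj$entry
  t10 <- entry[, "10"]
  if (any(is.na(t10))) {
    warning("dropping ", sum(is.na(t10)), " trajectories that never reach 10 cm")
    keep <- !is.na(t10)
    entry <- entry[keep, , drop = FALSE]
    t10 <- t10[keep]
  }
  values <- as.numeric(colnames(entry))
  # levels below the admission state were occupied before time 0
  entry[is.na(entry)] <- 0
  if (is.null(tau_grid)) {
    tau_grid <- seq(0, quantile(t10, 0.98, names = FALSE), by = 0.1)
  }
  rows <- lapply(tau_grid, function(tau) {
    sel <- t10 >= tau
    if (!any(sel)) return(NULL)
    x <- t10[sel] - tau
    occ <- rowSums(entry[sel, , drop = FALSE] <= x)
    tibble::tibble(hours_before_full = tau,
                   mean_dilatation = mean(values[occ]),
                   n = sum(sel))
  })
  dplyr::bind_rows(rows)
}
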