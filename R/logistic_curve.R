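# Three-parameter logistic growth mixed model for average labour curves.
#
# Dilatation y_ij of woman i at time t_ij follows
#   y_ij = beta0 + beta1 / (1 + exp(-(t_ij - (beta2 + b_i)))) + eps_ij,
# with a normal random shift b_i ~ N(0, sigma_b^2) of the inflection point and
# residual eps_ij ~ N(0, sigma_eps^2). Because women enter observation at
# different dilatations but all reach 10 cm, times are anchored at full
# dilatation: t = 0 at 10 cm, negative before it. Fitting is done on this
# signed axis; the reflected positive axis ("hours before full dilatation") is
# presentation-only.

#' Reverse-time anchored observation points
#'
#' Anchors each woman's exams at full dilatation: `t_signed = exam time - full
#' dilatation time` (nonpositive), with the reflected positive version
#' alongside. The 10-cm confirmation provides the anchor point (0, 10); it is
#' appended if the record lacks one.
#'
#' @param cohort included long cohort; `full_dilatation_time_h` required.
#' @return tibble with `woman_id`, `t_signed`, `hours_before_full`,
#'   `dilatation`.
#' @export
reverse_time <- function(cohort) {
  if (any(is.na(cohort$full_dilatation_time_h))) {
    bad <- unique(cohort$woman_id[is.na(cohort$full_dilatation_time_h)])
    stop("missing full-dilatation anchor for: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- tibble::tibble(
    woman_id = cohort$woman_id,
    t_signed = cohort$exam_time_h - cohort$full_dilatation_time_h,
    dilatation = as.numeric(cohort$dilatation_cm)
  )
  has_anchor <- out |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(anchored = any(.data$t_signed == 0 & .data$dilatation == 10),
                     .groups = "drop")
  missing_anchor <- has_anchor$woman_id[!has_anchor$anchored]
  if (length(missing_anchor)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      woman_id = missing_anchor, t_signed = 0, dilatation = 10
    ))
  }
  out$hours_before_full <- -out$t_signed
  out[order(out$woman_id, out$t_signed), ]
}

#' Mean of the three-parameter logistic growth model
#'
#' `beta0 + beta1 / (1 + exp(-(t - (beta2 + b))))` on the signed
#' (pre-reflection) time axis: `beta0` is the value as t -> -Inf, `beta1` the
#' asymptotic height, and `beta2 + b` the inflection point, where the curve
#' reaches half its height.
#'
#' @param params list or named vector with `beta0`, `beta1`, `beta2`.
#' @param t signed time (hours; 0 at full dilatation).
#' @param b random inflection shift (default 0, the population curve).
#' @return dilatation in cm.
#' @export
logistic_mean <- function(params, t, b = 0) {
  p <- as.list(params)
  p$beta0 + p$beta1 * plogis(t - (p$beta2 + b))
}

# Gauss-Hermite nodes/weights for weight exp(-x^2) via Golub-Welsch
.gauss_hermite <- function(n) {
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = (sqrt(pi) * e$vectors[1, ]^2)[idx])
}

# negative marginal log-likelihood by adaptive Gauss-Hermite quadrature;
# obs must carry integer woman index `i`, times `t`, responses `y`
.nlmm_nll <- function(par, obs, gh, n_women) {
  if (any(!is.finite(par)) || any(abs(par[4:5]) > 15) ||
      any(abs(par[1:3]) > 1e3)) {
    return(1e10)
  }
  beta0 <- par[1]; beta1 <- par[2]; beta2 <- par[3]
  sigma_b <- exp(par[4]); sigma_eps <- exp(par[5])
  t <- obs$t; y <- obs$y; i <- obs$i

  gfun <- function(b) {
    # per-woman joint log density at random effect b (vector over women)
    eta <- t - beta2 - b[i]
    p <- plogis(eta)
    r <- y - (beta0 + beta1 * p)
    ll_obs <- -0.5 * (r / sigma_eps)^2 - log(sigma_eps) - 0.5 * log(2 * pi)
    as.numeric(rowsum(ll_obs, i, reorder = TRUE)) +
      dnorm(b, 0, sigma_b, log = TRUE)
  }
  # mode of g per woman by damped Newton (Gauss-Newton curvature fallback)
  b <- numeric(n_women)
  for (iter in 1:30) {
    eta <- t - beta2 - b[i]
    p <- plogis(eta)
    fb <- -beta1 * p * (1 - p)
    r <- y - (beta0 + beta1 * p)
    g1 <- as.numeric(rowsum(r * fb, i, reorder = TRUE)) / sigma_eps^2 -
      b / sigma_b^2
    fbb <- beta1 * p * (1 - p) * (1 - 2 * p)
    g2 <- as.numeric(rowsum(r * fbb - fb^2, i, reorder = TRUE)) / sigma_eps^2 -
      1 / sigma_b^2
    g2 <- pmin(g2, -1e-8)
    stepv <- g1 / g2
    stepv[!is.finite(stepv)] <- 0
    stepv <- pmax(pmin(stepv, 2), -2)
    b <- b - stepv
    if (max(abs(stepv)) < 1e-10) break
  }
  # curvature at the mode
  eta <- t - beta2 - b[i]
  p <- plogis(eta)
  fb <- -beta1 * p * (1 - p)
  r <- y - (beta0 + beta1 * p)
  fbb <- beta1 * p * (1 - p) * (1 - 2 * p)
  g2 <- as.numeric(rowsum(r * fbb - fb^2, i, reorder = TRUE)) / sigma_eps^2 -
    1 / sigma_b^2
  shat <- 1 / sqrt(pmax(-g2, 1e-10))
  # adaptive nodes: b_k = bhat + sqrt(2) * shat * x_k
  K <- length(gh$nodes)
  logint <- matrix(NA_real_, n_women, K)
  for (k in seq_len(K)) {
    bk <- b + sqrt(2) * shat * gh$nodes[k]
    logint[, k] <- log(gh$weights[k]) + gh$nodes[k]^2 + gfun(bk)
  }
  ll <- log(sqrt(2) * shat) + .row_logsumexp(logint)
  out <- -sum(ll)
  if (!is.finite(out)) 1e10 else out
}

# pooled nonlinear least squares / MLE when sigma_b is fixed at zero
.nlmm_nll_sb0 <- function(par, obs) {
  beta0 <- par[1]; beta1 <- par[2]; beta2 <- par[3]
  sigma_eps <- exp(par[4])
  r <- obs$y - (beta0 + beta1 * plogis(obs$t - beta2))
  out <- -sum(dnorm(r, 0, sigma_eps, log = TRUE))
  if (!is.finite(out)) 1e10 else out
}

#' Fit the logistic growth nonlinear mixed model
#'
#' Maximises the marginal likelihood, integrating the random inflection shift
#' per woman by adaptive Gauss-Hermite quadrature (21 nodes by default).
#' `beta0`, `beta1` are fixed effects; the random term enters the inflection
#' point only. A residual SD `sigma_eps` completes the measurement model.
#'
#' @param observations tibble from [reverse_time()] (columns `woman_id`,
#'   `t_signed`, `dilatation`), or any tibble with those columns.
#' @param nodes number of quadrature nodes.
#' @param init optional named start values.
#' @param fix_sigma_b0 fit with `sigma_b = 0` (pooled nonlinear regression);
#'   used for degenerate-case checks.
#' @return object of class `logistic_nlmm`: `params` (`beta0`, `beta1`,
#'   `beta2`, `sigma_b`, `sigma_eps`), `se`, `loglik`, `converged`,
#'   `boundary_sigma_b`, `n_women`, `t_range`, `nodes`.
#' @export
fit_logistic_nlmm <- function(observations, nodes = 21, init = NULL,
                              fix_sigma_b0 = FALSE) {
  obs <- tibble::tibble(
    i = as.integer(factor(observations$woman_id)),
    t = observations$t_signed,
    y = observations$dilatation
  )
  n_women <- max(obs$i)
  n_per <- tabulate(obs$i)
  if (!fix_sigma_b0 && (n_women < 30 || any(n_per < 2))) {
    stop("need >= 30 women with >= 2 points each")
  }
  if (is.null(init)) {
    span <- stats::quantile(obs$t, 0.05, names = FALSE)
    init <- c(beta0 = 0, beta1 = 10, beta2 = span / 2,
              sigma_b = 1, sigma_eps = 0.5)
  }
  if (fix_sigma_b0) {
    par0 <- c(init[["beta0"]], init[["beta1"]], init[["beta2"]],
              log(init[["sigma_eps"]]))
    fit <- optim(par0, .nlmm_nll_sb0, obs = obs, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000))
    params <- c(beta0 = fit$par[1], beta1 = fit$par[2], beta2 = fit$par[3],
                sigma_b = 0, sigma_eps = exp(fit$par[4]))
    se <- rep(NA_real_, 5)
  } else {
    gh <- .gauss_hermite(nodes)
    par0 <- c(init[["beta0"]], init[["beta1"]], init[["beta2"]],
              log(init[["sigma_b"]]), log(init[["sigma_eps"]]))
    fit <- optim(par0, .nlmm_nll, obs = obs, gh = gh, n_women = n_women,
                 method = "BFGS", control = list(reltol = 1e-12, maxit = 1000))
    if (fit$convergence != 0) {
      fit2 <- optim(fit$par, .nlmm_nll, obs = obs, gh = gh, n_women = n_women,
                    method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 5000))
      if (fit2$value < fit$value) fit <- fit2
    }
    params <- c(beta0 = fit$par[1], beta1 = fit$par[2], beta2 = fit$par[3],
                sigma_b = exp(fit$par[4]), sigma_eps = exp(fit$par[5]))
    hess <- try(stats::optimHess(fit$par, .nlmm_nll, obs = obs, gh = gh,
                                 n_women = n_women), silent = TRUE)
    se <- rep(NA_real_, 5)
    if (!inherits(hess, "try-error")) {
      vc <- try(solve(hess), silent = TRUE)
      if (!inherits(vc, "try-error")) {
        d <- diag(vc)
        se_t <- rep(NA_real_, length(d))
        se_t[!is.na(d) & d > 0] <- sqrt(d[!is.na(d) & d > 0])
        # delta method back to the natural scale for the SDs
        se <- c(se_t[1:3], se_t[4] * params["sigma_b"],
                se_t[5] * params["sigma_eps"])
      }
    }
  }
  names(se) <- names(params)
  structure(list(
    params = params,
    se = se,
    loglik = -fit$value,
    converged = fit$convergence == 0 && fit$value < 1e9,
    boundary_sigma_b = !fix_sigma_b0 && params[["sigma_b"]] < 1e-4,
    n_women = n_women,
    t_range = range(obs$t),
    nodes = if (fix_sigma_b0) NA_integer_ else nodes
  ), class = "logistic_nlmm")
}

#' @export
print.logistic_nlmm <- function(x, ...) {
  cat("logistic growth mixed model (signed time axis, 0 = full dilatation)\n")
  print(round(rbind(estimate = x$params, se = x$se), 4))
  cat(sprintf("loglik %.2f over %d women%s%s\n", x$loglik, x$n_women,
              if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$boundary_sigma_b) "  [sigma_b at boundary]" else ""))
  invisible(x)
}

#' Evaluate the marginal log-likelihood of a fitted model
#'
#' Re-evaluates the adaptive quadrature at the fitted parameters, optionally
#' with a different number of nodes (quadrature-refinement check).
#'
#' @param fit a `logistic_nlmm`.
#' @param observations the data the model was fitted to.
#' @param nodes number of quadrature nodes.
#' @return the marginal log-likelihood.
#' @export
logistic_nlmm_loglik <- function(fit, observations, nodes = fit$nodes) {
  obs <- tibble::tibble(
    i = as.integer(factor(observations$woman_id)),
    t = observations$t_signed,
    y = observations$dilatation
  )
  p <- fit$params
  par <- c(p[["beta0"]], p[["beta1"]], p[["beta2"]],
           log(p[["sigma_b"]]), log(p[["sigma_eps"]]))
  -.nlmm_nll(par, obs, .gauss_hermite(nodes), max(obs$i))
}

#' Population average labour curve from a fitted model
#'
#' The population curve `logistic_mean(params, t, b = 0)` over the observed
#' time range only; extrapolation beyond the data is refused by default. A
#' flag marks inflection points falling outside the observed range (a known
#' behaviour of labour data, where the inflection is extrapolated).
#'
#' @param fit a converged `logistic_nlmm`.
#' @param grid signed times (default: 200 points over the observed range).
#' @param allow_extrapolation permit grid points outside the observed range.
#' @return tibble with `t_signed`, `hours_before_full`, `dilatation`;
#'   attribute `"inflection_outside_range"`.
#' @export
average_curve_logistic <- function(fit, grid = NULL,
                                   allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "logistic_nlmm"))
  if (!fit$converged) warning("curve from a non-converged fit")
  if (is.null(grid)) {
    grid <- seq(fit$t_range[1], fit$t_range[2], length.out = 200)
  } else if (!allow_extrapolation &&
             (min(grid) < fit$t_range[1] - 1e-9 ||
              max(grid) > fit$t_range[2] + 1e-9)) {
    stop("grid extends beyond the observed time range; ",
         "set allow_extrapolation = TRUE to override")
  }
  out <- tibble::tibble(
    t_signed = grid,
    hours_before_full = -grid,
    dilatation = logistic_mean(fit$params, grid)
  )
  attr(out, "inflection_outside_range") <-
    fit$params[["beta2"]] < fit$t_range[1] ||
    fit$params[["beta2"]] > fit$t_range[2]
  out
}

#' Fraction of women crossing the partograph alert line
#'
#' The alert line assumes dilatation of `rate` cm/hour from the first exam at
#' or above `start_dilatation`. A woman crosses it if any later exam records a
#' dilatation strictly below the line.
#'
#' @param cohort included long cohort.
#' @param start_dilatation anchor dilatation (default 4 cm).
#' @param rate alert slope in cm/hour (default 1).
#' @return tibble with `parity_group`, `n`, `n_crossed`, `fraction`; women
#'   with no exam at or above the anchor are omitted (counted in `n_skipped`).
#' @export
alert_line_crossing <- function(cohort, start_dilatation = 4, rate = 1) {
  recs <- split(cohort, cohort$woman_id)
  rows <- lapply(recs, function(r) {
    k <- which(r$dilatation_cm >= start_dilatation)[1]
    if (is.na(k)) {
      return(tibble::tibble(parity_group = r$parity_group[1],
                            eligible = FALSE, crossed = NA))
    }
    t0 <- r$exam_time_h[k]
    later <- r[r$exam_time_h > t0, ]
    alert <- start_dilatation + rate * (later$exam_time_h - t0)
    tibble::tibble(parity_group = r$parity_group[1], eligible = TRUE,
                   crossed = any(later$dilatation_cm < alert - 1e-9))
  })
  df <- dplyr::bind_rows(rows)
  df |>
    dplyr::group_by(.data$parity_group) |>
    dplyr::summarise(
      n = sum(.data$eligible),
      n_skipped = sum(!.data$eligible),
      n_crossed = sum(.data$crossed[.data$eligible]),
      fraction = .data$n_crossed / .data$n,
      .groups = "drop"
    )
}
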