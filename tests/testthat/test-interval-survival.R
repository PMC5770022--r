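# Interval-censored log-normal survival analysis.

test_that("reaching intervals bracket by definition", {
  rec <- tiny_record()  # exams (0 h, 4 cm), (3 h, 6 cm), full dilatation 6 h
  ri <- reaching_intervals(rec)
  expect_equal(ri$lower[ri$d == 5], 0)
  expect_equal(ri$upper[ri$d == 5], 3)
  expect_equal(ri$lower[ri$d == 6], 0)
  expect_equal(ri$upper[ri$d == 6], 3)
  expect_true(ri$exact[ri$d == 10])
  expect_equal(ri$lower[ri$d == 10], 6)
  # the admission level is exact at time zero
  expect_true(ri$exact[ri$d == 4])
  # levels below admission are omitted
  expect_false(any(ri$d < 4))
})

test_that("exams at every change instant make all intervals exact", {
  # paired exams at each change instant: every bracket has zero width
  rec <- tibble::tibble(
    woman_id = "W1", parity_group = "0",
    exam_time_h = c(0, 1, 1, 2.5, 2.5, 3.2, 3.2, 4, 4, 5.5),
    dilatation_cm = c(4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L, 8L, 10L),
    oxytocin = FALSE, onset_type = "spontaneous", presentation = "vertex",
    gest_age_wk = 39, prior_scar = FALSE, mode_of_birth = "vaginal",
    adverse_outcome = "none", full_dilatation_time_h = 5.5,
    delivery_time_h = 6
  )
  ri <- reaching_intervals(rec)
  expect_true(all(ri$exact))
  expect_equal(ri$lower[ri$d == 7], 3.2)
  expect_equal(ri$upper[ri$d == 7], 3.2)
})

test_that("regressing dilatations are rejected as outliers", {
  rec <- tiny_record()
  rec$dilatation_cm <- c(6L, 4L, 10L)
  expect_error(reaching_intervals(rec), "regress")
})

test_that("true reaching times and sojourns always fall inside their brackets", {
  cohort <- clean_parity0_cohort(300, seed = 71)
  lat <- attr(cohort, "latent")
  recs <- split(cohort, cohort$woman_id)
  for (id in names(recs)) {
    i <- match(id, lat$woman_id)
    ri <- reaching_intervals(recs[[id]])
    true_reach <- unlist(lat[i, paste0("reach_", ri$d)]) - lat$admission_time[i]
    expect_true(all(ri$lower - 1e-9 <= true_reach &
                      true_reach <= ri$upper + 1e-9))
  }
  # sojourn brackets contain the true sojourns for every transition
  for (k in seq_len(nrow(labourflow:::.sojourn_transitions))) {
    from <- labourflow:::.sojourn_transitions$from[k]
    to <- labourflow:::.sojourn_transitions$to[k]
    dat <- sojourn_data(cohort, from, to)
    truth <- lat[[paste0("sojourn_", from, "_", to)]][
      match(dat$woman_id, lat$woman_id)]
    expect_true(all(dat$lower - 1e-9 <= truth & truth <= dat$upper + 1e-9))
  }
})

test_that("sojourn bounds combine reaching brackets conservatively", {
  # reaching(4) in (0, 2], reaching(5) in (2, 5] -> sojourn in [0, 5]
  rec <- tibble::tibble(
    woman_id = "W1", parity_group = "0",
    exam_time_h = c(0, 2, 5, 8),
    dilatation_cm = c(3L, 4L, 5L, 8L),
    oxytocin = FALSE, onset_type = "spontaneous", presentation = "vertex",
    gest_age_wk = 39, prior_scar = FALSE, mode_of_birth = "vaginal",
    adverse_outcome = "none", full_dilatation_time_h = 9,
    delivery_time_h = 9.5
  )
  dat <- sojourn_data(rec, 4, 5)
  expect_equal(dat$lower, 0)
  expect_equal(dat$upper, 5)
  # reach(8) bracketed (5, 8], reach(10) exact at 9 -> sojourn in [1, 4]
  dat10 <- sojourn_data(rec, 8, 10)
  expect_equal(dat10$lower, 1)
  expect_equal(dat10$upper, 4)
  # two exact reaching times give an exact datum equal to their difference
  rec2 <- rec
  rec2$exam_time_h <- c(0, 2, 2, 8)   # zero-width bracket at 5 cm
  rec2$dilatation_cm <- c(4L, 4L, 5L, 8L)
  dat2 <- sojourn_data(rec2, 4, 5)
  expect_true(dat2$exact)
  expect_equal(dat2$lower, 2)
  expect_equal(dat2$upper, 2)
})

test_that("the MLE reduces to the complete-data closed form on exact data", {
  set.seed(72)
  t <- rlnorm(400, 0.3, 0.8)
  dat <- tibble::tibble(lower = t, upper = t, exact = TRUE)
  fit <- fit_lognormal(dat)
  expect_true(fit$converged)
  expect_equal(fit$mu, mean(log(t)), tolerance = 1e-5)
  expect_equal(fit$sigma, sqrt(mean((log(t) - mean(log(t)))^2)),
               tolerance = 1e-4)
  expect_equal(fit$n_exact, 400)
  # degenerate equal exact values are rejected
  same <- tibble::tibble(lower = rep(2, 20), upper = rep(2, 20), exact = TRUE)
  expect_error(fit_lognormal(same), "degenerate")
  # too few informative observations are rejected
  few <- tibble::tibble(lower = rep(0, 20), upper = rep(Inf, 20), exact = FALSE)
  expect_error(fit_lognormal(few), "informative")
})

test_that("the interval likelihood agrees with an established AFT fitter", {
  skip_if_not_installed("survival")
  set.seed(73)
  t <- rlnorm(600, 0.2, 0.9)
  # independent inspection grid brackets each duration
  grid <- seq(0.25, 8, by = 0.75)
  idx <- findInterval(t, grid)
  lo <- ifelse(idx == 0, 0, grid[pmax(idx, 1)])
  up <- ifelse(idx == length(grid), Inf, grid[pmin(idx + 1, length(grid))])
  dat <- tibble::tibble(lower = lo, upper = up, exact = FALSE)
  fit <- fit_lognormal(dat)
  sv <- survival::survreg(
    survival::Surv(time = ifelse(dat$lower <= 0, NA, dat$lower),
                   time2 = ifelse(is.finite(dat$upper), dat$upper, NA),
                   type = "interval2") ~ 1,
    dist = "lognormal")
  expect_equal(fit$mu, unname(coef(sv)[1]), tolerance = 1e-3)
  expect_equal(fit$sigma, sv$scale, tolerance = 1e-3)
})

test_that("exact-data fits recover simulated parameters within Monte Carlo error", {
  set.seed(74)
  t <- rlnorm(5000, 0.5423, 0.9213)
  fit <- fit_lognormal(tibble::tibble(lower = t, upper = t, exact = TRUE))
  se_mu <- 0.9213 / sqrt(5000)
  se_sigma <- 0.9213 / sqrt(2 * 5000)
  expect_lt(abs(fit$mu - 0.5423), 3 * se_mu)
  expect_lt(abs(fit$sigma - 0.9213), 3 * se_sigma)
})

test_that("interval fits approach the complete-data fit as exams densify", {
  truth <- default_truth("0")
  set.seed(75)
  paths <- simulate_path(truth, 800)
  paths$admission_dilatation <- 2L
  paths$admission_time <- 0
  fits <- lapply(c(2, 0.1), function(g) {
    tr <- truth
    tr$exam_gap <- c(mean = g, sd = g * 0.4, min = g * 0.2)
    ex <- observe_exams(paths, tr, seed = 76)
    ex$woman_id <- sprintf("W%04d", ex$woman)
    fit_lognormal(sojourn_data(ex, 4, 5))
  })
  complete <- fit_lognormal(tibble::tibble(
    lower = paths$sojourn_4_5, upper = paths$sojourn_4_5, exact = TRUE))
  err <- vapply(fits, function(f) abs(f$mu - complete$mu), 0)
  expect_lt(err[2], err[1])          # denser exams come closer
  expect_lt(err[2], 0.03)            # and nearly coincide at 0.1 h gaps
  err_s <- vapply(fits, function(f) abs(f$sigma - complete$sigma), 0)
  expect_lt(err_s[2], 0.03)
})

test_that("percentiles follow the quantile function and its ordering", {
  fit <- structure(list(mu = 0, sigma = 1.3, loglik = 0, n_exact = 10,
                        n_interval = 0, converged = TRUE),
                   class = "lognormal_fit")
  expect_equal(unname(lognormal_percentiles(fit, 0.5)), 1.0)
  fit2 <- structure(list(mu = log(1.72), sigma = 0.92135, loglik = 0,
                         n_exact = 10, n_interval = 0, converged = TRUE),
                    class = "lognormal_fit")
  expect_equal(unname(lognormal_percentiles(fit2, 0.95)), 7.83,
               tolerance = 1e-3)
  expect_error(lognormal_percentiles(fit, 1.2), "probs")
  set.seed(77)
  for (k in 1:20) {
    f <- structure(list(mu = rnorm(1), sigma = runif(1, 0.1, 2), loglik = 0,
                        n_exact = 10, n_interval = 0, converged = TRUE),
                   class = "lognormal_fit")
    q <- lognormal_percentiles(f)
    expect_true(q[1] <= q[2] && q[2] <= q[3])
  }
})

test_that("single-transition cumulative rows equal the matching sojourn fit", {
  cohort <- clean_parity0_cohort(1200, seed = 78)
  ws <- woman_summary(cohort)
  adm6 <- dplyr::filter(cohort, .data$woman_id %in%
                          ws$woman_id[ws$admission_dilatation == 6])
  cum <- cumulative_duration_table(adm6, admission_levels = 6)
  soj <- sojourn_data(adm6, 6, 7)
  fit <- fit_lognormal(soj)
  q <- lognormal_percentiles(fit)
  row <- cum[cum$to == 7, ]
  expect_equal(row$p50, unname(q["0.5"]), tolerance = 1e-6)
  expect_equal(row$p95, unname(q["0.95"]), tolerance = 1e-6)
})

test_that("cumulative rows are nondecreasing in the target level", {
  cohort <- clean_parity0_cohort(1500, seed = 79)
  inc <- apply_inclusion(cohort)$cohort
  cum <- cumulative_duration_table(inc)
  for (a in unique(cum$admission)) {
    sub <- cum[cum$admission == a, ]
    sub <- sub[order(sub$to), ]
    expect_false(is.unsorted(sub$p50))
    expect_false(is.unsorted(sub$p95))
  }
})

test_that("staircase series are monotone and ordered across percentiles", {
  cohort <- clean_parity0_cohort(1500, seed = 80)
  cum <- cumulative_duration_table(cohort)
  st95 <- staircase_series(cum, 4, 0.95)
  st50 <- staircase_series(cum, 4, 0.5)
  expect_false(is.unsorted(st95$hours))
  expect_true(all(st50$hours <= st95$hours))
  expect_error(staircase_series(cum, 8), "admission level")
})
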