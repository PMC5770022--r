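# Progressive multistate Markov model: transition probabilities, panel
# likelihood, fitting, simulation, tables and curves.

test_that("transition probabilities satisfy the basic identities", {
  Q <- build_intensity_matrix(c(0.5, 1, 1.5, 2, 1.2, 0.8, 0.9, 1.1))
  expect_equal(transition_probability(Q, 0), diag(9), ignore_attr = TRUE)
  expect_error(transition_probability(Q, -1), ">= 0")
  # two-state chain: P(t)[r, next] = 1 - exp(-lambda t)
  lam <- 0.7
  Q2 <- matrix(c(-lam, lam, 0, 0), 2, 2, byrow = TRUE)
  P2 <- as.matrix(Matrix::expm(Q2 * 1.3))
  expect_equal(P2[1, 2], 1 - exp(-lam * 1.3), tolerance = 1e-12)
  # rows sum to one, entries within [0, 1]
  P <- transition_probability(Q, 2.2)
  expect_equal(unname(rowSums(P)), rep(1, 9), tolerance = 1e-10)
  expect_true(all(P >= 0 & P <= 1))
})

test_that("Chapman-Kolmogorov holds on random intensity matrices", {
  set.seed(81)
  for (k in 1:5) {
    Q <- random_progressive_Q()
    s <- runif(1, 0.2, 2)
    t <- runif(1, 0.2, 2)
    expect_equal(transition_probability(Q, s) %*% transition_probability(Q, t),
                 transition_probability(Q, s + t), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the closed-form occupancy evaluator matches the matrix exponential", {
  set.seed(82)
  for (k in 1:10) {
    rates <- runif(8, 0.2, 3)
    Q <- build_intensity_matrix(rates)
    t <- runif(1, 0.1, 4)
    P <- transition_probability(Q, t)
    for (r in 1:8) {
      fast <- vapply(r:9, function(s) labourflow:::.p_occupancy(rates, r, s, t), 0)
      expect_lt(max(abs(unname(fast) - unname(P[r, r:9]))), 1e-8)
    }
  }
})

test_that("the panel likelihood matches closed forms on simple chains", {
  # single panel pair on a 2-state sub-chain: ln P[r, s](dt)
  rates <- c(0.6, 1.1, 0.9, 1.4, 1.0, 0.8, 1.2, 0.7)
  Q <- build_intensity_matrix(rates)
  one_pair <- tibble::tibble(
    woman_id = c(1, 1), time_h = c(0, 2), state = c(1L, 2L),
    exact = c(FALSE, FALSE))
  P <- transition_probability(Q, 2)
  expect_equal(panel_log_likelihood(Q, one_pair), log(P[1, 2]),
               tolerance = 1e-10)
  # an exactly-timed absorption contributes the density q e^{-q dt}
  exact_pair <- tibble::tibble(
    woman_id = c(1, 1), time_h = c(0, 1.5), state = c(8L, 9L),
    exact = c(FALSE, TRUE))
  expect_equal(panel_log_likelihood(Q, exact_pair),
               log(rates[8] * exp(-rates[8] * 1.5)), tolerance = 1e-10)
  # empty panels have zero log-likelihood
  expect_equal(panel_log_likelihood(Q, one_pair[0, ]), 0)
  # a backward move is impossible
  bad <- tibble::tibble(woman_id = c(1, 1), time_h = c(0, 1),
                        state = c(4L, 3L), exact = c(FALSE, FALSE))
  ll <- panel_log_likelihood(Q, bad)
  expect_identical(unclass(ll)[1], -Inf)
  expect_s3_class(attr(ll, "violations"), "tbl_df")
})

test_that("continuously observed paths reduce to the occupancy estimator", {
  set.seed(83)
  rates <- c(0.5, 0.9, 1.3, 1.8, 2.4, 2.0, 1.1)
  rows <- lapply(1:300, function(i) {
    soj <- rexp(7, rates)
    tibble::tibble(woman_id = i, time_h = c(0, cumsum(soj)),
                   state = 1:8, exact = c(FALSE, rep(TRUE, 7)))
  })
  panels <- dplyr::bind_rows(rows)
  fit <- fit_intensities(panels)
  # exponential MLE: transitions / total occupancy time, per state
  occupancy <- sapply(1:7, function(r) {
    o <- panels[panels$state %in% c(r, r + 1), ]
    sum(o$time_h[o$state == r + 1] - o$time_h[o$state == r])
  })
  expect_equal(unname(fit$rates[1:7]), 300 / occupancy, tolerance = 1e-4)
  expect_true(is.na(fit$rates[8]))   # no delivery observations
})

test_that("the likelihood peaks at the generating intensities", {
  set.seed(84)
  rates <- c(0.4, 0.55, 0.9, 1.1, 1.6, 2.2, 1.0, 1.3)
  panels <- simulate_exponential_panels(rates, 500)
  Q0 <- build_intensity_matrix(rates)
  ll0 <- panel_log_likelihood(Q0, panels)
  for (k in 1:5) {
    Qp <- build_intensity_matrix(rates * runif(8, 0.6, 1.6))
    expect_gt(ll0, panel_log_likelihood(Qp, panels))
  }
})

test_that("grid simulation reproduces the chain it is given", {
  # single transient state with rate ln 2: median sojourn 1 h +- one step
  rates <- c(log(2), rep(20, 7))
  Q <- build_intensity_matrix(rates)
  traj <- simulate_markov_cohort(Q, c("2" = 1), n = 20000, seed = 85)
  tab <- markov_sojourn_table(traj)
  expect_lt(abs(tab$p50[tab$from == 2] - 1.0), traj$step + 1e-9)
  # empirical occupancy at t matches P(t) within binomial error
  P <- transition_probability(Q, 1)
  emp <- mean(traj$entry[, "3"] <= 1, na.rm = TRUE)  # left state 2 by t = 1
  expect_lt(abs(emp - (1 - P[1, 1])), 4 * sqrt(0.25 / 20000) + 0.01)
  # same seed, same trajectories
  traj2 <- simulate_markov_cohort(Q, c("2" = 1), n = 100, seed = 86)
  traj3 <- simulate_markov_cohort(Q, c("2" = 1), n = 100, seed = 86)
  expect_identical(traj2$entry, traj3$entry)
})

test_that("a chain that cannot reach delivery is capped with a warning", {
  rates <- c(1e-9, rep(1, 7))
  Q <- build_intensity_matrix(rates)
  expect_warning(
    traj <- simulate_markov_cohort(Q, c("2" = 1), n = 20, horizon = 5,
                                   seed = 87),
    "did not reach"
  )
  expect_true(all(is.na(traj$entry[, "10"])))
})

test_that("simulated sojourn quantiles match the exponential closed form", {
  rates <- c(0.8, 0.6, 1.2, 1.5, 2.0, 2.5, 1.3, 1.1)
  Q <- build_intensity_matrix(rates)
  traj <- simulate_markov_cohort(Q, c("2" = 1), n = 30000, seed = 88)
  tab <- markov_sojourn_table(traj)
  ana <- exponential_sojourn_quantiles(Q)
  # the first transition, observed from entry for every woman
  for (p in c("p5", "p50", "p95")) {
    expect_lt(abs(tab[[p]][tab$from == 2] - ana[[p]][1]), traj$step + 1e-9)
  }
  # the five-minute grid floors the 5th percentile at one step (or zero)
  expect_true(all(tab$p5 >= 0))
  expect_true(all(tab$p5 <= 1e-9 | tab$p5 >= traj$step - 1e-9))
})

test_that("cumulative first-passage tables behave like sums of sojourns", {
  rates <- c(0.8, 0.6, 1.2, 1.5, 2.0, 2.5, 1.3, 1.1)
  Q <- build_intensity_matrix(rates)
  traj <- simulate_markov_cohort(Q, c("4" = 1), n = 30000, seed = 89)
  tab <- markov_cumulative_table(traj)
  expect_true(all(tab$admission == 4))
  # mean first passage to 10 equals the sum of mean sojourns 4 -> 10
  fp <- traj$entry[, "10"]
  expect_equal(mean(fp), sum(1 / rates[3:7]), tolerance = 0.03)
  sub <- tab[order(tab$to), ]
  expect_false(is.unsorted(sub$p50))
})

test_that("intensity recovery from cohort panels is accurate", {
  set.seed(90)
  rates <- c(0.35, 0.5, 0.8, 1.2, 1.8, 2.3, 1.0, 1.2)
  panels <- simulate_exponential_panels(rates, 800)
  fit <- fit_intensities(panels)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$rates[1:7] / rates[1:7] - 1)), 0.15)
  expect_true(all(fit$se_rates[1:7] > 0))
})

test_that("reverse-time average curves are anchored and monotone", {
  # deterministic staircase check: identical 1 cm/h trajectories from 4 cm
  entry <- matrix(NA_real_, 50, 8,
                  dimnames = list(NULL, c("2", "3", "4", "5", "6", "7", "8", "10")))
  entry[, 3:8] <- matrix(rep(c(0, 1, 2, 3, 4, 6), each = 50), 50)
  traj <- structure(list(entry = entry,
                         admission_state = rep("4", 50),
                         step = 1 / 12, horizon = 72),
                    class = "markov_trajectories")
  curve <- average_curve_markov(traj, tau_grid = seq(0, 6, by = 0.5))
  expect_equal(curve$mean_dilatation[curve$hours_before_full == 0], 10)
  expect_false(is.unsorted(rev(curve$mean_dilatation)))
  # slope ~ 1 cm/h within the single-step region (8 -> 10 jumps by 2)
  expect_equal(curve$mean_dilatation[curve$hours_before_full == 3], 7)

  # stochastic case: anchored at 10, monotone nonincreasing in tau
  rates <- c(0.5, 0.7, 0.9, 1.4, 1.9, 2.2, 1.2, 1.0)
  Q <- build_intensity_matrix(rates)
  sim <- simulate_markov_cohort(Q, c("3" = 0.5, "4" = 0.5), n = 4000,
                                seed = 91)
  curve2 <- average_curve_markov(sim)
  expect_equal(curve2$mean_dilatation[curve2$hours_before_full == 0], 10)
  # strictly nonincreasing where nearly all trajectories are still at risk;
  # beyond that the shrinking at-risk set may wiggle by Monte-Carlo amounts
  core <- curve2[curve2$n >= 0.95 * max(curve2$n), ]
  expect_true(all(diff(core$mean_dilatation) <= 1e-9))
  expect_true(all(diff(curve2$mean_dilatation) <= 0.05))
})
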