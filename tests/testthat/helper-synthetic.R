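# Shared fixture builders. Everything is generated in code under fixed seeds.

zero_exclusions <- function() {
  setNames(rep(0, 9), c("preterm", "postterm", "induced", "nonvertex",
                        "prior_scar", "cesarean", "adverse_outcome",
                        "severe_malformation", "few_exams"))
}

# clean parity-0 cohort (no planted exclusions)
clean_parity0_cohort <- function(n, seed) {
  generate_cohort(
    cohort_config(parity_n = c("0" = n, "1" = 0, "2+" = 0),
                  exclusion_rates = zero_exclusions()),
    seed = seed
  )
}

# a tiny hand-built record: exams (0 h, 4 cm), (3 h, 6 cm), full dilatation 6 h
tiny_record <- function() {
  tibble::tibble(
    woman_id = "W1",
    parity_group = "0",
    exam_time_h = c(0, 3, 6),
    dilatation_cm = c(4L, 6L, 10L),
    oxytocin = FALSE,
    onset_type = "spontaneous",
    presentation = "vertex",
    gest_age_wk = 39,
    prior_scar = FALSE,
    mode_of_birth = "vaginal",
    adverse_outcome = "none",
    full_dilatation_time_h = 6,
    delivery_time_h = 6.5
  )
}

# panel series simulated from a known progressive chain: exams at fixed gaps,
# absorption into 10 cm exactly timed (as in the real records)
simulate_exponential_panels <- function(rates, n, gap = 2.5) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    soj <- stats::rexp(7, rates[1:7])
    reach <- c(0, cumsum(soj))
    tt <- seq(0, max(reach), by = gap)
    st <- findInterval(tt, reach)
    keep <- which(st < 8)
    rows[[i]] <- tibble::tibble(
      woman_id = i,
      time_h = c(tt[keep], reach[8]),
      state = c(st[keep], 8L),
      exact = c(rep(FALSE, length(keep)), TRUE)
    )
  }
  dplyr::bind_rows(rows)
}

# observations drawn from the logistic growth mixed model itself
simulate_logistic_obs <- function(n, truth = c(beta0 = 0, beta1 = 10,
                                               beta2 = -6, sigma_b = 1.5,
                                               sigma_eps = 0.4),
                                  k_range = 3:6) {
  rows <- lapply(seq_len(n), function(i) {
    b <- stats::rnorm(1, 0, truth[["sigma_b"]])
    k <- sample(k_range, 1)
    t <- sort(c(stats::runif(k, -12, -0.5), 0))
    y <- logistic_mean(truth, t, b) +
      stats::rnorm(length(t), 0, truth[["sigma_eps"]])
    tibble::tibble(woman_id = i, t_signed = t, dilatation = y)
  })
  dplyr::bind_rows(rows)
}

# random valid progressive intensity matrix
random_progressive_Q <- function() {
  build_intensity_matrix(stats::runif(8, 0.2, 3))
}
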