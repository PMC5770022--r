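# Synthetic labour cohort generator
#
# Emulates the statistical structure the downstream analyses assume: per-parity
# log-normal sojourn times for each 1-cm transition (calibrated to published
# median / 95th-percentile pairs), the admission-dilatation mix, sparse exam
# schedules, oxytocin-augmentation flags, and records triggering each
# sample-selection exclusion.

# Published per-transition survival percentiles (median, p95, hours) by parity.
# Transitions: 3->4, 4->5, 5->6, 6->7, 7->8, 8->10 cm.
.calibration_survival <- list(
  "0" = cbind(
    median = c(2.82, 1.72, 1.19, 0.66, 0.25, 0.87),
    p95    = c(13.33, 7.83, 6.17, 4.92, 3.10, 4.19)
  ),
  "1" = cbind(
    median = c(2.42, 1.37, 0.79, 0.33, 0.09, 0.64),
    p95    = c(14.18, 7.65, 4.95, 3.67, 2.69, 3.56)
  ),
  "2+" = cbind(
    median = c(2.35, 1.18, 0.79, 0.31, 0.17, 0.68),
    p95    = c(17.85, 8.05, 6.24, 3.29, 2.44, 3.77)
  )
)

# Admission-dilatation stratum sizes (3..6 cm) and stratum totals by parity;
# the 2-cm mass is the remainder, consistent with a 10th percentile of 2 cm.
.calibration_admission_n <- list(
  "0"  = c(`3` = 249, `4` = 715, `5` = 316, `6` = 322, total = 2166),
  "1"  = c(`3` = 164, `4` = 491, `5` = 292, `6` = 320, total = 1488),
  "2+" = c(`3` = 231, `4` = 626, `5` = 385, `6` = 414, total = 1952)
)

.calibration_oxytocin <- c("0" = 0.400, "1" = 0.298, "2+" = 0.267)

.parity_levels <- c("0", "1", "2+")

.adverse_flags <- c(
  "stillbirth", "early_neonatal_death", "anticonvulsant", "cpr",
  "apgar5_lt6", "maternal_death_or_organ_dysfunction", "uterine_rupture"
)

#' Default generator truth for one parity group
#'
#' Builds the latent distributional "truth" the generator simulates from:
#' per-transition log-normal sojourn parameters inverted from published
#' median/95th-percentile pairs (`mu = ln(median)`,
#' `sigma = (ln(p95) - mu) / qnorm(0.95)`), the admission-dilatation mix
#' proportional to the published admission-stratum sizes, the exam-gap
#' schedule, the oxytocin-augmentation rate, and per-criterion exclusion
#' rates. The 2 to 3 cm transition is not tabulated in the source; its median
#' is set to 1.2 times the 3 to 4 cm median with the same log-scale SD.
#'
#' @param parity_group one of `"0"`, `"1"`, `"2+"`.
#' @return an object of class `generator_truth`: a list with elements
#'   `parity_group`, `transitions` (tibble with `from`, `to`, `median`, `p95`,
#'   `mu`, `sigma`), `admission_mix` (named probability vector over 2--6 cm),
#'   `exam_gap` (`mean`, `sd`, `min` hours), `oxytocin_rate`,
#'   `second_stage` (`mu`, `sigma` of the log-normal 10 cm-to-delivery time)
#'   and `exclusion_rates`.
#' @export
default_truth <- function(parity_group = c("0", "1", "2+")) {
  parity_group <- match.arg(parity_group)
  cal <- .calibration_survival[[parity_group]]
  z95 <- qnorm(0.95)
  mu <- unname(log(cal[, "median"]))
  sigma <- unname((log(cal[, "p95"]) - mu) / z95)
  # 2->3 cm: not tabulated; slightly slower than 3->4 with the same spread
  mu23 <- unname(log(1.2 * cal[1, "median"]))
  sigma23 <- sigma[1]
  transitions <- tibble::tibble(
    from = .sojourn_transitions$from,
    to = .sojourn_transitions$to,
    mu = c(mu23, mu),
    sigma = c(sigma23, sigma)
  )
  transitions$median <- exp(transitions$mu)
  transitions$p95 <- exp(transitions$mu + z95 * transitions$sigma)

  adm <- .calibration_admission_n[[parity_group]]
  counts <- c(`2` = unname(adm["total"] - sum(adm[c("3", "4", "5", "6")])),
              adm[c("3", "4", "5", "6")])
  mix <- counts / sum(counts)

  second_stage_median <- c("0" = 0.67, "1" = 0.33, "2+" = 0.25)[[parity_group]]

  truth <- structure(list(
    parity_group = parity_group,
    transitions = transitions,
    admission_mix = mix,
    exam_gap = c(mean = 2.5, sd = 1, min = 0.5),
    oxytocin_rate = unname(.calibration_oxytocin[parity_group]),
    second_stage = c(mu = log(second_stage_median), sigma = 0.6),
    exclusion_rates = c(
      preterm = 0.050, postterm = 0.015, induced = 0.100, nonvertex = 0.030,
      prior_scar = 0.030, cesarean = 0.090, adverse_outcome = 0.020,
      severe_malformation = 0.003, few_exams = 0.020
    )
  ), class = "generator_truth")
  validate_truth(truth)
}

#' Validate a generator truth object
#'
#' Checks the type invariants: positive log-scale SDs, an admission mix that
#' sums to one, and rates in `[0, 1]`.
#'
#' @param truth a `generator_truth` object.
#' @return `truth`, invisibly usable; errors on violation.
#' @export
validate_truth <- function(truth) {
  stopifnot(inherits(truth, "generator_truth"))
  if (any(truth$transitions$sigma <= 0)) {
    stop("generator truth invalid: every transition requires sigma > 0")
  }
  if (abs(sum(truth$admission_mix) - 1) > 1e-8 || any(truth$admission_mix < 0)) {
    stop("generator truth invalid: admission_mix must be a probability vector")
  }
  rates <- c(truth$oxytocin_rate, truth$exclusion_rates)
  if (any(rates < 0 | rates > 1)) {
    stop("generator truth invalid: probabilities must lie in [0, 1]")
  }
  if (sum(truth$exclusion_rates) >= 1) {
    stop("generator truth invalid: exclusion rates must sum to < 1")
  }
  invisible(truth)
}

#' Simulate latent dilatation paths
#'
#' Draws, for `n` women, an admission dilatation from the truth's admission
#' mix and independent log-normal sojourn times for every 1-cm transition
#' (8 to 10 cm as one transition). Paths start at 2 cm at time 0 (labour-onset
#' reference); cumulative sums give the time each level is reached. Women are
#' taken to present at the moment they reach their admission dilatation.
#'
#' @param truth a `generator_truth`.
#' @param n number of women.
#' @param seed optional integer seed (uses the current RNG stream when `NULL`).
#' @return a tibble with one row per woman: `admission_dilatation`,
#'   `admission_time`, reaching times `reach_2` ... `reach_8`, `reach_10`
#'   (hours since labour-onset reference) and per-transition sojourns
#'   `sojourn_2_3` ... `sojourn_8_10`.
#' @export
simulate_path <- function(truth, n, seed = NULL) {
  validate_truth(truth)
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(n >= 0)
  tr <- truth$transitions
  k <- nrow(tr)
  if (n == 0) {
    out <- tibble::tibble(
      admission_dilatation = integer(0), admission_time = numeric(0)
    )
  } else {
    sojourns <- matrix(
      rlnorm(n * k, meanlog = rep(tr$mu, each = n),
             sdlog = rep(tr$sigma, each = n)),
      nrow = n
    )
    reach <- cbind(0, t(apply(sojourns, 1L, cumsum)))
    if (n == 1) reach <- matrix(c(0, cumsum(sojourns[1, ])), nrow = 1)
    colnames(reach) <- paste0("reach_", .dilatation_levels)
    adm_levels <- as.integer(names(truth$admission_mix))
    adm <- sample(adm_levels, n, replace = TRUE, prob = truth$admission_mix)
    adm_time <- reach[cbind(seq_len(n), match(adm, .dilatation_levels))]
    out <- tibble::tibble(
      admission_dilatation = adm,
      admission_time = adm_time
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(reach))
    soj <- tibble::as_tibble(sojourns, .name_repair = "minimal")
    names(soj) <- paste0("sojourn_", tr$from, "_", tr$to)
    out <- dplyr::bind_cols(out, soj)
  }
  out
}

# dilatation level occupied at absolute time t (vectorised over one woman's
# exam times): largest level whose reaching time is <= t
.level_at <- function(reach_row, times) {
  .dilatation_levels[findInterval(times, reach_row)]
}

#' Observe a latent path through a sparse exam schedule
#'
#' Produces exam rows at admission and then at stochastic gaps (truncated
#' normal: mean 2.5 h, SD 1 h, minimum 0.5 h by default) until full
#' dilatation. The recorded dilatation is the integer level the latent path
#' occupies at the exam time; the 10-cm time is recorded exactly. Every woman
#' receives at least one examination between admission and full dilatation.
#'
#' @param paths tibble from [simulate_path()].
#' @param truth the `generator_truth` used to draw the paths.
#' @param seed optional integer seed.
#' @return a long tibble with columns `woman`, `exam_time_h` (hours since
#'   admission), `dilatation_cm`, plus per-woman `full_dilatation_time_h` and
#'   `delivery_time_h` repeated on each row. The final row of each woman is
#'   the full-dilatation confirmation (10 cm); first-stage assessments are the
#'   rows strictly before it.
#' @export
observe_exams <- function(paths, truth, seed = NULL) {
  validate_truth(truth)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(paths)
  if (n == 0) {
    return(tibble::tibble(
      woman = integer(0), exam_time_h = numeric(0), dilatation_cm = integer(0),
      full_dilatation_time_h = numeric(0), delivery_time_h = numeric(0)
    ))
  }
  gap_mean <- unname(truth$exam_gap["mean"])
  gap_sd <- unname(truth$exam_gap["sd"])
  p_lo <- pnorm((unname(truth$exam_gap["min"]) - gap_mean) / gap_sd)
  reach_cols <- as.matrix(paths[paste0("reach_", .dilatation_levels)])
  second <- rlnorm(n, truth$second_stage["mu"], truth$second_stage["sigma"])
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t_adm <- paths$admission_time[i]
    t_full <- unname(reach_cols[i, "reach_10"])
    times <- t_adm
    repeat {
      g <- gap_mean + gap_sd * qnorm(runif(1, p_lo, 1))
      nxt <- times[length(times)] + g
      if (nxt >= t_full) break
      times <- c(times, nxt)
    }
    if (length(times) < 2) {
      # attendants always examine at least once before confirming 10 cm
      times <- c(times, t_adm + (t_full - t_adm) / 2)
    }
    dil <- .level_at(reach_cols[i, ], times)
    rows[[i]] <- tibble::tibble(
      woman = i,
      exam_time_h = c(times, t_full) - t_adm,
      dilatation_cm = as.integer(c(dil, 10L)),
      full_dilatation_time_h = t_full - t_adm,
      delivery_time_h = t_full - t_adm + second[i]
    )
  }
  dplyr::bind_rows(rows)
}

#' Configuration for cohort generation
#'
#' @param n number of analysis-eligible (clean) women; records triggering
#'   exclusions are planted on top at `exclusion_rates`, interpreted as
#'   fractions of the screened total.
#' @param parity_mix probabilities over parity groups `0`, `1`, `2+`
#'   (defaults proportional to the published stratum sizes). Ignored when
#'   `parity_n` is given.
#' @param parity_n optional named integer vector of exact clean counts per
#'   parity group, e.g. `c("0" = 2166, "1" = 1488, "2+" = 1952)`.
#' @param oxytocin_rates named augmentation probabilities per parity group.
#' @param exclusion_rates named per-criterion planting rates; `NULL` uses the
#'   defaults in [default_truth()]. Set to a zero vector for a clean cohort.
#' @param couple_oxytocin when `TRUE`, augmentation flags the slowest
#'   `rate` fraction of each parity group by true 3--5 cm sojourn
#'   (emulating selection of slow labours for augmentation); when `FALSE`
#'   (default) flags are independent of the sojourns.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n = 600,
                          parity_mix = NULL,
                          parity_n = NULL,
                          oxytocin_rates = .calibration_oxytocin,
                          exclusion_rates = NULL,
                          couple_oxytocin = FALSE) {
  if (is.null(parity_mix)) {
    totals <- vapply(.calibration_admission_n, function(x) x[["total"]], 0)
    parity_mix <- totals / sum(totals)
  }
  structure(list(
    n = n, parity_mix = parity_mix, parity_n = parity_n,
    oxytocin_rates = oxytocin_rates, exclusion_rates = exclusion_rates,
    couple_oxytocin = couple_oxytocin
  ), class = "cohort_config")
}

# anomaly application for one planted criterion; record fields are per-woman
.plant_anomaly <- function(meta, criterion) {
  switch(criterion,
    preterm = {meta$gest_age_wk <- runif(1, 34, 36.99); meta},
    postterm = {meta$gest_age_wk <- runif(1, 42.01, 43.5); meta},
    induced = {meta$onset_type <- "induced"; meta},
    nonvertex = {meta$presentation <- "other"; meta},
    prior_scar = {meta$prior_scar <- TRUE; meta},
    cesarean = {meta$mode_of_birth <- "cesarean"; meta},
    adverse_outcome = {
      meta$adverse_outcome <- sample(.adverse_flags, 1)
      meta
    },
    severe_malformation = {meta$adverse_outcome <- "severe_malformation"; meta},
    few_exams = meta,  # handled at the exam level
    stop("unknown exclusion criterion: ", criterion)
  )
}

#' Generate a synthetic labour cohort
#'
#' Generates a long-format cohort with the structure the analyses assume:
#' clean records per parity group (exact counts), plus records planted to
#' trigger each sample-selection exclusion at the configured rates. Oxytocin
#' flags are independent of the sojourns by default; `couple_oxytocin = TRUE`
#' flags the slowest fraction instead.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer seed for full reproducibility.
#' @return a long tibble (one row per exam) with columns `woman_id`,
#'   `parity_group`, `exam_time_h`, `dilatation_cm`, `oxytocin`, `onset_type`,
#'   `presentation`, `gest_age_wk`, `prior_scar`, `mode_of_birth`,
#'   `adverse_outcome`, `full_dilatation_time_h`, `delivery_time_h`. The
#'   attribute `"latent"` carries per-woman generator bookkeeping (true
#'   reaching times, planted criterion, true sojourns) for oracle testing.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(config$parity_n)) {
    if (config$n < 0) stop("cohort size must be >= 0")
    parity_n <- round(config$n * config$parity_mix)
    names(parity_n) <- .parity_levels
  } else {
    parity_n <- config$parity_n[.parity_levels]
    parity_n[is.na(parity_n)] <- 0
    names(parity_n) <- .parity_levels
  }

  all_rows <- list()
  all_latent <- list()
  id_offset <- 0L
  for (pg in .parity_levels) {
    n_clean <- as.integer(parity_n[[pg]])
    if (n_clean == 0) next
    truth <- default_truth(pg)
    rates <- config$exclusion_rates
    if (is.null(rates)) rates <- truth$exclusion_rates
    n_excl <- round(n_clean * rates / (1 - sum(rates)))
    planted <- rep(c("none", names(n_excl)), times = c(n_clean, n_excl))
    n_tot <- length(planted)
    planted <- sample(planted)  # shuffle so ids carry no signal

    paths <- simulate_path(truth, n_tot)
    exams <- observe_exams(paths, truth)

    # per-woman covariates (clean defaults)
    gest <- qnorm(runif(n_tot, pnorm((37 - 38.74) / 1.10),
                        pnorm((41 + 6 / 7 - 38.74) / 1.10))) * 1.10 + 38.74
    meta <- tibble::tibble(
      woman = seq_len(n_tot),
      parity_group = pg,
      gest_age_wk = gest,
      onset_type = "spontaneous",
      presentation = "vertex",
      prior_scar = FALSE,
      mode_of_birth = sample(c("vaginal", "operative_vaginal"), n_tot,
                             replace = TRUE, prob = c(0.98, 0.02)),
      adverse_outcome = "none",
      planted = planted
    )
    for (i in which(planted != "none")) {
      meta[i, ] <- .plant_anomaly(meta[i, ], planted[i])
    }

    # oxytocin: independent draw, or deterministic selection of the slowest
    slow35 <- paths$sojourn_3_4 + paths$sojourn_4_5
    rate <- config$oxytocin_rates[[pg]]
    if (isTRUE(config$couple_oxytocin)) {
      thr <- quantile(slow35, 1 - rate, type = 7)
      meta$oxytocin <- slow35 > thr
    } else {
      meta$oxytocin <- runif(n_tot) < rate
    }

    # few-exams plants: strip intra-partum exams, keep admission + 10 cm rows
    few <- which(planted == "few_exams")
    if (length(few)) {
      exams <- exams |>
        dplyr::group_by(.data$woman) |>
        dplyr::filter(!(.data$woman %in% few) |
                        dplyr::row_number() == 1 |
                        dplyr::row_number() == dplyr::n()) |>
        dplyr::ungroup()
    }
    # cesarean plants never reach full dilatation: truncate the exam series
    ces <- which(planted == "cesarean")
    if (length(ces)) {
      exams <- exams |>
        dplyr::group_by(.data$woman) |>
        dplyr::filter(!(.data$woman %in% ces) |
                        dplyr::row_number() <= pmax(2, dplyr::n() - 1)) |>
        dplyr::ungroup() |>
        dplyr::mutate(
          full_dilatation_time_h = ifelse(.data$woman %in% ces, NA_real_,
                                          .data$full_dilatation_time_h),
          delivery_time_h = ifelse(.data$woman %in% ces, NA_real_,
                                   .data$delivery_time_h),
          dilatation_cm = ifelse(.data$woman %in% ces &
                                   .data$dilatation_cm == 10L,
                                 8L, .data$dilatation_cm)
        )
    }

    long <- dplyr::left_join(exams, meta, by = "woman")
    long$woman_id <- sprintf("W%06d", id_offset + long$woman)
    latent <- dplyr::bind_cols(
      tibble::tibble(woman_id = sprintf("W%06d", id_offset + seq_len(n_tot)),
                     parity_group = pg, planted = planted),
      paths
    )
    id_offset <- id_offset + n_tot
    all_rows[[pg]] <- long
    all_latent[[pg]] <- latent
  }

  cols <- c("woman_id", "parity_group", "exam_time_h", "dilatation_cm",
            "oxytocin", "onset_type", "presentation", "gest_age_wk",
            "prior_scar", "mode_of_birth", "adverse_outcome",
            "full_dilatation_time_h", "delivery_time_h")
  if (!length(all_rows)) {
    cohort <- tibble::as_tibble(setNames(
      list(character(0), character(0), numeric(0), integer(0), logical(0),
           character(0), character(0), numeric(0), logical(0), character(0),
           character(0), numeric(0), numeric(0)), cols))
    attr(cohort, "latent") <- tibble::tibble()
    return(cohort)
  }
  cohort <- dplyr::bind_rows(all_rows)[cols]
  attr(cohort, "latent") <- dplyr::bind_rows(all_latent)
  cohort
}
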