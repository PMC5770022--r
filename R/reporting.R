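# Cohort I/O, table assembly and the full-analysis driver (including the
# oxytocin-augmentation sensitivity comparison).

#' Read a long-format cohort CSV
#'
#' Validates the schema and drops malformed rows (non-integer or out-of-range
#' dilatations, negative times) with a message. A column-mapping vector adapts
#' externally deposited files whose columns are named differently.
#'
#' @param path CSV path.
#' @param col_map optional named character vector `c(schema_name = file_name)`.
#' @return a validated long cohort tibble; attribute `"n_dropped"` counts
#'   rejected rows.
#' @export
read_cohort <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      file_name <- col_map[[schema_name]]
      if (!file_name %in% names(raw)) {
        stop("mapped column not in file: ", file_name)
      }
      names(raw)[names(raw) == file_name] <- schema_name
    }
  }
  missing_cols <- setdiff(.required_columns, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  raw$dilatation_cm <- suppressWarnings(as.integer(raw$dilatation_cm))
  raw$exam_time_h <- suppressWarnings(as.numeric(raw$exam_time_h))
  ok <- !is.na(raw$woman_id) &
    !is.na(raw$dilatation_cm) & raw$dilatation_cm >= 0 &
    raw$dilatation_cm <= 10 &
    !is.na(raw$exam_time_h) & raw$exam_time_h >= 0 &
    raw$parity_group %in% .parity_levels
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message(n_dropped, " malformed row(s) dropped")
  }
  out <- tibble::as_tibble(raw[ok, ])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a cohort to CSV
#'
#' @param cohort long cohort tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(as.data.frame(cohort), path)
  invisible(path)
}

#' Configuration of a full analysis run
#'
#' @param cohort a long cohort tibble, or `NULL` to generate one.
#' @param generator a [cohort_config()] used when `cohort` is `NULL`.
#' @param methods subset of `c("survival", "markov", "logistic")`.
#' @param exclude_augmented also run the population without oxytocin
#'   augmentation and report median differences.
#' @param probs percentile probabilities (within (0, 1)).
#' @param admission_levels admission strata for cumulative tables.
#' @param markov_step simulation grid step (hours).
#' @param markov_nsim simulated trajectories per stratum.
#' @param quad_nodes quadrature nodes for the logistic model.
#' @param seed integer seed governing every stochastic stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(cohort = NULL,
                            generator = cohort_config(),
                            methods = c("survival", "markov", "logistic"),
                            exclude_augmented = FALSE,
                            probs = c(0.05, 0.5, 0.95),
                            admission_levels = 3:6,
                            markov_step = 1 / 12,
                            markov_nsim = 20000,
                            quad_nodes = 21,
                            seed = 1L) {
  methods <- match.arg(methods, c("survival", "markov", "logistic"),
                       several.ok = TRUE)
  if (!length(methods)) stop("at least one method required")
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
  structure(list(
    cohort = cohort, generator = generator, methods = methods,
    exclude_augmented = exclude_augmented, probs = probs,
    admission_levels = admission_levels, markov_step = markov_step,
    markov_nsim = markov_nsim, quad_nodes = quad_nodes, seed = seed
  ), class = "analysis_config")
}

# admission-state distribution of a stratum from its first exams
.admission_distribution <- function(cohort) {
  adm <- cohort |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(adm = dplyr::first(.data$dilatation_cm), .groups = "drop")
  tab <- table(factor(adm$adm, levels = .dilatation_levels[-8]))
  p <- as.numeric(tab) / sum(tab)
  setNames(p, names(tab))[p > 0]
}

# one stratum x one population: run the requested methods
.run_stratum <- function(sub, cfg, tag) {
  out <- list()
  if ("survival" %in% cfg$methods) {
    out$survival_sojourn <- sojourn_duration_table(sub, probs = cfg$probs)
    out$survival_cumulative <- cumulative_duration_table(
      sub, admission_levels = cfg$admission_levels, probs = cfg$probs)
  }
  if ("markov" %in% cfg$methods) {
    panels <- panels_from_cohort(sub)
    fit <- fit_intensities(panels)
    traj <- simulate_markov_cohort(
      fit$Q, .admission_distribution(sub), n = cfg$markov_nsim,
      step = cfg$markov_step)
    out$markov_fit <- fit
    out$markov_sojourn <- markov_sojourn_table(traj, probs = cfg$probs)
    out$markov_cumulative <- markov_cumulative_table(traj, probs = cfg$probs)
    out$markov_curve <- average_curve_markov(traj)
  }
  if ("logistic" %in% cfg$methods) {
    obs <- reverse_time(sub)
    lfit <- fit_logistic_nlmm(obs, nodes = cfg$quad_nodes)
    out$logistic_fit <- lfit
    out$logistic_curve <- average_curve_logistic(lfit)
  }
  lapply(out, function(x) {
    if (tibble::is_tibble(x)) {
      x$stratum <- tag$stratum
      x$population <- tag$population
    }
    x
  })
}

#' Signed difference of medians between two duration tables
#'
#' All-women medians minus non-augmented medians, joined on the table keys;
#' the sign is preserved (exclusion can lengthen as well as shorten medians).
#'
#' @param all_tab,woa_tab duration tables (same layout) for all women and for
#'   the population without oxytocin augmentation.
#' @return the join with `p50_all`, `p50_without`, `diff_p50`.
#' @export
difference_of_medians <- function(all_tab, woa_tab) {
  keys <- intersect(c("from", "to", "admission"), names(all_tab))
  a <- all_tab[, c(keys, "p50")]
  b <- woa_tab[, c(keys, "p50")]
  names(a)[names(a) == "p50"] <- "p50_all"
  names(b)[names(b) == "p50"] <- "p50_without"
  out <- dplyr::inner_join(a, b, by = keys)
  out$diff_p50 <- out$p50_all - out$p50_without
  out
}

#' Run the full labour-progression analysis
#'
#' Applies the sample-selection filters, then per parity stratum (and, when
#' requested, for the population excluding augmented labours) runs the
#' survival, Markov and logistic analyses, and assembles the report bundle:
#' sojourn and cumulative duration tables for both methods, average curves,
#' flow counts, difference-of-median tables and run metadata. Deterministic
#' under a fixed seed.
#'
#' @param config an [analysis_config()].
#' @return list of class `report_bundle`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  withr::local_seed(config$seed)
  cohort <- config$cohort
  if (is.null(cohort)) cohort <- generate_cohort(config$generator)
  filtered <- apply_inclusion(cohort)
  included <- filtered$cohort

  populations <- list(all = included)
  if (config$exclude_augmented) {
    populations$without_oxytocin <- exclude_augmented(included)
  }
  strata <- stratify(included, "parity_group")
  results <- list()
  errors <- list()
  for (pop_name in names(populations)) {
    pop <- populations[[pop_name]]
    for (st_name in names(strata)) {
      ids <- unique(strata[[st_name]]$woman_id)
      sub <- dplyr::filter(pop, .data$woman_id %in% ids)
      if (!nrow(sub)) next
      tag <- list(stratum = st_name, population = pop_name)
      res <- tryCatch(
        .run_stratum(sub, config, tag),
        error = function(e) e
      )
      key <- paste(st_name, pop_name, sep = "|")
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
      } else {
        results[[key]] <- res
      }
    }
  }

  gather <- function(field) {
    dplyr::bind_rows(lapply(results, function(r) r[[field]]))
  }
  bundle <- list(
    flow_counts = filtered$flow_counts,
    survival_sojourn = gather("survival_sojourn"),
    survival_cumulative = gather("survival_cumulative"),
    markov_sojourn = gather("markov_sojourn"),
    markov_cumulative = gather("markov_cumulative"),
    markov_curves = gather("markov_curve"),
    logistic_curves = gather("logistic_curve"),
    fits = lapply(results, function(r)
      r[intersect(names(r), c("markov_fit", "logistic_fit"))]),
    errors = errors,
    meta = list(
      seed = config$seed,
      methods = config$methods,
      n_included = filtered$flow_counts$n_included,
      package_version = as.character(utils::packageVersion("labourflow"))
    )
  )
  if (config$exclude_augmented) {
    diffs <- list()
    for (st_name in names(strata)) {
      for (field in c("survival_sojourn", "markov_sojourn",
                      "survival_cumulative", "markov_cumulative")) {
        a <- results[[paste(st_name, "all", sep = "|")]][[field]]
        b <- results[[paste(st_name, "without_oxytocin", sep = "|")]][[field]]
        if (is.null(a) || is.null(b)) next
        d <- difference_of_medians(a, b)
        d$stratum <- st_name
        d$table <- field
        diffs[[paste(st_name, field)]] <- d
      }
    }
    bundle$median_differences <- dplyr::bind_rows(diffs)
  }
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("labour progression report bundle\n")
  print(x$flow_counts)
  for (f in c("survival_sojourn", "survival_cumulative", "markov_sojourn",
              "markov_cumulative")) {
    if (!is.null(x[[f]]) && nrow(x[[f]])) {
      cat(sprintf("  %-20s %4d rows\n", f, nrow(x[[f]])))
    }
  }
  if (length(x$errors)) {
    cat("stratum errors:\n")
    for (k in names(x$errors)) cat("  ", k, ": ", x$errors[[k]], "\n", sep = "")
  }
  invisible(x)
}
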