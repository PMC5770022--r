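# Sample-selection filters and stratification
#
# Reproduces the analysis sample-selection chain: term gestation, vertex
# presentation, spontaneous onset, admission dilatation <= 6 cm, vaginal
# birth, no prior uterine scar, no severe adverse outcome or malformation, and
# at least two cervical dilatation assessments during the first stage. Also
# provides the oxytocin sensitivity split and parity/admission stratification.

.exclusion_criteria <- c(
  "outside_term_window", "non_vertex_presentation", "induced_onset",
  "prior_uterine_scar", "intrapartum_cesarean", "adverse_outcome",
  "severe_malformation", "admission_above_6cm", "fewer_than_two_exams"
)

.required_columns <- c(
  "woman_id", "parity_group", "exam_time_h", "dilatation_cm", "oxytocin",
  "onset_type", "presentation", "gest_age_wk", "prior_scar", "mode_of_birth",
  "adverse_outcome", "full_dilatation_time_h"
)

#' Per-woman summary of a long cohort
#'
#' Collapses the long exam table to one row per woman, deriving the admission
#' dilatation (first exam), the number of first-stage assessments (exam rows
#' strictly before full dilatation) and carrying the covariates.
#'
#' @param cohort long cohort tibble.
#' @return one-row-per-woman tibble.
#' @export
woman_summary <- function(cohort) {
  missing_cols <- setdiff(.required_columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cohort |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(
      parity_group = dplyr::first(.data$parity_group),
      admission_dilatation = dplyr::first(.data$dilatation_cm),
      n_exams_first_stage = sum(.data$dilatation_cm < 10L),
      n_exams = dplyr::n(),
      oxytocin = dplyr::first(.data$oxytocin),
      onset_type = dplyr::first(.data$onset_type),
      presentation = dplyr::first(.data$presentation),
      gest_age_wk = dplyr::first(.data$gest_age_wk),
      prior_scar = dplyr::first(.data$prior_scar),
      mode_of_birth = dplyr::first(.data$mode_of_birth),
      adverse_outcome = dplyr::first(.data$adverse_outcome),
      full_dilatation_time_h = dplyr::first(.data$full_dilatation_time_h),
      .groups = "drop"
    )
}

# first failing criterion for each woman-summary row, or "included"
.first_failing <- function(ws, order = .exclusion_criteria) {
  need <- c("parity_group", "gest_age_wk", "presentation", "onset_type",
            "prior_scar", "mode_of_birth", "adverse_outcome", "oxytocin")
  na_mask <- Reduce(`|`, lapply(ws[need], is.na))
  if (any(na_mask)) {
    stop("records with missing required fields: ",
         paste(utils::head(ws$woman_id[na_mask], 5), collapse = ", "))
  }
  checks <- list(
    outside_term_window = ws$gest_age_wk < 37 | ws$gest_age_wk > 41 + 6 / 7,
    non_vertex_presentation = ws$presentation != "vertex",
    induced_onset = ws$onset_type != "spontaneous",
    prior_uterine_scar = as.logical(ws$prior_scar),
    intrapartum_cesarean = ws$mode_of_birth == "cesarean",
    adverse_outcome = ws$adverse_outcome %in% .adverse_flags,
    severe_malformation = ws$adverse_outcome == "severe_malformation",
    admission_above_6cm = ws$admission_dilatation > 6,
    fewer_than_two_exams = ws$n_exams_first_stage < 2
  )
  out <- rep("included", nrow(ws))
  for (crit in rev(order)) out[checks[[crit]]] <- crit
  out
}

#' Apply the sample-selection chain
#'
#' Keeps records with term gestation (37+0 to 41+6, both ends inclusive),
#' vertex presentation, spontaneous labour onset, admission dilatation
#' <= 6 cm, vaginal birth, no prior uterine scar, no severe adverse outcome or
#' severe congenital malformation, and at least two first-stage assessments.
#' Each excluded record is attributed to its first failing criterion in
#' `order`; the set of included records is order-invariant.
#'
#' @param cohort long cohort tibble.
#' @param order attribution order of the exclusion criteria (a permutation of
#'   the default).
#' @return a list with `cohort` (included records, long format) and
#'   `flow_counts` (class `flow_counts`: per-criterion excluded counts plus
#'   input and included totals).
#' @export
apply_inclusion <- function(cohort, order = .exclusion_criteria) {
  stopifnot(setequal(order, .exclusion_criteria))
  ws <- woman_summary(cohort)
  status <- .first_failing(ws, order)
  counts <- tibble::tibble(
    criterion = order,
    n_excluded = vapply(order, function(cr) sum(status == cr), 0L,
                        USE.NAMES = FALSE)
  )
  fc <- structure(list(
    n_input = nrow(ws),
    n_included = sum(status == "included"),
    exclusions = counts
  ), class = "flow_counts")
  stopifnot(fc$n_input == fc$n_included + sum(counts$n_excluded))
  included_ids <- ws$woman_id[status == "included"]
  list(
    cohort = dplyr::filter(cohort, .data$woman_id %in% included_ids),
    flow_counts = fc
  )
}

#' @export
print.flow_counts <- function(x, ...) {
  cat(sprintf("records assessed: %d\n", x$n_input))
  for (i in seq_len(nrow(x$exclusions))) {
    cat(sprintf("  excluded | %-24s %6d\n",
                x$exclusions$criterion[i], x$exclusions$n_excluded[i]))
  }
  cat(sprintf("records included: %d\n", x$n_included))
  invisible(x)
}

#' Serialise flow counts to JSON
#' @param x a `flow_counts` object.
#' @return a JSON string.
#' @export
flow_counts_json <- function(x) {
  stopifnot(inherits(x, "flow_counts"))
  jsonlite::toJSON(list(
    n_input = x$n_input, n_included = x$n_included,
    exclusions = setNames(as.list(x$exclusions$n_excluded),
                          x$exclusions$criterion)
  ), auto_unbox = TRUE, pretty = TRUE)
}

#' Drop women with oxytocin-augmented labours
#'
#' The sensitivity split: returns only records of women without oxytocin
#' augmentation. The input is not modified.
#'
#' @param cohort long cohort tibble with an `oxytocin` flag.
#' @return the non-augmented subset, same format.
#' @export
exclude_augmented <- function(cohort) {
  if (!"oxytocin" %in% names(cohort)) stop("cohort lacks an oxytocin flag")
  dplyr::filter(cohort, !.data$oxytocin)
}

#' Stratify a cohort
#'
#' Partitions the cohort by parity group and/or admission dilatation. The
#' union of the parts equals the input.
#'
#' @param cohort long cohort tibble.
#' @param keys subset of `c("parity_group", "admission_dilatation")`.
#' @return a named list of subcohorts.
#' @export
stratify <- function(cohort, keys = "parity_group") {
  allowed <- c("parity_group", "admission_dilatation")
  if (!length(keys) || !all(keys %in% allowed)) {
    stop("stratify keys must be a subset of: ", paste(allowed, collapse = ", "))
  }
  if (!nrow(cohort)) return(list())
  ws <- cohort |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(
      parity_group = dplyr::first(.data$parity_group),
      admission_dilatation = dplyr::first(.data$dilatation_cm),
      .groups = "drop"
    )
  key_df <- ws[, keys, drop = FALSE]
  label <- do.call(paste, c(
    lapply(keys, function(k) paste0(k, "=", key_df[[k]])), list(sep = "|")
  ))
  split_ids <- split(ws$woman_id, label)
  lapply(split_ids, function(ids) {
    dplyr::filter(cohort, .data$woman_id %in% ids)
  })
}
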