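#!/usr/bin/env Rscript
# Average labour curves from the three-parameter logistic growth mixed model
# on reverse-time-anchored exams, plus the partograph alert-line crossing
# fractions.

library(labourflow)

cohort <- read_cohort("results/cohort_included.csv")
strata <- stratify(cohort, "parity_group")

params <- list(); curves <- list()
for (st in names(strata)) {
  message("logistic growth fit for ", st)
  obs <- reverse_time(strata[[st]])
  fit <- fit_logistic_nlmm(obs)
  print(fit)
  params[[st]] <- tibble::tibble(
    parameter = names(fit$params), estimate = fit$params, se = fit$se,
    stratum = st,
    inflection_outside_range = fit$params[["beta2"]] < fit$t_range[1])
  cv <- average_curve_logistic(fit)
  cv$stratum <- st
  curves[[st]] <- cv
}
readr::write_csv(dplyr::bind_rows(params), "results/logistic_params.csv")
readr::write_csv(dplyr::bind_rows(curves), "results/logistic_curves.csv")

alert <- alert_line_crossing(cohort)
readr::write_csv(alert, "results/alert_line_crossing.csv")
message("alert-line crossing fractions: ",
        paste(sprintf("parity %s: %.1f%%", alert$parity_group,
                      100 * alert$fraction), collapse = ", "))
message("wrote results/logistic_*.csv and results/alert_line_crossing.csv")
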