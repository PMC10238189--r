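#' Default synthetic cohort rates
#'
#' Per-marker mean methylated copies per mL of plasma for cases and
#' controls. Control rates reflect the low-level biological background of
#' methylation in cancer-free individuals; case rates were calibrated once
#' so that the population AUC of the logistic four-marker panel score is
#' 0.86 under the generator's Poisson sampling at 0.1 mL plasma.
#'
#' @return A tibble `marker`, `case_rate`, `control_rate` (copies/mL).
#' @export
default_marker_params <- function() {
  tibble(marker = c("SOX17", "CDO1", "TAC1", "HOXA7"),
         case_rate = c(8.2, 6.76, 4.76, 6.76),
         control_rate = c(2, 2.5, 0.5, 2.5))
}

#' Simulate a clinical cohort of per-marker copy concentrations
#'
#' For each sample and marker the measured concentration is
#' `Poisson(rate * plasma_volume) / plasma_volume`: the assay counts whole
#' molecules in the plasma-equivalent volume it digitizes (0.1 mL by
#' default), so concentrations are quantized to multiples of
#' `1 / plasma_volume`. Optional covariates are drawn independently of the
#' label - age ~ N(65, 8) years, pack-years ~ N(40, 20) truncated at 0 -
#' emulating risk factors that carry no additional signal beyond the
#' markers.
#'
#' @param n_case,n_control Number of cancer and control samples (the study
#'   cohort shape is 39 + 33).
#' @param marker_params Tibble `marker`, `case_rate`, `control_rate` in
#'   copies/mL; default [default_marker_params()].
#' @param seed Integer seed; same seed, same cohort.
#' @param plasma_volume Digitized plasma-equivalent volume, mL.
#' @param covariates Add `age` and `pack_years` columns?
#' @return A tibble `sample_id`, `label` ("case"/"control"), one
#'   copies-per-mL column per marker, and optional covariates.
#' @examples
#' cohort <- simulate_cohort(39, 33, seed = 1)
#' dplyr::count(cohort, label)
#' @export
simulate_cohort <- function(n_case = 39, n_control = 33,
                            marker_params = default_marker_params(),
                            seed = NULL, plasma_volume = 0.1,
                            covariates = TRUE) {
  if (any(marker_params$case_rate < 0) || any(marker_params$control_rate < 0)) {
    abort("marker rates must be non-negative.", class = "dmspr_domain_error")
  }
  if (plasma_volume <= 0) {
    abort("plasma_volume must be positive.", class = "dmspr_domain_error")
  }
  gen <- function() {
    n <- n_case + n_control
    out <- tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      label = rep(c("case", "control"), c(n_case, n_control))
    )
    for (i in seq_len(nrow(marker_params))) {
      rate <- ifelse(out$label == "case",
                     marker_params$case_rate[i], marker_params$control_rate[i])
      out[[marker_params$marker[i]]] <-
        rpois(n, rate * plasma_volume) / plasma_volume
    }
    if (covariates) {
      out$age <- round(rnorm(n, 65, 8))
      out$pack_years <- round(pmax(rnorm(n, 40, 20), 0))
    }
    out
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), gen()) else gen()
}
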