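#' Poisson correction for multi-occupancy
#'
#' Digital PCR counts positive wells, not molecules; when loading is dense,
#' several molecules can share a well. Under Poisson loading the mean
#' occupancy per well is `lambda_hat = -ln(1 - k/N)` for `k` positive of
#' `N` wells, and the corrected molecule count is `lambda_hat * N`. The
#' correction never decreases the raw count and is strictly increasing
#' in `k`.
#'
#' @param positive_count Positive wells per measurement (vectorized).
#' @param n_wells Total wells interrogated.
#' @return A tibble with columns `positive_count`, `lambda_hat`,
#'   `corrected_copies`.
#' @examples
#' poisson_correct(100, 10040)
#' @export
poisson_correct <- function(positive_count, n_wells) {
  if (any(positive_count < 0) || any(positive_count != floor(positive_count))) {
    abort("positive_count must be a non-negative integer.", class = "dmspr_domain_error")
  }
  if (any(positive_count > n_wells)) {
    abort("positive_count exceeds the number of wells.", class = "dmspr_domain_error")
  }
  if (any(positive_count == n_wells)) {
    abort("all wells positive: the assay is saturated and the Poisson estimate is undefined.",
          class = "dmspr_saturation_error")
  }
  lambda <- -log1p(-positive_count / n_wells)
  tibble(positive_count = as.integer(positive_count),
         lambda_hat = lambda,
         corrected_copies = lambda * n_wells)
}

#' Convert corrected copies to copies per mL of plasma
#'
#' @param corrected_copies Molecules measured in wells.
#' @param plasma_equiv_volume Plasma volume the loaded sample corresponds
#'   to, mL (the assay digitizes bisulfite-treated cfDNA equivalent to
#'   0.1 mL of plasma by default).
#' @param retention_fraction Fraction of the prepared mix that was actually
#'   digitized; dividing by it scales well counts back to the full sample.
#' @return Copies per mL (vectorized).
#' @examples
#' copies_per_ml(10, 0.1, 0.5)  # 200
#' @export
copies_per_ml <- function(corrected_copies, plasma_equiv_volume = 0.1,
                          retention_fraction = 0.5) {
  if (plasma_equiv_volume <= 0) {
    abort("plasma_equiv_volume must be positive.", class = "dmspr_domain_error")
  }
  if (!(retention_fraction > 0 && retention_fraction <= 1)) {
    abort("retention_fraction must be in (0, 1].", class = "dmspr_domain_error")
  }
  corrected_copies / (plasma_equiv_volume * retention_fraction)
}

#' Absolute quantification of a call result
#'
#' Reports, per channel, the raw positive-well count, the Poisson-corrected
#' copy number and the retention-adjusted concentration, as separate columns
#' so any convention can be compared; the headline concentration is the
#' Poisson-corrected, retention-adjusted `copies_per_ml`.
#'
#' @param result A [call_wells()] result.
#' @param plasma_equiv_volume,retention_fraction See [copies_per_ml()].
#' @return A tibble `channel`, `positive_count`, `lambda_hat`,
#'   `corrected_copies`, `copies_per_ml`, `plasma_equiv_volume`,
#'   `retention_fraction_used`.
#' @export
quantify_calls <- function(result, plasma_equiv_volume = 0.1,
                           retention_fraction = 0.5) {
  stopifnot(inherits(result, "call_result"))
  pc <- poisson_correct(result$positive_count, result$n_wells)
  tibble(channel = names(result$positive_count),
         positive_count = pc$positive_count,
         lambda_hat = pc$lambda_hat,
         corrected_copies = pc$corrected_copies,
         copies_per_ml = copies_per_ml(pc$corrected_copies,
                                       plasma_equiv_volume, retention_fraction),
         plasma_equiv_volume = plasma_equiv_volume,
         retention_fraction_used = retention_fraction)
}

#' Standard-curve performance metrics
#'
#' Ordinary least-squares fit of detected versus expected copies over the
#' nonzero ladder points (untransformed counts, matching the linear axes a
#' copy-number ladder is plotted on), plus the dilution-series limits:
#' LOD is the smallest nominal copy number detected (> 0 positives) in at
#' least one replicate, LOQ the smallest detected in all replicates, and
#' analytical specificity is LOQ divided by the unmethylated background
#' copy number, in percent. The 0-copy point is excluded from the
#' regression and the limit search; it is the negative control and its
#' false-positive wells are reported separately.
#'
#' @param ladder_results Tibble with columns `nominal_copies`, `replicate`,
#'   `detected`, and optionally `channel` (metrics are then computed per
#'   channel).
#' @param background_copies Unmethylated background copies per reaction.
#' @return A tibble (one row, or one row per channel) with `slope`,
#'   `intercept`, `r_squared`, `lod`, `loq`, `analytical_specificity`
#'   (percent) and `blank_false_positives` (NA when no 0-copy point).
#' @export
standard_curve_metrics <- function(ladder_results, background_copies) {
  req <- c("nominal_copies", "replicate", "detected")
  if (!all(req %in% names(ladder_results))) {
    abort("ladder_results needs columns nominal_copies, replicate, detected.",
          class = "dmspr_schema_error")
  }
  if (background_copies <= 0) {
    abort("background_copies must be positive.", class = "dmspr_domain_error")
  }
  if ("channel" %in% names(ladder_results)) {
    return(dplyr::reframe(dplyr::group_by(ladder_results, .data$channel),
                          .one_curve(dplyr::pick(dplyr::everything()),
                                     background_copies)))
  }
  .one_curve(ladder_results, background_copies)
}

.one_curve <- function(df, background_copies) {
  nz <- df[df$nominal_copies > 0, ]
  if (dplyr::n_distinct(nz$nominal_copies) < 3) {
    abort("need >= 3 distinct nonzero ladder points.", class = "dmspr_domain_error")
  }
  if (all(nz$detected == 0)) {
    abort("no ladder point was detected; the curve is undefined.",
          class = "dmspr_undefined_curve_error")
  }
  fit <- lm(detected ~ nominal_copies, data = nz)
  # computed from the sums of squares directly: summary.lm warns on an
  # exact fit, which is a legitimate outcome for an ideal ladder
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((nz$detected - mean(nz$detected))^2)
  r2 <- 1 - ss_res / ss_tot
  per_point <- dplyr::summarise(dplyr::group_by(nz, .data$nominal_copies),
                                any_det = any(.data$detected > 0),
                                all_det = all(.data$detected > 0))
  lod <- suppressWarnings(min(per_point$nominal_copies[per_point$any_det]))
  loq <- suppressWarnings(min(per_point$nominal_copies[per_point$all_det]))
  if (!is.finite(lod)) lod <- NA_real_
  if (!is.finite(loq)) loq <- NA_real_
  blank <- df[df$nominal_copies == 0, ]
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, lod = lod, loq = loq,
         analytical_specificity = if (is.na(loq)) NA_real_ else loq / background_copies * 100,
         blank_false_positives = if (nrow(blank)) sum(blank$detected) else NA_integer_)
}

#' Plot a standard curve with its linear fit
#'
#' @param ladder_results As in [standard_curve_metrics()].
#' @return A ggplot of detected vs expected copies, one panel per channel
#'   when a `channel` column is present.
#' @export
plot_standard_curve <- function(ladder_results) {
  p <- ggplot2::ggplot(ladder_results,
                       ggplot2::aes(x = .data$nominal_copies, y = .data$detected)) +
    ggplot2::geom_smooth(data = function(d) d[d$nominal_copies > 0, ],
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "expected copies", y = "detected copies")
  if ("channel" %in% names(ladder_results)) {
    p <- p + ggplot2::facet_wrap(~channel)
  }
  p
}
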