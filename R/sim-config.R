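#' Simulation configuration for the chip and cohort generators
#'
#' Collects every physical and optical parameter of the synthetic-data
#' generator. Defaults emulate the production assay: roughly half the master
#' mix ends up digitized in wells (`retention_fraction = 0.5`), essentially
#' every loaded template amplifies (`amplification_probability = 1`), the
#' four dyes have minimal spectral overlap (identity `crosstalk_matrix`),
#' and the negative/positive intensity populations are separated by well
#' over ten negative standard deviations so digital calling is unambiguous.
#'
#' Imaging defaults are rendering choices, not measurements: 20 um/pixel
#' scanner sampling (6-pixel well pitch at the default layout), 500 ADU
#' constant background, negative wells ~ N(1000, 60) ADU, positive wells
#' ~ N(12000, 800) ADU, a 1-pixel Gaussian point-spread function and 30 ADU
#' read noise on a 16-bit range.
#'
#' @param seed Integer seed; when non-NULL every simulation routine that
#'   receives this config produces bit-identical output for the same inputs.
#' @param retention_fraction Fraction of prepared molecules that end up in
#'   wells, in (0, 1].
#' @param amplification_probability Per-molecule probability of successful
#'   amplification, in (0, 1].
#' @param exact_copies If `TRUE`, integer nominal copy numbers are loaded
#'   exactly (counted spiked molecules); if `FALSE` (default) the realized
#'   molecule number is Poisson with the nominal mean, which models serial
#'   dilution and supports fractional nominals such as 6.25.
#' @param false_amplification_rate Per-well probability that an empty well
#'   amplifies anyway (methylation-specific primers make this 0 by default;
#'   raise it for robustness testing).
#' @param channels Channel (fluorophore) names, in imaging order.
#' @param negative_mean,negative_sd Intensity distribution (ADU) of wells
#'   without an amplified template.
#' @param positive_mean,positive_sd Intensity distribution (ADU) of wells
#'   with at least one amplified template.
#' @param psf_sigma Gaussian point-spread sigma in pixels (0 disables blur).
#' @param read_noise_sd Per-pixel Gaussian read noise, ADU.
#' @param background_level Constant background, ADU.
#' @param crosstalk_matrix Channels x channels linear mixing matrix; unit
#'   diagonal, off-diagonal entries between 0 and 0.05.
#' @param pixel_size_um Scanner sampling used by the default rendering map,
#'   micrometres per pixel.
#' @param margin_px Blank border around the rendered module, pixels.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       retention_fraction = 0.5,
                       amplification_probability = 1,
                       exact_copies = FALSE,
                       false_amplification_rate = 0,
                       channels = c("FAM", "HEX", "TexasRed", "Cy5"),
                       negative_mean = 1000, negative_sd = 60,
                       positive_mean = 12000, positive_sd = 800,
                       psf_sigma = 1, read_noise_sd = 30,
                       background_level = 500,
                       crosstalk_matrix = diag(length(channels)),
                       pixel_size_um = 20, margin_px = 18) {
  if (!(retention_fraction > 0 && retention_fraction <= 1)) {
    abort("retention_fraction must be in (0, 1].", class = "dmspr_domain_error")
  }
  if (!(amplification_probability > 0 && amplification_probability <= 1)) {
    abort("amplification_probability must be in (0, 1].", class = "dmspr_domain_error")
  }
  if (!(false_amplification_rate >= 0 && false_amplification_rate < 1)) {
    abort("false_amplification_rate must be in [0, 1).", class = "dmspr_domain_error")
  }
  k <- length(channels)
  crosstalk_matrix <- as.matrix(crosstalk_matrix)
  if (!all(dim(crosstalk_matrix) == c(k, k)) ||
      any(abs(diag(crosstalk_matrix) - 1) > 1e-12)) {
    abort("crosstalk_matrix must be channels x channels with unit diagonal.",
          class = "dmspr_domain_error")
  }
  off <- crosstalk_matrix[row(crosstalk_matrix) != col(crosstalk_matrix)]
  if (any(off < 0 | off > 0.05)) {
    abort("off-diagonal crosstalk must lie in [0, 0.05].", class = "dmspr_domain_error")
  }
  if (positive_mean <= negative_mean + 10 * negative_sd) {
    warn("positive and negative populations are separated by < 10 negative SDs; digital calling may be ambiguous.")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(
    seed = seed, retention_fraction = retention_fraction,
    amplification_probability = amplification_probability,
    exact_copies = isTRUE(exact_copies),
    false_amplification_rate = false_amplification_rate,
    channels = channels,
    negative_mean = negative_mean, negative_sd = negative_sd,
    positive_mean = positive_mean, positive_sd = positive_sd,
    psf_sigma = psf_sigma, read_noise_sd = read_noise_sd,
    background_level = background_level,
    crosstalk_matrix = crosstalk_matrix,
    pixel_size_um = pixel_size_um, margin_px = margin_px
  ), class = "sim_config")
}

# Run `expr` under the config seed when set, leaving the global RNG untouched;
# otherwise use the ambient RNG stream.
.with_config_seed <- function(config, expr) {
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, expr)
  } else {
    expr
  }
}
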