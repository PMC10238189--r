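#' Mean relative methylation (mean 2^-deltaCt) for bulk MethyLight
#'
#' The bulk comparator statistic: each of the three target Ct replicates is
#' compared against the mean reference-gene Ct, and the per-replicate
#' relative levels are averaged,
#' \deqn{\overline{2^{-\Delta Ct}} = (2^{-\Delta Ct_1} + 2^{-\Delta Ct_2} +
#'   2^{-\Delta Ct_3}) / 3.}
#' A replicate with no detected methylation is assigned Ct = 100, which
#' contributes a close-to-zero value rather than a missing one and so
#' reduces measurement bias at the very low methylation levels typical of
#' plasma cfDNA. Undetected replicates may be encoded as `NA`, `"ND"` or an
#' empty string.
#'
#' @param data A data frame with three replicate Ct columns and a reference
#'   column.
#' @param ct_cols Names of the three target-replicate Ct columns.
#' @param ref_col Name of the mean reference Ct column.
#' @return `data` as a tibble with an added `mean_2dct` column.
#' @examples
#' df <- tibble::tibble(sample_id = "s1", ct1 = 29, ct2 = 31, ct3 = "ND",
#'                      ref_mean_ct = 30)
#' mean_relative_methylation(df)
#' @export
mean_relative_methylation <- function(data, ct_cols = c("ct1", "ct2", "ct3"),
                                      ref_col = "ref_mean_ct") {
  if (length(ct_cols) != 3) {
    abort("exactly 3 replicate Ct columns are required.", class = "dmspr_schema_error")
  }
  if (!all(c(ct_cols, ref_col) %in% names(data))) {
    abort("missing Ct or reference columns.", class = "dmspr_schema_error")
  }
  cts <- vapply(ct_cols, function(cc) .parse_ct(data[[cc]]), numeric(nrow(data)))
  cts <- matrix(cts, nrow = nrow(data))
  ref <- as.numeric(data[[ref_col]])
  if (any(!is.finite(ref))) {
    abort("reference mean Ct must be detected and finite for every row.",
          class = "dmspr_domain_error")
  }
  detected <- is.finite(cts)
  if (any(cts[detected] <= 0) || any(cts[detected] >= 100)) {
    abort("detected Ct values must lie in (0, 100).", class = "dmspr_domain_error")
  }
  cts[!detected] <- 100
  rel <- 2^(-(cts - ref))  # per-replicate 2^-deltaCt
  out <- as_tibble(data)
  out$mean_2dct <- rowMeans(rel)
  out
}

.parse_ct <- function(v) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- trimws(as.character(v))
  v[v %in% c("", "ND", "nd", "NA")] <- NA
  suppressWarnings(as.numeric(v))
}

#' Scalar form of the mean 2^-deltaCt statistic
#'
#' @param target_cts Three target Ct values; `NA` marks an undetected
#'   replicate (assigned Ct = 100).
#' @param reference_mean_ct Mean reference-gene Ct.
#' @return The mean 2^-deltaCt.
#' @export
methylight_mean2dct <- function(target_cts, reference_mean_ct) {
  if (length(target_cts) != 3) {
    abort("exactly 3 target Ct replicates are required.", class = "dmspr_schema_error")
  }
  df <- tibble(ct1 = target_cts[1], ct2 = target_cts[2], ct3 = target_cts[3],
               ref_mean_ct = reference_mean_ct)
  mean_relative_methylation(df)$mean_2dct
}
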