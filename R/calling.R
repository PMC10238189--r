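#' Fit a two-population mixture to a channel's intensity values
#'
#' Expectation-maximization fit of a two-component Gaussian location-scale
#' mixture to per-well fluorescence intensities, the digital-PCR analogue of
#' fitting the intensity histogram with negative and positive populations.
#' Components are returned sorted by mean so the first is always the
#' negative population. Initialization is deterministic from data quantiles
#' (negative at the 10th percentile, positive at the 99.9th, both with the
#' sample MAD as scale), so the same input always yields the same fit.
#'
#' For samples larger than `bin_threshold` values the EM operates on a
#' `n_bins`-bin histogram (weighted EM over bin centers), which is
#' numerically indistinguishable at fine binning and keeps multi-million
#' well fits fast.
#'
#' Because the positive-component weight `w` equals the Poisson loading
#' probability `1 - exp(-lambda)` with lambda free, the Poisson-tied
#' parameterization coincides with the free-weight fit; the implied loading
#' is reported as `lambda_load` by [glance()].
#'
#' Degenerate samples: when the fitted positive mean lies below the
#' negative component's own five-sigma limit the two components are not a
#' digital signal but structure within a single population; the fit then
#' collapses to one population (`positive_weight = 0`, negative component =
#' moments of the whole sample, `collapsed = TRUE`).
#'
#' @param intensities Numeric vector of per-well intensities (>= 100 values).
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param sd_floor Lower bound applied to component standard deviations.
#' @param bin_threshold Sample size above which the histogram path is used.
#' @param n_bins Histogram resolution for the binned path.
#' @return An object of class `mixture_fit` with fields `negative_mean`,
#'   `negative_sd`, `positive_mean`, `positive_sd`, `positive_weight`,
#'   `converged`, `n_iterations`, `log_likelihood`, `collapsed`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(9800, 1000, 60), rnorm(240, 12000, 800))
#' fit <- fit_intensity_mixture(x)
#' glance(fit)
#' five_sigma_threshold(fit)
#' @export
fit_intensity_mixture <- function(intensities, max_iter = 500, tol = 1e-8,
                                  sd_floor = 1e-6, bin_threshold = 1e5,
                                  n_bins = 4096) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  if (length(x) < 100) {
    abort("need at least 100 intensity values to fit the mixture.",
          class = "dmspr_sample_size_error")
  }
  if (diff(range(x)) == 0) {
    abort("all intensity values are identical; mixture is undefined.",
          class = "dmspr_degenerate_data_error")
  }
  n_raw <- length(x)
  if (n_raw > bin_threshold) {
    br <- seq(min(x), max(x), length.out = n_bins + 1)
    ct <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
    mid <- (br[-1] + br[-(n_bins + 1)]) / 2
    keep <- ct > 0
    xs <- mid[keep]; wts <- as.numeric(ct[keep])
  } else {
    xs <- x; wts <- rep(1, n_raw)
  }
  fit <- .em_two_gaussian(xs, wts, max_iter, tol, sd_floor)
  # order components by mean
  if (fit$mu[1] > fit$mu[2]) {
    fit$mu <- rev(fit$mu); fit$s <- rev(fit$s); fit$w <- rev(fit$w)
  }
  collapsed <- (fit$mu[2] - fit$mu[1]) < 5 * fit$s[1]
  if (collapsed) {
    n <- sum(wts)
    m <- sum(wts * xs) / n
    s <- sqrt(sum(wts * (xs - m)^2) / n)
    out <- list(negative_mean = m, negative_sd = max(s, sd_floor),
                positive_mean = fit$mu[2], positive_sd = max(fit$s[2], sd_floor),
                positive_weight = 0)
  } else {
    out <- list(negative_mean = fit$mu[1], negative_sd = max(fit$s[1], sd_floor),
                positive_mean = fit$mu[2], positive_sd = max(fit$s[2], sd_floor),
                positive_weight = fit$w[2])
  }
  structure(c(out, list(converged = fit$converged, n_iterations = fit$iter,
                        log_likelihood = fit$ll, collapsed = collapsed,
                        n = n_raw, sd_floor = sd_floor)),
            class = "mixture_fit")
}

# weighted two-component Gaussian EM; deterministic quantile init
.em_two_gaussian <- function(xs, wts, max_iter, tol, sd_floor) {
  n <- sum(wts)
  ord <- order(xs)
  cw <- cumsum(wts[ord]) / n
  qat <- function(p) xs[ord][which(cw >= p)[1]]
  mu <- c(qat(0.10), qat(0.999))
  m0 <- sum(wts * xs) / n
  s0 <- sqrt(sum(wts * (xs - m0)^2) / n)
  med <- qat(0.5)
  madw <- {
    dev <- abs(xs - med)
    o2 <- order(dev); cw2 <- cumsum(wts[o2]) / n
    1.4826 * dev[o2][which(cw2 >= 0.5)[1]]
  }
  s <- rep(max(madw, s0 / 10, sd_floor), 2)
  w <- c(0.99, 0.01)
  if (mu[2] <= mu[1]) mu[2] <- mu[1] + 3 * s[1]
  ll0 <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(xs, mu[1], s[1])
    d2 <- w[2] * dnorm(xs, mu[2], s[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(wts * log(tot))
    if (abs(ll - ll0) < tol) { converged <- TRUE; break }
    ll0 <- ll
    n2 <- sum(wts * r2); n1 <- n - n2
    if (n2 < 1e-12 || n1 < 1e-12) break  # one component vanished
    mu_new <- c(sum(wts * (1 - r2) * xs) / n1, sum(wts * r2 * xs) / n2)
    s_new <- c(sqrt(sum(wts * (1 - r2) * (xs - mu_new[1])^2) / n1),
               sqrt(sum(wts * r2 * (xs - mu_new[2])^2) / n2))
    mu <- mu_new
    s <- pmax(s_new, sd_floor)
    w <- c(n1, n2) / n
  }
  list(mu = mu, s = s, w = w, ll = ll, iter = it, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> n = %d%s\n", x$n,
              if (x$collapsed) " (collapsed to a single population)" else ""))
  cat(sprintf("  negative: mean %.4g, sd %.4g  |  positive: mean %.4g, sd %.4g, weight %.3g\n",
              x$negative_mean, x$negative_sd, x$positive_mean, x$positive_sd,
              x$positive_weight))
  cat(sprintf("  %s after %d iteration(s); five-sigma threshold %.4g\n",
              if (x$converged) "converged" else "NOT converged", x$n_iterations,
              five_sigma_threshold(x)))
  invisible(x)
}

#' @method tidy mixture_fit
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble(component = c("negative", "positive"),
         mean = c(x$negative_mean, x$positive_mean),
         sd = c(x$negative_sd, x$positive_sd),
         weight = c(1 - x$positive_weight, x$positive_weight))
}

#' @method glance mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(negative_mean = x$negative_mean, negative_sd = x$negative_sd,
         positive_mean = x$positive_mean, positive_sd = x$positive_sd,
         positive_weight = x$positive_weight,
         lambda_load = -log1p(-min(x$positive_weight, 1 - 1e-15)),
         threshold = five_sigma_threshold(x),
         converged = x$converged, n_iterations = x$n_iterations,
         log_likelihood = x$log_likelihood, collapsed = x$collapsed, n = x$n)
}

#' Five-sigma positivity threshold of a mixture fit
#'
#' The calling threshold is the negative-population mean plus five of its
#' standard deviations, corresponding to an allowance of roughly one
#' false-positive observation per million nanowell measurements under a
#' Gaussian negative population (upper-tail mass ~ 2.87e-7).
#'
#' @param fit A `mixture_fit`.
#' @return Threshold in ADU. When the negative SD sits at the configured
#'   floor a warning is attached (`attr(, "warning")`) and emitted.
#' @export
five_sigma_threshold <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  thr <- fit$negative_mean + 5 * fit$negative_sd
  if (fit$negative_sd <= fit$sd_floor) {
    msg <- "negative SD is at the epsilon floor; threshold is degenerate."
    warn(msg)
    attr(thr, "warning") <- msg
  }
  thr
}

#' Fit per-channel mixtures for a well-intensity table
#'
#' @param table A well-intensity tibble from [extract_well_intensities()].
#' @param channels Channel columns to fit; default every non-identity column.
#' @param ... Passed to [fit_intensity_mixture()].
#' @return Named list of `mixture_fit`, one per channel.
#' @export
fit_channel_mixtures <- function(table, channels = NULL, ...) {
  channels <- channels %||% .channel_cols(table)
  fits <- lapply(channels, function(ch) fit_intensity_mixture(table[[ch]], ...))
  names(fits) <- channels
  fits
}

.id_cols <- c("module", "well_index", "row", "col", "x_um", "y_um",
              "x_px", "y_px", "aperture_pixels")

.channel_cols <- function(table) setdiff(names(table), .id_cols)

#' Call positive wells at the five-sigma threshold
#'
#' A well is positive in a channel when its mean intensity is strictly
#' greater than that channel's five-sigma threshold; ties at the threshold
#' are negative (conservative false-positive control).
#'
#' @param table A well-intensity tibble from [extract_well_intensities()].
#' @param fits Named list of per-channel `mixture_fit` objects (names must
#'   match the table's channel columns), e.g. from [fit_channel_mixtures()].
#' @return An object of class `call_result`: the per-well call tibble
#'   (`$calls`, original rows plus one logical column per channel), the
#'   fits, thresholds and per-channel positive counts. [tidy()] returns the
#'   per-channel summary; [glance()] the totals.
#' @export
call_wells <- function(table, fits) {
  channels <- .channel_cols(table)
  if (!setequal(channels, names(fits))) {
    abort(sprintf("channel mismatch: table has [%s], fits have [%s].",
                  paste(channels, collapse = ", "),
                  paste(names(fits), collapse = ", ")),
          class = "dmspr_schema_error")
  }
  thresholds <- vapply(fits[channels], function(f)
    as.numeric(five_sigma_threshold(f)), numeric(1))
  calls <- table[intersect(.id_cols, names(table))]
  for (ch in channels) calls[[ch]] <- table[[ch]] > thresholds[[ch]]
  positive_count <- vapply(channels, function(ch) sum(calls[[ch]]), integer(1))
  structure(list(calls = as_tibble(calls), fits = fits[channels],
                 thresholds = thresholds, positive_count = positive_count,
                 n_wells = nrow(table)),
            class = "call_result")
}

#' @export
print.call_result <- function(x, ...) {
  cat(sprintf("<call_result> %d wells, %d channel(s)\n", x$n_wells,
              length(x$thresholds)))
  print(tidy(x))
  invisible(x)
}

#' @method tidy call_result
#' @export
tidy.call_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(channel = names(x$thresholds)),
    dplyr::bind_rows(lapply(x$fits, function(f) glance(f)[1:5])),
    tibble(threshold = as.numeric(x$thresholds),
           positive_count = as.integer(x$positive_count))
  )
}

#' @method glance call_result
#' @export
glance.call_result <- function(x, ...) {
  tibble(n_wells = x$n_wells, n_channels = length(x$thresholds),
         total_positive = sum(x$positive_count))
}

#' Histogram of a fitted channel with components and threshold
#'
#' @param object A `mixture_fit`.
#' @param intensities The intensity vector the fit was computed from.
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, intensities, bins = 200, ...) {
  df <- tibble(intensity = as.numeric(intensities))
  thr <- as.numeric(five_sigma_threshold(object))
  grid <- tibble(x = seq(min(df$intensity), max(df$intensity), length.out = 512))
  dens <- dplyr::bind_rows(
    dplyr::mutate(grid, component = "negative",
                  d = (1 - object$positive_weight) *
                    dnorm(.data$x, object$negative_mean, object$negative_sd)),
    dplyr::mutate(grid, component = "positive",
                  d = object$positive_weight *
                    dnorm(.data$x, object$positive_mean, object$positive_sd)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = NA) +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$d,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "well mean intensity (ADU)", y = "density",
                  title = sprintf("five-sigma threshold at %.0f ADU", thr))
}
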