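#' Partition template molecules into the wells of one module
#'
#' The realized molecule number is `M ~ Poisson(n_copies)` (serial dilution;
#' fractional nominals such as 6.25 are meaningful), or exactly
#' `round(n_copies)` when `config$exact_copies` is set. Each molecule is
#' retained with probability `config$retention_fraction` (the rest stays in
#' the feed channels) and retained molecules land uniformly at random in the
#' module's wells.
#'
#' Uses the ambient RNG stream: seed control belongs to the calling
#' simulation routine (see [sim_config()]).
#'
#' @param n_copies Nominal mean copy number loaded (non-negative).
#' @param layout An [build_layout()] object.
#' @param module_id Target module.
#' @param config A [sim_config()].
#' @return Integer vector of per-well molecule counts, length
#'   `layout$wells_per_module`, in [layout_wells()] order.
#' @export
partition_molecules <- function(n_copies, layout, module_id = 1L,
                                config = sim_config()) {
  stopifnot(inherits(layout, "array_layout"))
  if (!is.numeric(n_copies) || length(n_copies) != 1L || n_copies < 0) {
    abort("n_copies must be a single non-negative number.", class = "dmspr_domain_error")
  }
  if (module_id < 1L || module_id > layout$n_modules) {
    abort("module_id outside the layout.", class = "dmspr_domain_error")
  }
  n_wells <- layout$wells_per_module
  m <- if (config$exact_copies) as.integer(round(n_copies)) else rpois(1L, n_copies)
  retained <- if (config$retention_fraction < 1) {
    rbinom(1L, m, config$retention_fraction)
  } else m
  counts <- integer(n_wells)
  if (retained > 0L) {
    hit <- sample.int(n_wells, retained, replace = TRUE)
    counts <- tabulate(hit, nbins = n_wells)
  }
  as.integer(counts)
}

#' Amplified state of wells given molecule counts
#'
#' Each molecule amplifies independently with
#' `config$amplification_probability`; a well is positive when at least one
#' of its molecules amplifies. Empty wells may fire spuriously at
#' `config$false_amplification_rate` (0 by default: methylation-specific
#' primers do not amplify the unmethylated background).
#'
#' @param counts Integer per-well molecule counts.
#' @param config A [sim_config()].
#' @return Logical vector of per-well amplified states.
#' @export
amplify_wells <- function(counts, config = sim_config()) {
  n <- length(counts)
  amp <- rbinom(n, counts, config$amplification_probability) > 0L
  if (config$false_amplification_rate > 0) {
    amp <- amp | (runif(n) < config$false_amplification_rate)
  }
  amp
}

#' Default rendering map for a simulated module
#'
#' A similarity homography taking layout-plane micrometres to pixels at
#' `config$pixel_size_um` per pixel with a `config$margin_px` border.
#'
#' @inheritParams partition_molecules
#' @return A `geometry_map`.
#' @export
default_geometry_map <- function(layout, module_id = 1L, config = sim_config()) {
  s <- 1 / config$pixel_size_um
  H <- matrix(c(s, 0, config$margin_px,
                0, s, config$margin_px,
                0, 0, 1), 3, 3, byrow = TRUE)
  structure(list(homography = .normalize_homography(H),
                 module_id = as.integer(module_id)),
            class = "geometry_map")
}

#' Render a multi-channel fluorescence image of one module
#'
#' Each well is drawn as a disk of `layout$well_diameter` at its mapped
#' center; the disk amplitude (above background) is one draw from the
#' positive or negative intensity distribution according to the well's
#' amplified state in that channel. The plane is then blurred with a
#' Gaussian PSF, offset by the constant background, degraded with per-pixel
#' Gaussian read noise, mixed across channels by the crosstalk matrix, and
#' finally rounded and clipped to the 16-bit range.
#'
#' @param layout An [build_layout()] object.
#' @param map A `geometry_map` for the module being rendered.
#' @param amplified_state Logical matrix, wells x channels (column names are
#'   taken as channel names; otherwise `config$channels` is used).
#' @param config A [sim_config()].
#' @param image_dim Optional `c(height, width)` in pixels; default is sized
#'   from the mapped well positions plus the configured margin.
#' @return A named list of integer matrices (one per channel) of class
#'   `chip_image`.
#' @export
render_image <- function(layout, map, amplified_state, config = sim_config(),
                         image_dim = NULL) {
  stopifnot(inherits(layout, "array_layout"), inherits(map, "geometry_map"))
  amplified_state <- as.matrix(amplified_state)
  n_wells <- layout$wells_per_module
  if (nrow(amplified_state) != n_wells) {
    abort("amplified_state must have one row per well.", class = "dmspr_domain_error")
  }
  channels <- colnames(amplified_state) %||% config$channels[seq_len(ncol(amplified_state))]
  centers <- well_centers(map, layout)
  # local pixel radius of each well disk under the map
  r_right <- .apply_homography(map$homography,
                               cbind(centers$x_um + layout$well_diameter / 2, centers$y_um))
  r_down <- .apply_homography(map$homography,
                              cbind(centers$x_um, centers$y_um + layout$well_diameter / 2))
  rad <- (sqrt((r_right[, 1] - centers$x_px)^2 + (r_right[, 2] - centers$y_px)^2) +
          sqrt((r_down[, 1] - centers$x_px)^2 + (r_down[, 2] - centers$y_px)^2)) / 2
  if (is.null(image_dim)) {
    image_dim <- c(ceiling(max(centers$y_px) + config$margin_px) + 1,
                   ceiling(max(centers$x_px) + config$margin_px) + 1)
  }
  h <- image_dim[1]; w <- image_dim[2]
  out_of_frame <- which(centers$x_px - rad < 0 | centers$x_px + rad > w - 1 |
                        centers$y_px - rad < 0 | centers$y_px + rad > h - 1)
  if (length(out_of_frame) > 0) {
    abort(sprintf("%d well(s) map outside the %d x %d image (first: %s).",
                  length(out_of_frame), h, w,
                  paste(head(out_of_frame, 5), collapse = ", ")),
          class = "dmspr_out_of_frame_error")
  }
  disk <- .disk_pixels(centers$x_px, centers$y_px, rad)
  planes <- .with_config_seed(config, {
    raw <- lapply(seq_along(channels), function(ci) {
      amp <- ifelse(amplified_state[, ci],
                    rnorm(n_wells, config$positive_mean, config$positive_sd),
                    rnorm(n_wells, config$negative_mean, config$negative_sd))
      img <- matrix(0, h, w)
      img[cbind(disk$py + 1L, disk$px + 1L)] <- amp[disk$well]
      if (config$psf_sigma > 0) img <- EBImage::gblur(img, sigma = config$psf_sigma)
      img <- img + config$background_level
      if (config$read_noise_sd > 0) img <- img + rnorm(h * w, 0, config$read_noise_sd)
      img
    })
    X <- config$crosstalk_matrix[seq_along(channels), seq_along(channels), drop = FALSE]
    mixed <- lapply(seq_along(channels), function(ci) {
      acc <- matrix(0, h, w)
      for (k in seq_along(channels)) if (X[ci, k] != 0) acc <- acc + X[ci, k] * raw[[k]]
      acc
    })
    lapply(mixed, function(img) {
      storage.mode(img) <- "double"
      matrix(as.integer(pmin(pmax(round(img), 0), 65535)), h, w)
    })
  })
  names(planes) <- channels
  structure(planes, class = "chip_image")
}

# pixel-center-in-disk stencil, vectorized over wells (0-based pixel coords)
.disk_pixels <- function(cx, cy, rad) {
  rmax <- ceiling(max(rad))
  offs <- expand.grid(dx = -rmax:rmax, dy = -rmax:rmax)
  n <- length(cx); k <- nrow(offs)
  well <- rep(seq_len(n), each = k)
  px <- round(cx)[well] + offs$dx
  py <- round(cy)[well] + offs$dy
  keep <- (px - cx[well])^2 + (py - cy[well])^2 <= rad[well]^2
  list(well = well[keep], px = as.integer(px[keep]), py = as.integer(py[keep]))
}

#' @export
print.chip_image <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<chip_image> %d channel(s) [%s], %d x %d px, 16-bit\n",
              length(x), paste(names(x), collapse = ", "), d[1], d[2]))
  invisible(x)
}

#' Simulate a full digital standard curve
#'
#' For each nominal copy number on the ladder and each replicate, all
#' channels are partitioned independently at the same nominal copies
#' (co-spiked targets), a module image is rendered, and per-well intensities
#' are extracted with the mapped mask. The unmethylated background copies
#' are carried as metadata; they never amplify in the digital channels
#' (methylation-specific primers).
#'
#' @param copies_ladder Non-negative nominal copy numbers.
#' @param replicates Replicates per ladder point.
#' @param background_copies Unmethylated background copies per reaction.
#' @param layout An [build_layout()] object.
#' @param config A [sim_config()]; its `seed` (when set) makes the whole
#'   curve reproducible.
#' @return A tibble with one row per (nominal_copies, replicate), list
#'   columns `truth` (per-channel loaded/retained/amplified-well counts) and
#'   `wells` (the extracted intensity table), and attribute
#'   `background_copies`.
#' @export
simulate_standard_curve <- function(copies_ladder, replicates = 2,
                                    background_copies = 200000,
                                    layout = build_layout(),
                                    config = sim_config()) {
  if (length(copies_ladder) == 0) {
    abort("copies_ladder must be non-empty.", class = "dmspr_domain_error")
  }
  if (any(copies_ladder < 0)) {
    abort("copies_ladder must be non-negative.", class = "dmspr_domain_error")
  }
  if (replicates < 1) abort("replicates must be >= 1.", class = "dmspr_domain_error")
  map <- default_geometry_map(layout, 1L, config)
  grid <- tidyr::expand_grid(nominal_copies = copies_ladder,
                             replicate = seq_len(replicates))
  inner <- config
  inner$seed <- NULL  # one seed governs the whole curve, set here
  run_one <- function(nominal) {
    counts <- sapply(config$channels, function(ch)
      partition_molecules(nominal, layout, map$module_id, inner))
    amp <- apply(counts, 2, amplify_wells, config = inner)
    img <- render_image(layout, map, amp, inner)
    wells <- extract_well_intensities(img, map, layout)
    truth <- tibble(
      channel = config$channels,
      nominal_copies = nominal,
      molecules_loaded = colSums(counts),
      amplified_wells = colSums(amp),
      background_copies = background_copies
    )
    list(truth = truth, wells = wells)
  }
  res <- .with_config_seed(config, lapply(grid$nominal_copies, run_one))
  out <- dplyr::mutate(grid,
                       truth = lapply(res, `[[`, "truth"),
                       wells = lapply(res, `[[`, "wells"))
  attr(out, "background_copies") <- background_copies
  attr(out, "config") <- config
  out
}

#' Run calling and quantification over a simulated standard curve
#'
#' Convenience wrapper: fits the per-channel mixture on every simulated
#' dataset, calls wells at the five-sigma threshold, and returns detected
#' counts in the long format expected by [standard_curve_metrics()].
#'
#' @param curve Output of [simulate_standard_curve()].
#' @return A tibble with columns `nominal_copies`, `replicate`, `channel`,
#'   `detected` (positive wells), `lambda_hat` and `corrected_copies`.
#' @export
call_standard_curve <- function(curve) {
  n_wells <- nrow(curve$wells[[1]])
  purrr::pmap_dfr(curve, function(nominal_copies, replicate, truth, wells) {
    res <- call_wells(wells, fit_channel_mixtures(wells))
    counts <- tidy(res)
    pc <- poisson_correct(counts$positive_count, n_wells)
    tibble(nominal_copies = nominal_copies, replicate = replicate,
           channel = counts$channel, detected = counts$positive_count,
           lambda_hat = pc$lambda_hat, corrected_copies = pc$corrected_copies)
  })
}

#' Simulate a limit-of-quantification dilution series
#'
#' Low-copy dilution series used to read off LOD/LOQ: integer copy numbers
#' are loaded exactly (counted spiked molecules), partitioned, amplified and
#' called through the full image pipeline.
#'
#' @param copies Integer copy numbers of the series.
#' @param replicates Replicates per copy number.
#' @param layout,config As in [simulate_standard_curve()]; `exact_copies`,
#'   full retention and perfect amplification are the conditions under which
#'   a single loaded molecule is always seen, so those are the defaults here.
#' @return A tibble `nominal_copies`, `replicate`, `detected`.
#' @export
simulate_loq_series <- function(copies = c(1, 2, 5, 10), replicates = 10,
                                layout = build_layout(),
                                config = sim_config(retention_fraction = 1,
                                                    amplification_probability = 1,
                                                    exact_copies = TRUE)) {
  curve <- simulate_standard_curve(copies, replicates,
                                   background_copies = 200000,
                                   layout = layout, config = config)
  calls <- call_standard_curve(curve)
  dplyr::select(calls, "nominal_copies", "replicate", "channel", "detected")
}
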