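#' Write and read multi-channel chip images
#'
#' Images are stored as multi-page 16-bit grayscale TIFF, one page per
#' channel in imaging order. Channel names are recorded in a JSON sidecar
#' (`<path>.channels.json`); when the sidecar is missing, channels are named
#' `ch1..chN` with a warning.
#'
#' @param image A `chip_image` (named list of integer matrices).
#' @param path TIFF file path.
#' @return `write_chip_image` returns `path` invisibly; `read_chip_image`
#'   returns a `chip_image`.
#' @export
write_chip_image <- function(image, path) {
  planes <- lapply(image, function(p) {
    m <- p / 65535
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "deflate")
  jsonlite::write_json(names(image), paste0(path, ".channels.json"))
  invisible(path)
}

#' @rdname write_chip_image
#' @export
read_chip_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("image file not found: %s", path), class = "dmspr_format_error")
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      abort(sprintf("cannot read %s as TIFF: %s", path, conditionMessage(e)),
                            class = "dmspr_format_error")
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) abort("TIFF has no pages.", class = "dmspr_format_error")
  if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1)))) {
    abort("all TIFF pages must be single-plane grayscale.", class = "dmspr_format_error")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("TIFF pages have mismatched dimensions.", class = "dmspr_format_error")
  }
  sidecar <- paste0(path, ".channels.json")
  if (file.exists(sidecar)) {
    ch <- as.character(jsonlite::read_json(sidecar, simplifyVector = TRUE))
    if (length(ch) != length(pages)) {
      abort("channel sidecar does not match TIFF page count.", class = "dmspr_format_error")
    }
  } else {
    ch <- paste0("ch", seq_along(pages))
    warn(sprintf("no channel metadata for %s; naming pages %s.",
                 path, paste(ch, collapse = ", ")))
  }
  planes <- lapply(pages, function(p) {
    m <- p
    storage.mode(m) <- "integer"
    m
  })
  names(planes) <- ch
  structure(planes, class = "chip_image")
}

#' Extract per-well mean fluorescence from a chip image
#'
#' For every well of the mapped module and every channel, averages the
#' pixels whose centers lie within `aperture_radius` of the mapped well
#' center (pixel-center-in-disk test; no partial-pixel weighting, so the
#' result is deterministic). No background subtraction is applied; the
#' constant background is absorbed by the mixture model's negative
#' population downstream.
#'
#' @param image A `chip_image` or a single matrix.
#' @param map A [fit_projective_map()] / [default_geometry_map()] result.
#' @param layout The chip layout.
#' @param aperture_radius Aperture radius in pixels. Default: 0.35 x the
#'   well pitch expressed in pixels under the map, which keeps the aperture
#'   inside the well at moderate registration error.
#' @return A tibble (one row per well, [layout_wells()] order) with columns
#'   `module`, `well_index`, `row`, `col`, `x_px`, `y_px`,
#'   `aperture_pixels`, then one mean-intensity column per channel.
#' @export
extract_well_intensities <- function(image, map, layout, aperture_radius = NULL) {
  if (is.matrix(image)) image <- structure(list(ch1 = image), class = "chip_image")
  stopifnot(inherits(map, "geometry_map"), inherits(layout, "array_layout"))
  centers <- well_centers(map, layout)
  if (is.null(aperture_radius)) {
    p2 <- .apply_homography(map$homography, cbind(layout$well_pitch, 0))
    p1 <- .apply_homography(map$homography, cbind(0, 0))
    pitch_px <- sqrt(sum((p2 - p1)^2))
    aperture_radius <- 0.35 * pitch_px
  }
  d <- dim(image[[1]]); h <- d[1]; w <- d[2]
  clipped <- which(centers$x_px - aperture_radius < 0 |
                   centers$x_px + aperture_radius > w - 1 |
                   centers$y_px - aperture_radius < 0 |
                   centers$y_px + aperture_radius > h - 1)
  if (length(clipped) > 0) {
    abort(sprintf("aperture clipped by the image edge for %d well(s) (first: %s).",
                  length(clipped), paste(head(clipped, 5), collapse = ", ")),
          class = "dmspr_out_of_frame_error")
  }
  disk <- .disk_pixels(centers$x_px, centers$y_px,
                       rep(aperture_radius, nrow(centers)))
  npix <- tabulate(disk$well, nbins = nrow(centers))
  if (any(npix == 0)) {
    abort("aperture contains zero pixels for at least one well; increase aperture_radius.",
          class = "dmspr_empty_aperture_error")
  }
  lin <- disk$py + 1L + h * disk$px  # column-major linear index
  out <- dplyr::mutate(centers, aperture_pixels = npix)
  for (ch in names(image)) {
    sums <- rowsum(as.numeric(image[[ch]][lin]), disk$well)
    out[[ch]] <- as.numeric(sums) / npix
  }
  out
}
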