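#' Fit the projective map registering the well mask onto an image
#'
#' Solves the four-point direct linear transform: the module's layout-plane
#' corner anchors (see [layout_corners()]) are mapped exactly onto four
#' user-supplied pixel coordinates given in TL, TR, BR, BL order. Four point
#' correspondences determine a homography uniquely up to scale, so a full
#' projective model (keystone included) is recovered, not just an affine one.
#'
#' Pixel coordinates are 0-based with x = column, y = row; continuous
#' coordinates refer to pixel centers.
#'
#' @param corner_points 4 x 2 numeric matrix of pixel coordinates in
#'   TL, TR, BR, BL order.
#' @param layout An [build_layout()] object.
#' @param module_id Module the map refers to.
#' @return An object of class `geometry_map` with elements `homography`
#'   (3 x 3, normalized to unit Frobenius scale with positive last entry when
#'   nonzero) and `module_id`.
#' @examples
#' layout <- build_layout(1, 6, 2, 3)
#' map <- fit_projective_map(layout_corners(layout) / 10 + 5, layout, 1)
#' well_centers(map, layout)
#' @export
fit_projective_map <- function(corner_points, layout, module_id = 1L) {
  corner_points <- as.matrix(corner_points)
  if (!all(dim(corner_points) == c(4L, 2L)) || !is.numeric(corner_points)) {
    abort("corner_points must be a 4 x 2 numeric matrix (TL, TR, BR, BL).",
          class = "dmspr_domain_error")
  }
  if (anyDuplicated(round(corner_points, 9)) || .any_collinear(corner_points)) {
    abort("corner points are degenerate: duplicated or three collinear.",
          class = "dmspr_degenerate_geometry_error")
  }
  src <- layout_corners(layout)
  H <- .solve_homography(src, corner_points)
  structure(list(homography = H, module_id = as.integer(module_id)),
            class = "geometry_map")
}

.any_collinear <- function(p, tol = 1e-8) {
  combs <- utils::combn(4L, 3L)
  scale2 <- max(apply(p, 2, function(v) diff(range(v))))^2
  for (j in seq_len(ncol(combs))) {
    a <- p[combs[1, j], ]; b <- p[combs[2, j], ]; c <- p[combs[3, j], ]
    cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cross) <= tol * max(scale2, 1)) return(TRUE)
  }
  FALSE
}

# 4-point DLT: rows of A h = 0 with h33 pinned via an 8x8 solve.
.solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    abort("corner correspondence is degenerate; cannot fit a homography.",
          class = "dmspr_degenerate_geometry_error")
  })
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  if (abs(det(H)) < 1e-12 * norm(H, "F")^3) {
    abort("fitted homography is singular.", class = "dmspr_degenerate_geometry_error")
  }
  .normalize_homography(H)
}

.normalize_homography <- function(H) {
  H <- H / norm(H, "F")
  if (H[3, 3] < 0) H <- -H
  H
}

#' Apply a homography to layout-plane points
#' @noRd
.apply_homography <- function(H, xy) {
  p <- H %*% rbind(t(xy), 1)
  cbind(x = p[1, ] / p[3, ], y = p[2, ] / p[3, ])
}

#' @export
print.geometry_map <- function(x, ...) {
  cat(sprintf("<geometry_map> module %d\n", x$module_id))
  print(signif(x$homography, 6))
  invisible(x)
}

#' Pixel coordinates of every well under a geometry map
#'
#' @param map A [fit_projective_map()] result.
#' @param layout The chip layout the map was fitted against.
#' @return A tibble in [layout_wells()] order for the map's module, with
#'   pixel-coordinate columns `x_px`, `y_px`.
#' @export
well_centers <- function(map, layout) {
  stopifnot(inherits(map, "geometry_map"), inherits(layout, "array_layout"))
  wells <- layout_wells(layout, module_id = map$module_id)
  px <- .apply_homography(map$homography, cbind(wells$x_um, wells$y_um))
  dplyr::mutate(wells, x_px = px[, "x"], y_px = px[, "y"])
}
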