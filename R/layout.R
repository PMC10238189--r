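#' Define the logical layout of a nanowell-array chip
#'
#' A chip consists of `n_modules` identical modules, each a rectangular
#' row-major grid of nanowells. Defaults describe the production device:
#' four modules of 10,040 wells each (40 rows x 251 columns, an exact
#' factorization so no grid slot is left unused), 1 nL per well. The grid may
#' be larger than `wells_per_module`; trailing grid slots are then absent
#' from the mask.
#'
#' @param n_modules Number of independent modules on the chip.
#' @param wells_per_module Number of nanowells per module.
#' @param grid_rows,grid_cols Grid dimensions of one module;
#'   `grid_rows * grid_cols >= wells_per_module`.
#' @param well_pitch Center-to-center well spacing, micrometres.
#' @param well_diameter Well diameter, micrometres; must be < `well_pitch`.
#' @param well_volume Well volume in nanolitres.
#'
#' @return An object of class `array_layout`.
#' @examples
#' layout <- build_layout()
#' layout
#' nrow(layout_wells(layout))  # 40160
#' @export
build_layout <- function(n_modules = 4, wells_per_module = 10040,
                         grid_rows = 40, grid_cols = 251,
                         well_pitch = 120, well_diameter = 90,
                         well_volume = 1) {
  counts <- c(n_modules = n_modules, wells_per_module = wells_per_module,
              grid_rows = grid_rows, grid_cols = grid_cols)
  if (any(counts < 1) || any(counts != floor(counts))) {
    abort("n_modules, wells_per_module, grid_rows and grid_cols must be positive integers.",
          class = "dmspr_domain_error")
  }
  if (grid_rows * grid_cols < wells_per_module) {
    abort(sprintf("grid of %d x %d holds only %d wells; %d requested.",
                  grid_rows, grid_cols, grid_rows * grid_cols, wells_per_module),
          class = "dmspr_capacity_error")
  }
  if (!(well_pitch > well_diameter && well_diameter > 0)) {
    abort("require well_pitch > well_diameter > 0.", class = "dmspr_domain_error")
  }
  if (!(well_volume > 0)) {
    abort("well_volume must be positive.", class = "dmspr_domain_error")
  }
  structure(
    list(n_modules = as.integer(n_modules),
         wells_per_module = as.integer(wells_per_module),
         grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         well_pitch = well_pitch, well_diameter = well_diameter,
         well_volume = well_volume),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("<array_layout> %d module(s) x %d wells (%d x %d grid)\n",
              x$n_modules, x$wells_per_module, x$grid_rows, x$grid_cols))
  cat(sprintf("  pitch %g um, diameter %g um, volume %g nL; %d wells total\n",
              x$well_pitch, x$well_diameter, x$well_volume,
              x$n_modules * x$wells_per_module))
  invisible(x)
}

#' Enumerate the wells of a layout
#'
#' Wells are enumerated row-major within each module: `well_index` runs
#' 1..`wells_per_module`, with `row = (well_index - 1) %/% grid_cols + 1`.
#' Layout-plane coordinates place well (1, 1) at the origin and advance by
#' `well_pitch` per row/column.
#'
#' @param layout An [build_layout()] object.
#' @param module_id Optional single module to enumerate; default all modules.
#' @return A tibble with columns `module`, `well_index`, `row`, `col`,
#'   `x_um`, `y_um`.
#' @export
layout_wells <- function(layout, module_id = NULL) {
  stopifnot(inherits(layout, "array_layout"))
  modules <- if (is.null(module_id)) seq_len(layout$n_modules) else as.integer(module_id)
  if (any(modules < 1L | modules > layout$n_modules)) {
    abort("module_id outside the layout.", class = "dmspr_domain_error")
  }
  idx <- seq_len(layout$wells_per_module)
  row <- (idx - 1L) %/% layout$grid_cols + 1L
  col <- (idx - 1L) %% layout$grid_cols + 1L
  one <- tibble(
    well_index = idx, row = row, col = col,
    x_um = (col - 1) * layout$well_pitch,
    y_um = (row - 1) * layout$well_pitch
  )
  dplyr::bind_rows(lapply(modules, function(m) dplyr::mutate(one, module = m, .before = 1)))
}

#' Bounding corner anchors of one module in the layout plane
#'
#' The four anchors are the outermost well centers in TL, TR, BR, BL order;
#' these are the points a user identifies on the image to register the mask.
#'
#' @inheritParams layout_wells
#' @return A 4 x 2 matrix of (x, y) layout-plane coordinates (micrometres).
#' @export
layout_corners <- function(layout) {
  stopifnot(inherits(layout, "array_layout"))
  w <- layout_wells(layout, module_id = 1L)
  xmax <- max(w$x_um); ymax <- max(w$y_um)
  matrix(c(0, 0, xmax, 0, xmax, ymax, 0, ymax),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("TL", "TR", "BR", "BL"), c("x", "y")))
}

#' Read or write a layout as a YAML config
#'
#' @param layout An `array_layout`.
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns an
#'   `array_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  yaml::write_yaml(list(
    n_modules = layout$n_modules, wells_per_module = layout$wells_per_module,
    grid_rows = layout$grid_rows, grid_cols = layout$grid_cols,
    pitch = layout$well_pitch, diameter = layout$well_diameter,
    volume_nl = layout$well_volume), path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  build_layout(y$n_modules, y$wells_per_module, y$grid_rows, y$grid_cols,
               y$pitch, y$diameter, y$volume_nl)
}
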