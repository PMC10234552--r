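#' Define a regular coarse-model grid
#'
#' Describes the regular grid of square cells on which the coarse (chemical
#' transport) model reports cell-average concentrations. Coordinates are
#' planar metres; there is no geodesy here, so real-world inputs must be
#' pre-projected. Cells are numbered row-major starting at the cell whose
#' lower-left corner is the grid origin.
#'
#' @param origin_x,origin_y Lower-left corner of the domain (m).
#' @param cell_size Cell edge length (m). Default 12000 (a 12-km grid).
#' @param n_rows,n_cols Number of cell rows / columns.
#' @return An object of class `grid_definition`.
#' @examples
#' g <- grid_definition(n_rows = 4, n_cols = 4)
#' n_cells(g)
#' @export
grid_definition <- function(origin_x = 0, origin_y = 0, cell_size = 12000,
                            n_rows = 4, n_cols = 4) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (n_rows < 1L || n_cols < 1L)
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  structure(
    list(origin_x = origin_x, origin_y = origin_y, cell_size = cell_size,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
    class = "grid_definition"
  )
}

#' @export
print.grid_definition <- function(x, ...) {
  cat(sprintf("<grid_definition> %d x %d cells of %g m (origin %g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A [grid_definition()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell centroids of a grid
#' @param grid A [grid_definition()].
#' @return A data.frame with columns `cell`, `x`, `y` in row-major cell order.
#' @export
cell_centroids <- function(grid) {
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  data.frame(
    cell = seq_len(n_cells(grid)),
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y + (row - 0.5) * grid$cell_size
  )
}

#' Map planar points to grid cells
#'
#' Every point inside the domain maps to exactly one cell; points on the
#' upper/right domain boundary belong to the last row/column.
#'
#' @param grid A [grid_definition()].
#' @param x,y Point coordinates (m), vectorised.
#' @return Integer cell ids (row-major). Points outside the domain give `NA`.
#' @export
point_to_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin_x) / cs) + 1L
  row <- floor((y - grid$origin_y) / cs) + 1L
  # points sitting exactly on the outer boundary belong to the last cell
  col[x == grid$origin_x + grid$n_cols * cs] <- grid$n_cols
  row[y == grid$origin_y + grid$n_rows * cs] <- grid$n_rows
  out <- (row - 1L) * grid$n_cols + col
  out[col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows] <- NA_integer_
  as.integer(out)
}

#' Domain extent of a grid
#' @param grid A [grid_definition()].
#' @return Named numeric vector `xmin`, `xmax`, `ymin`, `ymax` (m).
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$origin_x,
    xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymin = grid$origin_y,
    ymax = grid$origin_y + grid$n_rows * grid$cell_size)
}

#' Dense receptor subgrid for every cell
#'
#' Lays a `per_side` x `per_side` lattice of receptor points inside each cell
#' (at subcell centres), emulating the spatially distributed receptor grid the
#' dispersion model is evaluated on (default 144 receptors per 12-km cell).
#'
#' @param grid A [grid_definition()].
#' @param per_side Receptors per cell edge (default 12, i.e. 144 per cell).
#' @return data.frame `point_id`, `x`, `y`, `cell`.
#' @export
cell_receptors <- function(grid, per_side = 12L) {
  if (per_side < 1L) stop("`per_side` must be >= 1", call. = FALSE)
  step <- grid$cell_size / per_side
  offs <- (seq_len(per_side) - 0.5) * step
  cc <- cell_centroids(grid)
  x0 <- cc$x - grid$cell_size / 2
  y0 <- cc$y - grid$cell_size / 2
  nc <- nrow(cc)
  k <- per_side^2
  gx <- rep(rep(offs, times = per_side), times = nc)
  gy <- rep(rep(offs, each = per_side), times = nc)
  data.frame(
    point_id = seq_len(nc * k),
    x = rep(x0, each = k) + gx,
    y = rep(y0, each = k) + gy,
    cell = rep(cc$cell, each = k)
  )
}
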