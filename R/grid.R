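#' Define a regular analysis grid over a rectangular landscape
#'
#' The landscape is tiled with square cells of side `cell_size` km, origin at
#' the lower-left corner, planar km coordinates. Cells are indexed row-major
#' from 0 (`cell_id = row * n_cols + col`), row 0 at the bottom; a point
#' belongs to the half-open cell `[x0, x0 + cell_size) x [y0, y0 + cell_size)`
#' so boundary points are never double-assigned.
#'
#' @param n_rows,n_cols Grid dimensions in cells (each >= 1).
#' @param cell_size Cell side length in km (default 5, roughly a gorilla
#'   home-range diameter).
#' @return An object of class `occu_grid`.
#' @export
#' @examples
#' g <- landscape_grid(10, 12)
#' grid_cells(g)
landscape_grid <- function(n_rows, n_cols, cell_size = 5) {
  if (!is.numeric(n_rows) || n_rows < 1 || n_rows != round(n_rows))
    abort("`n_rows` must be a positive integer.")
  if (!is.numeric(n_cols) || n_cols < 1 || n_cols != round(n_cols))
    abort("`n_cols` must be a positive integer.")
  if (!is.numeric(cell_size) || cell_size <= 0)
    abort("`cell_size` must be a positive length in km.")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size)),
    class = "occu_grid"
  )
}

#' @export
print.occu_grid <- function(x, ...) {
  cat(sprintf("<occu_grid> %d x %d cells of %g km (%g x %g km landscape)\n",
              x$n_rows, x$n_cols, x$cell_size,
              x$n_cols * x$cell_size, x$n_rows * x$cell_size))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell index table for a grid
#'
#' @param grid An `occu_grid`.
#' @return A tibble with `cell_id` (0-based, row-major), `row`, `col`
#'   (0-based) and cell-centre coordinates `x_km`, `y_km`.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "occu_grid"))
  id <- seq_len(n_cells(grid)) - 1L
  row <- id %/% grid$n_cols
  col <- id %% grid$n_cols
  tibble::tibble(
    cell_id = id, row = row, col = col,
    x_km = (col + 0.5) * grid$cell_size,
    y_km = (row + 0.5) * grid$cell_size
  )
}

## point -> cell id; NA outside the landscape
point_cell <- function(grid, x, y) {
  col <- floor(x / grid$cell_size)
  row <- floor(y / grid$cell_size)
  out <- row * grid$n_cols + col
  bad <- col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  out[bad] <- NA_real_
  as.integer(out)
}

#' Queen (8-neighbour) adjacency for a grid
#'
#' Each cell is adjacent to the up-to-eight cells sharing an edge or corner.
#' Interior cells have 8 neighbours, edge cells 5 and corner cells 3. The
#' intrinsic CAR spatial prior conditions each cell's effect on the mean of
#' these neighbours.
#'
#' @param grid An `occu_grid` with at least 2 cells in one dimension.
#' @return An object of class `occu_adjacency`: a list with `neighbors`
#'   (list of 0-based neighbour cell ids per cell), `n_neighbors`, and the
#'   flattened arrays `adj_ids` / `adj_start` used by the samplers.
#' @export
#' @examples
#' adj <- build_adjacency(landscape_grid(3, 3))
#' adj$n_neighbors  # corner cells have 3, the centre has 8
build_adjacency <- function(grid) {
  stopifnot(inherits(grid, "occu_grid"))
  if (n_cells(grid) < 2)
    abort("Grid must have at least 2 cells to define adjacency.")
  nr <- grid$n_rows; nc <- grid$n_cols
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  cells <- grid_cells(grid)
  nbr <- vector("list", nrow(cells))
  for (k in seq_len(nrow(offs))) {
    r2 <- cells$row + offs$dr[k]
    c2 <- cells$col + offs$dc[k]
    ok <- r2 >= 0 & r2 < nr & c2 >= 0 & c2 < nc
    id2 <- r2 * nc + c2
    for (i in which(ok)) nbr[[i]] <- c(nbr[[i]], id2[i])
  }
  nbr <- lapply(nbr, function(v) sort(as.integer(v)))
  nn <- vapply(nbr, length, integer(1))
  structure(
    list(neighbors = nbr, n_neighbors = nn,
         adj_ids = as.integer(unlist(nbr)),
         adj_start = as.integer(c(0L, cumsum(nn))),
         n_rows = nr, n_cols = nc),
    class = "occu_adjacency"
  )
}

## sparse symmetric adjacency check used in tests and validation
adjacency_is_symmetric <- function(adj) {
  all(vapply(seq_along(adj$neighbors), function(i) {
    all(vapply(adj$neighbors[[i]] + 1L,
               function(j) (i - 1L) %in% adj$neighbors[[j]], logical(1)))
  }, logical(1)))
}
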