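#' Build a cell-level spatial-replicate detection table from survey tracks
#'
#' Converts georeferenced survey point sequences into the detection
#' histories the occupancy model consumes. Each track polyline is cut at
#' grid-cell boundaries into cell-segments; each contiguous in-cell segment
#' is then divided into consecutive 1-km units (residual portions shorter
#' than 1 km are discarded), and a unit scores a detection when any
#' sign-flagged point falls on it by arc-length position. Unit cutting
#' restarts at every cell boundary and at every track start, so units never
#' span cells or tracks. Cells accumulating fewer than `min_units` replicates
#' are excluded from the model table.
#'
#' @param tracks A tibble of survey points with columns `track_id`, `x_km`,
#'   `y_km` and logical `sign` (gorilla sign recorded at that fix). Points
#'   are taken in input order within each track. An optional logical
#'   `chimp_sign` column is tallied into `y_chimp` but never modelled.
#' @param grid An [landscape_grid()] covering the points.
#' @param min_units Minimum replicates for a cell to enter the table
#'   (default 2 — occupancy needs replication; observed patrol data ranged
#'   from two to 50 units per cell, and no upper cap is applied).
#' @param unit_km Replicate length (default 1 km).
#' @param clip If `TRUE`, out-of-grid points break the track into in-bounds
#'   pieces (with a warning); if `FALSE` (default) they raise an error.
#' @return A cell-effort tibble: `cell_id`, `row`, `col`, `n_units`, `y`,
#'   `detections` (list of 0/1 per unit), `y_chimp`, `is_forced_absence`.
#' @export
build_cell_effort <- function(tracks, grid, min_units = 2, unit_km = 1,
                              clip = FALSE) {
  stopifnot(inherits(grid, "occu_grid"))
  req <- c("track_id", "x_km", "y_km", "sign")
  miss <- setdiff(req, names(tracks))
  if (length(miss) > 0)
    abort(paste0("`tracks` is missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(tracks) == 0) abort("`tracks` is empty.")
  has_chimp <- "chimp_sign" %in% names(tracks)
  nx <- grid$n_cols * grid$cell_size
  ny <- grid$n_rows * grid$cell_size
  out_of_bounds <- tracks$x_km < 0 | tracks$x_km > nx |
                   tracks$y_km < 0 | tracks$y_km > ny
  if (any(out_of_bounds)) {
    if (!clip) abort("Track points fall outside the grid; set `clip = TRUE` to drop them.")
    warn(sprintf("%d out-of-grid point(s) dropped; tracks split at the gaps.",
                 sum(out_of_bounds)))
  }

  units <- list(); u <- 0L
  for (tid in unique(tracks$track_id)) {
    tk <- tracks[tracks$track_id == tid, ]
    ## split at out-of-bounds points into in-bounds runs
    inb <- !(tk$x_km < 0 | tk$x_km > nx | tk$y_km < 0 | tk$y_km > ny)
    runs <- split(which(inb), cumsum(!inb)[inb])
    for (idx in runs) {
      if (length(idx) < 2) next
      piece <- tk[idx, ]
      segs <- cut_track_cells(piece$x_km, piece$y_km, grid)
      if (is.null(segs)) {
        warn(sprintf("Track %s has zero length; skipped.", as.character(tid)))
        next
      }
      s_sign <- segs$arc_at_point[which(piece$sign)]
      s_chimp <- if (has_chimp) segs$arc_at_point[which(piece$chimp_sign)] else numeric(0)
      for (k in seq_len(nrow(segs$segments))) {
        a <- segs$segments$arc_from[k]; b <- segs$segments$arc_to[k]
        n_u <- floor((b - a) / unit_km + 1e-9)
        if (n_u < 1) next
        for (j in seq_len(n_u)) {
          lo <- a + (j - 1) * unit_km; hi <- a + j * unit_km
          u <- u + 1L
          units[[u]] <- c(cell = segs$segments$cell_id[k],
                          det = as.integer(any(s_sign >= lo & s_sign < hi)),
                          chimp = as.integer(any(s_chimp >= lo & s_chimp < hi)))
        }
      }
    }
  }
  if (u == 0L) {
    return(tibble::tibble(cell_id = integer(), row = integer(), col = integer(),
                          n_units = integer(), y = numeric(),
                          detections = list(), y_chimp = numeric(),
                          is_forced_absence = logical()))
  }
  um <- do.call(rbind, units)
  by_cell <- split(seq_len(nrow(um)), um[, "cell"])
  tab <- tibble::tibble(
    cell_id = as.integer(names(by_cell)),
    n_units = unname(vapply(by_cell, length, integer(1))),
    y = unname(vapply(by_cell, function(i) sum(um[i, "det"]), numeric(1))),
    detections = unname(purrr::map(by_cell, function(i) as.integer(um[i, "det"]))),
    y_chimp = unname(vapply(by_cell, function(i) sum(um[i, "chimp"]), numeric(1)))
  )
  tab <- tab[tab$n_units >= min_units, ]
  tab$row <- tab$cell_id %/% grid$n_cols
  tab$col <- tab$cell_id %% grid$n_cols
  tab$is_forced_absence <- FALSE
  dplyr::select(tab, "cell_id", "row", "col", "n_units", "y",
                "detections", "y_chimp", "is_forced_absence")
}

## Split one in-bounds polyline into cell-segments.
## Returns list(segments = tibble(cell_id, arc_from, arc_to),
##              arc_at_point = arc length at each input vertex).
cut_track_cells <- function(x, y, grid) {
  cs <- grid$cell_size
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  arc_at_point <- c(0, cumsum(seg_len))
  total <- arc_at_point[length(arc_at_point)]
  if (total <= 0) return(NULL)

  ## subdivide every vertex-to-vertex leg at gridline crossings
  cell <- integer(0); from <- numeric(0); to <- numeric(0)
  for (i in seq_along(seg_len)) {
    if (seg_len[i] == 0) next
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1]; y2 <- y[i + 1]
    ts <- c(0, 1)
    for (g in grid_crossings(x1, x2, cs)) ts <- c(ts, g)
    for (g in grid_crossings(y1, y2, cs)) ts <- c(ts, g)
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    for (j in seq_len(length(ts) - 1)) {
      t0 <- ts[j]; t1 <- ts[j + 1]
      if (t1 - t0 < 1e-12) next
      tm <- (t0 + t1) / 2
      cid <- point_cell(grid,
                        pmin(x1 + tm * (x2 - x1), grid$n_cols * cs - 1e-9),
                        pmin(y1 + tm * (y2 - y1), grid$n_rows * cs - 1e-9))
      cell <- c(cell, cid)
      from <- c(from, arc_at_point[i] + t0 * seg_len[i])
      to <- c(to, arc_at_point[i] + t1 * seg_len[i])
    }
  }
  ## merge consecutive pieces in the same cell into cell-segments
  brk <- c(TRUE, cell[-1] != cell[-length(cell)])
  gid <- cumsum(brk)
  segments <- tibble::tibble(
    cell_id = cell[brk],
    arc_from = tapply(from, gid, min)[unique(gid)],
    arc_to = tapply(to, gid, max)[unique(gid)]
  )
  list(segments = segments, arc_at_point = arc_at_point)
}

## parameters t in (0,1) where the coordinate crosses a multiple of cs
grid_crossings <- function(a, b, cs) {
  if (a == b) return(numeric(0))
  lo <- min(a, b); hi <- max(a, b)
  ks <- seq(ceiling(lo / cs), floor(hi / cs))
  ks <- ks[ks * cs > lo & ks * cs < hi]
  (ks * cs - a) / (b - a)
}

#' Add forced-absence cells to an effort table
#'
#' Cells where the species is certainly absent (lakes, agricultural land,
#' settlements, areas well beyond the historical range) are appended with
#' zero detections and a small pseudo-effort, anchoring the suitability
#' surface to known absences.
#'
#' @param effort A cell-effort tibble from [build_cell_effort()] or
#'   [simulate_effort()].
#' @param mask Integer cell ids to force absent.
#' @param grid The [landscape_grid()] the ids refer to.
#' @param pseudo_units Replicates assigned to each forced cell (default 2).
#' @param override If `FALSE` (default), masking a cell that already has
#'   detections is an error.
#' @return The effort tibble with the masked cells appended
#'   (`is_forced_absence = TRUE`, `y = 0`); cells already present with
#'   `y = 0` are flagged in place.
#' @export
add_forced_absences <- function(effort, mask, grid, pseudo_units = 2,
                                override = FALSE) {
  stopifnot(inherits(grid, "occu_grid"))
  mask <- unique(as.integer(mask))
  if (length(mask) == 0) return(effort)
  if (any(mask < 0 | mask >= n_cells(grid)))
    abort("`mask` contains cell ids outside the grid.")
  hit <- effort$cell_id %in% mask & effort$y > 0
  if (any(hit) && !override)
    abort(sprintf("%d masked cell(s) already have detections; set `override = TRUE` to replace them.",
                  sum(hit)))
  effort <- effort[!(effort$cell_id %in% mask), ]
  add <- tibble::tibble(
    cell_id = mask,
    row = mask %/% grid$n_cols,
    col = mask %% grid$n_cols,
    n_units = as.integer(pseudo_units),
    y = 0,
    detections = purrr::map(mask, ~ rep(0L, pseudo_units)),
    is_forced_absence = TRUE
  )
  if ("y_chimp" %in% names(effort)) add$y_chimp <- 0
  dplyr::bind_rows(effort, add)
}

#' Standardize covariate columns
#'
#' Centres each covariate to mean 0 and scales to standard deviation 1
#' (sample sd, denominator n - 1), returning the transform parameters so the
#' identical transform can be reapplied when predicting over the full
#' landscape.
#'
#' @param values A numeric matrix or data frame, one column per covariate.
#' @return A list: `values` (standardized matrix), `center`, `scale`
#'   (named numeric vectors).
#' @export
#' @examples
#' standardize_covariates(cbind(elev = c(1, 2, 3)))$values
standardize_covariates <- function(values) {
  m <- as.matrix(values)
  if (!is.numeric(m)) abort("Covariates must be numeric.")
  if (any(!is.finite(m))) abort("Covariates contain non-finite values.")
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  flat <- scl == 0 | !is.finite(scl)
  if (any(flat))
    abort(paste0("Constant covariate(s): ",
                 paste(colnames(m)[flat], collapse = ", ")))
  std <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  list(values = std, center = ctr, scale = scl)
}
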