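g5 <- landscape_grid(4, 4, cell_size = 5)

# a straight track along y = 2.5 from x0 to x1, with sign fixes at given x
straight_track <- function(x0, x1, sign_at = numeric(0), id = 1, step = 0.1) {
  xs <- sort(unique(c(seq(x0, x1, by = step), x1, sign_at)))
  tibble::tibble(track_id = id, x_km = xs, y_km = 2.5,
                 sign = xs %in% sign_at)
}

test_that("a 3.7-km in-cell segment yields 3 one-km units, residual discarded", {
  tab <- build_cell_effort(straight_track(0.5, 4.2), g5, min_units = 1)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$cell_id, 0L)
  expect_equal(tab$n_units, 3L)
  expect_equal(tab$y, 0)
})

test_that("sign placement lands in the right unit by arc length", {
  tab <- build_cell_effort(straight_track(0, 3.2, sign_at = 1.5), g5, min_units = 1)
  expect_equal(tab$n_units, 3L)
  expect_equal(tab$detections[[1]], c(0L, 1L, 0L))
  expect_equal(tab$y, 1)
})

test_that("unit cutting restarts at cell boundaries", {
  # 10 km straight through two 5-km cells: 5 units in each, none spanning
  tab <- build_cell_effort(straight_track(0, 9.9), g5, min_units = 1)
  expect_equal(tab$n_units, c(5L, 4L))  # second cell gets 4.9 km -> 4 full units
  tab2 <- build_cell_effort(straight_track(0, 10.0001), g5, min_units = 1)
  expect_equal(sort(tab2$n_units), c(5L, 5L))
})

test_that("cells below the replication minimum are excluded", {
  # 1.5 km in cell 0 -> 1 unit, dropped at min_units = 2
  tab <- build_cell_effort(straight_track(0, 1.6), g5)
  expect_equal(nrow(tab), 0)
  tab1 <- build_cell_effort(straight_track(0, 1.6), g5, min_units = 1)
  expect_equal(tab1$n_units, 1L)
})

test_that("unit counts never exceed exact in-cell lengths on random tracks", {
  set.seed(42)
  for (rep in 1:8) {
    n_pts <- 30
    pts <- tibble::tibble(
      track_id = 1,
      x_km = cumsum(c(runif(1, 0, 20), runif(n_pts - 1, -1.5, 1.5))),
      y_km = cumsum(c(runif(1, 0, 20), runif(n_pts - 1, -1.5, 1.5))),
      sign = FALSE)
    pts$x_km <- pmin(pmax(pts$x_km, 0), 20 - 1e-6)
    pts$y_km <- pmin(pmax(pts$y_km, 0), 20 - 1e-6)
    tab <- build_cell_effort(pts, g5, min_units = 1)
    # geometric oracle: exact polyline-cell intersection lengths
    segs <- occuRange:::cut_track_cells(pts$x_km, pts$y_km, g5)
    len_by_cell <- tapply(segs$segments$arc_to - segs$segments$arc_from,
                          segs$segments$cell_id, sum)
    for (k in seq_len(nrow(tab))) {
      exact <- len_by_cell[[as.character(tab$cell_id[k])]]
      expect_lte(tab$n_units[k], floor(exact + 1e-9))
    }
    total_len <- sum(sqrt(diff(pts$x_km)^2 + diff(pts$y_km)^2))
    expect_lte(sum(tab$n_units), floor(total_len + 1e-9))
  }
})

test_that("round trip: axis-aligned synthetic tracks recover floor(in-cell km) units", {
  tr <- make_world(4, 4, v_rho = 0, seed = 33)
  g <- attr(tr, "grid")
  pts <- simulate_tracks(tr, n_tracks = 4, length_km = 18, step_km = 0.25,
                         axis_aligned = TRUE, seed = 8)
  tab <- build_cell_effort(pts, g, min_units = 1)
  # independent geometric oracle: an eastbound track at constant y crosses
  # cell column c over the x-interval [5c, 5c+5); its in-cell length is the
  # interval overlap and the unit count is its floor
  expected <- integer(16)
  for (tid in unique(pts$track_id)) {
    tk <- pts[pts$track_id == tid, ]
    expect_equal(length(unique(tk$y_km)), 1L)
    row <- floor(tk$y_km[1] / 5)
    x0 <- min(tk$x_km); x1 <- max(tk$x_km)
    for (col in 0:3) {
      overlap <- max(0, min(x1, 5 * col + 5) - max(x0, 5 * col))
      cid <- row * 4 + col + 1
      expected[cid] <- expected[cid] + floor(overlap + 1e-9)
    }
  }
  got <- integer(16)
  got[tab$cell_id + 1L] <- tab$n_units
  expect_equal(got, expected)
})

test_that("adding sign points never decreases any cell's detections", {
  set.seed(7)
  base <- straight_track(0, 18, sign_at = c(2.5, 7.3))
  more <- straight_track(0, 18, sign_at = c(2.5, 7.3, 11.1, 16.9))
  t1 <- build_cell_effort(base, g5, min_units = 1)
  t2 <- build_cell_effort(more, g5, min_units = 1)
  merged <- dplyr::left_join(t1, t2, by = "cell_id", suffix = c("_base", "_more"))
  expect_true(all(merged$y_more >= merged$y_base))
})

test_that("out-of-grid points error unless clipping is enabled", {
  bad <- straight_track(-2, 3)
  expect_error(build_cell_effort(bad, g5), "clip")
  expect_warning(tab <- build_cell_effort(bad, g5, min_units = 1, clip = TRUE),
                 "dropped")
  expect_equal(tab$n_units, 3L)  # in-bounds 0..3 km remains
})

test_that("chimp sign is tallied but kept separate from gorilla detections", {
  tk <- straight_track(0, 4.5, sign_at = 1.5)
  tk$chimp_sign <- abs(tk$x_km - 2.5) < 0.01
  tab <- build_cell_effort(tk, g5, min_units = 1)
  expect_equal(tab$y, 1)
  expect_equal(tab$y_chimp, 1)
})

test_that("forced absences append flagged zero-detection rows", {
  tr <- make_world(6, 6, seed = 13)
  eff <- simulate_effort(tr, n_units = 5, delta = 0.4, prop_sampled = 0.5, seed = 2)
  g <- attr(tr, "grid")
  expect_identical(add_forced_absences(eff, integer(0), g), eff)
  free <- setdiff(0:35, eff$cell_id)[1:10]
  out <- add_forced_absences(eff, free, g)
  expect_equal(nrow(out), nrow(eff) + 10)
  added <- out[out$is_forced_absence, ]
  expect_true(all(added$y == 0))
  expect_true(all(added$n_units == 2))
  # masking a detection cell errors unless overridden
  det_cell <- eff$cell_id[eff$y > 0][1]
  expect_error(add_forced_absences(eff, det_cell, g), "override")
  ov <- add_forced_absences(eff, det_cell, g, override = TRUE)
  expect_equal(ov$y[ov$cell_id == det_cell], 0)
})

test_that("standardization has the closed form, is idempotent and column-wise", {
  s <- standardize_covariates(cbind(a = c(1, 2, 3)))
  expect_equal(drop(s$values), c(-1, 0, 1))  # sample sd = 1
  expect_equal(unname(s$center), 2)
  expect_equal(unname(s$scale), 1)
  # idempotence
  s2 <- standardize_covariates(s$values)
  expect_equal(s2$values, s$values, tolerance = 1e-10)
  # columns handled independently
  m <- cbind(a = c(1, 5, 9, 2), b = c(100, 150, 120, 90))
  sm <- standardize_covariates(m)
  expect_equal(colMeans(sm$values), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(sm$values, 2, sd), c(a = 1, b = 1), tolerance = 1e-10)
  expect_equal(drop(standardize_covariates(m[, 1, drop = FALSE])$values),
               unname(sm$values[, 1]))
  expect_error(standardize_covariates(cbind(flat = rep(3, 4))), "flat")
})
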