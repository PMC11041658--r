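# A 3-vertex truth is the smallest unit the generator can target.
tiny_truth <- function(lat, lrt) {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8, 0)),
                   matrix(1:3, 1))
  list(mesh = mesh, lat = lat, lrt = lrt)
}

test_that("LAT lands on the steepest downstroke, LRT on the steepest T upslope", {
  tr <- tiny_truth(lat = c(120, 126, 133), lrt = c(310, 316, 323))
  s <- synth_egm_set(tr, inverted = FALSE, seed = 1)
  for (i in 1:3) {
    a <- annotate_lat(s$egms[[i]], s$windows)
    expect_length(a$flags, 0)
    expect_lte(abs(a$time_ms - tr$lat[i]), 1)
    r <- annotate_lrt(s$egms[[i]], s$windows)
    expect_length(r$flags, 0)
    expect_lte(abs(r$time_ms - tr$lrt[i]), 1)
  }
})

test_that("the Wyatt rule recovers LRT from inverted T waves too", {
  tr <- tiny_truth(lat = c(100, 104, 108), lrt = c(295, 299, 303))
  s <- synth_egm_set(tr, inverted = TRUE, seed = 1)
  for (i in 1:3) {
    r <- annotate_lrt(s$egms[[i]], s$windows)
    expect_lte(abs(r$time_ms - tr$lrt[i]), 1)
  }
})

test_that("flat signals yield no annotation and a flag", {
  flat <- electrogram(rep(0.5, 400), 1000)
  a <- annotate_lat(flat, c(50, 300))
  expect_true(is.na(a$time_ms))
  expect_true("flat" %in% a$flags)
  expect_true("flat" %in% annotate_lrt(flat, c(50, 300))$flags)
})

test_that("equal extremal slopes resolve to the earliest time", {
  # piecewise-linear trace with identical steepest downstrokes at 100 and 140
  s <- rep(0, 400)
  s[101:141] <- -2            # drop of 2 mV across sample 100->101
  s[142:400] <- -4            # identical drop across 140->141
  s[101] <- -1; s[142] <- -3  # make the two-sample ramps symmetric
  egm <- electrogram(s, 1000, t_start_ms = 0)
  d <- annotate_lat(egm, c(50, 350))
  expect_equal(d$time_ms, 100)
})

test_that("a window missing the deflection flags the edge extremum", {
  tr <- tiny_truth(lat = c(100, 104, 108), lrt = c(300, 304, 308))
  s <- synth_egm_set(tr, inverted = FALSE, seed = 2)
  r <- annotate_lrt(s$egms[[1]], c(150, 240))  # excludes the T wave
  expect_true("edge" %in% r$flags)
})

test_that("annotation is shift-equivariant and amplitude-scale invariant", {
  tr <- tiny_truth(lat = c(110, 115, 121), lrt = c(320, 326, 331))
  s <- synth_egm_set(tr, inverted = c(FALSE, TRUE, FALSE), seed = 4)
  for (i in 1:3) {
    egm <- s$egms[[i]]
    base_lat <- annotate_lat(egm, s$windows)$time_ms
    base_lrt <- annotate_lrt(egm, s$windows)$time_ms
    shift <- 37.5
    egm2 <- electrogram(egm$samples_mv, egm$fs_hz,
                        t_start_ms = egm$t_start_ms + shift)
    w2 <- annotation_windows(s$windows$activation + shift,
                             s$windows$repolarization + shift)
    expect_equal(annotate_lat(egm2, w2)$time_ms, base_lat + shift)
    expect_equal(annotate_lrt(egm2, w2)$time_ms, base_lrt + shift)
    egm3 <- electrogram(egm$samples_mv * 12.5, egm$fs_hz,
                        t_start_ms = egm$t_start_ms)
    expect_equal(annotate_lat(egm3, s$windows)$time_ms, base_lat)
    expect_equal(annotate_lrt(egm3, s$windows)$time_ms, base_lrt)
  }
})

test_that("map annotation keeps flagged and unprojectable sites invalid", {
  mesh <- make_sheet_mesh(10, 10, 5)
  lat <- planar_wave_lat(mesh, c(1, 0, 0), 0.9)
  truth <- list(mesh = mesh, lat = lat, lrt = lat + 250)
  s <- synth_egm_set(truth, inverted = 0.3, seed = 9)
  map <- annotate_map(s$egms, s$windows, mesh)
  expect_equal(sum(map$valid), 100)
  expect_lte(max(abs(map$lat[map$valid] - truth$lat[map$valid])), 0.5 + 1e-9)
  # corrupt five sites into flat traces -> invalid, not deleted
  s$egms[1:5] <- lapply(s$egms[1:5], function(e)
    electrogram(rep(0, length(e$samples_mv)), e$fs_hz,
                t_start_ms = e$t_start_ms, position = e$position))
  map2 <- annotate_map(s$egms, s$windows, mesh)
  expect_equal(sum(map2$valid), 95)
  expect_false(any(map2$valid[1:5]))
  # a site 10 mm off the mesh fails the 7 mm projection cut
  far <- s$egms[[6]]
  far$position <- far$position + c(0, 0, 10)
  map3 <- annotate_map(c(s$egms[-(1:6)], list(far)), s$windows, mesh)
  expect_false(map3$valid[6])
  expect_true(is.na(map3$lat[6]))
  # nothing annotatable -> error
  allflat <- lapply(s$egms[1:5], function(e) e)
  expect_error(annotate_map(allflat, s$windows, mesh), "empty")
})

test_that("outlier screening flags an isolated spike and nothing else", {
  mesh <- make_sheet_mesh(11, 11, 5)
  lat <- planar_wave_lat(mesh, c(1, 0.2, 0), 1.0)
  map <- build_surface_map(mesh, lat = lat, lrt = lat + 250)
  # smooth field: nothing flagged at any reasonable k
  expect_length(flag_outliers(map, "lat", k = 3)$flagged, 0)
  # one isolated +200 ms spike
  spike <- 61
  lat2 <- lat
  lat2[spike] <- lat2[spike] + 200
  map2 <- build_surface_map(mesh, lat = lat2, lrt = lat2 + 250)
  res <- flag_outliers(map2, "lat", k = 5)
  expect_equal(res$flagged, spike)
  expect_false(res$map$valid[spike])
  # too few valid vertices: insufficient evidence, nothing flagged
  few <- build_surface_map(mesh, lat = lat2, lrt = lat2 + 250,
                           valid = c(rep(TRUE, 2), rep(FALSE, 119)))
  expect_length(flag_outliers(few, "lat", k = 5)$flagged, 0)
})

test_that("ill-formed annotation windows are rejected", {
  expect_error(annotation_windows(c(100, 50), c(200, 300)), "end > start")
  expect_error(annotation_windows(c(0, 150), c(100, 300)), "overlap")
})
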