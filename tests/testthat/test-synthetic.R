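test_that("sheet meshes have the expected counts and geometry", {
  m <- make_sheet_mesh(2, 2, 10)
  expect_equal(n_vertices(m), 4)
  expect_equal(nrow(m$triangles), 2)
  m2 <- make_sheet_mesh(11, 11, 5)
  expect_equal(n_vertices(m2), 121)
  expect_equal(nrow(m2$triangles), 200)
  expect_equal(sum(triangle_areas(m2)), 50 * 50)
  expect_error(make_sheet_mesh(5, 5, 0), "> 0")
  expect_error(make_sheet_mesh(1, 5, 2), ">= 2")
})

test_that("icospheres are closed, regular and correctly scaled", {
  s <- make_icosphere(25, 2)
  expect_equal(n_vertices(s), 162)
  expect_equal(nrow(s$triangles), 320)
  expect_equal(sqrt(rowSums(s$vertices^2)), rep(25, 162))
  # closed surface: every edge is shared by exactly two triangles
  e <- mesh_edges(s)
  expect_equal(nrow(e), 480)
  expect_equal(sum(triangle_areas(s)), 4 * pi * 25^2, tolerance = 0.05)
})

test_that("planar wavefronts follow the closed form", {
  m <- make_sheet_mesh(7, 3, 5)
  lat <- planar_wave_lat(m, c(1, 0, 0), 1.0)
  expect_equal(lat[m$vertices[, 1] == 30], rep(30, 3))
  expect_equal(planar_wave_lat(m, c(2, 0, 0), 0.5)[m$vertices[, 1] == 30],
               rep(60, 3))
  laty <- planar_wave_lat(m, c(0, 1, 0), 1.0)
  expect_equal(unique(laty[m$vertices[, 2] == 5]), 5)
  expect_error(planar_wave_lat(m, c(0, 0, 0), 1), "nonzero")
})

test_that("graph-eikonal arrival equals the path sum on a strip", {
  strip <- make_sheet_mesh(10, 2, 10)
  lat <- eikonal_lat(strip, 1.0, sources = 1)
  bottom <- which(strip$vertices[, 2] == 0)
  expect_equal(lat[bottom], (seq_along(bottom) - 1) * 10)
})

test_that("graph-eikonal stays within 10 percent of the continuum bound", {
  sheet <- make_sheet_mesh(15, 15, 4)
  src <- 1L
  lat <- eikonal_lat(sheet, 0.8, sources = src)
  eucl <- sqrt(rowSums(sweep(sheet$vertices, 2,
                             sheet$vertices[src, ])^2)) / 0.8
  expect_true(all(lat >= eucl - 1e-9))
  expect_true(all(lat[-src] <= 1.10 * eucl[-src]))
})

test_that("slow patches delay arrival and scaling speeds rescales time", {
  sheet <- make_sheet_mesh(15, 15, 4)
  src <- which(sheet$vertices[, 1] == 0)
  base <- eikonal_lat(sheet, 0.9, sources = src)
  slow <- rep(0.9, 225)
  r <- sqrt(rowSums(sweep(sheet$vertices, 2, c(28, 28, 0))^2))
  slow[r <= 10] <- 0.1
  lat_slow <- eikonal_lat(sheet, slow, sources = src)
  expect_true(all(lat_slow >= base - 1e-9))
  expect_gt(max(lat_slow - base), 10)
  # multiplying all speeds by c divides arrival times by c
  expect_equal(eikonal_lat(sheet, 2 * 0.9, sources = src), base / 2,
               tolerance = 1e-9)
})

test_that("APD fields compose base, gradient and patches", {
  m <- make_sheet_mesh(11, 11, 1)
  expect_equal(make_apd_field(m, 250), rep(250, 121))
  apd <- make_apd_field(m, 250, gradient = c(1, 0, 0))
  expect_equal(diff(range(apd)), 10)
  patchy <- make_apd_field(m, 250, patches = list(
    list(center = c(5, 5, 0), radius = 4, delta = -60)))
  expect_equal(min(patchy), 190)                  # full delta at the center
  expect_equal(patchy[1], 250)                    # corner is outside the patch
  expect_error(make_apd_field(m, 40, patches = list(
    list(center = c(5, 5, 0), radius = 8, delta = -60))), "APD <= 0")
})

test_that("scenario builds are deterministic and internally consistent", {
  cfg <- scenario_config("wt_s4", seed = 7)
  a <- build_scenario(cfg)
  b <- build_scenario(cfg)
  expect_identical(a$map$lat, b$map$lat)
  expect_identical(a$map$lrt, b$map$lrt)
  expect_identical(a$truth, b$truth)
  # pre-noise consistency: LRT - LAT is exactly the APD field
  quiet <- build_scenario(scenario_config("wt_s4", seed = 7,
                                          noise_lat_sd = 0,
                                          noise_lrt_sd = 0))
  expect_equal(quiet$map$lrt - quiet$map$lat, quiet$truth$apd)
  expect_true(all(quiet$truth$lrt > quiet$truth$lat))
  expect_error(scenario_config("wt_s4", bogus = 1), "unknown scenario")
  expect_error(scenario_config("custom", base_speed = -1), "> 0")
})

test_that("generator presets encode the intended substrate contrast", {
  wt <- build_scenario(scenario_config("wt_s4", seed = 11))
  ts <- build_scenario(scenario_config("ts1_s4", seed = 11))
  expect_equal(ts$truth$expected_block_area_cm2, 2 * pi)
  expect_equal(wt$truth$expected_block_area_cm2, 0)
  expect_gt(summarize_map(ts$map)$lat_range_ms,
            summarize_map(wt$map)$lat_range_ms)
})

test_that("synthetic electrogram sets are reproducible and annotatable", {
  mesh <- make_sheet_mesh(4, 4, 6)
  lat <- planar_wave_lat(mesh, c(1, 0, 0), 0.9)
  truth <- list(mesh = mesh, lat = lat, lrt = lat + 230)
  s1 <- synth_egm_set(truth, snr_db = 25, seed = 5)
  s2 <- synth_egm_set(truth, snr_db = 25, seed = 5)
  expect_identical(s1$egms[[7]]$samples_mv, s2$egms[[7]]$samples_mv)
  expect_identical(s1$inverted, s2$inverted)
  s3 <- synth_egm_set(truth, snr_db = 25, seed = 6)
  expect_false(identical(s1$egms[[7]]$samples_mv, s3$egms[[7]]$samples_mv))
  # RNG state of the session is untouched by seeded generation
  set.seed(99); before <- .Random.seed
  invisible(synth_egm_set(truth, snr_db = 25, seed = 5))
  expect_identical(.Random.seed, before)
})
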