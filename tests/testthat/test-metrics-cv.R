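# Closed-form check triangle: planar wave along +x at 1 m/s.
cv_example_map <- function(lat = c(0, 10, 5)) {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8.66, 0)),
                   matrix(1:3, 1))
  build_surface_map(mesh, lat = lat)
}

test_that("the trigonometric estimator reproduces the hand-worked triangle", {
  est <- triangle_cv(cv_example_map())
  expect_true(est$admissible)
  expect_equal(est$theta, pi / 3, tolerance = 1e-3)   # 60 degrees
  expect_equal(est$alpha, 0, tolerance = 1e-12)
  expect_equal(est$v, 1.0, tolerance = 1e-3)
  expect_equal(est$t_a, 10)
  expect_equal(est$t_b, 5)
})

test_that("planar waves are recovered exactly over random admissible triangles", {
  set.seed(101)
  recovered <- 0
  for (i in 1:300) {
    P <- random_triangle()
    dir <- random_inplane_direction(P)
    v_true <- sample(c(0.25, 0.5, 1.0, 2.0), 1)
    lat <- as.numeric(P %*% dir) / v_true
    est <- triangle_cv(build_surface_map(tri_mesh(P, matrix(1:3, 1)),
                                         lat = lat))
    if (!est$admissible) next   # dt bound or wave exiting through bc
    recovered <- recovered + 1
    expect_equal(est$v, v_true, tolerance = 1e-6)
  }
  expect_gt(recovered, 50)
})

test_that("estimates are invariant to vertex relabeling and rigid motion", {
  set.seed(55)
  for (i in 1:25) {
    P <- random_triangle()
    dir <- random_inplane_direction(P)
    lat <- as.numeric(P %*% dir) / 0.7
    est <- triangle_cv(build_surface_map(tri_mesh(P, matrix(1:3, 1)), lat))
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      est_p <- triangle_cv(build_surface_map(
        tri_mesh(P[perm, ], matrix(order(perm), 1)), lat[perm]))
      expect_equal(est_p$admissible, est$admissible)
      if (est$admissible) expect_equal(est_p$v, est$v, tolerance = 1e-9)
    }
    tf <- random_rigid()
    est_r <- triangle_cv(build_surface_map(
      tri_mesh(apply_rigid(P, tf), matrix(1:3, 1)), lat))
    expect_equal(est_r$admissible, est$admissible)
    if (est$admissible) expect_equal(est_r$v, est$v, tolerance = 1e-9)
  }
})

test_that("admissibility bounds reject with the correct reason", {
  # |dLAT| < 3 ms between two vertices
  est <- triangle_cv(cv_example_map(lat = c(0, 0, 8.66)))
  expect_false(est$admissible)
  expect_equal(est$reason, "dt_bound")
  # a 25 mm edge breaks the 3..20 mm distance bound
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(25, 0, 0), c(12, 9, 0)),
                   matrix(1:3, 1))
  est2 <- triangle_cv(build_surface_map(mesh, lat = c(0, 25, 12)))
  expect_equal(est2$reason, "distance_bound")
  # edges shorter than 3 mm are rejected too
  mesh3 <- tri_mesh(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0)),
                    matrix(1:3, 1))
  est3 <- triangle_cv(build_surface_map(mesh3, lat = c(0, 8, 4)))
  expect_equal(est3$reason, "distance_bound")
  # invalid LAT at any vertex
  sm <- suppressWarnings(build_surface_map(
    tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8.66, 0)), matrix(1:3, 1)),
    lat = c(0, 10, NA)))
  expect_equal(triangle_cv(sm)$reason, "invalid_lat")
  # wave leaving through the far edge: |alpha| >= 90 degrees
  esta <- triangle_cv(cv_example_map(lat = c(0, 10, 18)))
  expect_true(esta$reason %in% c("angle_bound", "ok"))
  expect_error(triangle_cv(build_surface_map(cv_example_map()$mesh)),
               "lat")
})

test_that("vertex CV averages admissible incident triangles only", {
  mesh <- make_sheet_mesh(5, 5, 6)
  sm <- build_surface_map(mesh, lat = planar_wave_lat(mesh, c(1, 0.4, 0), 1))
  est <- triangle_cv(sm)
  vcv <- vertex_cv(est, mesh)
  expect_true(all(abs(vcv$values[vcv$valid] - 1) < 1e-6))
  # a map where no triangle is admissible gives an all-invalid field
  sm0 <- build_surface_map(mesh, lat = rep(0, 25))
  vcv0 <- vertex_cv(triangle_cv(sm0), mesh)
  expect_false(any(vcv0$valid))
  # hand mean of two incident speeds
  fake <- triangle_cv(sm)
  fake$v[] <- NA; fake$admissible[] <- FALSE
  fake$v[1:2] <- c(0.4, 0.6); fake$admissible[1:2] <- TRUE
  shared <- intersect(mesh$triangles[1, ], mesh$triangles[2, ])
  vcv2 <- vertex_cv(fake, mesh)
  expect_equal(unique(vcv2$values[shared]), 0.5)
})

test_that("block detection measures slow-patch area and components", {
  cfg <- scenario_config("custom",
    patches = list(list(center = c(39, 39, 0), radius = 10, speed = 0.1)),
    noise_lat_sd = 0, noise_lrt_sd = 0, seed = 1)
  sc <- build_scenario(cfg)
  est <- triangle_cv(sc$map)
  blk <- detect_block(est, sc$map$mesh)
  expect_equal(blk$area_cm2, pi, tolerance = 0.2)
  expect_equal(blk$n_components, 1)
  # homogeneous fast sheet: no block anywhere
  fast <- build_scenario(scenario_config("custom", noise_lat_sd = 0,
                                         noise_lrt_sd = 0, seed = 1))
  blk0 <- detect_block(triangle_cv(fast$map), fast$map$mesh)
  expect_equal(blk0$area_cm2, 0)
  expect_equal(blk0$n_components, 0)
  # two disjoint slow patches -> two components
  cfg2 <- scenario_config("custom",
    patches = list(list(center = c(21, 21, 0), radius = 8, speed = 0.1),
                   list(center = c(57, 57, 0), radius = 8, speed = 0.1)),
    noise_lat_sd = 0, noise_lrt_sd = 0, seed = 1)
  sc2 <- build_scenario(cfg2)
  blk2 <- detect_block(triangle_cv(sc2$map), sc2$map$mesh)
  expect_equal(blk2$n_components, 2)
})

test_that("blocked area grows monotonically with the threshold", {
  cfg <- scenario_config("ts1_s4", seed = 3)
  sc <- build_scenario(cfg)
  est <- triangle_cv(sc$map)
  areas <- vapply(c(0.05, 0.1, 0.2, 0.4, 1.0), function(th)
    detect_block(est, sc$map$mesh, th)$area_cm2, numeric(1))
  expect_true(all(diff(areas) >= 0))
})
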