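#' Scenario configuration for the synthetic map generator
#'
#' Assembles (and validates) the full parameter set that defines a synthetic
#' mapping scenario: mesh geometry, wavefront source, conduction speed field,
#' APD field, annotation noise and seed. Two presets bundle the package's
#' reference conditions:
#' \describe{
#'   \item{\code{wt_s4}}{healthy-substrate S4 map: base CV 0.9 m/s, APD
#'     240 ms, one mild 4-mm slow patch (0.3 m/s), shallow APD heterogeneity.}
#'   \item{\code{ts1_s4}}{severe-substrate S4 map: base CV halved to
#'     0.45 m/s, APD 320 ms, two 10-mm functional-block patches (0.1 m/s)
#'     with co-located steep APD patches (-60 / +40 ms).}
#' }
#' Preset constants are package conventions chosen to echo the qualitative
#' substrate contrasts (halved conduction, larger block, steeper
#' repolarization gradients); they are not fitted to any animal data. Any
#' field can be overridden through \code{...}.
#'
#' @param preset \code{"custom"}, \code{"wt_s4"} or \code{"ts1_s4"}.
#' @param ... overrides for any config field: \code{mesh} (list: sheet
#'   \code{nx, ny, spacing} or icosphere \code{radius, subdivisions}),
#'   \code{source} ("left_edge" or vertex indices), \code{base_speed} (m/s),
#'   \code{patches} (list of \code{list(center, radius, speed)}),
#'   \code{apd_base} (ms), \code{apd_gradient} (ms/mm vector),
#'   \code{apd_patches} (list of \code{list(center, radius, delta)}),
#'   \code{noise_lat_sd}, \code{noise_lrt_sd} (ms), \code{seed}.
#' @return a \code{scenario_config} list.
#' @export
scenario_config <- function(preset = c("custom", "wt_s4", "ts1_s4"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    mesh = list(type = "sheet", nx = 27, ny = 27, spacing = 3),
    source = "left_edge",
    base_speed = 0.9,
    patches = list(),
    apd_base = 240,
    apd_gradient = c(0, 0, 0),
    apd_patches = list(),
    noise_lat_sd = 2,
    noise_lrt_sd = 5,
    seed = 1L)
  if (preset == "wt_s4") {
    cfg$patches <- list(list(center = c(30, 45, 0), radius = 4, speed = 0.3))
    cfg$apd_gradient <- c(0.3, 0, 0)
    cfg$apd_patches <- list(list(center = c(48, 30, 0), radius = 8,
                                 delta = -15))
  } else if (preset == "ts1_s4") {
    cfg$base_speed <- 0.45
    cfg$apd_base <- 320
    cfg$patches <- list(
      list(center = c(30, 24, 0), radius = 10, speed = 0.1),
      list(center = c(48, 54, 0), radius = 10, speed = 0.1))
    cfg$apd_gradient <- c(1.0, 0.5, 0)
    cfg$apd_patches <- list(
      list(center = c(30, 24, 0), radius = 8, delta = -60),
      list(center = c(48, 54, 0), radius = 8, delta = 40))
  }
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  if (cfg$base_speed <= 0) stop("`base_speed` must be > 0")
  if (cfg$apd_base <= 0) stop("`apd_base` must be > 0")
  if (cfg$noise_lat_sd < 0 || cfg$noise_lrt_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (is.null(cfg$seed)) stop("`seed` is mandatory")
  structure(cfg, class = "scenario_config")
}

scenario_mesh <- function(cfg) {
  m <- cfg$mesh
  if (m$type == "sheet") make_sheet_mesh(m$nx, m$ny, m$spacing)
  else if (m$type == "icosphere") make_icosphere(m$radius, m$subdivisions)
  else stop("unknown mesh type: ", m$type)
}

scenario_sources <- function(cfg, mesh) {
  if (is.numeric(cfg$source)) return(as.integer(cfg$source))
  if (identical(cfg$source, "left_edge")) {
    x <- mesh$vertices[, 1]
    return(which(abs(x - min(x)) < 1e-9))
  }
  stop("unknown source specification: ", format(cfg$source))
}

#' Build a synthetic map with ground truth
#'
#' Realizes a scenario: builds the mesh, propagates the activation wavefront
#' through the heterogeneous speed field (graph eikonal from the source set),
#' sets LRT = LAT + APD, then adds independent Gaussian annotation noise
#' (seeded) to LAT and LRT. The pre-noise fields are returned as ground
#' truth; identical configs (including seed) give identical output.
#'
#' @param config a \code{scenario_config}.
#' @return list with \code{map} (a noisy \code{surface_map}) and \code{truth}
#'   (list: \code{mesh}, \code{speed}, \code{lat}, \code{apd}, \code{lrt},
#'   \code{patches}, \code{expected_block_area_cm2} — the summed analytic
#'   area of patches slower than 0.2 m/s).
#' @export
build_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  mesh <- scenario_mesh(config)
  speed <- speed_field(mesh, config$base_speed, config$patches)
  sources <- scenario_sources(config, mesh)
  lat <- eikonal_lat(mesh, speed, sources)
  apd <- make_apd_field(mesh, config$apd_base, config$apd_gradient,
                        config$apd_patches)
  lrt <- lat + apd
  n <- length(lat)
  noisy <- with_seed(config$seed, list(
    lat = lat + stats::rnorm(n, 0, config$noise_lat_sd),
    lrt = lrt + stats::rnorm(n, 0, config$noise_lrt_sd)))
  blocked <- Filter(function(p) p$speed < 0.2, config$patches)
  expected_area <- sum(vapply(blocked, function(p) pi * p$radius^2,
                              numeric(1))) / 100
  map <- suppressWarnings(build_surface_map(
    mesh, lat = noisy$lat, lrt = noisy$lrt,
    meta = list(protocol = "S4", preset = config$preset,
                time_ref = "source_onset", seed = config$seed)))
  list(map = map,
       truth = list(mesh = mesh, speed = speed, lat = lat, apd = apd,
                    lrt = lrt, sources = sources, patches = config$patches,
                    expected_block_area_cm2 = expected_area))
}

# Analytic clean electrogram: an RS-shaped depolarization wavelet whose most
# negative first derivative falls exactly at `lat`, plus a Gaussian T wave
# whose most positive first derivative falls exactly at `lrt` (peak at
# lrt + tau for upright T, nadir at lrt - tau for inverted T).
egm_trace <- function(t, lat, lrt, inverted = FALSE,
                      amp_dep = 1.0, sigma_dep = 4,
                      amp_t = 0.4, tau_t = 12) {
  u <- (t - lat) / sigma_dep
  dep <- -amp_dep * u * exp(-u^2 / 2)
  if (inverted) {
    tw <- -amp_t * exp(-(t - (lrt - tau_t))^2 / (2 * tau_t^2))
  } else {
    tw <- amp_t * exp(-(t - (lrt + tau_t))^2 / (2 * tau_t^2))
  }
  dep + tw
}

#' Synthetic unipolar electrogram set with known annotations
#'
#' One electrogram per vertex of a ground truth: a biphasic depolarization
#' wavelet placing the steepest negative slope analytically at the true LAT,
#' a T wave (upright or inverted per site) placing the maximum positive slope
#' analytically at the true LRT, and optional additive Gaussian noise.
#'
#' @param truth a truth list from \code{\link{build_scenario}}, or any list
#'   with \code{mesh}, \code{lat}, \code{lrt}.
#' @param fs_hz sampling rate (Hz), default 1000.
#' @param noise_sd_mv additive Gaussian noise sd (mV), default 0.
#' @param snr_db if non-NULL, overrides \code{noise_sd_mv} with the sd giving
#'   this signal-to-noise ratio relative to each clean trace's RMS.
#' @param inverted fraction of sites with inverted T waves (drawn with the
#'   seed), or a logical vector per vertex.
#' @param seed RNG seed for polarity draw and noise.
#' @return list with \code{egms} (list of \code{electrogram}, one per vertex,
#'   positions attached), \code{windows} (suitable
#'   \code{annotation_windows}), \code{inverted} (logical per vertex).
#' @export
synth_egm_set <- function(truth, fs_hz = 1000, noise_sd_mv = 0,
                          snr_db = NULL, inverted = 0.25, seed = 1) {
  lat <- truth$lat
  lrt <- truth$lrt
  mesh <- as_tri_mesh(truth$mesh)
  n <- length(lat)
  stopifnot(length(lrt) == n, nrow(mesh$vertices) == n)
  if (fs_hz <= 0) stop("`fs_hz` must be > 0")
  dt <- 1000 / fs_hz
  t0 <- floor(min(lat)) - 60
  t1 <- ceiling(max(lrt)) + 80
  t <- seq(t0, t1, by = dt)
  with_seed(seed, {
    if (is.logical(inverted)) {
      inv <- rep(inverted, length.out = n)
    } else {
      inv <- stats::runif(n) < inverted
    }
    egms <- vector("list", n)
    for (i in seq_len(n)) {
      s <- egm_trace(t, lat[i], lrt[i], inv[i])
      sdv <- if (!is.null(snr_db)) {
        sqrt(mean(s^2)) / 10^(snr_db / 20)
      } else noise_sd_mv
      if (sdv > 0) s <- s + stats::rnorm(length(s), 0, sdv)
      egms[[i]] <- electrogram(s, fs_hz, site_id = i, t_start_ms = t0,
                               position = mesh$vertices[i, ])
    }
    windows <- annotation_windows(
      activation = c(min(lat) - 25, max(lat) + 25),
      repolarization = c(min(lrt) - 45, max(lrt) + 45))
    list(egms = egms, windows = windows, inverted = inv)
  })
}
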