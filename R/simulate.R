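#' Simulation configuration
#'
#' Collects every randomly sampled quantity of the forward simulator into
#' one validated object. The defaults reproduce the training conditions:
#' sample-to-detector distances uniform in 200-300 mm, wavelength 0.9795
#' Angstrom, background scales uniform in 0.01-1.25, a 50/25/25 mixture of
#' 1/2/3 lattices for the overlap task with misorientation spreads drawn
#' from {0.1, 1, 10} degrees and rotational mosaic spread below 0.01
#' degrees. The resolution task simulates single-lattice images whose B
#' factor is set from a target resolution through the B/resolution trend.
#'
#' @param task `"resolution"` (single-lattice images labeled by inverse
#'   resolution) or `"overlap"` (1-3 lattices labeled by overlap boolean).
#' @param detectors Character vector of [detector_preset()] names sampled
#'   uniformly per image. Defaults: PILATUS-6M/EIGER-16M-like for the
#'   resolution task, Rayonix-340-like for the overlap task.
#' @param distance_range Distance range in mm, sampled uniformly.
#' @param wavelength Wavelength in Angstrom (fixed).
#' @param resolution_range Target-resolution band in Angstrom; labels are
#'   drawn uniformly in inverse resolution over this band and converted to a
#'   B factor through `trend`.
#' @param trend The [trend_model()] linking B factor and resolution.
#' @param lattice_probs Named probabilities for 1, 2 and 3 lattices
#'   (must sum to 1). The resolution task forces `c(1, 0, 0)`.
#' @param misorientation_choices Misorientation spreads in degrees; one is
#'   chosen per scene.
#' @param mosaic_range Rotational mosaic-spread range in degrees.
#' @param background_range Background scale range (dimensionless).
#' @param ice_ring_prob Probability that a scene carries sharp ice rings at
#'   3.90/3.67/3.44 Angstrom.
#' @param beamstop_range_mm Beamstop radius range in mm.
#' @param hot_pixel_mean Mean number of hot (saturated) pixels per image.
#' @param bad_region_max Maximum number of rectangular bad-pixel regions.
#' @param beam_jitter_px Beam center is displaced from the detector center
#'   uniformly within this many raw pixels on each axis.
#' @param cell_edges Cubic unit-cell edges (Angstrom) sampled uniformly; a
#'   small discrete library keeps reflection-grid caching effective.
#' @param flux_scale Photon scale of the Bragg spots (expectation of a
#'   unit-amplitude reflection at zero scattering angle).
#' @param spot_sigma_px Gaussian spot profile width in raw pixels.
#' @param read_noise_sd Gaussian electronic noise, detector counts.
#' @param delta_phi Rotation width in degrees (0 = still images).
#' @param bandwidth Fractional spectral bandwidth feeding the excitation
#'   envelope of still images.
#' @param excitation_floor Base excitation width in 1/Angstrom (beam
#'   divergence floor).
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(task = c("resolution", "overlap"),
                              detectors = NULL,
                              distance_range = c(200, 300),
                              wavelength = 0.9795,
                              resolution_range = c(1.3, 5.5),
                              trend = trend_model(),
                              lattice_probs = c(`1` = 0.5, `2` = 0.25, `3` = 0.25),
                              misorientation_choices = c(0.1, 1, 10),
                              mosaic_range = c(0.001, 0.01),
                              background_range = c(0.01, 1.25),
                              ice_ring_prob = 0.1,
                              beamstop_range_mm = c(1, 4),
                              hot_pixel_mean = 20,
                              bad_region_max = 3L,
                              beam_jitter_px = 3,
                              cell_edges = c(60, 70, 80),
                              flux_scale = 1000,
                              spot_sigma_px = 1.2,
                              read_noise_sd = 1,
                              delta_phi = 0,
                              bandwidth = 1e-3,
                              excitation_floor = 3e-4) {
  task <- match.arg(task)
  if (is.null(detectors)) {
    detectors <- if (task == "resolution") c("pilatus6m", "eiger16m") else "rayonix340"
  }
  if (task == "resolution") lattice_probs <- c(`1` = 1, `2` = 0, `3` = 0)
  if (length(lattice_probs) != 3L || any(lattice_probs < 0) ||
      abs(sum(lattice_probs) - 1) > 1e-8) {
    stop("lattice_probs must be 3 non-negative values summing to 1",
         call. = FALSE)
  }
  if (distance_range[1] <= 0 || distance_range[1] > distance_range[2]) {
    stop("malformed distance_range", call. = FALSE)
  }
  if (resolution_range[1] <= 0 || resolution_range[1] > resolution_range[2]) {
    stop("malformed resolution_range", call. = FALSE)
  }
  stopifnot(inherits(trend, "trend_model"))
  structure(
    list(task = task, detectors = detectors, distance_range = distance_range,
         wavelength = wavelength, resolution_range = resolution_range,
         trend = trend, lattice_probs = setNames(as.numeric(lattice_probs),
                                                 c("1", "2", "3")),
         misorientation_choices = misorientation_choices,
         mosaic_range = mosaic_range, background_range = background_range,
         ice_ring_prob = ice_ring_prob, beamstop_range_mm = beamstop_range_mm,
         hot_pixel_mean = hot_pixel_mean,
         bad_region_max = as.integer(bad_region_max),
         beam_jitter_px = beam_jitter_px, cell_edges = cell_edges,
         flux_scale = flux_scale, spot_sigma_px = spot_sigma_px,
         read_noise_sd = read_noise_sd, delta_phi = delta_phi,
         bandwidth = bandwidth, excitation_floor = excitation_floor),
    class = "simulation_config")
}

#' Desk-scale simulation configuration
#'
#' The [simulation_config()] defaults restricted to the small `"toy"`
#' detector, with the resolution band narrowed to 2.3-5.5 Angstrom so that
#' the band straddles the toy detector's edge over the 200-300 mm distance
#' range (close distances resolve the full band; far distances truncate its
#' high-resolution end, as on real detectors).
#'
#' @inheritParams simulation_config
#' @param ... Further arguments passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
toy_config <- function(task = c("resolution", "overlap"), ...) {
  task <- match.arg(task)
  args <- list(...)
  defaults <- list(task = task, detectors = "toy",
                   resolution_range = c(2.3, 5.5),
                   beamstop_range_mm = c(0.5, 2), hot_pixel_mean = 5,
                   bad_region_max = 2L, cell_edges = c(60, 70, 80))
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# uniform random rotation matrix (Arvo's method via quaternion)
random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_mat(q)
}

quat_to_mat <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rotation by `angle_deg` about a uniformly random axis
random_small_rotation <- function(angle_deg) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- angle_deg * pi / 180
  w <- cos(th / 2); v <- ax * sin(th / 2)
  quat_to_mat(c(v, w))
}

#' Sample a fully specified simulation scene
#'
#' Draws every randomized quantity of one exposure from the configured
#' distributions: detector model, distance, beam-center jitter, beamstop
#' size, unit cell, crystal orientation(s), lattice count (50/25/25 mixture
#' of 1/2/3 at the overlap-task defaults), misorientation spread, mosaic
#' spread, B factor (from a target resolution through the trend), background
#' scale, ice rings, hot pixels and bad-pixel regions. The scene records its
#' own seed, so the same `(config, seed)` pair always yields an identical
#' scene and, downstream, an identical image.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for this scene.
#' @return An object of class `sim_scene`.
#' @export
sample_scene <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    det <- detector_preset(sample(config$detectors, 1L))
    distance <- runif(1, config$distance_range[1], config$distance_range[2])
    jf <- runif(1, -config$beam_jitter_px, config$beam_jitter_px)
    js <- runif(1, -config$beam_jitter_px, config$beam_jitter_px)
    beam <- beam_spec(
      wavelength = config$wavelength,
      center_fast = (det$n_fast - 1) / 2 + jf,
      center_slow = (det$n_slow - 1) / 2 + js,
      beamstop_mm = runif(1, config$beamstop_range_mm[1],
                          config$beamstop_range_mm[2]),
      flux_scale = config$flux_scale)
    geometry <- geometry_context(det, beam, distance)

    inv_d <- runif(1, 1 / config$resolution_range[2],
                   1 / config$resolution_range[1])
    d_target <- 1 / inv_d
    B <- b_from_resolution(d_target, config$trend, quiet = TRUE)

    n_lat <- sample(1:3, 1L, prob = config$lattice_probs)
    sigma_mis <- sample(config$misorientation_choices, 1L)
    mosaic <- runif(1, config$mosaic_range[1], config$mosaic_range[2])
    cell_edge <- sample(config$cell_edges, 1L)
    u0 <- random_rotation()
    crystals <- vector("list", n_lat)
    for (i in seq_len(n_lat)) {
      u <- if (i == 1L) u0 else random_small_rotation(abs(rnorm(1, 0, sigma_mis))) %*% u0
      crystals[[i]] <- list(cell_edge = cell_edge, orientation = u,
                            mosaic_deg = mosaic, B = B,
                            amplitude = config$flux_scale)
    }

    n_bad <- sample(0:config$bad_region_max, 1L)
    bad_regions <- lapply(seq_len(n_bad), function(i) {
      h <- sample.int(max(1L, det$n_slow %/% 20), 1L)
      w <- sample.int(max(1L, det$n_fast %/% 20), 1L)
      r0 <- sample.int(det$n_slow - h + 1L, 1L)
      c0 <- sample.int(det$n_fast - w + 1L, 1L)
      c(row = r0, col = c0, height = h, width = w)
    })

    structure(
      list(task = config$task, geometry = geometry,
           ensemble = list(n_lattices = n_lat, sigma_mis = sigma_mis,
                           crystals = crystals),
           B = B, d_target = d_target,
           background_scale = runif(1, config$background_range[1],
                                    config$background_range[2]),
           ice_rings = runif(1) < config$ice_ring_prob,
           hot_pixel_count = rpois(1, config$hot_pixel_mean),
           bad_regions = bad_regions,
           delta_phi = config$delta_phi,
           spot_sigma_px = config$spot_sigma_px,
           read_noise_sd = config$read_noise_sd,
           bandwidth = config$bandwidth,
           excitation_floor = config$excitation_floor,
           trend = config$trend,
           rng_seed = as.integer(seed)),
      class = "sim_scene")
  })
}

# Miller-index grid cache: one integer matrix per (cell edge, q_max) pair
.hkl_cache <- new.env(parent = emptyenv())

hkl_grid <- function(cell_edge, q_max) {
  hmax <- ceiling(cell_edge * q_max)
  key <- paste0(cell_edge, "_", hmax)
  got <- get0(key, envir = .hkl_cache)
  if (!is.null(got)) return(got)
  h <- seq.int(-hmax, hmax)
  g <- as.matrix(expand.grid(h = h, k = h, l = h))
  q2 <- rowSums(g^2) / cell_edge^2
  g <- g[q2 > 0 & q2 <= q_max^2, , drop = FALSE]
  assign(key, g, envir = .hkl_cache)
  g
}

#' Render the Bragg-spot photon expectation of a scene
#'
#' Kinematic forward model: for every lattice, Miller indices within the
#' resolution sphere subtended by the detector corner are enumerated, the
#' excitation error of each reciprocal-lattice point relative to the Ewald
#' sphere is computed, and reflections receive a Gaussian excitation weight
#' (stills) or full weight if they sweep through the sphere within the
#' rotation width. Expected spot intensity is
#' `amplitude * F^2 * exp(-B / (2 d^2)) * weight` with `F^2` drawn from the
#' exponential (Wilson) distribution, and each spot is splatted as a
#' 2-D Gaussian at its projected pixel position. Contributions from all
#' lattices are summed.
#'
#' @param scene A [sample_scene()] result.
#' @return A numeric matrix (slow, fast) of photon expectations, with a
#'   `"spots"` attribute: a tibble of per-reflection `lattice`, `d`,
#'   `weight`, `f2`, `intensity`, `slow_px`, `fast_px`.
#' @export
render_spots <- function(scene) {
  stopifnot(inherits(scene, "sim_scene"))
  geom <- scene$geometry
  det <- geom$detector
  lam <- geom$beam$wavelength
  D <- geom$distance_mm
  p <- det$pixel_mm
  img <- matrix(0, det$n_slow, det$n_fast)

  # widest angle reachable on the detector face: corner farthest from beam
  corner_mm <- p * sqrt(
    max(abs(c(0, det$n_fast - 1) - geom$beam$center_fast))^2 +
    max(abs(c(0, det$n_slow - 1) - geom$beam$center_slow))^2)
  q_max <- min(2 / lam, 1 / resolution_at_radius(corner_mm, D, lam))
  if (!is.finite(q_max) || q_max <= 0 ||
      ceiling(scene$ensemble$crystals[[1]]$cell_edge * q_max) < 1) {
    warning("empty pattern: no reflections reachable for this cell/geometry",
            call. = FALSE)
    attr(img, "spots") <- empty_spot_table()
    return(img)
  }

  spots <- with_seed(scene$rng_seed + 1L, {
    out <- lapply(seq_along(scene$ensemble$crystals), function(i) {
      cr <- scene$ensemble$crystals[[i]]
      lattice_spots(cr, i, scene, q_max)
    })
    dplyr::bind_rows(out)
  })

  if (nrow(spots)) {
    img <- splat_gaussian(img, spots$slow_px, spots$fast_px, spots$intensity,
                          scene$spot_sigma_px)
  }
  attr(img, "spots") <- spots
  img
}

empty_spot_table <- function() {
  tibble::tibble(lattice = integer(), d = numeric(), weight = numeric(),
                 f2 = numeric(), intensity = numeric(), slow_px = numeric(),
                 fast_px = numeric())
}

# excitation, projection and intensity for one lattice of a scene
lattice_spots <- function(cr, lattice_id, scene, q_max) {
  geom <- scene$geometry
  lam <- geom$beam$wavelength
  D <- geom$distance_mm
  p <- geom$detector$pixel_mm
  g <- hkl_grid(cr$cell_edge, q_max)
  qm <- (g %*% t(cr$orientation)) / cr$cell_edge  # reciprocal coords, 1/A
  qlen <- sqrt(rowSums(qm^2))
  s0 <- c(0, 0, 1 / lam)
  sx <- qm[, 1] + s0[1]; sy <- qm[, 2] + s0[2]; sz <- qm[, 3] + s0[3]
  slen <- sqrt(sx^2 + sy^2 + sz^2)
  eps <- slen - 1 / lam

  mosaic_rad <- cr$mosaic_deg * pi / 180
  sigma_e <- scene$excitation_floor + (mosaic_rad + scene$bandwidth / 2) * qlen

  if (scene$delta_phi > 0) {
    # rotation exposure about the fast (x) axis: full-pass acceptance for
    # reflections whose excitation error changes sign across the wedge
    half <- scene$delta_phi / 2 * pi / 180
    eps_at <- function(ang) {
      ca <- cos(ang); sa <- sin(ang)
      qy <- ca * qm[, 2] - sa * qm[, 3]
      qz <- sa * qm[, 2] + ca * qm[, 3]
      sqrt(qm[, 1]^2 + qy^2 + (qz + s0[3])^2) - 1 / lam
    }
    keep <- (eps_at(-half) * eps_at(half) < 0) | (abs(eps) < 3.5 * sigma_e)
    w <- ifelse(eps_at(-half) * eps_at(half) < 0, 1,
                exp(-eps^2 / (2 * sigma_e^2)))
    keep_idx <- which(keep)
  } else {
    keep_idx <- which(abs(eps) < 3.5 * sigma_e)
    w <- exp(-eps^2 / (2 * sigma_e^2))
  }
  if (!length(keep_idx)) return(empty_spot_table())

  kx <- sx[keep_idx]; ky <- sy[keep_idx]; kz <- sz[keep_idx]
  fwd <- kz > 1e-9
  keep_idx <- keep_idx[fwd]
  if (!length(keep_idx)) return(empty_spot_table())
  kx <- kx[fwd]; ky <- ky[fwd]; kz <- kz[fwd]

  x_mm <- D * kx / kz
  y_mm <- D * ky / kz
  fast_px <- geom$beam$center_fast + x_mm / p
  slow_px <- geom$beam$center_slow + y_mm / p
  pad <- 4 * scene$spot_sigma_px
  on_det <- fast_px > -pad & fast_px < geom$detector$n_fast - 1 + pad &
    slow_px > -pad & slow_px < geom$detector$n_slow - 1 + pad
  keep_idx <- keep_idx[on_det]
  if (!length(keep_idx)) return(empty_spot_table())

  d <- 1 / qlen[keep_idx]
  f2 <- rexp(length(keep_idx))
  intensity <- cr$amplitude * f2 * exp(-cr$B / (2 * d^2)) * w[keep_idx]
  tibble::tibble(lattice = lattice_id, d = d, weight = w[keep_idx], f2 = f2,
                 intensity = intensity,
                 slow_px = slow_px[on_det], fast_px = fast_px[on_det])
}

# accumulate photon-conserving 2-D Gaussian stamps at subpixel positions
splat_gaussian <- function(img, slow_px, fast_px, intensity, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  R <- max(1L, ceiling(3 * sigma))
  off <- seq.int(-R, R)
  r0 <- round(slow_px); c0 <- round(fast_px)
  n <- length(slow_px)
  k <- length(off)
  # separable truncated-Gaussian stamp weights, normalized to conserve
  # photons per spot
  wr <- exp(-(outer(r0 - slow_px, off, `+`))^2 / (2 * sigma^2))
  wc <- exp(-(outer(c0 - fast_px, off, `+`))^2 / (2 * sigma^2))
  ir <- rep(seq_len(k), times = k)
  ic <- rep(seq_len(k), each = k)
  wmat <- wr[, ir, drop = FALSE] * wc[, ic, drop = FALSE]
  wmat <- wmat / rowSums(wmat) * intensity
  rows <- rep(r0, k * k) + rep(off[ir], each = n)
  cols <- rep(c0, k * k) + rep(off[ic], each = n)
  vals <- as.vector(wmat)
  ok <- rows >= 0 & rows < nr & cols >= 0 & cols < nc
  idx <- rows[ok] + nr * cols[ok] + 1
  vals <- vals[ok]
  # plain img[idx] <- img[idx] + vals drops duplicate hits; peel duplicates
  while (length(idx)) {
    dup <- duplicated(idx)
    first <- idx[!dup]
    img[first] <- img[first] + vals[!dup]
    idx <- idx[dup]
    vals <- vals[dup]
  }
  img
}

#' Add radially symmetric background scatter
#'
#' Adds `background_scale` times a fixed radial profile: a steep low-angle
#' falloff (direct-beam halo and solvent small-angle scatter) plus a broad
#' diffuse ring centered near 3.7 Angstrom (the water ring). When the scene
#' carries ice rings, three sharp rings at 3.90, 3.67 and 3.44 Angstrom are
#' superimposed. The added component is linear in `background_scale`.
#'
#' @param image Photon-expectation matrix from [render_spots()].
#' @param scene The scene that produced it.
#' @return The image plus background, `"spots"` attribute preserved.
#' @export
add_background <- function(image, scene) {
  stopifnot(inherits(scene, "sim_scene"))
  b <- scene$background_scale
  if (b == 0) return(image)
  geom <- scene$geometry
  det <- geom$detector
  r_px <- pixel_radius_grid(det$n_slow, det$n_fast,
                            geom$beam$center_slow, geom$beam$center_fast)
  stol <- sin(0.5 * atan(r_px * det$pixel_mm / geom$distance_mm)) /
    geom$beam$wavelength  # sin(theta)/lambda = 1/(2d)
  prof <- background_profile(stol, ice = scene$ice_rings)
  out <- image + b * prof
  attr(out, "spots") <- attr(image, "spots")
  out
}

# unit-scale radial background profile in photons, argument sin(theta)/lambda
background_profile <- function(stol, ice = FALSE) {
  base_amp <- 40
  low_angle <- 2 * exp(-stol / 0.05)
  water <- exp(-(stol - 1 / (2 * 3.7))^2 / (2 * 0.02^2))
  prof <- base_amp * (low_angle + water)
  if (ice) {
    for (d_ice in c(3.90, 3.67, 3.44)) {
      prof <- prof + 4 * base_amp *
        exp(-(stol - 1 / (2 * d_ice))^2 / (2 * 0.0025^2))
    }
  }
  prof
}

#' Detector response: noise, masks, saturation
#'
#' Converts a photon-expectation image into recorded counts: Poisson photon
#' counting scaled by the detector gain plus Gaussian electronic noise,
#' rounded to integers and clipped to `[0, saturation]`. Pixels behind the
#' beamstop are set to 0, bad-pixel regions to the mask sentinel `-1`, and
#' the scene's hot pixels to the saturation value.
#'
#' @param image Non-negative photon-expectation matrix.
#' @param scene The scene (provides gain, read noise, masks, seed).
#' @param noise Set `FALSE` to skip Poisson/Gaussian sampling (masks are
#'   still applied); used for noise-free diagnostics.
#' @return An integer-valued matrix of detector counts.
#' @export
apply_detector <- function(image, scene, noise = TRUE) {
  stopifnot(inherits(scene, "sim_scene"))
  if (any(image < 0)) {
    stop("internal error: negative photon expectations", call. = FALSE)
  }
  geom <- scene$geometry
  det <- geom$detector
  out <- with_seed(scene$rng_seed + 2L, {
    v <- as.vector(image)
    if (noise) {
      v <- rpois(length(v), v) * det$gain
      if (scene$read_noise_sd > 0) {
        v <- v + rnorm(length(v), 0, scene$read_noise_sd)
      }
    } else {
      v <- v * det$gain
    }
    v <- round(v)
    v[v < 0] <- 0
    v[v > det$saturation] <- det$saturation
    m <- matrix(v, det$n_slow, det$n_fast)

    # beamstop shadow
    if (geom$beam$beamstop_mm > 0) {
      r_stop_px <- geom$beam$beamstop_mm / det$pixel_mm
      r_px <- pixel_radius_grid(det$n_slow, det$n_fast,
                                geom$beam$center_slow, geom$beam$center_fast)
      m[r_px <= r_stop_px] <- 0
    }
    for (reg in scene$bad_regions) {
      m[reg["row"]:(reg["row"] + reg["height"] - 1L),
        reg["col"]:(reg["col"] + reg["width"] - 1L)] <- -1
    }
    if (scene$hot_pixel_count > 0) {
      hot <- sample.int(length(m), scene$hot_pixel_count)
      m[hot] <- det$saturation
    }
    storage.mode(m) <- "integer"
    m
  })
  out
}

#' Simulate one labeled diffraction image
#'
#' Full pipeline `scene -> spots -> background -> detector`, with ground
#' truth attached: the inverse resolution implied by the scene's B factor
#' through the trend (a B factor realizing 2 Angstrom labels the image
#' 0.5 1/Angstrom), the lattice count and the overlap boolean
#' (`n_lattices > 1`).
#'
#' @param config A [simulation_config()].
#' @param seed Scene seed.
#' @param noise Passed to [apply_detector()].
#' @return An object of class `labeled_image`: list with `pixels` (integer
#'   matrix), `labels` (one-row tibble: `inverse_resolution`, `B`,
#'   `n_lattices`, `is_overlapped`, `seed`) and `scene`.
#' @export
make_labeled_example <- function(config, seed, noise = TRUE) {
  scene <- sample_scene(config, seed)
  img <- render_spots(scene)
  img <- add_background(img, scene)
  pixels <- apply_detector(img, scene, noise = noise)
  d <- as.numeric(resolution_from_b(scene$B, scene$trend))
  structure(
    list(pixels = pixels,
         labels = tibble::tibble(
           inverse_resolution = 1 / d, B = scene$B,
           n_lattices = scene$ensemble$n_lattices,
           is_overlapped = scene$ensemble$n_lattices > 1L,
           seed = as.integer(seed)),
         scene = scene),
    class = "labeled_image")
}

#' Simulate a labeled image set
#'
#' @param config A [simulation_config()].
#' @param n Number of images.
#' @param seed Master seed; per-image seeds are derived from it and recorded
#'   in the label table and manifest.
#' @param noise Passed through to [apply_detector()].
#' @return An object of class `image_set`: list with `images` (list of
#'   integer matrices), `labels` (tibble), `geometries` (list of
#'   [geometry_context()]), `seeds`.
#' @export
simulate_image_set <- function(config, n, seed = 1L, noise = TRUE) {
  seeds <- derive_seeds(seed, n)
  examples <- lapply(seeds, function(s) make_labeled_example(config, s, noise))
  structure(
    list(images = lapply(examples, `[[`, "pixels"),
         labels = dplyr::bind_rows(lapply(examples, `[[`, "labels")),
         geometries = lapply(examples, function(e) e$scene$geometry),
         seeds = seeds),
    class = "image_set")
}

#' Write / read an image-set container
#'
#' The on-disk container is a directory holding `labels.csv`, one
#' `geometry_<i>.yaml` per distinct geometry (with an index column in the
#' labels), a `manifest.txt` of per-image seeds, and the pixel stack
#' (`images.rds`, run-time serialized).
#'
#' @param x An `image_set`.
#' @param dir Directory to create/read.
#' @return `write_image_set()` returns `dir` invisibly; `read_image_set()`
#'   returns an `image_set`.
#' @export
write_image_set <- function(x, dir) {
  stopifnot(inherits(x, "image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  writeLines(as.character(x$seeds), file.path(dir, "manifest.txt"))
  for (i in seq_along(x$geometries)) {
    write_geometry_config(x$geometries[[i]],
                          file.path(dir, sprintf("geometry_%04d.yaml", i)))
  }
  saveRDS(x$images, file.path(dir, "images.rds"))
  invisible(dir)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(dir) {
  labels <- tibble::as_tibble(utils::read.csv(file.path(dir, "labels.csv")))
  seeds <- as.integer(readLines(file.path(dir, "manifest.txt")))
  geo_files <- sort(list.files(dir, pattern = "^geometry_\\d+\\.yaml$",
                               full.names = TRUE))
  structure(
    list(images = readRDS(file.path(dir, "images.rds")),
         labels = labels,
         geometries = lapply(geo_files, read_geometry_config),
         seeds = seeds),
    class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d images, %d overlapped, 1/d in [%.3f, %.3f] 1/A\n",
              length(x$images), sum(x$labels$is_overlapped),
              min(x$labels$inverse_resolution),
              max(x$labels$inverse_resolution)))
  invisible(x)
}

#' Count diffraction peaks by brute force
#'
#' Local maxima over 3 x 3 neighborhoods whose value exceeds `threshold`.
#' Intended for diagnostics (e.g. comparing spot counts of single- and
#' multi-lattice renders), not as a production spot finder.
#'
#' @param image Numeric matrix.
#' @param threshold Minimum value for a peak.
#' @return Integer count of local maxima.
#' @export
count_peaks <- function(image, threshold) {
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3L || nc < 3L) return(0L)
  ctr <- image[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- image[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
    is_max <- is_max & (ctr >= nb)
  }
  sum(is_max)
}
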