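#' Detector description
#'
#' A flat, normally incident single-panel detector. Real multi-panel cameras
#' are handled upstream by casting them to one two-dimensional array; here a
#' detector is fully described by its pixel grid, pixel pitch, block-max
#' downsampling factor and response constants.
#'
#' @param name Identifier string.
#' @param n_fast,n_slow Number of pixels along the fast and slow axes.
#' @param pixel_mm Pixel pitch in mm (square pixels).
#' @param downsample Block-max downsampling factor `N` used by the
#'   conditioning stage; shipped presets use 2 or 4.
#' @param gain Detector units recorded per photon.
#' @param saturation Count value at which pixels clip.
#'
#' @return An object of class `detector_spec`.
#' @seealso [detector_preset()] for the shipped detector models.
#' @export
detector_spec <- function(name, n_fast, n_slow, pixel_mm, downsample = 2L,
                          gain = 1, saturation = 65535) {
  stopifnot(is.character(name), length(name) == 1L)
  n_fast <- as.integer(n_fast); n_slow <- as.integer(n_slow)
  downsample <- as.integer(downsample)
  if (n_fast < 1L || n_slow < 1L) stop("pixel counts must be >= 1", call. = FALSE)
  if (downsample < 1L) stop("downsample factor must be >= 1", call. = FALSE)
  if (pixel_mm <= 0) stop("pixel_mm must be positive", call. = FALSE)
  if (gain <= 0) stop("gain must be positive", call. = FALSE)
  structure(
    list(name = name, n_fast = n_fast, n_slow = n_slow, pixel_mm = pixel_mm,
         downsample = downsample, gain = gain, saturation = saturation),
    class = "detector_spec")
}

#' Incident-beam description
#'
#' @param wavelength Wavelength in Angstrom.
#' @param center_fast,center_slow Beam-center position in raw-pixel units
#'   (0-based, measured from the first pixel center).
#' @param beamstop_mm Radius of the circular beamstop shadow in mm (0 for none).
#' @param flux_scale Expected photon count of the strongest reflection;
#'   only used by the simulator.
#'
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(wavelength = 0.9795, center_fast, center_slow,
                      beamstop_mm = 0, flux_scale = 1000) {
  if (wavelength <= 0) stop("wavelength must be positive", call. = FALSE)
  if (beamstop_mm < 0) stop("beamstop_mm must be >= 0", call. = FALSE)
  structure(
    list(wavelength = wavelength, center_fast = center_fast,
         center_slow = center_slow, beamstop_mm = beamstop_mm,
         flux_scale = flux_scale),
    class = "beam_spec")
}

#' Combine detector, beam and sample-to-detector distance
#'
#' @param detector A [detector_spec()].
#' @param beam A [beam_spec()]; defaults to a beam centered on the detector.
#' @param distance_mm Sample-to-detector distance in mm.
#'
#' @return An object of class `geometry_context`.
#' @export
geometry_context <- function(detector, beam = NULL, distance_mm) {
  stopifnot(inherits(detector, "detector_spec"))
  if (is.null(beam)) {
    beam <- beam_spec(center_fast = (detector$n_fast - 1) / 2,
                      center_slow = (detector$n_slow - 1) / 2)
  }
  stopifnot(inherits(beam, "beam_spec"))
  if (distance_mm <= 0) stop("distance_mm must be positive", call. = FALSE)
  margin <- 0.25
  if (beam$center_fast < -margin * detector$n_fast ||
      beam$center_fast > (1 + margin) * detector$n_fast ||
      beam$center_slow < -margin * detector$n_slow ||
      beam$center_slow > (1 + margin) * detector$n_slow) {
    stop("beam center lies too far off the detector face", call. = FALSE)
  }
  structure(list(detector = detector, beam = beam, distance_mm = distance_mm),
            class = "geometry_context")
}

#' Shipped detector presets
#'
#' Four single-panel detector models: large-area photon counters resembling
#' the PILATUS 6M (N = 2) and EIGER 16M (N = 4), an integrating Rayonix-340
#' style camera (N = 4), and a small `"toy"` detector (512 x 512 raw pixels,
#' N = 2) sized for desk-scale simulation and training runs.
#'
#' @param name One of `"pilatus6m"`, `"eiger16m"`, `"rayonix340"`, `"toy"`.
#' @return A [detector_spec()].
#' @export
detector_preset <- function(name = c("pilatus6m", "eiger16m", "rayonix340", "toy")) {
  name <- match.arg(name)
  switch(name,
    pilatus6m = detector_spec("pilatus6m", 2463L, 2527L, 0.172, 2L,
                              gain = 1, saturation = 1048575),
    eiger16m = detector_spec("eiger16m", 4148L, 4362L, 0.075, 4L,
                             gain = 1, saturation = 65535),
    rayonix340 = detector_spec("rayonix340", 3840L, 3840L, 0.0885, 4L,
                               gain = 1.8, saturation = 65535),
    toy = detector_spec("toy", 512L, 512L, 0.35, 2L, gain = 1,
                        saturation = 65535))
}

#' Bragg resolution at a radial detector position
#'
#' Converts a radial distance from the beam center on a flat detector at
#' normal incidence into the Bragg resolution `d = lambda / (2 sin theta)`
#' with `2 theta = arctan(r / D)`. Forward scattering (`r = 0`) carries no
#' resolution bound and is reported as `Inf` so that vectorized maps are
#' total.
#'
#' @param r_mm Radial distance(s) from the beam center, mm.
#' @param distance_mm Sample-to-detector distance, mm.
#' @param wavelength Wavelength, Angstrom.
#' @return Resolution(s) in Angstrom; `Inf` at `r = 0`.
#' @export
resolution_at_radius <- function(r_mm, distance_mm, wavelength) {
  if (distance_mm <= 0 || wavelength <= 0) {
    stop("invalid geometry: distance and wavelength must be positive",
         call. = FALSE)
  }
  if (any(r_mm < 0)) stop("radius must be >= 0", call. = FALSE)
  d <- wavelength / (2 * sin(0.5 * atan(r_mm / distance_mm)))
  d[r_mm == 0] <- Inf
  d
}

#' Radial detector position of a Bragg resolution
#'
#' Inverse of [resolution_at_radius()]: `r = D tan(2 arcsin(lambda / 2d))`.
#'
#' @inheritParams resolution_at_radius
#' @param d Resolution(s), Angstrom. Must satisfy `d >= lambda / 2` for the
#'   Bragg condition to be solvable.
#' @return Radius in mm.
#' @export
radius_at_resolution <- function(d, distance_mm, wavelength) {
  if (distance_mm <= 0 || wavelength <= 0) {
    stop("invalid geometry: distance and wavelength must be positive",
         call. = FALSE)
  }
  if (any(d < wavelength / 2)) {
    stop("unreachable resolution: d < lambda/2 cannot satisfy the Bragg condition",
         call. = FALSE)
  }
  distance_mm * tan(2 * asin(wavelength / (2 * d)))
}

#' Per-pixel resolution map
#'
#' Resolution of every pixel of a geometry context, computed from each pixel
#' center's radial distance to the beam center. With `downsampled = TRUE` the
#' map is computed on the block-pixel grid using the effective pitch
#' `pixel_mm * N` and the beam center rescaled accordingly.
#'
#' @param ctx A [geometry_context()].
#' @param downsampled Compute on the downsampled grid?
#' @return A numeric matrix (slow x fast) of resolutions in Angstrom; the
#'   pixel containing the beam center maps to `Inf`.
#' @export
pixel_resolution_map <- function(ctx, downsampled = FALSE) {
  stopifnot(inherits(ctx, "geometry_context"))
  det <- ctx$detector
  if (downsampled) {
    n_fast <- ceiling(det$n_fast / det$downsample)
    n_slow <- ceiling(det$n_slow / det$downsample)
    p <- det$pixel_mm * det$downsample
    cf <- ctx$beam$center_fast / det$downsample
    cs <- ctx$beam$center_slow / det$downsample
  } else {
    n_fast <- det$n_fast; n_slow <- det$n_slow; p <- det$pixel_mm
    cf <- ctx$beam$center_fast; cs <- ctx$beam$center_slow
  }
  r <- pixel_radius_grid(n_slow, n_fast, cs, cf) * p
  m <- resolution_at_radius(r, ctx$distance_mm, ctx$beam$wavelength)
  matrix(m, nrow = n_slow, ncol = n_fast)
}

# radius (in pixel units) of every pixel center from (cs, cf), 0-based
pixel_radius_grid <- function(n_slow, n_fast, cs, cf) {
  ds2 <- (seq_len(n_slow) - 1 - cs)^2
  df2 <- (seq_len(n_fast) - 1 - cf)^2
  sqrt(outer(ds2, df2, `+`))
}

#' Serialize / read a geometry context as a flat key-value config
#'
#' The on-disk form is a flat YAML mapping with dotted keys
#' (`detector.name`, `detector.nfast`, `detector.nslow`, `detector.pixel_mm`,
#' `detector.downsample`, `beam.wavelength_A`, `beam.center_fast_px`,
#' `beam.center_slow_px`, `distance_mm`, plus optional `beam.beamstop_mm`,
#' `detector.gain`, `detector.saturation`).
#'
#' @param ctx A [geometry_context()].
#' @param path File to write to / read from.
#' @return `write_geometry_config()` returns `path` invisibly;
#'   `read_geometry_config()` returns a [geometry_context()].
#' @export
write_geometry_config <- function(ctx, path) {
  stopifnot(inherits(ctx, "geometry_context"))
  cfg <- list(
    "detector.name" = ctx$detector$name,
    "detector.nfast" = ctx$detector$n_fast,
    "detector.nslow" = ctx$detector$n_slow,
    "detector.pixel_mm" = ctx$detector$pixel_mm,
    "detector.downsample" = ctx$detector$downsample,
    "detector.gain" = ctx$detector$gain,
    "detector.saturation" = ctx$detector$saturation,
    "beam.wavelength_A" = ctx$beam$wavelength,
    "beam.center_fast_px" = ctx$beam$center_fast,
    "beam.center_slow_px" = ctx$beam$center_slow,
    "beam.beamstop_mm" = ctx$beam$beamstop_mm,
    "distance_mm" = ctx$distance_mm)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_geometry_config
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("detector.name", "detector.nfast", "detector.nslow",
            "detector.pixel_mm", "detector.downsample", "beam.wavelength_A",
            "beam.center_fast_px", "beam.center_slow_px", "distance_mm")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("geometry config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  det <- detector_spec(cfg[["detector.name"]], cfg[["detector.nfast"]],
                       cfg[["detector.nslow"]], cfg[["detector.pixel_mm"]],
                       cfg[["detector.downsample"]],
                       gain = cfg[["detector.gain"]] %||% 1,
                       saturation = cfg[["detector.saturation"]] %||% 65535)
  beam <- beam_spec(cfg[["beam.wavelength_A"]], cfg[["beam.center_fast_px"]],
                    cfg[["beam.center_slow_px"]],
                    beamstop_mm = cfg[["beam.beamstop_mm"]] %||% 0)
  geometry_context(det, beam, cfg[["distance_mm"]])
}

#' @export
print.geometry_context <- function(x, ...) {
  cat(sprintf("<geometry_context> %s %dx%d px @ %.4g mm/px (N=%d)\n",
              x$detector$name, x$detector$n_slow, x$detector$n_fast,
              x$detector$pixel_mm, x$detector$downsample))
  cat(sprintf("  lambda %.4f A, distance %.1f mm, beam center (%.1f, %.1f) px\n",
              x$beam$wavelength, x$distance_mm,
              x$beam$center_fast, x$beam$center_slow))
  invisible(x)
}
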