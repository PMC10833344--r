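test_that("scene sampling honors degenerate distributions and is deterministic", {
  cfg <- toy_config("overlap", lattice_probs = c(`1` = 1, `2` = 0, `3` = 0))
  for (s in 1:20) {
    expect_equal(sample_scene(cfg, s)$ensemble$n_lattices, 1L)
  }
  cfg2 <- toy_config("overlap")
  expect_identical(sample_scene(cfg2, 77), sample_scene(cfg2, 77))
  expect_false(identical(sample_scene(cfg2, 77), sample_scene(cfg2, 78)))
})

test_that("malformed configurations are rejected", {
  expect_error(simulation_config("overlap",
                                 lattice_probs = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(simulation_config(distance_range = c(300, 200)), "distance")
  expect_error(simulation_config(resolution_range = c(-1, 3)), "resolution")
})

test_that("the resolution task always produces single-lattice scenes", {
  cfg <- toy_config("resolution")
  expect_equal(unname(cfg$lattice_probs), c(1, 0, 0))
})

test_that("expected spot intensities carry the exact Debye-Waller factor", {
  cfg <- quiet_toy_config()
  sc <- sample_scene(cfg, 5)
  sp <- attr(render_spots(sc), "spots")
  expect_gt(nrow(sp), 20)
  # intensity / (amplitude * F^2 * excitation weight) == exp(-B / (2 d^2))
  dw <- sp$intensity / (sc$ensemble$crystals[[1]]$amplitude * sp$f2 * sp$weight)
  expect_equal(dw, exp(-sc$B / (2 * sp$d^2)), tolerance = 1e-12)
  # pairwise ratio of two equal-F^2 reflections is the closed form
  i1 <- 1L; i2 <- nrow(sp)
  ratio <- (sp$intensity[i1] / sp$f2[i1] / sp$weight[i1]) /
    (sp$intensity[i2] / sp$f2[i2] / sp$weight[i2])
  expect_equal(ratio,
               exp(-(sc$B / 2) * (1 / sp$d[i1]^2 - 1 / sp$d[i2]^2)),
               tolerance = 1e-12)
})

test_that("background is absent at zero scale, linear, and azimuthally flat", {
  cfg <- quiet_toy_config()
  sc <- sample_scene(cfg, 9)
  img <- matrix(0, 512, 512)
  sc$background_scale <- 0
  expect_identical(add_background(img, sc), img)

  sc$background_scale <- 0.4
  b1 <- add_background(img, sc)
  sc$background_scale <- 0.8
  b2 <- add_background(img, sc)
  expect_equal(2 * b1, b2, tolerance = 1e-12)

  # azimuthal flatness: coefficient of variation of shell means is tiny
  geom <- sc$geometry
  r <- sqrt(outer((0:511 - geom$beam$center_slow / 1)^2,
                  (0:511 - geom$beam$center_fast / 1)^2, `+`))
  shell <- cut(r, seq(10, 240, by = 10))
  for (sh in levels(shell)[c(2, 10, 20)]) {
    px <- b1[!is.na(shell) & shell == sh]
    wedge <- atan2(row(b1)[!is.na(shell) & shell == sh] - geom$beam$center_slow,
                   col(b1)[!is.na(shell) & shell == sh] - geom$beam$center_fast)
    m <- tapply(px, cut(wedge, 8), mean)
    expect_lt(stats::sd(m) / mean(m), 0.01)
  }
})

test_that("detector response reproduces expectation, masks and saturation", {
  cfg <- quiet_toy_config()
  sc <- sample_scene(cfg, 21)
  sc$read_noise_sd <- 0

  # zero expectation, zero read noise: all-zero image
  z <- apply_detector(matrix(0, 512, 512), sc)
  expect_true(all(z == 0))

  # constant expectation: sample mean matches expectation * gain within 3 SE
  mu <- 7.3
  counts <- apply_detector(matrix(mu, 512, 512), sc)
  se <- sqrt(mu / length(counts))
  expect_lt(abs(mean(counts) - mu * sc$geometry$detector$gain), 3 * se)

  # beamstop zeros, bad regions -1, hot pixels saturated
  sc2 <- sample_scene(toy_config("resolution", background_range = c(0, 0)), 22)
  sc2$read_noise_sd <- 0
  counts2 <- apply_detector(matrix(mu, 512, 512), sc2)
  geom <- sc2$geometry
  if (geom$beam$beamstop_mm > 0) {
    r_px <- geom$beam$beamstop_mm / geom$detector$pixel_mm
    inside <- which(sqrt(outer((0:511 - geom$beam$center_slow)^2,
                               (0:511 - geom$beam$center_fast)^2, `+`)) <=
                      r_px, arr.ind = TRUE)
    expect_true(all(counts2[inside] == 0))
  }
  for (reg in sc2$bad_regions) {
    expect_true(all(counts2[reg["row"]:(reg["row"] + reg["height"] - 1),
                            reg["col"]:(reg["col"] + reg["width"] - 1)] == -1))
  }
  expect_gte(sum(counts2 == geom$detector$saturation), 0)
  expect_error(apply_detector(matrix(-1, 2, 2), sc), "negative")
})

test_that("labels are consistent with the scene ground truth", {
  cfg <- toy_config("overlap", misorientation_choices = 10)
  seeds <- 1:12
  for (s in seeds) {
    ex <- make_labeled_example(cfg, s)
    expect_identical(ex$labels$is_overlapped, ex$labels$n_lattices > 1L)
    expect_equal(ex$labels$inverse_resolution,
                 1 / as.numeric(resolution_from_b(ex$labels$B, cfg$trend)),
                 tolerance = 1e-12)
  }
})

test_that("the full pipeline is byte-deterministic under a fixed seed", {
  cfg <- toy_config("resolution")
  a <- make_labeled_example(cfg, 1234)
  b <- make_labeled_example(cfg, 1234)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$labels, b$labels)
})

test_that("image-set containers round-trip through the on-disk layout", {
  cfg <- quiet_toy_config()
  iset <- simulate_image_set(cfg, 3, seed = 8)
  expect_length(iset$images, 3)
  expect_equal(nrow(iset$labels), 3)
  dir <- withr::local_tempdir()
  write_image_set(iset, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  back <- read_image_set(dir)
  expect_identical(back$images, iset$images)
  expect_equal(back$labels$inverse_resolution, iset$labels$inverse_resolution)
  expect_equal(back$seeds, iset$seeds)
  expect_equal(back$geometries[[2]]$distance_mm,
               iset$geometries[[2]]$distance_mm, tolerance = 1e-6)
})

test_that("the brute-force peak counter finds isolated local maxima", {
  img <- matrix(0, 9, 9)
  img[3, 3] <- 10; img[7, 6] <- 4; img[7, 7] <- 3
  expect_equal(count_peaks(img, 1), 2L)
  expect_equal(count_peaks(img, 5), 1L)
})

test_that("multi-lattice scenes multiply the rendered peak count", {
  one <- quiet_toy_config("overlap", lattice_probs = c(`1` = 1, `2` = 0, `3` = 0),
                          misorientation_choices = 10)
  three <- quiet_toy_config("overlap", lattice_probs = c(`1` = 0, `2` = 0, `3` = 1),
                            misorientation_choices = 10)
  n1 <- mean(sapply(1:4, function(s) count_peaks(render_spots(sample_scene(one, s)), 1)))
  n3 <- mean(sapply(1:4, function(s) count_peaks(render_spots(sample_scene(three, s)), 1)))
  expect_gt(n3 / n1, 2)
})
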