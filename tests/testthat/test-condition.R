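# independent straight-line reference for the pooling/quantization steps
brute_maxpool <- function(raw, N) {
  nr <- ceiling(nrow(raw) / N); nc <- ceiling(ncol(raw) / N)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- ((i - 1) * N + 1):min(i * N, nrow(raw))
    cols <- ((j - 1) * N + 1):min(j * N, ncol(raw))
    out[i, j] <- max(raw[rows, cols])
  }
  out
}

test_that("block-max pooling reduces blocks to their maxima", {
  expect_equal(maxpool_downsample(matrix(c(4, 2, 9, 1), 2, 2), 2),
               matrix(9, 1, 1))
  const <- matrix(7, 8, 12)
  expect_equal(maxpool_downsample(const, 4), matrix(7, 2, 3))
  expect_identical(maxpool_downsample(const, 1), const)
  expect_error(maxpool_downsample(const, 0), "positive")
  expect_error(maxpool_downsample(matrix(numeric(0), 0, 0), 2), "non-empty")
})

test_that("pooling matches a nested-loop oracle on odd shapes with sentinels", {
  set.seed(3)
  for (N in c(2L, 4L)) {
    for (rep in 1:5) {
      raw <- matrix(rpois(17 * 13, 40), 17, 13)
      raw[sample(length(raw), 25)] <- -1
      expect_equal(maxpool_downsample(raw, N), brute_maxpool(raw, N))
    }
  }
  # a fully masked block stays masked
  raw <- matrix(5, 4, 4); raw[1:2, 1:2] <- -1
  expect_equal(maxpool_downsample(raw, 2)[1, 1], -1)
})

test_that("pooling is monotone: raising a raw pixel never lowers output", {
  set.seed(5)
  raw <- matrix(rpois(20 * 22, 10), 20, 22)
  base <- maxpool_downsample(raw, 4)
  for (rep in 1:20) {
    raw2 <- raw
    k <- sample(length(raw), 1)
    raw2[k] <- raw2[k] + sample(1:50, 1)
    expect_true(all(maxpool_downsample(raw2, 4) >= base))
  }
})

test_that("square-root quantization floors and passes the mask through", {
  expect_equal(sqrt_quantize(matrix(c(9, 8, 0, -1), 2, 2)),
               matrix(c(3, 2, 0, -1), 2, 2))
  expect_error(sqrt_quantize(matrix(c(1, -0.5), 1, 2)), "sentinel")
})

test_that("quadrants are always 512x512 with the beam center at element (1,1)", {
  ctx <- geometry_context(detector_preset("toy"),
                          beam_spec(0.9795, 255, 259), 250)
  raw <- matrix(rpois(512 * 512, 5), 512, 512)
  qs <- condition_image(raw, ctx)
  expect_named(qs, c("UL", "UR", "LL", "LR"))
  for (q in qs) expect_equal(dim(q$pixels), c(512L, 512L))
  # element (1,1) of each quadrant is the conditioned beam-center pixel
  ds <- sqrt_quantize(maxpool_downsample(raw, 2))
  bc <- ds[floor(259 / 2) + 1, floor(255 / 2) + 1]  # low-side anchor
  expect_equal(qs$UL$pixels[1, 1], bc)
  # padding beyond the toy detector's 256x256 downsampled extent is zero
  expect_true(all(qs$LR$pixels[200:512, 200:512] == 0))
  expect_equal(qs$UL$effective_pixel_mm, 0.7)
})

test_that("a point-symmetric pattern yields four identical quadrants", {
  n <- 31L
  det <- detector_spec("sym", n, n, 0.1, 1L)
  ctx <- geometry_context(det, beam_spec(1, (n - 1) / 2, (n - 1) / 2), 100)
  r <- sqrt(outer((0:(n - 1) - 15)^2, (0:(n - 1) - 15)^2, `+`))
  img <- round(100 * exp(-r / 6))
  qs <- extract_quadrants(img, ctx, size = 16L)
  expect_equal(qs$UR$pixels, qs$UL$pixels)
  expect_equal(qs$LL$pixels, qs$UL$pixels)
  expect_equal(qs$LR$pixels, qs$UL$pixels)
})

test_that("a centered 1024x1024 image is tiled exactly by its quadrants", {
  det <- detector_spec("even", 1024L, 1024L, 0.1, 1L)
  # beam center on the array center: between pixels 511 and 512 (0-based)
  ctx <- geometry_context(det, beam_spec(1, 511.5, 511.5), 100)
  set.seed(9)
  img <- matrix(rpois(1024^2, 3), 1024, 1024)
  qs <- extract_quadrants(img, ctx)
  rebuilt <- rbind(
    cbind(qs$UL$pixels[512:1, 512:1], qs$UR$pixels[512:1, ]),
    cbind(qs$LL$pixels[, 512:1], qs$LR$pixels))
  expect_equal(rebuilt, img, ignore_attr = TRUE)
})

test_that("an off-detector beam center is a geometry error", {
  det <- detector_spec("t", 64L, 64L, 0.1, 1L)
  ctx <- geometry_context(det, beam_spec(1, 70, 32), 100)
  expect_error(extract_quadrants(matrix(0, 64, 64), ctx), "margin")
})

test_that("pipeline composition equals a straight-line reference", {
  ctx <- geometry_context(detector_preset("toy"),
                          beam_spec(0.9795, 250, 261), 250)
  set.seed(13)
  raw <- matrix(rpois(512 * 512, 20), 512, 512)
  raw[30:40, 100:130] <- -1
  qs <- condition_image(raw, ctx)
  ref <- extract_quadrants(sqrt_quantize(brute_maxpool(raw, 2)), ctx)
  for (id in names(qs)) expect_equal(qs[[id]]$pixels, ref[[id]]$pixels)
  # single-quadrant fast path equals the corresponding full-pass quadrant
  q1 <- condition_image(raw, ctx, quadrants = 1L, which = "UL")
  expect_equal(q1$UL$pixels, qs$UL$pixels)
})

test_that("maximum composites behave as element-wise maxima", {
  set.seed(17)
  imgs <- replicate(3, matrix(rpois(64, 9), 8, 8), simplify = FALSE)
  expect_identical(max_composite(imgs[1]), imgs[[1]])
  expect_identical(max_composite(list(imgs[[1]], imgs[[1]])), imgs[[1]])
  comp <- max_composite(imgs)
  oracle <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    oracle[i, j] <- max(imgs[[1]][i, j], imgs[[2]][i, j], imgs[[3]][i, j])
  }
  expect_equal(comp, oracle)
  expect_error(max_composite(list(imgs[[1]], matrix(0, 4, 4))), "shape")
  expect_error(max_composite(list()), "non-empty")
})
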