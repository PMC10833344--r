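test_that("parameter accounting is exact for every backbone depth", {
  res50 <- count_parameters(architecture_spec("50", "geometry_resolution"))
  expect_identical(res50$backbone, 25550760)
  expect_identical(res50$total, 25650961)
  ovl34 <- count_parameters(architecture_spec("34", "sigmoid_overlap"))
  expect_identical(ovl34$backbone, 21791400)
  expect_identical(ovl34$total, 21891601)
  for (depth in c("toy", "18", "34", "50")) {
    pc <- count_parameters(architecture_spec(depth, "geometry_resolution"))
    expect_equal(pc$fc1, 100100)
    expect_equal(pc$fc2, 101)
    expect_equal(pc$total, pc$backbone + pc$fc1 + pc$fc2)
    expect_equal(sum(backbone_layer_table(depth)$params), pc$backbone)
  }
  # toy backbone is a fixed feature stage: no trainable backbone parameters
  expect_equal(count_parameters(architecture_spec("toy", "sigmoid_overlap"))$total,
               100201)
})

test_that("a three-channel stem would not match the published counts", {
  t1 <- backbone_layer_table("50", in_channels = 1L)
  t3 <- backbone_layer_table("50", in_channels = 3L)
  expect_equal(sum(t3$params) - sum(t1$params), 64 * 7 * 7 * 2)
})

test_that("the toy model runs a forward pass on arbitrary-size inputs", {
  model <- build_model(architecture_spec("toy", "geometry_resolution"), seed = 2)
  img <- matrix(rpois(128 * 128, 4), 128, 128)
  out <- model_forward(model, img, wavelength = 0.9795, pixel_eff_mm = 0.7,
                       distance_mm = 250)
  expect_length(out, 1)
  expect_true(is.finite(out) && out >= 0)
  outs <- model_forward(model, list(img, img + 1L))
  expect_length(outs, 2)
  # overlap head produces probabilities
  m2 <- build_model(architecture_spec("toy", "sigmoid_overlap"), seed = 2)
  p <- model_forward(m2, img)
  expect_true(p >= 0 && p <= 1)
  m50 <- build_model(architecture_spec("50", "geometry_resolution"))
  expect_error(model_forward(m50, img), "toy depth")
})

test_that("the geometry head matches and inverts the Bragg closed forms", {
  lam <- 0.9795
  expect_equal(geometry_head(0, lam, 0.7, 250), 0)
  expect_equal(geometry_head(-5, lam, 0.7, 250), 0)
  # s * p_eff = D means 2theta = 45 degrees
  expect_equal(geometry_head(250 / 0.7, lam, 0.7, 250),
               2 * sin(pi / 8) / lam, tolerance = 1e-12)
  # exact inverse of the geometry-module conversions
  set.seed(23)
  for (i in 1:25) {
    D <- runif(1, 150, 400); p_eff <- runif(1, 0.1, 1.5)
    d <- runif(1, 1.2, 8)
    s <- radius_at_resolution(d, D, lam) / p_eff
    expect_equal(geometry_head(s, lam, p_eff, D), 1 / d, tolerance = 1e-9)
  }
  # monotone increasing in s
  s_grid <- seq(0.1, 800, length.out = 200)
  expect_true(all(diff(geometry_head(s_grid, lam, 0.7, 250)) > 0))
  expect_error(geometry_head(1, -1, 0.7, 250), "invalid geometry")
})

test_that("losses reduce to their closed forms and batch means", {
  expect_equal(loss_resolution(0.4, 0.4, "mse"), 0)
  expect_equal(loss_resolution(0.5, 0.4, "mse"), 0.01, tolerance = 1e-12)
  expect_equal(loss_resolution(0.5, 0.4, "mae"), 0.1, tolerance = 1e-12)
  set.seed(31)
  p <- runif(10); y <- runif(10)
  expect_equal(loss_resolution(p, y, "mse"),
               mean(sapply(1:10, function(i) loss_resolution(p[i], y[i], "mse"))))
  expect_equal(loss_overlap(0, 1), log(2), tolerance = 1e-12)
  expect_lt(loss_overlap(30, 1), 1e-12)
  z <- rnorm(20)
  expect_equal(loss_overlap(z, rep(1, 20)), loss_overlap(-z, rep(0, 20)),
               tolerance = 1e-12)
})

test_that("the regression accuracy is a thresholded fraction", {
  y <- seq(0.2, 0.5, length.out = 10)
  expect_equal(accuracy_resolution(y, y), 1)
  expect_equal(accuracy_resolution(0.48, 0.40), 0)
  expect_equal(accuracy_resolution(0.47, 0.40), 1)  # boundary: <= 0.07
  set.seed(37)
  p <- runif(100, 0, 0.6); t <- runif(100, 0, 0.6)
  brute <- sum(abs(p - t) <= 0.07) / 100
  expect_equal(accuracy_resolution(p, t), brute)
  expect_equal(accuracy_resolution(p, t, threshold = 0.2),
               sum(abs(p - t) <= 0.2) / 100)
  expect_error(accuracy_resolution(numeric(0), numeric(0)), "undefined")
})

test_that("quadrant features have fixed length and ignore masked pixels", {
  set.seed(41)
  img <- matrix(rpois(512 * 512, 3), 512, 512)
  f <- quadrant_features(img)
  expect_length(f, 1000)
  masked <- img; masked[5, 5] <- -1
  zeroed <- img; zeroed[5, 5] <- 0
  expect_equal(quadrant_features(masked), quadrant_features(zeroed))
})

test_that("training rejects mismatched heads and non-toy depths", {
  cfg <- quiet_toy_config()
  iset <- fixture("tiny_set", simulate_image_set(cfg, 12, seed = 55))
  td <- prepare_training_data(iset)
  expect_error(
    train_model(td, architecture_spec("toy", "sigmoid_overlap"),
                train_config("resolution", epochs = 1)),
    "disagree")
  expect_error(
    train_model(td, architecture_spec("50", "geometry_resolution"),
                train_config("resolution", epochs = 1)),
    "toy depth")
})

test_that("training is bit-reproducible under a fixed seed", {
  iset <- fixture("tiny_set", simulate_image_set(quiet_toy_config(), 12, seed = 55))
  td <- prepare_training_data(iset)
  f1 <- train_model(td, config = train_config("resolution", epochs = 3, seed = 9))
  f2 <- train_model(td, config = train_config("resolution", epochs = 3, seed = 9))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
})

test_that("a short training run reduces the held-out loss", {
  td <- fixture("progress_td",
                simulate_training_data(toy_config("resolution"), 200, seed = 61))
  fit <- train_model(td,
                     config = train_config("resolution", epochs = 15, seed = 63))
  h <- fit$history
  expect_lt(h$test_loss[nrow(h)], h$test_loss[1])
  expect_equal(nrow(h), 15)
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  g <- glance(fit)
  expect_equal(g$best_epoch, fit$best_epoch)
  expect_identical(tidy(fit), h)
})

test_that("checkpoints round-trip through disk", {
  iset <- fixture("tiny_set", simulate_image_set(quiet_toy_config(), 12, seed = 55))
  fit <- train_model(prepare_training_data(iset),
                     config = train_config("resolution", epochs = 2, seed = 9))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$history, fit$history)
})
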