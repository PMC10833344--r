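test_that("quadrant resolutions aggregate as min and inverse-mean", {
  vals <- c(0.5, 0.4, 0.45, 0.42)
  agg <- aggregate_quadrant_resolutions(vals)
  expect_equal(agg[["d_min"]], 2.0)
  expect_equal(agg[["d_mean"]], 1 / mean(vals), tolerance = 1e-12)
  expect_equal(agg[["d_mean"]], 2.259887, tolerance = 1e-6)
  expect_lte(agg[["d_min"]], agg[["d_mean"]])
  # degenerate: identical values collapse both aggregates
  agg2 <- aggregate_quadrant_resolutions(rep(0.3, 4))
  expect_equal(agg2[["d_min"]], agg2[["d_mean"]])
})

test_that("inference records are consistent across 1- and 4-quadrant passes", {
  fit <- constant_fit("geometry_resolution", b2 = 0.3)
  ctx <- geometry_context(detector_preset("toy"), distance_mm = 250)
  set.seed(71)
  raw <- matrix(rpois(512 * 512, 4), 512, 512)
  qs <- condition_image(raw, ctx)
  rec4 <- infer_image(fit, qs, ctx, n_quadrants = 4L)
  rec1 <- infer_image(fit, qs, ctx, n_quadrants = 1L)
  expect_equal(rec1$q1, rec4$q1)
  expect_true(is.na(rec1$q2))
  # constant model: four identical predictions, d_min == d_mean
  expect_equal(rec4$d_min_A, rec4$d_mean_A)
  expect_equal(rec4$B_min_A2,
               b_from_resolution(rec4$d_min_A, quiet = TRUE))
  expect_error(infer_image(fit, qs[c("UR", "LL")], ctx, n_quadrants = 4L),
               "missing")
})

test_that("a zero logit sits exactly on the overlap decision boundary", {
  fit <- constant_fit("sigmoid_overlap", b2 = 0)
  ctx <- geometry_context(detector_preset("toy"), distance_mm = 250)
  raw <- matrix(0L, 512, 512)
  qs <- condition_image(raw, ctx)
  rec <- infer_image(fit, qs, ctx, n_quadrants = 1L)
  expect_equal(rec$p_overlap, 0.5)
  expect_true(rec$overlap_label)  # p >= 0.5 labels overlapped
})

test_that("overlap classification thresholds as specified", {
  expect_false(classify_overlap(0.49))
  expect_true(classify_overlap(0.5))
  expect_false(classify_overlap(0))
  expect_true(classify_overlap(1))
  expect_true(classify_overlap(0.3, threshold = 0.25))
  expect_equal(classify_overlap(c(0.1, 0.9)), c(FALSE, TRUE))
  expect_error(classify_overlap(1.2), "\\[0, 1\\]")
})

test_that("sorting and splitting yields near-equal stable groups", {
  rec4 <- tibble::tibble(image_id = 1:4, p_overlap = c(0.9, 0.1, 0.5, 0.3))
  out4 <- sort_and_split(rec4, "p_overlap", 2)
  expect_equal(unname(table(out4$group)), c(2L, 2L), ignore_attr = TRUE)
  rec5 <- tibble::tibble(image_id = 1:5, p_overlap = c(0.9, 0.1, 0.5, 0.3, 0.2))
  out5 <- sort_and_split(rec5, "p_overlap", 2)
  expect_equal(as.integer(table(out5$group)), c(3L, 2L))
  expect_equal(out5$image_id, c(2, 5, 4, 3, 1))  # ascending p
  b <- attr(out5, "boundaries")
  expect_equal(b$hi[1], 0.3)
  expect_equal(b$lo[2], 0.5)

  set.seed(73)
  rec <- tibble::tibble(image_id = 1:100, p_overlap = runif(100))
  out <- sort_and_split(rec, "p_overlap", 3)
  expect_equal(out$p_overlap, sort(rec$p_overlap))
  expect_equal(as.integer(table(out$group)), c(34L, 33L, 33L))
  expect_error(sort_and_split(rec[0, ], "p_overlap", 2), "no records")
  expect_error(sort_and_split(rec4, "p_overlap", 10), "at least as many")
})

test_that("data-set summaries are per-image arithmetic means", {
  one <- tibble::tibble(image_id = 1, d_min_A = 2.1, d_mean_A = 2.4,
                        B_min_A2 = 29.6, p_overlap = NA_real_,
                        overlap_label = NA)
  s1 <- summarize_dataset(one)
  expect_equal(s1$d_min_mean_A, 2.1)
  expect_equal(s1$B_min_mean_A2, 29.6)
  expect_true(is.na(s1$overlap_fraction))

  ovl <- tibble::tibble(image_id = 1:3, d_min_A = NA_real_, d_mean_A = NA_real_,
                        B_min_A2 = NA_real_, p_overlap = c(0.9, 0.8, 0.7),
                        overlap_label = c(TRUE, TRUE, TRUE))
  expect_equal(summarize_dataset(ovl)$overlap_fraction, 1)

  set.seed(79)
  rec <- tibble::tibble(image_id = 1:50,
                        d_min_A = runif(50, 1.5, 4),
                        d_mean_A = runif(50, 2, 5),
                        B_min_A2 = runif(50, 20, 80),
                        p_overlap = runif(50),
                        overlap_label = runif(50) > 0.5)
  s <- summarize_dataset(rec)
  acc_d <- 0; acc_B <- 0; acc_o <- 0
  for (i in 1:50) {
    acc_d <- acc_d + rec$d_min_A[i]
    acc_B <- acc_B + rec$B_min_A2[i]
    acc_o <- acc_o + as.numeric(rec$overlap_label[i])
  }
  expect_equal(s$d_min_mean_A, acc_d / 50)
  expect_equal(s$B_min_mean_A2, acc_B / 50)
  expect_equal(s$overlap_fraction, acc_o / 50)
  expect_error(summarize_dataset(rec[0, ]), "no records")
})

test_that("inferred <d_min> rises monotonically with the simulated B factor", {
  fit <- resolution_training_run()$fit
  d_targets <- c(2.6, 3.5, 4.8)
  for (s in 1:5) {
    means <- sapply(seq_along(d_targets), function(k) {
      cfg <- toy_config("resolution",
                        resolution_range = rep(d_targets[k], 2))
      iset <- simulate_image_set(cfg, 8, seed = 9000 + 100 * s + k)
      rep <- infer_image_set(fit, iset, n_quadrants = 1L)
      mean(rep$d_min_A)
    })
    expect_equal(order(means), 1:3)  # rank correlation 1 across the groups
  }
})
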