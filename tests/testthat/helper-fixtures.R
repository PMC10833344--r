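# Shared fixtures. Heavy objects (simulated sets, trained fits) are built
# once per test run and cached, so acceptance and unit files can share them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  got <- get0(key, envir = .fixture_cache, inherits = FALSE)
  if (!is.null(got)) return(got)
  val <- force(expr)
  assign(key, val, envir = .fixture_cache)
  val
}

# a quiet toy config: no masks/hot pixels, so pixel-level oracles are clean
quiet_toy_config <- function(task = "resolution", ...) {
  toy_config(task, background_range = c(0, 0), hot_pixel_mean = 0,
             bad_region_max = 0L, beamstop_range_mm = c(0, 0),
             ice_ring_prob = 0, ...)
}

# desk-scale resolution training run (also used by the end-to-end checks);
# features are generated streaming so the pixel stacks never co-reside
resolution_training_run <- function() {
  fixture("resolution_run", {
    td <- simulate_training_data(toy_config("resolution"), 2000, seed = 101)
    fit <- train_model(td, config = train_config("resolution", epochs = 60,
                                                 seed = 103))
    list(fit = fit)
  })
}

# desk-scale overlap training run on the easy (10 degree) misorientation split
overlap_training_run <- function() {
  fixture("overlap_run", {
    td <- simulate_training_data(toy_config("overlap",
                                            misorientation_choices = 10),
                                 1000, seed = 202)
    fit <- train_model(td, config = train_config("overlap", epochs = 60,
                                                 seed = 204))
    list(fit = fit)
  })
}

# a constant-prediction fit handle with hand-set weights, for exercising
# inference plumbing without a training run
constant_fit <- function(head = "geometry_resolution", b2 = 0.3) {
  spec <- architecture_spec("toy", head)
  structure(
    list(spec = spec,
         config = train_config(
           if (head == "geometry_resolution") "resolution" else "overlap"),
         weights = list(W1 = matrix(0, 1000, 100), b1 = rep(0, 100),
                        W2 = matrix(0, 100, 1), b2 = b2),
         feature_norm = list(mu = rep(0, 1000), sd = rep(1, 1000)),
         history = tibble::tibble(epoch = 1L, train_loss = NA_real_,
                                  test_loss = NA_real_, train_acc = NA_real_,
                                  test_acc = NA_real_),
         best_epoch = 1L, quadrant = "UL", n_shells = 125L,
         n_train = 0L, n_test = 0L),
    class = "braggnet_fit")
}
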