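# Toy-backbone feature stage and the SGD training loop for the FC head.

.shell_cache <- new.env(parent = emptyenv())

# group the pixels of an (nr x nc) beam-anchored quadrant into radial
# shells; cached permutation + shell sizes per array shape
shell_plan <- function(nr, nc, n_shells) {
  key <- paste(nr, nc, n_shells, sep = "_")
  got <- get0(key, envir = .shell_cache)
  if (!is.null(got)) return(got)
  r <- sqrt(outer((0:(nr - 1))^2, (0:(nc - 1))^2, `+`))
  width <- sqrt(2) * max(nr, nc) / n_shells
  shell <- pmin(floor(r / width) + 1L, n_shells)
  ord <- order(shell)
  counts <- tabulate(shell, nbins = n_shells)
  plan <- list(ord = ord, counts = counts, ends = cumsum(counts))
  assign(key, plan, envir = .shell_cache)
  plan
}

#' Radial-shell features of a conditioned quadrant
#'
#' The fixed feature stage of the `"toy"` backbone: the quadrant is divided
#' into 125 radial shells about the beam-anchored origin and 8 summary
#' statistics are computed per shell (mean, standard deviation, maximum,
#' 90th and 99th percentiles, fraction of pixels more than 3 SD above the
#' shell mean, fraction of non-zero pixels, and log total), yielding
#' exactly 1000 features. Masked pixels (`-1`) are treated as empty (0).
#'
#' @param quadrant A `conditioned_quadrant` or a plain matrix.
#' @param n_shells Number of radial shells (default 125; `8 * n_shells`
#'   features are produced).
#' @return A numeric vector of length `8 * n_shells`.
#' @export
quadrant_features <- function(quadrant, n_shells = 125L) {
  px <- if (inherits(quadrant, "conditioned_quadrant")) quadrant$pixels else quadrant
  stopifnot(is.matrix(px))
  plan <- shell_plan(nrow(px), ncol(px), n_shells)
  v <- as.vector(px)
  v[v < 0] <- 0
  vs <- v[plan$ord]
  feats <- matrix(0, n_shells, 8L)
  start <- 1L
  for (i in seq_len(n_shells)) {
    n <- plan$counts[i]
    if (n > 0L) {
      slice <- vs[start:plan$ends[i]]
      ss <- sort.int(slice, method = "quick")
      m <- sum(ss) / n
      s <- if (n > 1L) sqrt(max(0, sum(ss^2) / n - m^2)) else 0
      feats[i, ] <- c(m, s, ss[n],
                      ss[ceiling(0.90 * n)], ss[ceiling(0.99 * n)],
                      sum(slice > m + 3 * s) / n,
                      sum(slice > 0) / n,
                      log1p(sum(ss)))
      start <- plan$ends[i] + 1L
    }
  }
  as.vector(feats)
}

#' Condition an image set and extract training features
#'
#' Runs the conditioning pipeline on every image of an [simulate_image_set()]
#' result, keeps one quadrant (the training quadrant, default `"UL"` in
#' memory convention), and extracts the toy-backbone radial-shell features
#' together with the per-image geometry needed by the resolution head.
#'
#' @param image_set An `image_set`.
#' @param quadrant Which quadrant to train on.
#' @param n_shells Passed to [quadrant_features()].
#' @return A list of class `training_data`: `features` (n x 1000 matrix),
#'   `labels` (tibble), `geometry` (tibble with `wavelength`,
#'   `pixel_eff_mm`, `distance_mm`).
#' @export
prepare_training_data <- function(image_set, quadrant = "UL", n_shells = 125L) {
  stopifnot(inherits(image_set, "image_set"))
  n <- length(image_set$images)
  feats <- vector("list", n)
  geom <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- image_set$geometries[[i]]
    q <- condition_image(image_set$images[[i]], ctx, quadrants = 1L,
                         which = quadrant)[[1]]
    feats[[i]] <- quadrant_features(q, n_shells)
    geom[[i]] <- tibble::tibble(
      wavelength = ctx$beam$wavelength,
      pixel_eff_mm = ctx$detector$pixel_mm * ctx$detector$downsample,
      distance_mm = ctx$distance_mm)
  }
  structure(
    list(features = do.call(rbind, feats),
         labels = image_set$labels,
         geometry = dplyr::bind_rows(geom),
         quadrant = quadrant, n_shells = n_shells),
    class = "training_data")
}

#' Simulate straight to training features
#'
#' Streaming composition of [make_labeled_example()], [condition_image()]
#' and [quadrant_features()]: each image is rendered, conditioned to the
#' training quadrant and reduced to its 1000 features before the next one
#' is generated, so arbitrarily large training sets occupy only the feature
#' matrix (n x 1000) in memory.
#'
#' @inheritParams simulate_image_set
#' @inheritParams prepare_training_data
#' @return A `training_data` object, as from [prepare_training_data()].
#' @export
simulate_training_data <- function(config, n, seed = 1L, quadrant = "UL",
                                   n_shells = 125L) {
  seeds <- derive_seeds(seed, n)
  feats <- vector("list", n)
  labels <- vector("list", n)
  geom <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- make_labeled_example(config, seeds[i])
    ctx <- ex$scene$geometry
    q <- condition_image(ex$pixels, ctx, quadrants = 1L, which = quadrant)[[1]]
    feats[[i]] <- quadrant_features(q, n_shells)
    labels[[i]] <- ex$labels
    geom[[i]] <- tibble::tibble(
      wavelength = ctx$beam$wavelength,
      pixel_eff_mm = ctx$detector$pixel_mm * ctx$detector$downsample,
      distance_mm = ctx$distance_mm)
  }
  structure(
    list(features = do.call(rbind, feats),
         labels = dplyr::bind_rows(labels),
         geometry = dplyr::bind_rows(geom),
         quadrant = quadrant, n_shells = n_shells),
    class = "training_data")
}

#' Training configuration
#'
#' Defaults follow the published hyperparameters per task: stochastic
#' gradient descent with momentum 0.9, learning rate 6e-3 and mean-absolute
#' loss for resolution regression; momentum 0.9983, weight decay 2.5e-4,
#' learning rate 1.04e-3 and binary cross-entropy for overlap
#' classification. 10% of the images are set aside for per-epoch
#' validation. Batch size, epoch count and the accuracy tolerance are
#' configurable; all randomness (split, initialization, shuffling, dropout)
#' derives from `seed`.
#'
#' @param task `"resolution"` or `"overlap"`.
#' @param learning_rate,momentum,weight_decay SGD hyperparameters.
#' @param loss `"mae"`, `"mse"` (resolution) or `"bce"` (overlap).
#' @param test_fraction Held-out fraction in `[0, 1)`; 0 disables the test
#'   split (all images train, test metrics are `NA`).
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param accuracy_threshold Tolerance of [accuracy_resolution()], 1/Angstrom.
#' @param seed Master seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(task = c("resolution", "overlap"),
                         learning_rate = NULL, momentum = NULL,
                         weight_decay = NULL, loss = NULL,
                         test_fraction = 0.1, epochs = 40L, batch_size = 32L,
                         accuracy_threshold = 0.07, seed = 1L) {
  task <- match.arg(task)
  if (task == "resolution") {
    learning_rate <- learning_rate %||% 6e-3
    momentum <- momentum %||% 0.9
    weight_decay <- weight_decay %||% 0
    loss <- loss %||% "mae"
    if (!loss %in% c("mae", "mse")) stop("resolution loss must be mae or mse",
                                         call. = FALSE)
  } else {
    learning_rate <- learning_rate %||% 1.04e-3
    momentum <- momentum %||% 0.9983
    weight_decay <- weight_decay %||% 2.5e-4
    loss <- loss %||% "bce"
    if (loss != "bce") stop("overlap loss must be bce", call. = FALSE)
  }
  if (test_fraction < 0 || test_fraction >= 1) {
    stop("test_fraction must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(task = task, learning_rate = learning_rate, momentum = momentum,
         weight_decay = weight_decay, loss = loss,
         test_fraction = test_fraction, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         accuracy_threshold = accuracy_threshold, seed = as.integer(seed)),
    class = "train_config")
}

# forward pass of the FC head on standardized features; returns the task
# prediction and intermediates needed for backprop
fc_forward <- function(X, w, spec, geom = NULL, drop_mask = NULL) {
  Z1 <- sweep(X %*% w$W1, 2, w$b1, `+`)
  H <- pmax(Z1, 0)
  if (!is.null(drop_mask)) H <- H * drop_mask
  s_net <- drop(H %*% w$W2) + w$b2
  if (spec$head == "geometry_resolution") {
    # network output is the dimensionless radial ratio u = s * p_eff / D;
    # convert to the pixel-unit scalar the geometry head expects
    s_px <- s_net * geom$distance_mm / geom$pixel_eff_mm
    pred <- geometry_head(s_px, geom$wavelength, geom$pixel_eff_mm,
                          geom$distance_mm)
    dpred_ds <- geometry_head_grad(s_px, geom$wavelength, geom$pixel_eff_mm,
                                   geom$distance_mm) *
      geom$distance_mm / geom$pixel_eff_mm
    list(pred = pred, s_net = s_net, Z1 = Z1, H = H, dpred_ds = dpred_ds)
  } else {
    list(pred = sigmoid_head(s_net), s_net = s_net, Z1 = Z1, H = H,
         dpred_ds = NULL)
  }
}

eval_metrics <- function(X, y, w, spec, config, geom) {
  if (length(y) == 0L) return(c(loss = NA_real_, acc = NA_real_))
  f <- fc_forward(X, w, spec, geom)
  if (spec$head == "geometry_resolution") {
    c(loss = loss_resolution(f$pred, y, config$loss),
      acc = accuracy_resolution(f$pred, y, config$accuracy_threshold))
  } else {
    c(loss = loss_overlap(f$s_net, y),
      acc = accuracy_overlap(f$pred, y))
  }
}

#' Train a toy-depth model
#'
#' Minibatch stochastic gradient descent with momentum and weight decay on
#' the FC1/FC2 head of a `"toy"`-depth model, with the task head (geometry
#' conversion or sigmoid) differentiated through. Features are standardized
#' using training-split statistics (stored in the returned fit). After each
#' epoch the model is evaluated on the training and held-out splits and the
#' weights at the best held-out accuracy are checkpointed.
#'
#' @param data A `training_data` object from [prepare_training_data()] (or
#'   an `image_set`, which is prepared first).
#' @param spec An [architecture_spec()] with depth `"toy"`; defaults to the
#'   head matching `config$task`.
#' @param config A [train_config()].
#' @return An object of class `braggnet_fit`: the best and final weights,
#'   feature standardization, per-epoch `history` tibble (`epoch`,
#'   `train_loss`, `test_loss`, `train_acc`, `test_acc`), `best_epoch`, and
#'   the spec/config/quadrant provenance.
#' @export
train_model <- function(data, spec = NULL, config = train_config()) {
  if (inherits(data, "image_set")) data <- prepare_training_data(data)
  stopifnot(inherits(data, "training_data"), inherits(config, "train_config"))
  if (is.null(spec)) {
    spec <- architecture_spec(
      "toy",
      if (config$task == "resolution") "geometry_resolution" else "sigmoid_overlap")
  }
  if (spec$depth != "toy") {
    stop("only the toy depth is trainable at desk scale; deep backbones are ",
         "provided for architecture accounting", call. = FALSE)
  }
  head_ok <- (config$task == "resolution") ==
    (spec$head == "geometry_resolution")
  if (!head_ok) stop("config task and spec head disagree", call. = FALSE)
  y <- if (config$task == "resolution") {
    data$labels$inverse_resolution
  } else {
    as.numeric(data$labels$is_overlapped)
  }
  n <- nrow(data$features)
  seeds <- derive_seeds(config$seed, 3L)

  test_idx <- integer(0)
  if (config$test_fraction > 0) {
    test_idx <- with_seed(seeds[1],
                          sample.int(n, max(1L, round(config$test_fraction * n))))
  }
  train_idx <- setdiff(seq_len(n), test_idx)

  mu <- colMeans(data$features[train_idx, , drop = FALSE])
  sg <- apply(data$features[train_idx, , drop = FALSE], 2, stats::sd)
  sg[!is.finite(sg) | sg < 1e-8] <- 1
  X <- sweep(sweep(data$features, 2, mu), 2, sg, `/`)
  Xtr <- X[train_idx, , drop = FALSE]
  Xte <- X[test_idx, , drop = FALSE]
  gtr <- data$geometry[train_idx, , drop = FALSE]
  gte <- data$geometry[test_idx, , drop = FALSE]
  ytr <- y[train_idx]; yte <- y[test_idx]

  w <- with_seed(seeds[2], init_fc_weights(spec))
  vel <- lapply(w, function(z) z * 0)
  history <- vector("list", config$epochs)
  best <- list(metric = -Inf, loss = Inf, epoch = NA_integer_, w = w)

  with_seed(seeds[3], {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(length(train_idx))
      starts <- seq(1L, length(perm), by = config$batch_size)
      for (b in starts) {
        sel <- perm[b:min(b + config$batch_size - 1L, length(perm))]
        Xb <- Xtr[sel, , drop = FALSE]
        yb <- ytr[sel]
        gb <- gtr[sel, , drop = FALSE]
        m <- length(sel)
        drop_mask <- NULL
        if (spec$fc1_dropout) {
          drop_mask <- matrix(
            stats::rbinom(m * spec$fc1[2], 1L, 1 - spec$dropout_p),
            m, spec$fc1[2]) / (1 - spec$dropout_p)
        }
        f <- fc_forward(Xb, w, spec, gb, drop_mask)
        if (spec$head == "geometry_resolution") {
          dpred <- if (config$loss == "mae") {
            sign(f$pred - yb) / m
          } else {
            2 * (f$pred - yb) / m
          }
          ds <- dpred * f$dpred_ds
        } else {
          ds <- (f$pred - yb) / m
        }
        dH <- tcrossprod(matrix(ds), w$W2)
        if (!is.null(drop_mask)) dH <- dH * drop_mask
        dH[f$Z1 <= 0] <- 0
        grads <- list(
          W1 = crossprod(Xb, dH) + config$weight_decay * w$W1,
          b1 = colSums(dH),
          W2 = crossprod(f$H, matrix(ds)) + config$weight_decay * w$W2,
          b2 = sum(ds))
        for (nm in names(w)) {
          vel[[nm]] <- config$momentum * vel[[nm]] -
            config$learning_rate * grads[[nm]]
          w[[nm]] <- w[[nm]] + vel[[nm]]
        }
      }
      tr <- eval_metrics(Xtr, ytr, w, spec, config, gtr)
      te <- eval_metrics(Xte, yte, w, spec, config, gte)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr[["loss"]], test_loss = te[["loss"]],
        train_acc = tr[["acc"]], test_acc = te[["acc"]])
      sel_metric <- if (length(test_idx)) te[["acc"]] else tr[["acc"]]
      sel_loss <- if (length(test_idx)) te[["loss"]] else tr[["loss"]]
      if (sel_metric > best$metric ||
          (sel_metric == best$metric && sel_loss < best$loss)) {
        best <- list(metric = sel_metric, loss = sel_loss, epoch = epoch, w = w)
      }
    }
  })

  structure(
    list(spec = spec, config = config, weights = best$w, final_weights = w,
         feature_norm = list(mu = mu, sd = sg),
         history = dplyr::bind_rows(history), best_epoch = best$epoch,
         quadrant = data$quadrant, n_shells = data$n_shells,
         n_train = length(train_idx), n_test = length(test_idx)),
    class = "braggnet_fit")
}

# predict from raw (unstandardized) features with the checkpointed weights
fit_predict <- function(fit, features, geometry) {
  X <- sweep(sweep(features, 2, fit$feature_norm$mu), 2,
             fit$feature_norm$sd, `/`)
  f <- fc_forward(X, fit$weights, fit$spec, geometry)
  if (fit$spec$head == "geometry_resolution") f$pred else drop(f$pred)
}

#' Save / load a fit checkpoint
#'
#' The checkpoint bundles weights, architecture spec, training config,
#' feature standardization and the geometry conventions (training quadrant,
#' shell count), so inference needs nothing else.
#'
#' @param fit A `braggnet_fit`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   the fit.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "braggnet_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "braggnet_fit"))
  fit
}

#' @export
print.braggnet_fit <- function(x, ...) {
  cat(sprintf("<braggnet_fit> %s head, %d train / %d test images\n",
              x$spec$head, x$n_train, x$n_test))
  cat(sprintf("  best epoch %d of %d (held-out accuracy %.3f)\n",
              x$best_epoch, nrow(x$history),
              x$history$test_acc[x$best_epoch] %||% NA))
  invisible(x)
}

#' Tidy the training history of a fit
#'
#' @param x A `braggnet_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`, `test_loss`,
#'   `train_acc`, `test_acc`).
#' @export
tidy.braggnet_fit <- function(x, ...) x$history

#' @rdname tidy.braggnet_fit
#' @return `glance()` returns a one-row tibble: task, best epoch and its
#'   held-out metrics, split sizes.
#' @export
glance.braggnet_fit <- function(x, ...) {
  b <- x$history[x$best_epoch, ]
  tibble::tibble(task = x$config$task, best_epoch = x$best_epoch,
                 test_loss = b$test_loss, test_acc = b$test_acc,
                 train_loss = b$train_loss, train_acc = b$train_acc,
                 n_train = x$n_train, n_test = x$n_test)
}
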