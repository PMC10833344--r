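#' Model architecture specification
#'
#' The models share one layout: a single-channel backbone producing 1000
#' features, a fully connected layer FC1 (1000 -> 100, with bias), a
#' rectified-linear activation (optionally followed by dropout), a second
#' fully connected layer FC2 (100 -> 1, with bias), and a task head that
#' turns the scalar into either an inverse resolution (geometry head) or an
#' overlap probability (sigmoid head).
#'
#' Backbones `"18"`, `"34"` and `"50"` are the standard residual networks of
#' those depths with the first convolution reshaped to one input channel;
#' they are exactly parameter-countable here (see [count_parameters()]) and
#' depth 50 / depth 34 are the published resolution / overlap backbones.
#' Backbone `"toy"` is a desk-scale variant whose feature stage is a fixed
#' (untrained) radial-shell summary of the conditioned quadrant producing
#' the same 1000 features; only FC1/FC2 carry trainable parameters, which
#' makes the toy model trainable on a single CPU in minutes.
#'
#' @param depth `"toy"`, `"18"`, `"34"` or `"50"`.
#' @param head `"geometry_resolution"` or `"sigmoid_overlap"`.
#' @param fc1_dropout Apply dropout after the FC1 activation? Defaults to
#'   the published choice: off for the resolution head, on for the overlap
#'   head.
#' @param dropout_p Dropout probability when enabled (default 0.5); dropout
#'   is active during training only.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(depth = c("toy", "18", "34", "50"),
                              head = c("geometry_resolution", "sigmoid_overlap"),
                              fc1_dropout = NULL, dropout_p = 0.5) {
  depth <- match.arg(as.character(depth), c("toy", "18", "34", "50"))
  head <- match.arg(head)
  if (is.null(fc1_dropout)) fc1_dropout <- head == "sigmoid_overlap"
  structure(
    list(depth = depth, head = head, in_channels = 1L,
         backbone_features = 1000L, fc1 = c(1000L, 100L), fc2 = c(100L, 1L),
         fc1_dropout = isTRUE(fc1_dropout), dropout_p = dropout_p),
    class = "architecture_spec")
}

# ---- exact residual-backbone parameter accounting ------------------------

bn_params <- function(ch) 2L * ch  # affine scale + shift per channel

basic_block_params <- function(inp, out, stride) {
  n <- 9 * inp * out + bn_params(out) + 9 * out * out + bn_params(out)
  if (stride != 1L || inp != out) n <- n + inp * out + bn_params(out)
  n
}

bottleneck_params <- function(inp, width, stride) {
  out <- 4L * width
  n <- inp * width + bn_params(width) + 9 * width * width +
    bn_params(width) + width * out + bn_params(out)
  if (stride != 1L || inp != out) n <- n + inp * out + bn_params(out)
  n
}

#' Per-stage layer table of a residual backbone
#'
#' Trainable-parameter accounting for the 18/34/50-layer residual networks
#' with a single-channel first convolution: the 7x7 stem convolution (no
#' bias) with batch norm, four block stages, and the final 1000-way linear
#' feature layer. The `"toy"` backbone has no trainable parameters.
#'
#' @param depth `"toy"`, `"18"`, `"34"` or `"50"`.
#' @param in_channels Input channels of the stem convolution (default 1).
#' @return A tibble with columns `stage` and `params`.
#' @export
backbone_layer_table <- function(depth, in_channels = 1L) {
  depth <- match.arg(as.character(depth), c("toy", "18", "34", "50"))
  if (depth == "toy") {
    return(tibble::tibble(stage = "fixed radial-shell features", params = 0L))
  }
  cfg <- switch(depth,
    "18" = list(block = basic_block_params, blocks = c(2L, 2L, 2L, 2L), expansion = 1L),
    "34" = list(block = basic_block_params, blocks = c(3L, 4L, 6L, 3L), expansion = 1L),
    "50" = list(block = bottleneck_params, blocks = c(3L, 4L, 6L, 3L), expansion = 4L))
  widths <- c(64L, 128L, 256L, 512L)
  strides <- c(1L, 2L, 2L, 2L)
  stages <- character(0); params <- numeric(0)
  stages <- c(stages, "conv1 (7x7) + bn")
  params <- c(params, 64 * in_channels * 49 + bn_params(64L))
  cur <- 64L
  for (i in 1:4) {
    tot <- 0
    for (j in seq_len(cfg$blocks[i])) {
      s <- if (j == 1L) strides[i] else 1L
      tot <- tot + cfg$block(cur, widths[i], s)
      cur <- widths[i] * cfg$expansion
    }
    stages <- c(stages, sprintf("layer%d (%d blocks)", i, cfg$blocks[i]))
    params <- c(params, tot)
  }
  stages <- c(stages, "feature fc (-> 1000)")
  params <- c(params, cur * 1000 + 1000)
  tibble::tibble(stage = stages, params = params)
}

#' Build a model handle
#'
#' For the `"toy"` depth this allocates trainable FC1/FC2 weights (seeded
#' He-style initialization) on top of the fixed radial-shell feature stage,
#' producing a model that can run forward passes and be trained. For depths
#' 18/34/50 the handle carries the exact layer accounting of the deep
#' backbone (so parameter counts are reproducible) but no instantiated
#' weights: training a 20M+ parameter convolutional network is outside this
#' package's single-CPU scope.
#'
#' @param spec An [architecture_spec()].
#' @param seed Seed for weight initialization (toy depth).
#' @return An object of class `braggnet_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  weights <- NULL
  if (spec$depth == "toy") {
    weights <- with_seed(seed, init_fc_weights(spec))
  }
  structure(
    list(spec = spec, weights = weights,
         backbone_table = backbone_layer_table(spec$depth, spec$in_channels)),
    class = "braggnet_model")
}

init_fc_weights <- function(spec) {
  list(
    W1 = matrix(rnorm(spec$fc1[1] * spec$fc1[2], 0, sqrt(2 / spec$fc1[1])),
                spec$fc1[1], spec$fc1[2]),
    b1 = rep(0, spec$fc1[2]),
    W2 = matrix(rnorm(spec$fc2[1] * spec$fc2[2], 0, sqrt(2 / spec$fc2[1])),
                spec$fc2[1], spec$fc2[2]),
    b2 = if (spec$head == "geometry_resolution") 0.25 else 0)
}

#' Exact trainable-parameter counts by stage
#'
#' @param model A [build_model()] handle (or an [architecture_spec()]).
#' @return A list with `backbone`, `fc1`, `fc2` and `total` scalar counts.
#'   FC1 is always `1000 * 100 + 100 = 100100` and FC2 always
#'   `100 * 1 + 1 = 101`; the heads add no trainable parameters.
#' @export
count_parameters <- function(model) {
  spec <- if (inherits(model, "braggnet_model")) model$spec else model
  stopifnot(inherits(spec, "architecture_spec"))
  backbone <- as.numeric(sum(backbone_layer_table(spec$depth, spec$in_channels)$params))
  fc1 <- as.numeric(spec$fc1[1] * spec$fc1[2] + spec$fc1[2])
  fc2 <- as.numeric(spec$fc2[1] * spec$fc2[2] + spec$fc2[2])
  list(backbone = backbone, fc1 = fc1, fc2 = fc2,
       total = backbone + fc1 + fc2)
}

# ---- heads ---------------------------------------------------------------

#' Geometry output stage: scalar to inverse resolution
#'
#' Interprets the network's scalar output `s` as an effective radial extent
#' in downsampled-pixel units and converts it through flat-detector Bragg
#' geometry: `1/d = (2 / lambda) * sin(0.5 * arctan(s * p_eff / D))`.
#' Non-positive `s` maps to 0 (forward beam); the map is smooth and
#' monotone increasing for `s > 0`, and exactly inverts
#' [radius_at_resolution()] divided by the effective pixel size.
#'
#' @param s Scalar model output(s), downsampled-pixel units.
#' @param wavelength Wavelength, Angstrom.
#' @param pixel_eff_mm Effective (downsampled) pixel size, mm.
#' @param distance_mm Sample-to-detector distance, mm.
#' @return Inverse resolution(s), 1/Angstrom.
#' @export
geometry_head <- function(s, wavelength, pixel_eff_mm, distance_mm) {
  if (any(wavelength <= 0) || any(pixel_eff_mm <= 0) || any(distance_mm <= 0)) {
    stop("invalid geometry: wavelength, pixel size and distance must be positive",
         call. = FALSE)
  }
  u <- pmax(s, 0) * pixel_eff_mm / distance_mm
  (2 / wavelength) * sin(0.5 * atan(u))
}

# d(1/d)/ds of the geometry head; right-derivative used at s <= 0 so
# gradient descent can recover from the clipped region
geometry_head_grad <- function(s, wavelength, pixel_eff_mm, distance_mm) {
  u <- pmax(s, 0) * pixel_eff_mm / distance_mm
  (2 / wavelength) * cos(0.5 * atan(u)) * 0.5 / (1 + u^2) *
    (pixel_eff_mm / distance_mm)
}

#' Sigmoid overlap head
#'
#' @param logit Scalar model output(s).
#' @return Overlap probability in (0, 1).
#' @export
sigmoid_head <- function(logit) 1 / (1 + exp(-logit))

# ---- losses and metrics --------------------------------------------------

#' Resolution-regression loss in inverse units
#'
#' Mean-absolute (default, the published hyperparameter choice) or
#' mean-squared error between predicted and labeled inverse resolutions.
#'
#' @param pred,label Inverse resolutions, 1/Angstrom.
#' @param kind `"mae"` or `"mse"`.
#' @return Scalar mean loss.
#' @export
loss_resolution <- function(pred, label, kind = c("mae", "mse")) {
  kind <- match.arg(kind)
  stopifnot(length(pred) == length(label), all(is.finite(pred)),
            all(is.finite(label)))
  if (kind == "mae") mean(abs(pred - label)) else mean((pred - label)^2)
}

#' Binary cross-entropy loss on the sigmoid of a logit
#'
#' Numerically stable form `max(z, 0) - z y + log(1 + exp(-|z|))`.
#'
#' @param logit Model logit(s).
#' @param label 0/1 label(s) (single / overlapping lattices).
#' @return Scalar mean loss.
#' @export
loss_overlap <- function(logit, label) {
  stopifnot(length(logit) == length(label), all(is.finite(logit)),
            all(label %in% c(0, 1)))
  mean(pmax(logit, 0) - logit * label + log1p(exp(-abs(logit))))
}

#' Resolution accuracy: fraction within a tolerance in inverse units
#'
#' The regression accuracy used for the training curves: the fraction of
#' images whose predicted inverse resolution lies within `threshold`
#' (default 0.07 1/Angstrom) of the ground truth.
#'
#' @param preds,labels Inverse resolutions, 1/Angstrom.
#' @param threshold Tolerance in 1/Angstrom.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_resolution <- function(preds, labels, threshold = 0.07) {
  if (length(preds) == 0L) {
    stop("undefined metric: no predictions", call. = FALSE)
  }
  stopifnot(length(preds) == length(labels))
  mean(abs(preds - labels) <= threshold)
}

#' Classification accuracy for overlap detection
#'
#' @param probs Overlap probabilities in `[0, 1]`.
#' @param labels 0/1 ground truth.
#' @param threshold Decision threshold (overlapped iff `p >= threshold`).
#' @return Fraction of correct labels.
#' @export
accuracy_overlap <- function(probs, labels, threshold = 0.5) {
  if (length(probs) == 0L) {
    stop("undefined metric: no predictions", call. = FALSE)
  }
  stopifnot(length(probs) == length(labels))
  mean((probs >= threshold) == (labels == 1))
}

#' Forward pass of a freshly built toy-depth model
#'
#' Runs the fixed feature stage and the FC head on one or more
#' single-channel images, returning one head output per image. Intended for
#' shape/contract checks and as the untrained starting point of
#' [train_model()]; deep backbones cannot run forward passes here.
#'
#' @param model A toy-depth [build_model()] handle.
#' @param images A matrix, `conditioned_quadrant`, or list of either.
#' @param wavelength,pixel_eff_mm,distance_mm Geometry for the resolution
#'   head (scalars or one value per image); ignored by the sigmoid head.
#' @return Numeric vector, one value per image (inverse resolution in
#'   1/Angstrom or overlap probability).
#' @export
model_forward <- function(model, images, wavelength = 0.9795,
                          pixel_eff_mm = 0.7, distance_mm = 250) {
  stopifnot(inherits(model, "braggnet_model"))
  if (model$spec$depth != "toy") {
    stop("forward passes are implemented for the toy depth only", call. = FALSE)
  }
  if (!is.list(images) || inherits(images, "conditioned_quadrant")) {
    images <- list(images)
  }
  X <- do.call(rbind, lapply(images, quadrant_features))
  geom <- tibble::tibble(wavelength = wavelength, pixel_eff_mm = pixel_eff_mm,
                         distance_mm = distance_mm)
  if (nrow(geom) == 1L) geom <- geom[rep(1L, nrow(X)), ]
  f <- fc_forward(X, model$weights, model$spec, geom)
  drop(f$pred)
}

#' Aggregate per-quadrant inverse resolutions
#'
#' `d_min` is the best resolution across the quadrants (the reciprocal of
#' the largest inverse resolution); `d_mean` averages in inverse-resolution
#' units -- the model's native space -- and reports the reciprocal of the
#' mean.
#'
#' @param inv_d Vector of per-quadrant inverse resolutions, 1/Angstrom.
#' @return Named numeric: `d_min`, `d_mean` (Angstrom).
#' @export
aggregate_quadrant_resolutions <- function(inv_d) {
  stopifnot(length(inv_d) >= 1L, all(inv_d > 0))
  c(d_min = 1 / max(inv_d), d_mean = 1 / mean(inv_d))
}

#' @export
print.braggnet_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<braggnet_model> depth %s, head %s\n", x$spec$depth, x$spec$head))
  cat(sprintf("  parameters: backbone %s, fc1 %s, fc2 %s, total %s\n",
              format(pc$backbone, big.mark = ","), format(pc$fc1, big.mark = ","),
              format(pc$fc2, big.mark = ","), format(pc$total, big.mark = ",")))
  invisible(x)
}
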