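#' Block-maximum downsampling
#'
#' Groups raw pixels into `N x N` blocks and keeps the maximum of each block.
#' Partial blocks at the high edges (when a dimension is not a multiple of
#' `N`) reduce over the pixels that exist, so the full field of view is kept
#' and the output dimensions are `ceiling(dim / N)`. The mask sentinel `-1`
#' participates as the minimum value: a block survives as `-1` only if every
#' raw pixel in it is masked.
#'
#' @param raw Numeric matrix of detector counts (`-1` marks masked pixels).
#' @param N Positive integer block edge.
#' @return A numeric matrix of dimension `ceiling(dim(raw) / N)`.
#' @export
maxpool_downsample <- function(raw, N) {
  if (!is.matrix(raw) || length(raw) == 0L) {
    stop("raw must be a non-empty matrix", call. = FALSE)
  }
  N <- as.integer(N)
  if (is.na(N) || N <= 0L) stop("N must be a positive integer", call. = FALSE)
  if (N == 1L) return(raw)
  nr <- nrow(raw); nc <- ncol(raw)
  nrp <- N * ceiling(nr / N); ncp <- N * ceiling(nc / N)
  if (nrp != nr || ncp != nc) {
    pad <- matrix(-Inf, nrp, ncp)
    pad[seq_len(nr), seq_len(nc)] <- raw
    raw <- pad
  }
  rows <- matrix(-Inf, nrp / N, ncp)
  for (k in seq_len(N)) {
    rows <- pmax(rows, raw[seq(k, nrp, by = N), , drop = FALSE])
  }
  out <- matrix(-Inf, nrp / N, ncp / N)
  for (k in seq_len(N)) {
    out <- pmax(out, rows[, seq(k, ncp, by = N), drop = FALSE])
  }
  out
}

#' Square-root integer quantization
#'
#' Replaces every non-negative value by the floor of its square root; the
#' `-1` mask sentinel passes through unchanged. This compresses the dynamic
#' range of photon-counting data into small integers ("square-root-photon
#' units") ahead of model evaluation.
#'
#' @param x Numeric matrix with values `>= 0` or exactly `-1`.
#' @return Integer-valued matrix of the same shape.
#' @export
sqrt_quantize <- function(x) {
  bad <- x < 0 & x != -1
  if (any(bad)) {
    stop("sqrt_quantize: values must be >= 0 or the -1 mask sentinel",
         call. = FALSE)
  }
  out <- x
  pos <- x >= 0
  out[pos] <- floor(sqrt(x[pos]))
  out
}

#' Beam-anchored 512 x 512 quadrant extraction
#'
#' Splits a downsampled image into four quadrants about the beam center and
#' reorients each so that element (1,1) holds the pixel at the beam center
#' and the radius grows with the indices. Every quadrant is exactly
#' `512 x 512`: regions past the detector edge are zero-padded and regions
#' farther than 512 block-pixels from the center are truncated. When the
#' beam center falls on a pixel center, that row/column of pixels is shared
#' between the adjacent quadrants, so a pattern that is point-symmetric
#' about the beam center yields four identical quadrants.
#'
#' @param ds_image Downsampled (and typically quantized) image matrix,
#'   oriented (slow, fast).
#' @param ctx The [geometry_context()] of the raw image; the raw beam center
#'   is rescaled by the detector's downsampling factor.
#' @param size Quadrant edge length (default 512).
#' @return A named list of four `conditioned_quadrant` objects, in the fixed
#'   order `UL`, `UR`, `LL`, `LR` (memory convention: UL = lower indices on
#'   both axes).
#' @export
extract_quadrants <- function(ds_image, ctx, size = 512L) {
  stopifnot(is.matrix(ds_image), inherits(ctx, "geometry_context"))
  det <- ctx$detector
  bs <- ctx$beam$center_slow / det$downsample
  bf <- ctx$beam$center_fast / det$downsample
  nr <- nrow(ds_image); nc <- ncol(ds_image)
  margin <- 0.1 * max(nr, nc)
  if (bs < -margin || bs > nr - 1 + margin || bf < -margin || bf > nc - 1 + margin) {
    stop("beam center lies off the downsampled image by more than the margin",
         call. = FALSE)
  }
  # 0-based index runs: low side walks from the beam-center pixel to the
  # first pixel; high side walks from the beam-center pixel to the edge
  idx_low <- function(b) if (floor(b) < 0) integer(0) else seq(floor(b), 0L)
  idx_high <- function(b, n) if (ceiling(b) > n - 1) integer(0) else seq(ceiling(b), n - 1L)
  rl <- idx_low(bs); rh <- idx_high(bs, nr)
  cl <- idx_low(bf); ch <- idx_high(bf, nc)
  take <- function(rows, cols, id) {
    q <- matrix(0, size, size)
    nrq <- min(size, length(rows)); ncq <- min(size, length(cols))
    if (nrq > 0L && ncq > 0L) {
      q[seq_len(nrq), seq_len(ncq)] <-
        ds_image[rows[seq_len(nrq)] + 1L, cols[seq_len(ncq)] + 1L, drop = FALSE]
    }
    structure(
      list(pixels = q, quadrant_id = id,
           effective_pixel_mm = det$pixel_mm * det$downsample,
           geometry = ctx),
      class = "conditioned_quadrant")
  }
  list(UL = take(rl, cl, "UL"), UR = take(rl, ch, "UR"),
       LL = take(rh, cl, "LL"), LR = take(rh, ch, "LR"))
}

#' Full conditioning pipeline
#'
#' Applies, in fixed order, block-maximum downsampling by the detector's
#' factor, square-root integer quantization, and beam-anchored quadrant
#' extraction. The same pipeline is applied to simulated and experimental
#' images.
#'
#' @param raw Raw image matrix (slow, fast) in detector counts.
#' @param ctx The image's [geometry_context()].
#' @param quadrants Either `4` (all quadrants) or `1` (the fast path: only
#'   the quadrant named by `which`).
#' @param which Quadrant used when `quadrants = 1` (default `"UL"`, the
#'   quadrant the shipped models are trained on, in memory convention).
#' @param size Quadrant edge (default 512).
#' @return A list of `conditioned_quadrant` objects (length 4 or 1).
#' @export
condition_image <- function(raw, ctx, quadrants = 4L, which = "UL",
                            size = 512L) {
  stopifnot(quadrants %in% c(1L, 4L))
  ds <- maxpool_downsample(raw, ctx$detector$downsample)
  qn <- sqrt_quantize(ds)
  qs <- extract_quadrants(qn, ctx, size = size)
  if (quadrants == 1L) qs[which] else qs
}

#' Maximum-composite image
#'
#' Element-wise maximum across a set of equally shaped images, used to
#' visualize the aggregate diffraction extent of an image subset.
#'
#' @param images A list of numeric matrices of identical shape.
#' @return A matrix of the common shape.
#' @export
max_composite <- function(images) {
  if (!is.list(images) || length(images) == 0L) {
    stop("images must be a non-empty list of matrices", call. = FALSE)
  }
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all images must share the same shape", call. = FALSE)
  }
  Reduce(pmax, images)
}

#' @export
print.conditioned_quadrant <- function(x, ...) {
  cat(sprintf("<conditioned_quadrant %s> %dx%d, effective pixel %.4g mm\n",
              x$quadrant_id, nrow(x$pixels), ncol(x$pixels),
              x$effective_pixel_mm))
  invisible(x)
}
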