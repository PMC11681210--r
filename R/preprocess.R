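#' Preprocessing configuration
#'
#' Parameters of the image preparation chain applied before the network:
#' contrast-limited adaptive histogram equalization (CLAHE), denoising,
#' min-max intensity normalization, and resampling to a uniform input size.
#' The same chain is applied at training and inference time.
#'
#' @slot claheClipLimit per-bin clip limit as a fraction of the tile pixel
#'   count (> 0; larger values allow more contrast amplification).
#' @slot claheTiles tiles per image side.
#' @slot claheBins histogram bins.
#' @slot denoiseKernel odd kernel width in pixels; 1 disables denoising.
#' @slot denoiseMethod `"median"` (edge-preserving, the default for CT
#'   speckle) or `"gaussian"`.
#' @slot gaussianSigma standard deviation used by the Gaussian alternative.
#' @slot targetSize pixels per side after resizing (>= 32).
#' @slot normalizeRange numeric(2), target (low, high) intensities.
#' @export
setClass("PreprocessConfig", representation(
  claheClipLimit = "numeric", claheTiles = "integer", claheBins = "integer",
  denoiseKernel = "integer", denoiseMethod = "character",
  gaussianSigma = "numeric", targetSize = "integer",
  normalizeRange = "numeric"
))

setValidity("PreprocessConfig", function(object) {
  msg <- character(0)
  if (object@claheClipLimit <= 0)
    msg <- c(msg, "claheClipLimit must be > 0")
  if (object@claheTiles < 1L) msg <- c(msg, "claheTiles must be >= 1")
  if (object@claheBins < 2L) msg <- c(msg, "claheBins must be >= 2")
  k <- object@denoiseKernel
  if (k < 1L || k %% 2L == 0L)
    msg <- c(msg, "denoiseKernel must be odd and >= 1")
  if (!object@denoiseMethod %in% c("median", "gaussian"))
    msg <- c(msg, "denoiseMethod must be 'median' or 'gaussian'")
  if (object@targetSize < 32L) msg <- c(msg, "targetSize must be >= 32")
  r <- object@normalizeRange
  if (length(r) != 2L || r[1] >= r[2])
    msg <- c(msg, "normalizeRange must be (low, high) with low < high")
  if (length(msg)) msg else TRUE
})

#' Create a preprocessing configuration
#'
#' @param claheClipLimit CLAHE clip limit (fraction of tile pixels per bin).
#' @param claheTiles CLAHE tiles per side.
#' @param denoiseKernel odd median-filter width; 1 = no-op.
#' @param targetSize output pixels per side.
#' @param normalizeRange numeric(2) target intensity range.
#' @param denoiseMethod "median" or "gaussian".
#' @param gaussianSigma sigma for the Gaussian option.
#' @param claheBins CLAHE histogram bins.
#' @return A [PreprocessConfig-class].
#' @export
preprocessConfig <- function(claheClipLimit = 0.01, claheTiles = 8L,
                             denoiseKernel = 3L, targetSize = 256L,
                             normalizeRange = c(0, 1),
                             denoiseMethod = "median", gaussianSigma = 0.8,
                             claheBins = 256L) {
  obj <- tryCatch(new("PreprocessConfig",
    claheClipLimit = as.numeric(claheClipLimit),
    claheTiles = as.integer(claheTiles), claheBins = as.integer(claheBins),
    denoiseKernel = as.integer(denoiseKernel),
    denoiseMethod = as.character(denoiseMethod),
    gaussianSigma = as.numeric(gaussianSigma),
    targetSize = as.integer(targetSize),
    normalizeRange = as.numeric(normalizeRange)),
    error = function(e) stop_param(conditionMessage(e)))
  obj
}

.check_image2d <- function(image, what = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_shape(sprintf("%s must be a 2D numeric matrix", what))
  if (any(!is.finite(image)))
    stop_shape(sprintf("%s must be finite-valued", what))
  invisible(image)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit. The image is mapped
#' to \[0, 1\] by its own range, split into `claheTiles` x `claheTiles`
#' contiguous tiles (sizes differing by at most one pixel, so any image
#' size works), each tile's histogram is clipped at
#' `claheClipLimit * tilePixels` per bin with the excess redistributed
#' uniformly, and each pixel is mapped through a bilinear blend of the four
#' neighbouring tile CDFs. A constant image is returned unchanged (there is
#' no contrast to redistribute); because every tile CDF reaches exactly 1
#' at the top occupied bin, the map preserves the ordering of image values.
#'
#' @param image 2D numeric matrix.
#' @param cfg a [PreprocessConfig-class].
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
equalizeAdaptive <- function(image, cfg = preprocessConfig()) {
  .check_image2d(image)
  rng <- range(image)
  if (rng[1] == rng[2]) return(image)
  v <- (image - rng[1]) / (rng[2] - rng[1])
  nb <- cfg@claheBins
  t_ <- cfg@claheTiles
  h <- nrow(v); w <- ncol(v)
  bin <- pmin(floor(v * nb) + 1L, nb)
  # contiguous tile index per row/column (sizes differ by <= 1)
  rt <- as.integer(ceiling(seq_len(h) / h * t_))
  ct <- as.integer(ceiling(seq_len(w) / w * t_))
  # per-tile clipped CDFs: array (tiles_r, tiles_c, bins)
  cdf <- array(0, c(t_, t_, nb))
  for (i in seq_len(t_)) {
    for (j in seq_len(t_)) {
      b <- bin[rt == i, ct == j]
      counts <- tabulate(b, nbins = nb)
      ntile <- length(b)
      clip <- max(cfg@claheClipLimit * ntile, 1)
      excess <- sum(pmax(counts - clip, 0))
      counts <- pmin(counts, clip) + excess / nb
      cdf[i, j, ] <- cumsum(counts) / ntile
    }
  }
  # tile centres, then a bilinear blend of the 4 neighbouring tile maps
  centre <- function(npix, tiles) {
    sizes <- tabulate(as.integer(ceiling(seq_len(npix) / npix * tiles)),
                      nbins = tiles)
    cumsum(sizes) - (sizes - 1) / 2
  }
  rc <- centre(h, t_); cc <- centre(w, t_)
  low_high <- function(pos, centres) {
    t0 <- findInterval(pos, centres)
    t0c <- pmin(pmax(t0, 1L), length(centres))
    t1c <- pmin(t0 + 1L, length(centres))
    t1c <- pmax(t1c, 1L)
    wgt <- ifelse(t0 < 1 | t0 >= length(centres), 0,
                  (pos - centres[pmax(t0, 1L)]) /
                    (centres[pmin(t0 + 1L, length(centres))] -
                       centres[pmax(t0, 1L)]))
    wgt[t0 < 1] <- 1  # above: weight goes to t1c (== tile 1)
    list(lo = t0c, hi = t1c, w = wgt)
  }
  rr <- low_high(seq_len(h), rc)
  cw <- low_high(seq_len(w), cc)
  rlo <- matrix(rr$lo, h, w); rhi <- matrix(rr$hi, h, w)
  rw <- matrix(rr$w, h, w)
  clo <- matrix(cw$lo, h, w, byrow = TRUE)
  chi <- matrix(cw$hi, h, w, byrow = TRUE)
  cwg <- matrix(cw$w, h, w, byrow = TRUE)
  # within-bin linear interpolation of the CDF keeps the map continuous
  # even when a tile's values fall inside a single histogram bin
  frac <- pmin(pmax(v * nb - (bin - 1L), 0), 1)
  gather <- function(ri, ci) {
    ii <- cbind(as.vector(ri), as.vector(ci), as.vector(bin))
    c1 <- cdf[ii]
    ii[, 3] <- pmax(ii[, 3] - 1L, 1L)
    c0 <- cdf[ii]
    c0[as.vector(bin) == 1L] <- 0
    matrix(c0 + as.vector(frac) * (c1 - c0), h, w)
  }
  out <- (1 - rw) * (1 - cwg) * gather(rlo, clo) +
    (1 - rw) * cwg * gather(rlo, chi) +
    rw * (1 - cwg) * gather(rhi, clo) +
    rw * cwg * gather(rhi, chi)
  pmin(pmax(out, 0), 1)
}

#' Denoise an image
#'
#' Median filter of width `denoiseKernel` with replicate edge padding
#' (kernel 1 returns the input unchanged), or a Gaussian blur when
#' `denoiseMethod = "gaussian"`.
#'
#' @inheritParams equalizeAdaptive
#' @return matrix of the same shape.
#' @export
denoiseImage <- function(image, cfg = preprocessConfig()) {
  .check_image2d(image)
  k <- cfg@denoiseKernel
  if (k %% 2L == 0L) stop_param("denoise kernel must be odd")
  if (k == 1L) return(image)
  if (cfg@denoiseMethod == "median") {
    cpp_median_filter(image, k)
  } else {
    .gaussian_blur(image, k, cfg@gaussianSigma)
  }
}

# Separable Gaussian blur with replicate padding.
.gaussian_blur <- function(x, k, sigma) {
  r <- (k - 1L) / 2L
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  blur1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (d in (-r):r) {
      idx <- pmin(pmax(seq_len(n) + d, 1L), n)
      out <- out + kern[d + r + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(x))))
}

#' Min-max intensity normalization
#'
#' Linearly rescales the image so its minimum and maximum land on
#' `normalizeRange`. A constant image maps to the range midpoint by
#' convention.
#'
#' @inheritParams equalizeAdaptive
#' @return matrix of the same shape.
#' @export
normalizeIntensity <- function(image, cfg = preprocessConfig()) {
  .check_image2d(image)
  r <- cfg@normalizeRange
  rng <- range(image)
  if (rng[1] == rng[2]) {
    out <- image
    out[] <- mean(r)
    return(out)
  }
  r[1] + (image - rng[1]) / (rng[2] - rng[1]) * (r[2] - r[1])
}

# Nearest-neighbour resampling: output index i (0-based) reads input index
# floor(i * in/out), i.e. plain subsampling on integer downscales.
.resize_nearest <- function(x, h2, w2) {
  h <- nrow(x); w <- ncol(x)
  ri <- pmin(floor((seq_len(h2) - 1L) * h / h2) + 1L, h)
  ci <- pmin(floor((seq_len(w2) - 1L) * w / w2) + 1L, w)
  x[ri, ci, drop = FALSE]
}

# Separable bilinear resampling with half-pixel alignment:
# src = (i + 0.5) * in/out - 0.5, clamped to the valid range.
.resize_weights <- function(nin, nout) {
  src <- pmin(pmax((seq_len(nout) - 0.5) * nin / nout - 0.5, 0), nin - 1)
  i0 <- pmin(floor(src), nin - 1)
  frac <- src - i0
  wmat <- matrix(0, nout, nin)
  wmat[cbind(seq_len(nout), i0 + 1)] <-
    wmat[cbind(seq_len(nout), i0 + 1)] + (1 - frac)
  i1 <- pmin(i0 + 1, nin - 1)
  wmat[cbind(seq_len(nout), i1 + 1)] <-
    wmat[cbind(seq_len(nout), i1 + 1)] + frac
  wmat
}

.resize_bilinear <- function(x, h2, w2) {
  .resize_weights(nrow(x), h2) %*% x %*% t(.resize_weights(ncol(x), w2))
}

#' Resize an image or mask to a uniform square size
#'
#' Images use bilinear resampling; binary masks must use nearest-neighbour
#' (`method = "nearest"`) so values remain exactly \{0, 1\}.
#'
#' @param image 2D numeric matrix.
#' @param size target pixels per side (defaults to `cfg@targetSize`).
#' @param method "bilinear" or "nearest".
#' @param cfg a [PreprocessConfig-class].
#' @return `size` x `size` matrix.
#' @export
resizeImage <- function(image, size = cfg@targetSize,
                        method = c("bilinear", "nearest"),
                        cfg = preprocessConfig()) {
  .check_image2d(image)
  method <- match.arg(method)
  size <- as.integer(size)
  if (all(dim(image) == size)) return(image)
  if (method == "nearest") .resize_nearest(image, size, size)
  else .resize_bilinear(image, size, size)
}

#' Run the full preprocessing chain on a labeled sample
#'
#' Applies equalize -> denoise -> normalize -> resize to the image, and
#' only the geometric resize (nearest-neighbour) to the mask, so mask
#' values stay binary and image/mask shapes stay equal.
#'
#' @param sample a [LabeledSample-class].
#' @param cfg a [PreprocessConfig-class].
#' @return A preprocessed [LabeledSample-class].
#' @export
preprocessSample <- function(sample, cfg = preprocessConfig()) {
  if (!is(sample, "LabeledSample"))
    stop_param("sample must be a LabeledSample")
  img <- equalizeAdaptive(sampleImage(sample), cfg)
  img <- denoiseImage(img, cfg)
  img <- normalizeIntensity(img, cfg)
  img <- resizeImage(img, cfg@targetSize, "bilinear", cfg)
  msk <- resizeImage(sampleMask(sample) + 0, cfg@targetSize, "nearest", cfg)
  storage.mode(msk) <- "integer"
  meta <- sampleMeta(sample)
  meta$preprocessed <- TRUE
  new("LabeledSample", image = img, mask = msk, meta = meta)
}
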