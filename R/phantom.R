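#' Phantom specification
#'
#' Parameters of the synthetic CT-venography phantom generator. Each phantom
#' is a grayscale cross-section containing one or more bright elliptical
#' vessel lumina, each with a darker clot-like subregion (clots are filling
#' defects in contrast-enhanced CT), drawn over a low-frequency textured
#' background with additive Gaussian noise. The clot pixels are the
#' segmentation foreground and are recorded pixel-exactly in the mask before
#' any noise is added.
#'
#' @slot imageSize pixels per side of the square image (>= 32).
#' @slot nVessels number of vessels (>= 0; 0 gives an empty scene and is
#'   intended for degenerate-input tests).
#' @slot vesselRadiusRange numeric(2), min/max semi-axis length in pixels;
#'   the maximum must be below `imageSize / 2`.
#' @slot clotFraction fraction of each vessel's area occupied by the clot,
#'   in (0, 1].
#' @slot noiseSigma standard deviation of additive Gaussian intensity noise.
#' @slot backgroundLevel mean background intensity in \[0, 1\].
#' @slot seed integer RNG seed; identical (spec, seed) pairs reproduce
#'   bit-identical phantoms.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec", representation(
  imageSize = "integer",
  nVessels = "integer",
  vesselRadiusRange = "numeric",
  clotFraction = "numeric",
  noiseSigma = "numeric",
  backgroundLevel = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@imageSize < 32L)
    msg <- c(msg, "imageSize must be >= 32")
  if (object@nVessels < 0L)
    msg <- c(msg, "nVessels must be >= 0")
  r <- object@vesselRadiusRange
  if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
    msg <- c(msg, "vesselRadiusRange must be increasing and positive")
  if (length(r) == 2L && r[2] >= object@imageSize / 2)
    msg <- c(msg, "vesselRadiusRange max must be < imageSize/2")
  if (object@clotFraction <= 0 || object@clotFraction > 1)
    msg <- c(msg, "clotFraction must be in (0, 1]")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
    msg <- c(msg, "backgroundLevel must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a phantom specification
#'
#' Defaults describe a 64-pixel slice with two vessels of 6--14 px semi-axes,
#' a clot occupying half of each lumen, mild noise (sigma 0.03 on a \[0, 1\]
#' intensity scale) and a dim textured background.
#'
#' @param imageSize pixels per side (square image), >= 32.
#' @param nVessels number of vessels, >= 0.
#' @param vesselRadiusRange numeric(2) semi-axis range in pixels.
#' @param clotFraction fraction of vessel area marked as clot, in (0, 1].
#' @param noiseSigma additive Gaussian noise standard deviation.
#' @param backgroundLevel mean background intensity in \[0, 1\].
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(imageSize = 64, nVessels = 1, seed = 7)
#' s <- generatePhantom(spec)
#' sum(sampleMask(s))  # clot pixel count
#' @export
phantomSpec <- function(imageSize = 64L, nVessels = 2L,
                        vesselRadiusRange = c(6, 14), clotFraction = 0.5,
                        noiseSigma = 0.03, backgroundLevel = 0.2,
                        seed = 1L) {
  obj <- tryCatch(new("PhantomSpec",
    imageSize = as.integer(imageSize), nVessels = as.integer(nVessels),
    vesselRadiusRange = as.numeric(vesselRadiusRange),
    clotFraction = as.numeric(clotFraction),
    noiseSigma = as.numeric(noiseSigma),
    backgroundLevel = as.numeric(backgroundLevel), seed = as.integer(seed)),
    error = function(e) stop_param(conditionMessage(e)))
  obj
}

#' Labeled image/mask sample
#'
#' A grayscale image in \[0, 1\] with an aligned binary ground-truth mask
#' and a provenance record (the generating spec, seed, index, and the
#' rendered vessel geometry when synthetic).
#'
#' @slot image numeric matrix in \[0, 1\].
#' @slot mask integer matrix with values in \{0, 1\}, same shape as `image`.
#' @slot meta list of provenance fields.
#' @seealso [generatePhantom()], [preprocessSample()]
#' @export
setClass("LabeledSample", representation(
  image = "matrix", mask = "matrix", meta = "list"
))

setValidity("LabeledSample", function(object) {
  msg <- character(0)
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask shapes must be identical")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask values must be in {0, 1}")
  if (length(msg)) msg else TRUE
})

#' @describeIn LabeledSample-class image accessor
#' @param x a `LabeledSample`
#' @export
sampleImage <- function(x) x@image

#' @describeIn LabeledSample-class mask accessor
#' @export
sampleMask <- function(x) x@mask

#' @describeIn LabeledSample-class provenance accessor
#' @export
sampleMeta <- function(x) x@meta

setMethod("show", "LabeledSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledSample %dx%d, %d foreground px (%.1f%%)\n",
              d[1], d[2], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %dpx, %d vessel(s), radii [%g, %g], clot %.0f%%, noise %g, seed %d\n",
    object@imageSize, object@nVessels, object@vesselRadiusRange[1],
    object@vesselRadiusRange[2], 100 * object@clotFraction,
    object@noiseSigma, object@seed))
})

# Pixel-centre point-in-ellipse rasterization; returns a logical matrix.
# (cr, cc) is the centre in (row, col) coordinates, a/b the semi-axes,
# theta the orientation, scale a common shrink factor of both axes.
.ellipse_raster <- function(n, cr, cc, a, b, theta, scale = 1) {
  rr <- matrix(seq_len(n), n, n) - cr
  cc_ <- matrix(seq_len(n), n, n, byrow = TRUE) - cc
  u <- rr * cos(theta) + cc_ * sin(theta)
  w <- -rr * sin(theta) + cc_ * cos(theta)
  (u / (a * scale))^2 + (w / (b * scale))^2 <= 1
}

#' Generate one synthetic vascular phantom
#'
#' Renders `nVessels` bright elliptical lumina with darker concentric clot
#' subregions (area fraction `clotFraction` of the lumen, axes scaled by
#' `sqrt(clotFraction)`) on a low-frequency textured background, then adds
#' Gaussian noise and clamps to \[0, 1\]. The mask marks clot pixels exactly
#' as rasterized, before noise; noise never alters the mask. Vessels drawn
#' later overwrite earlier ones, and the mask tracks that overwriting.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [LabeledSample-class]; `sampleMeta()` carries the spec, seed
#'   and a `vessels` data frame with the rendered geometry (centre, axes,
#'   orientation, clot scale) for independent verification.
#' @export
generatePhantom <- function(spec) {
  if (!is(spec, "PhantomSpec")) stop_param("spec must be a PhantomSpec")
  v <- validObject(spec, test = TRUE)
  if (!isTRUE(v)) stop_param(paste(v, collapse = "; "))
  n <- spec@imageSize
  with_seed(spec@seed, {
    # background: mean level plus smoothed coarse-grid noise whose
    # amplitude scales with the level (a zero background stays zero)
    gs <- max(4L, n %/% 8L)
    coarse <- matrix(rnorm((gs + 1L)^2, 0, spec@backgroundLevel / 4),
                     gs + 1L, gs + 1L)
    tex <- .resize_bilinear(coarse, n, n)
    img <- spec@backgroundLevel + tex
    mask <- matrix(0L, n, n)
    geom <- data.frame(cr = numeric(0), cc = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0),
                       clotScale = numeric(0))
    cs <- sqrt(spec@clotFraction)
    for (k in seq_len(spec@nVessels)) {
      a <- runif(1, spec@vesselRadiusRange[1], spec@vesselRadiusRange[2])
      b <- runif(1, spec@vesselRadiusRange[1], spec@vesselRadiusRange[2])
      theta <- runif(1, 0, pi)
      margin <- max(a, b) + 1
      lim <- c(margin, n + 1 - margin)
      if (lim[1] >= lim[2]) lim <- c(n / 2, n / 2)
      cr <- runif(1, lim[1], lim[2])
      cc <- runif(1, lim[1], lim[2])
      lumen <- .ellipse_raster(n, cr, cc, a, b, theta)
      clot <- .ellipse_raster(n, cr, cc, a, b, theta, scale = cs)
      img[lumen] <- 0.78 + runif(1, 0, 0.04)
      img[clot] <- 0.45
      mask[lumen] <- 0L
      mask[clot] <- 1L
      geom <- rbind(geom, data.frame(cr = cr, cc = cc, a = a, b = b,
                                     theta = theta, clotScale = cs))
    }
    if (spec@noiseSigma > 0)
      img <- img + matrix(rnorm(n * n, 0, spec@noiseSigma), n, n)
    img <- pmin(pmax(img, 0), 1)
    new("LabeledSample", image = img, mask = mask,
        meta = list(spec = spec, seed = spec@seed, index = NA_integer_,
                    vessels = geom))
  })
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms with per-sample seeds split off a root seed, so the
#' sequence is reproducible while samples stay independent. Optionally
#' writes 8-bit grayscale PNG image/mask pairs (`_img.png` / `_mask.png`,
#' masks \{0, 255\} on disk) plus a tab-separated manifest
#' (columns `image`, `mask`, `seed`).
#'
#' @param spec a [PhantomSpec-class] shared by all samples (its own seed is
#'   ignored in favour of per-sample seeds).
#' @param n number of samples, >= 1.
#' @param seed root seed for the per-sample seed sequence.
#' @param dir optional output directory; created if missing.
#' @param prefix file-name prefix used when writing.
#' @return A list of [LabeledSample-class]; when `dir` is given, the
#'   manifest path is attached as attribute `"manifest"`.
#' @export
generateDataset <- function(spec, n, seed = spec@seed, dir = NULL,
                            prefix = "phantom") {
  if (!is.numeric(n) || n < 1) stop_param("n must be >= 1")
  n <- as.integer(n)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si@seed <- seeds[i]
    s <- generatePhantom(si)
    s@meta$index <- i
    samples[[i]] <- s
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop_io(sprintf("cannot create output directory '%s'", dir))
    rows <- lapply(seq_len(n), function(i) {
      ip <- file.path(dir, sprintf("%s_%04d_img.png", prefix, i))
      mp <- file.path(dir, sprintf("%s_%04d_mask.png", prefix, i))
      writeGrayscalePNG(sampleImage(samples[[i]]), ip)
      writeMaskPNG(sampleMask(samples[[i]]), mp)
      data.frame(image = ip, mask = mp, seed = seeds[i])
    })
    manifest <- file.path(dir, "manifest.tsv")
    writeManifest(do.call(rbind, rows), manifest)
    attr(samples, "manifest") <- manifest
  }
  samples
}

#' Construct a mask pair with exact confusion counts
#'
#' Builds a (ground truth, prediction) mask pair whose pixel-wise confusion
#' counts equal the four arguments exactly: a fixture for checking the
#' evaluation formulas. Pixels are laid out on the most square rectangle
#' dividing the total count and shuffled under `seed`.
#'
#' @param pCorrect true positives.
#' @param nCorrect true negatives.
#' @param pIncorrect false positives.
#' @param nIncorrect false negatives.
#' @param seed RNG seed for the pixel shuffle.
#' @return list with integer matrices `truth` and `pred`.
#' @export
generateConfusionFixture <- function(pCorrect, nCorrect, pIncorrect,
                                     nIncorrect, seed = 1L) {
  counts <- c(pCorrect, nCorrect, pIncorrect, nIncorrect)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_param("confusion counts must be non-negative integers")
  total <- sum(counts)
  if (total < 1) stop_param("confusion counts must sum to at least 1")
  h <- floor(sqrt(total))
  while (total %% h != 0) h <- h - 1
  w <- total %/% h
  truth <- c(rep(1L, pCorrect), rep(0L, nCorrect),
             rep(0L, pIncorrect), rep(1L, nIncorrect))
  pred <- c(rep(1L, pCorrect), rep(0L, nCorrect),
            rep(1L, pIncorrect), rep(0L, nIncorrect))
  perm <- with_seed(seed, sample.int(total))
  list(truth = matrix(truth[perm], h, w),
       pred = matrix(pred[perm], h, w))
}
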