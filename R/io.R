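# PNG image/mask I/O and the tab-separated dataset manifest.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG (or single-slice TIFF if the `tiff` package
#' is available) as a numeric matrix in \[0, 1\]. Color images are
#' converted with the standard luminance weights (0.299, 0.587, 0.114).
#' NIfTI volumes (`.nii`, `.nii.gz`; requires the `RNifti` package) are
#' read as a single axial slice, min-max scaled to \[0, 1\].
#'
#' @param path image file.
#' @param slice axial slice index for NIfTI volumes (default: middle
#'   slice); ignored for 2D formats.
#' @return numeric matrix in \[0, 1\].
#' @export
readGrayscale <- function(path, slice = NULL) {
  if (!file.exists(path)) stop_io(sprintf("image '%s' not found", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop_io("reading NIfTI requires the 'RNifti' package")
    vol <- RNifti::readNifti(path)
    v <- as.array(vol)
    if (length(dim(v)) >= 3L) {
      k <- slice %||% ((dim(v)[3] + 1L) %/% 2L)
      if (k < 1L || k > dim(v)[3])
        stop_valid(sprintf("slice %d outside volume (1..%d)", k, dim(v)[3]))
      v <- v[, , k]
    }
    rng <- range(v)
    return(if (rng[1] == rng[2]) matrix(0, nrow(v), ncol(v))
           else (v - rng[1]) / (rng[2] - rng[1]))
  }
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop_io("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  img
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param image numeric matrix; values are clamped to \[0, 1\].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGrayscalePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Write a binary mask as PNG
#'
#' Masks are strictly \{0, 255\} on disk, mapped to \{0, 1\} in memory.
#'
#' @param mask matrix with values in \{0, 1\}.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeMaskPNG <- function(mask, path) {
  .check_binary_mask(mask, "mask")
  png::writePNG(mask + 0, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' @param path mask file with on-disk values \{0, 255\}.
#' @return integer matrix with values in \{0, 1\}.
#' @export
readMaskPNG <- function(path) {
  m <- readGrayscale(path)
  if (any(m > 1 / 255 & m < 254 / 255))
    stop_valid(sprintf("mask '%s' is not binary", path))
  out <- (m > 0.5) + 0L
  storage.mode(out) <- "integer"
  out
}

#' Write a dataset manifest
#'
#' One row per sample: image path, mask path, seed; tab-separated.
#'
#' @param df data frame with columns `image`, `mask`, `seed`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeManifest <- function(df, path) {
  stopifnot(all(c("image", "mask", "seed") %in% names(df)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path manifest file written by [writeManifest()].
#' @return data frame with columns `image`, `mask`, `seed`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("manifest '%s' not found", path))
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("image", "mask") %in% names(df)))
    stop_valid("manifest must have 'image' and 'mask' columns")
  df
}

# Load the samples listed in a manifest, reporting every offending row.
.load_manifest_samples <- function(manifest) {
  df <- readManifest(manifest)
  if (nrow(df) == 0) stop_valid("manifest is empty")
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  bad <- character(0)
  samples <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ip <- resolve(df$image[i])
    mp <- resolve(df$mask[i])
    res <- tryCatch({
      img <- readGrayscale(ip)
      msk <- readMaskPNG(mp)
      if (!identical(dim(img), dim(msk)))
        stop_valid("image/mask shape mismatch")
      new("LabeledSample", image = img, mask = msk,
          meta = list(image = ip, mask = mp,
                      seed = if ("seed" %in% names(df)) df$seed[i]
                      else NA_integer_))
    }, thromboseg_error = function(e) conditionMessage(e),
       error = function(e) conditionMessage(e))
    if (is.character(res)) bad <- c(bad, sprintf("row %d: %s", i, res))
    else samples[[i]] <- res
  }
  if (length(bad))
    stop_valid(paste(c("manifest rows failed validation:", bad),
                     collapse = "\n  "))
  samples
}
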