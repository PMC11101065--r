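#' @title Image feature extraction
#' @description The three predictor families used by the classifier: per-channel
#'   intensity means, grayscale (luma) conversion, and one-dimensional Shannon
#'   entropy of the 256-bin grayscale histogram.
#' @name image-features
NULL

as_pixel_array <- function(image) {
  if (inherits(image, "rgb_image")) return(image$pixels)
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3L] >= 3L)
    return(image[, , 1:3, drop = FALSE])
  stop("expected an rgb_image or a height x width x 3 array")
}

# round half away from zero (pixel intensities are non-negative, so this is
# floor(x + 0.5)); base round() is round-half-even
round_half_up <- function(x) floor(x + 0.5)

#' Convert an RGB image to grayscale
#'
#' Per-pixel ITU-R BT.601 luma: `round(0.299 R + 0.587 G + 0.114 B)` with
#' round-half-away-from-zero, giving integer gray levels in \[0, 255\].
#'
#' @param image An `rgb_image` (from [render_image()] / [read_image()]) or a
#'   height x width x 3 integer array with intensities in \[0, 255\].
#' @return Integer matrix (height x width) of gray levels.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(px)  # 76
#' @export
to_grayscale <- function(image) {
  px <- as_pixel_array(image)
  if (prod(dim(px)[1:2]) < 1L) stop("image has no pixels")
  g <- 0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
  matrix(as.integer(round_half_up(g)), nrow = dim(px)[1L])
}

#' Per-channel mean intensities
#'
#' The exact arithmetic mean of each channel over all N pixels,
#' `avg_C = (C_1 + ... + C_N) / N`, unrounded.
#'
#' @inheritParams to_grayscale
#' @return Named numeric vector `c(avg_r, avg_g, avg_b)`.
#' @export
channel_means <- function(image) {
  px <- as_pixel_array(image)
  if (prod(dim(px)[1:2]) < 1L) stop("image has no pixels")
  c(avg_r = mean(px[, , 1L]), avg_g = mean(px[, , 2L]), avg_b = mean(px[, , 3L]))
}

#' One-dimensional entropy of a grayscale image
#'
#' Shannon entropy of the 256-bin gray-level histogram,
#' `H = -sum_i P_i log2 P_i`, where `P_i` is the proportion of pixels with
#' gray level `i` (0-255). Empty bins contribute zero (`0 log 0 = 0`), so
#' `H` lies in \[0, 8\] bits, with 0 for a constant image and 8 for an image
#' using all 256 levels equally.
#'
#' @param gray Integer matrix of gray levels in \[0, 255\] (e.g. from
#'   [to_grayscale()]), or an RGB image which is converted first.
#' @return Entropy in bits.
#' @examples
#' gray_entropy(matrix(c(0L, 0L, 255L, 255L), 2))  # 1 bit
#' @export
gray_entropy <- function(gray) {
  if (inherits(gray, "rgb_image") ||
      (is.array(gray) && length(dim(gray)) == 3L))
    gray <- to_grayscale(gray)
  v <- as.integer(gray)
  if (length(v) < 1L) stop("image has no pixels")
  if (any(v < 0L | v > 255L)) stop("gray levels must lie in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts[counts > 0L] / length(v)
  -sum(p * log2(p))
}

#' Read an 8-bit RGB image from disk
#'
#' Reads PNG (via the png package) or TIFF (via the tiff package, if
#' installed). Grayscale images are promoted to three identical channels; an
#' alpha channel is dropped. Inputs that do not decode to 8-bit integer
#' intensities are rejected with a format diagnostic.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An `rgb_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format '.", ext, "' (supported: png, tif/tiff)")
  )
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3L] == 2L)                       # gray + alpha
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  raw <- raw[, , 1:3, drop = FALSE]
  scaled <- raw * 255
  if (max(abs(scaled - round(scaled))) > 1e-6)
    stop("not an 8-bit image: ", path,
         " (decoded intensities are not multiples of 1/255)")
  px <- array(as.integer(round(scaled)), dim = dim(raw))
  structure(list(pixels = px, clipped = FALSE, clip_fraction = 0,
                 target = NULL, window = NA_integer_),
            class = "rgb_image")
}

#' Extract the feature table from an image manifest
#'
#' Applies [channel_means()], [to_grayscale()] and [gray_entropy()] to every
#' image listed in a manifest, preserving row order. Unreadable or malformed
#' files do not abort the batch: the row is dropped and the failure recorded.
#'
#' @param manifest A data.frame with columns `image_id`, `path` and optionally
#'   `label`, or the path to such a CSV (as written by [generate_dataset()]).
#' @param gray_dir Optional directory; when given, the grayscale conversion of
#'   every image is written there as `<image_id>_gray.png` for audit.
#' @return Feature table data.frame (`image_id`, `label` if present, `avg_r`,
#'   `avg_g`, `avg_b`, `entropy`) with a `failures` attribute: a data.frame of
#'   `image_id`, `path`, `error` for any rows that could not be processed.
#' @export
extract_features <- function(manifest, gray_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(manifest))
  if (nrow(manifest) > 0L && !all(c("image_id", "path") %in% names(manifest)))
    stop("manifest needs columns image_id and path")
  has_label <- "label" %in% names(manifest)
  if (!is.null(gray_dir) && !dir.exists(gray_dir))
    dir.create(gray_dir, recursive = TRUE)

  rows <- vector("list", nrow(manifest))
  fails <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      img <- read_image(manifest$path[i])
      gray <- to_grayscale(img)
      if (!is.null(gray_dir))
        png::writePNG(gray / 255,
                      file.path(gray_dir, paste0(manifest$image_id[i], "_gray.png")))
      cm <- channel_means(img)
      c(cm, entropy = gray_entropy(gray))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        image_id = manifest$image_id[i], path = manifest$path[i],
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        image_id = manifest$image_id[i],
        label = if (has_label) manifest$label[i] else NA_character_,
        avg_r = res[["avg_r"]], avg_g = res[["avg_g"]], avg_b = res[["avg_b"]],
        entropy = res[["entropy"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(image_id = character(), label = character(),
                      avg_r = numeric(), avg_g = numeric(), avg_b = numeric(),
                      entropy = numeric(), stringsAsFactors = FALSE)
  if (!has_label) out$label <- NULL
  else out$label <- factor(out$label, levels = c("benign", "malignant"))
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(image_id = character(), path = character(), error = character())
  out
}
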