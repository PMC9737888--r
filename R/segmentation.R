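# Canopy/background segmentation: ExG conversion, 1-D 2-means binarisation,
# morphological cleanup.

#' Excess-green (ExG) map of an RGB image
#'
#' Computes per-pixel ExG = 2g - r - b on channels scaled to 0..1, the
#' standard RGB-only greenness index used to separate vegetation from soil.
#'
#' @param image H x W x 3 8-bit RGB array.
#' @return H x W numeric matrix with values in \eqn{[-2, 2]}.
#' @examples
#' img <- array(c(0, 255, 0), dim = c(1, 1, 3))  # pure green pixel
#' exg_map(img)  # 2
#' @export
exg_map <- function(image) {
  assert_image(image)
  matrix((2 * image[, , 2] - image[, , 1] - image[, , 3]) / 255,
         dim(image)[1], dim(image)[2])
}

#' Binarise a grayscale raster by two-cluster K-means
#'
#' Clusters the pixel values into two groups with 1-D K-means initialised at
#' the 25th/75th percentiles; the cluster with the higher mean value is
#' labelled canopy (1). The rule is value-ordered, not semantic: on an
#' inverted scene the brighter (greener, for ExG input) cluster is still 1.
#'
#' @param gray Numeric matrix (typically an ExG map).
#' @param seed Integer seed (K-means with fixed percentile centres is already
#'   deterministic; the seed guards the fallback restarts).
#' @return Binary 0/1 matrix of the same shape.
#' @export
kmeans_binarize <- function(gray, seed = 0L) {
  if (!is.matrix(gray)) stop_param("`gray` must be a numeric matrix")
  v <- as.vector(gray)
  if (anyNA(v)) stop_param("`gray` contains missing values")
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    stop_param("raster is constant: no canopy separable into two clusters")
  }
  centers <- unname(quantile(v, c(0.25, 0.75)))
  if (diff(centers) < 1e-12) {
    # Degenerate quartiles (heavily tied data); spread to the data range.
    centers <- rng + c(0.25, -0.25) * diff(rng)
  }
  km <- with_seed(seed,
                  kmeans(v, centers = matrix(centers, 2, 1), iter.max = 100))
  hi <- which.max(km$centers)
  matrix(as.integer(km$cluster == hi), nrow(gray), ncol(gray))
}

# Binary dilation/erosion with a disk structuring element and replicate
# border padding, via shift-and-combine over the disk's offsets.
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_replicate <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[clamp(seq_len(h) - dy, 1, h), clamp(seq_len(w) - dx, 1, w), drop = FALSE]
}

binary_dilate <- function(mask, offsets) {
  out <- mask
  for (k in seq_len(nrow(offsets))) {
    out <- pmax(out, shift_replicate(mask, offsets$dy[k], offsets$dx[k]))
  }
  out
}

binary_erode <- function(mask, offsets) {
  out <- mask
  for (k in seq_len(nrow(offsets))) {
    out <- pmin(out, shift_replicate(mask, offsets$dy[k], offsets$dx[k]))
  }
  out
}

#' Morphological opening-then-closing of a binary mask
#'
#' Opening (erosion then dilation) with a disk of `open_radius` removes
#' speckle noise; closing (dilation then erosion) with `close_radius` fills
#' small holes. Borders are padded by replication, so an all-ones mask stays
#' all ones, and re-applying the same radii is idempotent.
#'
#' @param mask Binary 0/1 matrix.
#' @param open_radius,close_radius Disk radii in pixels (0 disables the step).
#' @return Cleaned binary matrix.
#' @export
morphological_clean <- function(mask, open_radius = 2, close_radius = 2) {
  assert_mask(mask)
  if (open_radius < 0 || close_radius < 0) {
    stop_param("morphology radii must be non-negative")
  }
  out <- mask
  if (open_radius > 0) {
    off <- disk_offsets(open_radius)
    out <- binary_dilate(binary_erode(out, off), off)
  }
  if (close_radius > 0) {
    off <- disk_offsets(close_radius)
    out <- binary_erode(binary_dilate(out, off), off)
  }
  out
}

#' Segment canopy from background
#'
#' The full segmentation chain: ExG conversion, two-cluster K-means
#' binarisation (higher-ExG cluster = canopy), then morphological
#' opening/closing. Fails explicitly when the ExG raster carries no contrast
#' (e.g. a pure-soil image).
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param seed Integer seed for the binarisation step.
#' @param open_radius,close_radius Disk radii for [morphological_clean()].
#' @return Binary H x W matrix, 1 = canopy.
#' @examples
#' sc <- scene_config(image_size = c(64, 64))
#' scn <- generate_plot_image(sc, days_to_maturity = 30, plot_id = 1)
#' m <- segment_canopy(scn$image)
#' mean(m == scn$mask)  # pixel agreement with ground truth
#' @export
segment_canopy <- function(image, seed = 0L, open_radius = 2, close_radius = 2) {
  exg <- exg_map(image)
  if (diff(range(exg)) < 1e-12) {
    stop_param("no canopy separable: image has constant ExG")
  }
  mask <- kmeans_binarize(exg, seed = seed)
  morphological_clean(mask, open_radius, close_radius)
}

#' Write a canopy mask as a grayscale PNG with a JSON sidecar
#'
#' @param mask Binary matrix from [segment_canopy()].
#' @param path Output PNG path; the sidecar `<path>.json` records the canopy
#'   fraction.
#' @return Invisibly, the canopy fraction.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask + 0, path)
  frac <- mean(mask)
  jsonlite::write_json(list(canopy_fraction = frac), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(frac)
}
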