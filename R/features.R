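# The 22-dimensional per-plot feature vector: 5 vegetation indices, 9 colour
# components, 8 texture statistics, each aggregated over canopy pixels.

#' Canonical feature names, in table order
#' @return Character vector of the 22 feature names.
#' @export
feature_names <- function() {
  c("NGRDI", "GLA", "VARI", "ExG", "NDYI",
    "HSV_H", "HSV_S", "HSV_V", "HLS_H", "HLS_L", "HLS_S",
    "Lab_L", "Lab_a", "Lab_b",
    "HOM", "CON", "DIS", "ENT", "ASM", "COR", "LBP", "Gabor")
}

#' @rdname feature_names
#' @export
vegetation_index_names <- function() c("NGRDI", "GLA", "VARI", "ExG", "NDYI")

#' @rdname feature_names
#' @export
color_feature_names <- function() {
  c("HSV_H", "HSV_S", "HSV_V", "HLS_H", "HLS_L", "HLS_S",
    "Lab_L", "Lab_a", "Lab_b")
}

#' @rdname feature_names
#' @export
texture_feature_names <- function() {
  c("HOM", "CON", "DIS", "ENT", "ASM", "COR", "LBP", "Gabor")
}

# Ratio-index mean with a denominator guard: pixels whose denominator
# magnitude falls below `eps` are excluded; all excluded is an error.
guarded_mean <- function(num, den, name, eps = 1e-6) {
  ok <- abs(den) >= eps
  if (!any(ok)) {
    stop_param("all canopy pixels excluded for index %s (vanishing denominator)",
               name)
  }
  mean(num[ok] / den[ok])
}

#' Canopy-mean vegetation indices
#'
#' Computes NGRDI = (g-r)/(g+r), GLA = (2g-r-b)/(2g+r+b), VARI = (g-r)/(g+r-b),
#' ExG = 2g-r-b and NDYI = (g-b)/(g+b) per canopy pixel on unit-scaled
#' channels and averages each over the canopy. Pixels whose denominator is
#' smaller than 1e-6 in magnitude are excluded from that index's mean.
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param mask Binary canopy mask with at least one canopy pixel.
#' @return Named numeric vector of the 5 index means.
#' @examples
#' img <- array(rep(c(64, 128, 64), each = 4), dim = c(2, 2, 3))
#' vegetation_indices(img, matrix(1, 2, 2))["NGRDI"]  # (g-r)/(g+r) = 1/3
#' @export
vegetation_indices <- function(image, mask) {
  assert_image(image); assert_mask(mask, image)
  if (sum(mask) == 0) stop_param("empty mask: no canopy pixels")
  m <- channel_matrix(image, mask)
  r <- m[, 1]; g <- m[, 2]; b <- m[, 3]
  c(NGRDI = guarded_mean(g - r, g + r, "NGRDI"),
    GLA = guarded_mean(2 * g - r - b, 2 * g + r + b, "GLA"),
    VARI = guarded_mean(g - r, g + r - b, "VARI"),
    ExG = mean(2 * g - r - b),
    NDYI = guarded_mean(g - b, g + b, "NDYI"))
}

#' Canopy-mean colour components in HSV, HLS and Lab
#'
#' Converts canopy pixels to HSV, HLS (hue on [0,1), saturation/value/
#' lightness on 0..1) and CIE Lab (sRGB primaries, D65 white; L in 0..100,
#' a/b on their native scale), then averages each component over the canopy.
#' Hue, being circular, is aggregated with a circular mean.
#'
#' @inheritParams vegetation_indices
#' @return Named numeric vector of the 9 component means.
#' @export
color_features <- function(image, mask) {
  assert_image(image); assert_mask(mask, image)
  if (sum(mask) == 0) stop_param("empty mask: no canopy pixels")
  m <- channel_matrix(image, mask)
  hsv <- rgb_to_hsv_mat(m)
  hls <- rgb_to_hls_mat(m)
  lab <- rgb_to_lab_mat(m)
  c(HSV_H = circular_mean01(hsv[, "h"]),
    HSV_S = mean(hsv[, "s"]),
    HSV_V = mean(hsv[, "v"]),
    HLS_H = circular_mean01(hls[, "h"]),
    HLS_L = mean(hls[, "l"]),
    HLS_S = mean(hls[, "s"]),
    Lab_L = mean(lab[, "l"]),
    Lab_a = mean(lab[, "a"]),
    Lab_b = mean(lab[, "b"]))
}

# Standard luminance grayscale on the 0-255 scale.
gray_luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Extraction parameters for the texture features
#'
#' @param glcm_levels Grey levels for GLCM quantization.
#' @param glcm_distance Co-occurrence pair distance in pixels.
#' @param glcm_angles Angles (degrees) averaged in the GLCM.
#' @param lbp_radius,lbp_points LBP neighbourhood geometry.
#' @param gabor_frequency Gabor spatial frequency, cycles/pixel.
#' @param gabor_orientations Number of Gabor orientations.
#' @param gabor_sigma Gabor envelope standard deviation, pixels.
#' @return A list of texture parameters, suitable for [extract_features()].
#' @export
texture_params <- function(glcm_levels = 32L, glcm_distance = 1L,
                           glcm_angles = c(0, 45, 90, 135),
                           lbp_radius = 1L, lbp_points = 8L,
                           gabor_frequency = 0.25, gabor_orientations = 4L,
                           gabor_sigma = 2) {
  list(glcm_levels = glcm_levels, glcm_distance = glcm_distance,
       glcm_angles = glcm_angles, lbp_radius = lbp_radius,
       lbp_points = lbp_points, gabor_frequency = gabor_frequency,
       gabor_orientations = gabor_orientations, gabor_sigma = gabor_sigma)
}

#' Extract the full 22-feature vector from one plot image
#'
#' Composes [vegetation_indices()], [color_features()] and the texture
#' statistics (GLCM on the canopy-masked quantized luminance, LBP and Gabor
#' means over canopy pixels) into the fixed 22-feature vector.
#'
#' @inheritParams vegetation_indices
#' @param params Texture parameters from [texture_params()].
#' @return Named numeric vector with the 22 entries of [feature_names()].
#' @examples
#' sc <- scene_config(image_size = c(64, 64))
#' scn <- generate_plot_image(sc, days_to_maturity = 17, plot_id = 1)
#' fv <- extract_features(scn$image, scn$mask)
#' length(fv)  # 22
#' @export
extract_features <- function(image, mask, params = texture_params()) {
  vi <- vegetation_indices(image, mask)
  cf <- color_features(image, mask)
  gray <- gray_luminance(image)
  q <- quantize_gray(gray, params$glcm_levels)
  P <- glcm(q, levels = params$glcm_levels, distance = params$glcm_distance,
            angles = params$glcm_angles, mask = mask)
  gs <- glcm_stats(P)
  lbp <- lbp_mean(gray, mask, params$lbp_radius, params$lbp_points)
  gab <- gabor_mean(gray, mask, params$gabor_frequency,
                    params$gabor_orientations, params$gabor_sigma)
  out <- c(vi, cf, gs, LBP = lbp, Gabor = gab)[feature_names()]
  bad <- names(out)[!is.finite(out)]
  if (length(bad) > 0) {
    stop_param("feature(s) %s could not be computed (degenerate input)",
               paste(bad, collapse = ", "))
  }
  out
}

#' Extract a feature table from a simulated or segmented campaign
#'
#' Runs segmentation (unless ground-truth masks are requested) and feature
#' extraction for every plot-date row of a campaign tibble, returning one row
#' per sample with the 22 features plus identifiers.
#'
#' @param series Tibble from [generate_time_series()], or any tibble with
#'   `plot_id`, `capture_date` and an `image` list-column (and a `mask`
#'   list-column when `use_truth_masks = TRUE`).
#' @param params Texture parameters, see [texture_params()].
#' @param use_truth_masks Use the generator's ground-truth masks instead of
#'   running [segment_canopy()] (useful to isolate extraction from
#'   segmentation error).
#' @param seed Seed forwarded to the segmentation step.
#' @return A tibble: `plot_id`, `capture_date`, a `mask` list-column (the
#'   masks actually used) and the 22 feature columns.
#' @export
extract_feature_table <- function(series, params = texture_params(),
                                  use_truth_masks = FALSE, seed = 0L) {
  stopifnot(is.data.frame(series), "image" %in% names(series))
  masks <- if (use_truth_masks) {
    series$mask
  } else {
    purrr::imap(series$image, function(img, i) {
      segment_canopy(img, seed = derive_seed(seed, i))
    })
  }
  feats <- purrr::map2(series$image, masks,
                       function(img, m) extract_features(img, m, params))
  out <- dplyr::bind_cols(
    tibble(plot_id = series$plot_id, capture_date = series$capture_date),
    as_tibble(do.call(rbind, feats)))
  out$mask <- masks
  dplyr::relocate(out, "mask", .after = "capture_date")
}

#' Write a feature table to CSV
#'
#' Drops list-columns (masks/images) and writes the tabular part.
#'
#' @param table Feature table tibble.
#' @param path Output CSV path.
#' @return Invisibly, the written tibble.
#' @export
write_feature_table <- function(table, path) {
  flat <- table[, !vapply(table, is.list, logical(1)), drop = FALSE]
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(flat)
}
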