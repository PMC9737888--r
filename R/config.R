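#' Configuration for the synthetic plot-scene generator
#'
#' Describes a simulated field campaign: a grid of plot crops imaged at a
#' handful of dates spanning squaring to maturity. Canopy cover rises as the
#' crop grows, canopy colour drifts from vivid green towards a dull
#' green-brown, an increasing fraction of canopy pixels is drawn from a brown
#' "mature grain" distribution, and the early row structure fades. The
#' defaults correspond to a 3 x 3 m plot crop at roughly centimetre ground
#' resolution imaged six times between 36 and 3 days before harvest.
#'
#' @param image_size Integer vector `c(H, W)` in pixels; both at least 32.
#' @param n_plots Number of plots in the campaign.
#' @param capture_offsets Days before harvest for each imaging date, strictly
#'   decreasing. The default mirrors a six-date September-October campaign.
#' @param row_spacing Sowing-row period in pixels.
#' @param blob_scale Correlation length (pixels) of the canopy placement
#'   field: canopy occurs in leaf-scale blobs of roughly this radius rather
#'   than independent pixels, so morphological cleanup behaves as it would
#'   on real canopies.
#' @param canopy_fraction_curve Function mapping days-to-maturity to the
#'   expected fraction of the plot covered by canopy (non-increasing in days).
#' @param color_trajectory Function mapping days-to-maturity to a list with
#'   elements `canopy_rgb` (mean 8-bit RGB of live canopy), `brown_rgb` (mean
#'   RGB of mature/brown canopy pixels) and `brown_fraction` (probability a
#'   canopy pixel is drawn from the brown distribution; non-decreasing as
#'   days-to-maturity shrinks).
#' @param soil_rgb Mean 8-bit RGB of background soil.
#' @param row_contrast_curve Function mapping days-to-maturity to the relative
#'   amplitude of the sinusoidal row modulation of canopy cover (rows are
#'   sharp early and fade as the canopy closes).
#' @param illumination_jitter_sd Standard deviation of the per-image
#'   multiplicative log-normal brightness factor.
#' @param pixel_noise_sd Additive per-channel Gaussian noise, 8-bit units.
#' @param exg_margin Required minimum gap between mean canopy ExG and mean
#'   soil ExG (on the -2..2 scale); generation fails if a configuration
#'   cannot honour it.
#' @param seed Master integer seed; all randomness derives from it.
#'
#' @return An object of class `scene_config`.
#' @seealso [generate_plot_image()], [generate_time_series()]
#' @export
scene_config <- function(image_size = c(256L, 256L),
                         n_plots = 35L,
                         capture_offsets = c(36, 30, 24, 17, 7, 3),
                         row_spacing = 16,
                         blob_scale = 3,
                         canopy_fraction_curve = default_canopy_fraction,
                         color_trajectory = default_color_trajectory,
                         soil_rgb = c(115, 75, 70),
                         row_contrast_curve = default_row_contrast,
                         illumination_jitter_sd = 0.05,
                         pixel_noise_sd = 6,
                         exg_margin = 0.1,
                         seed = 1L) {
  image_size <- as.integer(rep(image_size, length.out = 2L))
  if (any(image_size < 32L)) {
    stop_param("image_size must be at least 32 x 32 (got %d x %d)",
               image_size[1], image_size[2])
  }
  if (n_plots < 1L) stop_param("n_plots must be positive")
  if (length(capture_offsets) == 0L) {
    stop_param("capture_offsets must be non-empty")
  }
  if (any(capture_offsets < 0)) stop_param("capture_offsets must be >= 0")
  if (length(capture_offsets) > 1L && any(diff(capture_offsets) >= 0)) {
    stop_param("capture_offsets must be strictly decreasing")
  }
  if (row_spacing < 2) stop_param("row_spacing must be >= 2 pixels")
  if (blob_scale <= 0) stop_param("blob_scale must be positive")
  if (illumination_jitter_sd < 0 || pixel_noise_sd < 0) {
    stop_param("noise standard deviations must be non-negative")
  }
  stopifnot(is.function(canopy_fraction_curve), is.function(color_trajectory),
            is.function(row_contrast_curve))
  structure(
    list(image_size = image_size, n_plots = as.integer(n_plots),
         capture_offsets = capture_offsets, row_spacing = row_spacing,
         blob_scale = blob_scale,
         canopy_fraction_curve = canopy_fraction_curve,
         color_trajectory = color_trajectory,
         soil_rgb = as.numeric(soil_rgb),
         row_contrast_curve = row_contrast_curve,
         illumination_jitter_sd = illumination_jitter_sd,
         pixel_noise_sd = pixel_noise_sd,
         exg_margin = exg_margin, seed = as.integer(seed)),
    class = "scene_config")
}

# Maturity progress on [0, 1]: 0 at 36+ days to harvest, 1 at harvest.
maturity_progress <- function(days_to_maturity, span = 36) {
  clamp(1 - days_to_maturity / span, 0, 1)
}

#' @rdname scene_config
#' @param days_to_maturity Days remaining until harvest.
#' @export
default_canopy_fraction <- function(days_to_maturity) {
  0.35 + 0.5 * maturity_progress(days_to_maturity)
}

#' @rdname scene_config
#' @export
default_color_trajectory <- function(days_to_maturity) {
  u <- maturity_progress(days_to_maturity)
  green_early <- c(50, 110, 40)
  green_late <- c(90, 100, 55)
  list(canopy_rgb = green_early + u * (green_late - green_early),
       brown_rgb = c(150, 112, 35),
       brown_fraction = 0.85 * u)
}

#' @rdname scene_config
#' @export
default_row_contrast <- function(days_to_maturity) {
  0.5 * clamp(days_to_maturity / 36, 0, 1)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  %d plots, %d x %d px, offsets {%s} days before harvest\n",
              x$n_plots, x$image_size[1], x$image_size[2],
              paste(x$capture_offsets, collapse = ", ")))
  cat(sprintf("  soil RGB (%s), pixel noise sd %.1f, illumination sd %.2f, seed %d\n",
              paste(round(x$soil_rgb), collapse = ","), x$pixel_noise_sd,
              x$illumination_jitter_sd, x$seed))
  invisible(x)
}

#' Configuration for the synthetic feature-table generator
#'
#' Generates a tabular regression problem with known structure: informative
#' columns that drive the label linearly, redundant columns that are noisy
#' near-copies of informative ones (population correlation about
#' `redundant_r`), and pure-noise columns independent of the label. Used to
#' exercise correlation pruning and recursive feature elimination where the
#' ground truth is known by construction.
#'
#' @param n_samples Number of rows (at least 3; correlation is undefined below).
#' @param n_informative Number of label-driving columns (at least 1).
#' @param n_redundant Number of near-duplicate columns; redundant column `j`
#'   copies informative column `((j - 1) %% n_informative) + 1`.
#' @param n_noise Number of label-independent columns.
#' @param effect_sizes Coefficient per informative column; recycled.
#' @param noise_sd Standard deviation of the additive label noise.
#' @param redundant_r Target population correlation between a redundant column
#'   and its parent (must exceed 0.95 for the pruning guarantees to hold).
#' @param seed Integer seed.
#'
#' @return An object of class `table_config`.
#' @seealso [generate_feature_table()]
#' @export
table_config <- function(n_samples = 500L,
                         n_informative = 3L,
                         n_redundant = 2L,
                         n_noise = 5L,
                         effect_sizes = c(3, 2, 1),
                         noise_sd = 0.5,
                         redundant_r = 0.98,
                         seed = 1L) {
  if (n_samples < 3L) stop_param("n_samples must be >= 3")
  if (n_informative < 1L) stop_param("n_informative must be >= 1")
  if (n_redundant < 0L || n_noise < 0L) {
    stop_param("column counts must be non-negative")
  }
  if (noise_sd < 0) stop_param("noise_sd must be non-negative")
  if (redundant_r <= 0 || redundant_r >= 1) {
    stop_param("redundant_r must lie in (0, 1)")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_informative = as.integer(n_informative),
         n_redundant = as.integer(n_redundant),
         n_noise = as.integer(n_noise),
         effect_sizes = rep_len(as.numeric(effect_sizes), n_informative),
         noise_sd = noise_sd, redundant_r = redundant_r,
         seed = as.integer(seed)),
    class = "table_config")
}

#' @export
print.table_config <- function(x, ...) {
  cat(sprintf(
    "<table_config> %d rows; %d informative + %d redundant (r ~ %.2f) + %d noise cols; label sd %.2f; seed %d\n",
    x$n_samples, x$n_informative, x$n_redundant, x$redundant_r, x$n_noise,
    x$noise_sd, x$seed))
  invisible(x)
}
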