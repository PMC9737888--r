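# Synthetic plot-scene rendering.
#
# A scene is an 8-bit RGB raster in which background soil, live (green)
# canopy and mature (brown) canopy pixels are drawn from three Gaussian
# colour distributions. Canopy placement follows a per-pixel Bernoulli field
# whose probability carries a sinusoidal row modulation that fades as the
# canopy closes, so both coverage and texture change with growth stage.

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

hash_id <- function(id) sum(utf8ToInt(as.character(id))) %% 99991L

# Spatially correlated field with an exactly uniform [0, 1] marginal:
# Gaussian white noise smoothed with a Gaussian kernel, then rank-mapped.
smooth_uniform_field <- function(h, w, sigma = 3) {
  g <- matrix(rnorm(h * w), h, w)
  half <- ceiling(3 * sigma)
  ax <- (-half):half
  k1 <- exp(-ax^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  sm <- conv2_same(g, kern / sum(kern))
  matrix(rank(sm, ties.method = "first") / (h * w + 1), h, w)
}

#' Render one synthetic plot image
#'
#' Draws a single plot crop at a given number of days before harvest. Canopy
#' pixels are placed by a row-modulated Bernoulli field; each canopy pixel is
#' independently brown with the trajectory's brown fraction; per-channel
#' Gaussian pixel noise and a per-image multiplicative illumination factor
#' are applied last. The ground-truth canopy mask and the realised brown
#' fraction (the generator's own category assignments) are returned with the
#' image, so downstream stages can be validated against exact truth.
#'
#' @param config A [scene_config()].
#' @param days_to_maturity Days remaining until harvest (>= 0).
#' @param plot_id Plot identifier (used both as metadata and, together with
#'   `days_to_maturity`, to derive the default seed).
#' @param seed Integer seed for this image; default derives deterministically
#'   from `config$seed`, `plot_id` and `days_to_maturity`.
#'
#' @return A `plot_scene` list: `image` (H x W x 3 array, values 0-255),
#'   `mask` (H x W 0/1 matrix, 1 = canopy), `brown_fraction` (realised
#'   fraction of canopy pixels drawn brown), `days_to_maturity`, `plot_id`.
#' @examples
#' sc <- scene_config(image_size = c(64, 64))
#' scn <- generate_plot_image(sc, days_to_maturity = 30, plot_id = 1)
#' mean(scn$mask)          # realised canopy cover
#' scn$brown_fraction      # 0 early in the season
#' @export
generate_plot_image <- function(config, days_to_maturity, plot_id = 1L,
                                seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (length(days_to_maturity) != 1L || is.na(days_to_maturity) ||
      days_to_maturity < 0) {
    stop_param("days_to_maturity must be a single non-negative number")
  }
  seed <- seed %||% derive_seed(config$seed, hash_id(plot_id),
                                round(days_to_maturity * 10))
  h <- config$image_size[1]; w <- config$image_size[2]
  traj <- config$color_trajectory(days_to_maturity)
  stopifnot(all(c("canopy_rgb", "brown_rgb", "brown_fraction") %in% names(traj)))
  p_brown <- traj$brown_fraction
  if (p_brown < 0 || p_brown > 1) {
    stop_param("color_trajectory brown_fraction must lie in [0, 1]")
  }
  cover <- config$canopy_fraction_curve(days_to_maturity)
  amp <- config$row_contrast_curve(days_to_maturity)

  with_seed(seed, {
    # Row structure runs along image columns; clamp keeps it a probability.
    row_mod <- 1 + amp * sin(2 * pi * seq_len(w) / config$row_spacing)
    p_cov <- clamp(outer(rep(1, h), cover * row_mod), 0, 0.98)
    # Canopy placement: a spatially correlated uniform field thresholded at
    # the coverage probability. Each pixel is marginally Bernoulli(p) (the
    # rank transform makes the field exactly uniform), but neighbouring
    # pixels are correlated, so canopy forms leaf-scale blobs rather than
    # salt-and-pepper speckle.
    field <- smooth_uniform_field(h, w, sigma = config$blob_scale)
    mask <- matrix(as.integer(field <= p_cov), h, w)
    n_canopy <- sum(mask)
    brown <- matrix(0L, h, w)
    if (n_canopy > 0 && p_brown > 0) {
      brown[mask == 1] <- rbinom(n_canopy, 1L, p_brown)
    }

    img <- array(0, dim = c(h, w, 3))
    light <- exp(rnorm(1, 0, config$illumination_jitter_sd))
    for (ch in 1:3) {
      base <- matrix(config$soil_rgb[ch], h, w)
      base[mask == 1] <- traj$canopy_rgb[ch]
      base[brown == 1] <- traj$brown_rgb[ch]
      img[, , ch] <- clamp(round(light * (base + rnorm(h * w, 0, config$pixel_noise_sd))),
                           0, 255)
    }

    if (n_canopy > 0 && n_canopy < h * w) {
      exg <- exg_map(img)
      gap <- mean(exg[mask == 1]) - mean(exg[mask == 0])
      if (gap < config$exg_margin) {
        stop_param(paste0("generated canopy/soil ExG separation %.3f is below ",
                          "the configured margin %.3f; adjust scene colours"),
                   gap, config$exg_margin)
      }
    }

    structure(
      list(image = img, mask = mask,
           brown_fraction = if (n_canopy > 0) sum(brown) / n_canopy else 0,
           days_to_maturity = days_to_maturity, plot_id = plot_id),
      class = "plot_scene")
  })
}

#' Simulate a full imaging campaign
#'
#' Renders every plot at every capture offset and returns one row per
#' plot-date with the image, its ground-truth canopy mask, the realised brown
#' fraction and the true days-to-maturity label (which depends only on the
#' capture date).
#'
#' @param config A [scene_config()].
#' @param harvest_date Harvest date used to materialise ISO capture dates
#'   from the day offsets.
#'
#' @return A tibble with columns `plot_id`, `capture_date`,
#'   `days_to_maturity`, `true_brown_fraction`, and list-columns `image`,
#'   `mask`.
#' @examples
#' sc <- scene_config(image_size = c(48, 48), n_plots = 2,
#'                    capture_offsets = c(30, 7))
#' series <- generate_time_series(sc)
#' nrow(series)  # 2 plots x 2 dates = 4
#' @export
generate_time_series <- function(config, harvest_date = as.Date("2021-10-15")) {
  stopifnot(inherits(config, "scene_config"))
  grid <- tidyr::expand_grid(plot_id = seq_len(config$n_plots),
                             days_to_maturity = config$capture_offsets)
  scenes <- purrr::pmap(grid, function(plot_id, days_to_maturity) {
    generate_plot_image(config, days_to_maturity, plot_id = plot_id)
  })
  tibble(
    plot_id = grid$plot_id,
    capture_date = harvest_date - grid$days_to_maturity,
    days_to_maturity = grid$days_to_maturity,
    true_brown_fraction = purrr::map_dbl(scenes, "brown_fraction"),
    image = purrr::map(scenes, "image"),
    mask = purrr::map(scenes, "mask"))
}

#' Write a simulated campaign to disk
#'
#' Writes each plot-date image as an 8-bit RGB PNG (and its ground-truth mask
#' as a 0/255 grayscale PNG) plus a `manifest.csv` with plot id, ISO capture
#' date, file paths and the ground-truth label columns.
#'
#' @param series Output of [generate_time_series()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_scene <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- series |>
    dplyr::mutate(
      file = sprintf("plot%03d_%s.png", .data$plot_id,
                     format(.data$capture_date, "%Y%m%d")),
      mask_file = sub("\\.png$", "_mask.png", .data$file))
  purrr::pwalk(list(manifest$image, manifest$mask, manifest$file,
                    manifest$mask_file),
               function(img, mask, f, mf) {
                 png::writePNG(img / 255, file.path(dir, f))
                 png::writePNG(mask + 0, file.path(dir, mf))
               })
  out <- manifest |>
    dplyr::transmute(.data$plot_id,
                     capture_date = format(.data$capture_date),
                     .data$file, .data$mask_file,
                     true_days_to_maturity = .data$days_to_maturity,
                     .data$true_brown_fraction)
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}

#' Read a plot image from PNG or TIFF
#'
#' @param path Path to an 8-bit RGB PNG or TIFF file.
#' @return An H x W x 3 array with values in 0-255.
#' @export
read_plot_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_param("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop_param("unsupported image format '%s' (use PNG or TIFF)", ext))
  if (length(dim(img)) == 2L) stop_param("expected an RGB image, got grayscale")
  round(img[, , 1:3, drop = FALSE] * 255)
}
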