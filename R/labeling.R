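# Maturity labels: calendar days-to-harvest, brown-pixel correction.
#
# The nominal label MD_i is the number of days between a plot image's capture
# date and the harvest date. Because plots ripen unevenly, MD_i is corrected
# by a per-plot index D_i in (-1.5, 1.5) days derived from the fraction of
# brown canopy pixels: a plot browner than the date's average matured
# earlier, so fewer days remain. The corrected label is MMD_i = MD_i + D_i.

#' Nominal maturity period from calendar dates
#'
#' @param capture_date,harvest_date `Date`s (or strings coercible to `Date`);
#'   capture must not be after harvest.
#' @return Integer number of days between capture and harvest.
#' @examples
#' maturity_days("2021-09-09", "2021-10-15")  # 36
#' @export
maturity_days <- function(capture_date, harvest_date) {
  capture_date <- as.Date(capture_date); harvest_date <- as.Date(harvest_date)
  if (any(capture_date > harvest_date)) {
    stop_param("capture_date is after harvest_date")
  }
  as.integer(harvest_date - capture_date)
}

#' Default brown-pixel rule
#'
#' The HSV window treated as "brown/mature": hue within `hue_range` degrees,
#' saturation at least `min_saturation`, value within `value_range`. The
#' window is a package design choice (validated against the synthetic
#' generator's brown reference colour), and fully configurable.
#'
#' @param hue_range Hue window in degrees on the 0-360 circle.
#' @param min_saturation Minimum HSV saturation.
#' @param value_range Allowed HSV value window.
#' @return A list of rule parameters for [brown_fraction()].
#' @export
brown_rule <- function(hue_range = c(20, 50), min_saturation = 0.15,
                       value_range = c(0.15, 0.85)) {
  list(hue_range = hue_range, min_saturation = min_saturation,
       value_range = value_range)
}

#' Fraction of brown canopy pixels
#'
#' Classifies each canopy pixel as brown or not with an HSV window rule and
#' returns the brown fraction, the maturity index driving the label
#' correction.
#'
#' @param image H x W x 3 8-bit RGB array.
#' @param mask Binary canopy mask with at least one canopy pixel.
#' @param rule Rule parameters from [brown_rule()].
#' @return Scalar in \eqn{[0, 1]}.
#' @export
brown_fraction <- function(image, mask, rule = brown_rule()) {
  assert_image(image); assert_mask(mask, image)
  if (sum(mask) == 0) stop_param("empty mask: no canopy pixels")
  hsv <- rgb_to_hsv_mat(channel_matrix(image, mask))
  hue_deg <- hsv[, "h"] * 360
  brown <- hue_deg >= rule$hue_range[1] & hue_deg <= rule$hue_range[2] &
    hsv[, "s"] >= rule$min_saturation &
    hsv[, "v"] >= rule$value_range[1] & hsv[, "v"] <= rule$value_range[2]
  mean(brown)
}

#' Correction index from the brown fraction
#'
#' Maps the brown fraction linearly onto the open interval (-1.5, 1.5) days:
#' `D_i = 1.5 * (1 - 2p)`, so a fully green plot (p = 0) gets +1.5 (matures
#' later than the date suggests) and a fully brown plot (p = 1) gets -1.5
#' (matured earlier). Strictly monotone decreasing in p; endpoints are nudged
#' inside the open interval.
#'
#' @param p Brown fraction in \eqn{[0, 1]} (vectorised).
#' @return Correction in days, inside (-1.5, 1.5).
#' @examples
#' correction_index(0.5)   # 0
#' correction_index(0.25)  # 0.75
#' @export
correction_index <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_param("brown fraction must lie in [0, 1]")
  }
  d <- 1.5 * (1 - 2 * p)
  eps <- 1e-9
  clamp(d, -1.5 + eps, 1.5 - eps)
}

#' Corrected maturity label
#'
#' @param md Nominal maturity days (from [maturity_days()]).
#' @param d Correction index (from [correction_index()]).
#' @return `md + d`, the corrected days-to-maturity label.
#' @export
corrected_maturity <- function(md, d) {
  if (any(abs(d) >= 1.5)) stop_param("correction index must lie in (-1.5, 1.5)")
  md + d
}

#' Label a campaign's feature table
#'
#' Augments a table that carries `capture_date` and a `mask` list-column
#' (plus the source images) with the label columns: `MD` (calendar days to
#' harvest), `brown_frac`, `D` (correction index), and the corrected label
#' `MMD`.
#'
#' @param table Feature table from [extract_feature_table()].
#' @param series The campaign tibble holding the `image` list-column the
#'   table was extracted from (row order must match).
#' @param harvest_date Harvest date.
#' @param rule Brown-pixel rule, see [brown_rule()].
#' @return The table with `MD`, `brown_frac`, `D`, `MMD` appended.
#' @export
label_table <- function(table, series, harvest_date = as.Date("2021-10-15"),
                        rule = brown_rule()) {
  stopifnot(nrow(table) == nrow(series))
  md <- maturity_days(table$capture_date, harvest_date)
  p <- purrr::map2_dbl(series$image, table$mask,
                       function(img, m) brown_fraction(img, m, rule))
  d <- correction_index(p)
  dplyr::mutate(table, MD = md, brown_frac = p, D = d,
                MMD = corrected_maturity(md, d))
}
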