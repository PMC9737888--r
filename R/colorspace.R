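# Colour-space conversions on n x 3 matrices of [0,1] RGB values.
# HSV comes from grDevices; HLS is implemented from its piecewise definition
# (its hue is mathematically identical to HSV hue, which the feature tests
# exploit as a cross-check); Lab uses grDevices::convertColor (sRGB, D65).

rgb_to_hsv_mat <- function(rgb) {
  out <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  colnames(out) <- c("h", "s", "v")
  out
}

rgb_to_hls_mat <- function(rgb) {
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  c_ <- mx - mn
  l <- (mx + mn) / 2
  h <- numeric(length(r))
  nz <- c_ > 0
  # Sector-wise hue in units of 1/6 turn.
  is_r <- nz & mx == r
  is_g <- nz & !is_r & mx == g
  is_b <- nz & !is_r & !is_g
  h[is_r] <- ((g[is_r] - b[is_r]) / c_[is_r]) %% 6
  h[is_g] <- (b[is_g] - r[is_g]) / c_[is_g] + 2
  h[is_b] <- (r[is_b] - g[is_b]) / c_[is_b] + 4
  h <- h / 6
  s <- numeric(length(r))
  den <- 1 - abs(2 * l - 1)
  ok <- nz & den > 0
  s[ok] <- c_[ok] / den[ok]
  cbind(h = h, l = l, s = clamp(s, 0, 1))
}

rgb_to_lab_mat <- function(rgb) {
  out <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  colnames(out) <- c("l", "a", "b")
  out
}
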