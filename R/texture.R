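# Texture features: grey-level co-occurrence matrix (GLCM) statistics,
# rotation-invariant uniform local binary patterns, Gabor filter-bank means.

#' Quantize a grayscale raster to a fixed number of levels
#'
#' @param gray Numeric matrix with values in 0..255.
#' @param levels Number of grey levels (>= 2).
#' @return Integer matrix with values in `0:(levels - 1)`.
#' @export
quantize_gray <- function(gray, levels = 32L) {
  if (levels < 2L) stop_param("levels must be >= 2")
  q <- floor(clamp(gray, 0, 255) / 256 * levels)
  matrix(as.integer(pmin(q, levels - 1L)), nrow(gray), ncol(gray))
}

glcm_angle_offsets <- function(distance) {
  # 0, 45, 90, 135 degrees; rows increase downward so "up" is dy = -d.
  list(`0` = c(0L, distance), `45` = c(-distance, distance),
       `90` = c(-distance, 0L), `135` = c(-distance, -distance))
}

#' Grey-level co-occurrence matrix
#'
#' Counts co-occurring grey-level pairs at the given pixel distance along each
#' angle, symmetrises (each pair counted in both directions), normalises each
#' angle's matrix to sum to one, and averages over angles. When a mask is
#' supplied, only pairs whose two pixels both lie inside the mask contribute,
#' so background never pollutes canopy texture.
#'
#' @param gray_q Integer matrix quantized to `0:(levels - 1)`
#'   (see [quantize_gray()]).
#' @param levels Number of grey levels.
#' @param distance Pair offset in pixels.
#' @param angles Angles in degrees, subset of `c(0, 45, 90, 135)`.
#' @param mask Optional binary matrix restricting pairs to mask == 1 pixels.
#' @return A `levels` x `levels` symmetric matrix summing to 1.
#' @export
glcm <- function(gray_q, levels = 32L, distance = 1L,
                 angles = c(0, 45, 90, 135), mask = NULL) {
  if (levels < 2L) stop_param("levels must be >= 2")
  if (min(gray_q) < 0 || max(gray_q) >= levels) {
    stop_param("gray_q must be quantized to [0, levels)")
  }
  h <- nrow(gray_q); w <- ncol(gray_q)
  if (h < distance + 1L && w < distance + 1L) {
    stop_param("raster (%d x %d) too small for pair distance %d", h, w, distance)
  }
  offs <- glcm_angle_offsets(as.integer(distance))
  angles <- as.character(angles)
  if (!all(angles %in% names(offs))) {
    stop_param("angles must be a subset of {0, 45, 90, 135} degrees")
  }
  acc <- matrix(0, levels, levels)
  n_used <- 0L
  for (a in angles) {
    dy <- offs[[a]][1]; dx <- offs[[a]][2]
    rows <- seq_len(h)[(seq_len(h) + dy) >= 1 & (seq_len(h) + dy) <= h]
    cols <- seq_len(w)[(seq_len(w) + dx) >= 1 & (seq_len(w) + dx) <= w]
    if (length(rows) == 0L || length(cols) == 0L) next
    i <- gray_q[rows, cols, drop = FALSE]
    j <- gray_q[rows + dy, cols + dx, drop = FALSE]
    keep <- rep(TRUE, length(i))
    if (!is.null(mask)) {
      keep <- mask[rows, cols, drop = FALSE] == 1 &
        mask[rows + dy, cols + dx, drop = FALSE] == 1
    }
    if (!any(keep)) next
    counts <- tabulate(i[keep] * levels + j[keep] + 1L, nbins = levels^2)
    P <- matrix(counts, levels, levels, byrow = TRUE)
    P <- P + t(P)
    acc <- acc + P / sum(P)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop_param("no valid pixel pairs for the GLCM")
  acc / n_used
}

#' Haralick statistics of a normalized GLCM
#'
#' Computes the six co-occurrence statistics used as texture features:
#' homogeneity, contrast, dissimilarity, entropy (natural log), angular
#' second moment, and correlation. Correlation is undefined for a constant
#' texture (zero marginal variance) and is returned as `NA` in that case.
#'
#' @param P Normalized symmetric GLCM (entries sum to 1).
#' @return Named numeric vector `HOM, CON, DIS, ENT, ASM, COR`.
#' @export
glcm_stats <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop_param("P must be square")
  if (abs(sum(P) - 1) > 1e-8) stop_param("P must be normalized (sum to 1)")
  n <- nrow(P)
  idx <- seq_len(n) - 1
  D <- outer(idx, idx, `-`)
  hom <- sum(P / (1 + D^2))
  con <- sum(P * D^2)
  dis <- sum(P * abs(D))
  ent <- -sum(ifelse(P > 0, P * log(P), 0))
  asm <- sum(P^2)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(idx * pi_); mu_j <- sum(idx * pj_)
  s_i <- sqrt(sum((idx - mu_i)^2 * pi_)); s_j <- sqrt(sum((idx - mu_j)^2 * pj_))
  cor_ <- if (s_i < 1e-12 || s_j < 1e-12) NA_real_ else
    sum(outer(idx - mu_i, idx - mu_j) * P) / (s_i * s_j)
  c(HOM = hom, CON = con, DIS = dis, ENT = ent, ASM = asm, COR = cor_)
}

# Neighbour offsets at 8 circular positions, integer-rounded for radius r.
lbp_offsets <- function(radius, n_points) {
  ang <- 2 * pi * (seq_len(n_points) - 1) / n_points
  data.frame(dy = as.integer(round(-radius * sin(ang))),
             dx = as.integer(round(radius * cos(ang))))
}

# Rotation-invariant uniform LBP code per pixel (codes 0..n_points + 1).
lbp_map <- function(gray, radius = 1L, n_points = 8L) {
  offs <- lbp_offsets(radius, n_points)
  bits <- lapply(seq_len(n_points), function(k) {
    (shift_replicate(gray, -offs$dy[k], -offs$dx[k]) >= gray) + 0L
  })
  transitions <- 0L
  ones <- 0L
  for (k in seq_len(n_points)) {
    nxt <- if (k == n_points) 1L else k + 1L
    transitions <- transitions + (bits[[k]] != bits[[nxt]])
    ones <- ones + bits[[k]]
  }
  code <- ifelse(transitions <= 2L, ones, n_points + 1L)
  matrix(code, nrow(gray), ncol(gray))
}

#' Mean local binary pattern code over the canopy
#'
#' Assigns each pixel its rotation-invariant uniform LBP code (neighbours at
#' 8 integer positions on a circle of the given radius compared to the
#' centre; uniform patterns map to their number of ones, non-uniform patterns
#' to `n_points + 1`) and averages the codes over canopy pixels.
#'
#' @param gray Numeric grayscale matrix.
#' @param mask Binary canopy mask (NULL averages over the whole raster).
#' @param radius Neighbourhood radius in pixels.
#' @param n_points Number of circular neighbours.
#' @return Mean LBP code (scalar).
#' @export
lbp_mean <- function(gray, mask = NULL, radius = 1L, n_points = 8L) {
  if (nrow(gray) <= 2 * radius + 1 && ncol(gray) <= 2 * radius + 1) {
    stop_param("raster too small for LBP radius %d", radius)
  }
  code <- lbp_map(gray, radius, n_points)
  if (is.null(mask)) return(mean(code))
  if (sum(mask) == 0) stop_param("empty mask: no canopy pixels for LBP")
  mean(code[mask == 1])
}

# 2-D "same" convolution via FFT with replicate border padding: the image is
# extended by edge replication before filtering, so a constant raster yields
# an exactly constant (and, for zero-mean kernels, zero) response everywhere.
conv2_replicate <- function(img, kernel) {
  rpad <- nrow(kernel) %/% 2L; cpad <- ncol(kernel) %/% 2L
  ridx <- clamp(seq(1L - rpad, nrow(img) + rpad), 1L, nrow(img))
  cidx <- clamp(seq(1L - cpad, ncol(img) + cpad), 1L, ncol(img))
  padded <- img[ridx, cidx, drop = FALSE]
  full <- conv2_same(padded, kernel)
  full[rpad + seq_len(nrow(img)), cpad + seq_len(ncol(img)), drop = FALSE]
}

# 2-D "same" convolution via FFT with zero padding.
conv2_same <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- h + kh - 1L; pw <- w + kw - 1L
  A <- matrix(0, ph, pw); A[1:h, 1:w] <- img
  K <- matrix(0, ph, pw); K[1:kh, 1:kw] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (ph * pw)
  r0 <- (kh - 1L) %/% 2L; c0 <- (kw - 1L) %/% 2L
  full[r0 + seq_len(h), c0 + seq_len(w)]
}

gabor_kernel <- function(frequency, theta, sigma) {
  half <- ceiling(3 * sigma)
  g <- expand.grid(y = -half:half, x = -half:half)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  re <- env * cos(2 * pi * frequency * xr)
  im <- env * sin(2 * pi * frequency * xr)
  side <- 2L * half + 1L
  # Remove the DC component of the even part so flat regions respond ~0.
  list(re = matrix(re - mean(re), side, side), im = matrix(im, side, side))
}

#' Mean Gabor response magnitude over the canopy
#'
#' Filters the raster with a bank of zero-DC Gabor kernels (one spatial
#' frequency, several orientations), takes the complex response magnitude per
#' pixel, averages over orientations, then over canopy pixels. Captures the
#' strength of oriented row/grain texture.
#'
#' @param gray Numeric grayscale matrix (0-255 scale).
#' @param mask Binary canopy mask (NULL averages the whole raster).
#' @param frequency Spatial frequency in cycles/pixel.
#' @param n_orientations Number of evenly spaced orientations.
#' @param sigma Gaussian envelope standard deviation in pixels.
#' @return Mean response magnitude (scalar).
#' @export
gabor_mean <- function(gray, mask = NULL, frequency = 0.25,
                       n_orientations = 4L, sigma = 2) {
  if (!is.null(mask) && sum(mask) == 0) {
    stop_param("empty mask: no canopy pixels for Gabor")
  }
  thetas <- pi * (seq_len(n_orientations) - 1) / n_orientations
  mag <- matrix(0, nrow(gray), ncol(gray))
  for (th in thetas) {
    k <- gabor_kernel(frequency, th, sigma)
    re <- conv2_replicate(gray, k$re)
    im <- conv2_replicate(gray, k$im)
    mag <- mag + sqrt(re^2 + im^2)
  }
  mag <- mag / n_orientations
  if (is.null(mask)) mean(mag) else mean(mag[mask == 1])
}
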