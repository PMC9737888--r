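# Internal helpers shared across modules.

# Deterministic child seed from a master seed and one or two indices.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, i, j = 0L) {
  s <- (as.double(seed) %% 1e6) * 2011 + as.double(i) * 7919 + as.double(j) * 104729
  as.integer(s %% 2147483647)
}

stop_param <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "buckmat_param_error")
}

assert_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop_param("`%s` must be an H x W x 3 array of RGB values", arg)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop_param("`%s` must hold 8-bit values in [0, 255]", arg)
  }
  invisible(image)
}

assert_mask <- function(mask, image = NULL, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop_param("`%s` must be a binary (0/1) matrix", arg)
  }
  if (!is.null(image) && !identical(dim(mask), dim(image)[1:2])) {
    stop_param("`%s` (%d x %d) does not match the image raster (%d x %d)",
               arg, nrow(mask), ncol(mask), dim(image)[1], dim(image)[2])
  }
  invisible(mask)
}

# Channels of an RGB array scaled to [0, 1], as an n x 3 matrix (optionally
# restricted to mask == 1 pixels).
channel_matrix <- function(image, mask = NULL) {
  m <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3])) / 255
  if (!is.null(mask)) m <- m[as.vector(mask) == 1, , drop = FALSE]
  m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Circular mean of values on [0, 1), used for hue aggregation.
circular_mean01 <- function(x) {
  a <- 2 * pi * x
  m <- atan2(mean(sin(a)), mean(cos(a))) / (2 * pi)
  m %% 1
}
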