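# Shared fixtures, built once per test run.

# A small scene configuration used wherever full 256 px plots are overkill.
small_scene_config <- function(seed = 1L, ...) {
  scene_config(image_size = c(64, 64), n_plots = 3L,
               capture_offsets = c(30, 17, 3), seed = seed, ...)
}

# Uniform-colour image helper: every pixel gets the same 8-bit RGB triple.
uniform_image <- function(rgb, h = 8L, w = 8L) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

full_mask <- function(h = 8L, w = 8L) matrix(1L, h, w)

# Lazily-built campaign table shared across modeling tests: a small simulated
# series with segmentation + extraction + labels. Built on first use.
campaign_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scene_config(image_size = c(64, 64), n_plots = 6L, seed = 42L)
      series <- generate_time_series(cfg)
      tab <- extract_feature_table(series, seed = 7L)
      tab <- label_table(tab, series)
      cache <<- list(config = cfg, series = series, table = tab)
    }
    cache
  }
})

# Brute-force GLCM oracle: enumerate every pixel pair at the offset, count
# symmetrically, normalise. Deliberately slow and simple.
glcm_oracle <- function(gray_q, levels, distance, angle) {
  offs <- list(`0` = c(0, distance), `45` = c(-distance, distance),
               `90` = c(-distance, 0), `135` = c(-distance, -distance))
  dy <- offs[[as.character(angle)]][1]
  dx <- offs[[as.character(angle)]][2]
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(gray_q))) {
    for (j in seq_len(ncol(gray_q))) {
      i2 <- i + dy; j2 <- j + dx
      if (i2 >= 1 && i2 <= nrow(gray_q) && j2 >= 1 && j2 <= ncol(gray_q)) {
        a <- gray_q[i, j] + 1; b <- gray_q[i2, j2] + 1
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P / sum(P)
}
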