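# The 22-feature extraction stage: index arithmetic, colour conversions,
# texture statistics, and the composed vector.

test_that("vegetation indices match their closed forms on uniform canopies", {
  img <- uniform_image(255 * c(0.25, 0.50, 0.25))
  vi <- vegetation_indices(img, full_mask())
  expect_equal(unname(vi["NGRDI"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(vi["VARI"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(vi["NDYI"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(vi["ExG"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(vi["GLA"]), 1 / 3, tolerance = 1e-12)

  gray <- uniform_image(c(100, 100, 100))
  expect_true(all(abs(vegetation_indices(gray, full_mask())) < 1e-12))

  green <- uniform_image(c(0, 255, 0))
  vg <- vegetation_indices(green, full_mask())
  expect_equal(unname(vg[c("NGRDI", "NDYI", "GLA", "VARI")]), rep(1, 4))
  expect_equal(unname(vg["ExG"]), 2)

  expect_error(vegetation_indices(img, matrix(0L, 8, 8)), "empty mask")
})

test_that("ratio indices stay bounded and guard vanishing denominators", {
  set.seed(4)
  for (i in 1:10) {
    img <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
    vi <- vegetation_indices(img, full_mask())
    expect_true(all(abs(vi[c("NGRDI", "NDYI")]) <= 1))
    expect_true(abs(vi["GLA"]) <= 1)
  }
  # all denominators vanish for VARI when g + r = b everywhere
  img <- uniform_image(255 * c(0.2, 0.3, 0.5))
  expect_error(vegetation_indices(img, full_mask()), "VARI")
})

test_that("colour components follow their colour-space definitions", {
  red <- uniform_image(c(255, 0, 0))
  cf <- color_features(red, full_mask())
  expect_equal(unname(cf[c("HSV_H", "HSV_S", "HSV_V")]), c(0, 1, 1))

  gray <- uniform_image(c(128, 128, 128))
  cg <- color_features(gray, full_mask())
  expect_equal(unname(cg["HSV_S"]), 0)
  expect_equal(unname(cg["HLS_S"]), 0)
  expect_lt(abs(cg["Lab_a"]), 0.5)
  expect_lt(abs(cg["Lab_b"]), 0.5)
  expect_error(color_features(gray, matrix(0L, 8, 8)), "empty mask")
})

test_that("HSV hue and HLS hue are the same quantity", {
  # two independent implementations (grDevices vs the piecewise HLS formula)
  # must agree pixel-for-pixel
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(runif(300), ncol = 3)
    hsv <- buckmat:::rgb_to_hsv_mat(m)
    hls <- buckmat:::rgb_to_hls_mat(m)
    expect_equal(hsv[, "h"], unname(hls[, "h"]), tolerance = 1e-12)
  }
})

test_that("the GLCM matches hand-counted pairs and its contracts", {
  # rows [0,0] and [1,1]: two horizontal pairs, both level-equal
  P <- glcm(matrix(c(0L, 1L, 0L, 1L), 2, 2), levels = 2, distance = 1,
            angles = 0)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))

  const <- matrix(3L, 4, 4)
  Pc <- glcm(const, levels = 4)
  expect_equal(sum(Pc), 1)
  expect_equal(Pc[4, 4], 1)

  set.seed(5)
  q <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  Pr <- glcm(q, levels = 4)
  expect_equal(sum(Pr), 1)
  expect_equal(Pr, t(Pr))

  expect_error(glcm(matrix(0L, 1, 1), levels = 2), "too small")
  expect_error(glcm(matrix(5L, 4, 4), levels = 4), "quantized")
})

test_that("GLCM stats evaluate the Haralick definitions", {
  # perfectly diagonal two-level GLCM
  s <- glcm_stats(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(unname(s["ASM"]), 0.5)
  expect_equal(unname(s["CON"]), 0)
  expect_equal(unname(s["ENT"]), log(2))
  expect_equal(unname(s["COR"]), 1)

  # uniform 2x2 GLCM
  u <- glcm_stats(matrix(0.25, 2, 2))
  expect_equal(unname(u["CON"]), 0.5)
  expect_equal(unname(u["DIS"]), 0.5)
  expect_equal(unname(u["ASM"]), 0.25)
  expect_equal(unname(u["COR"]), 0)

  # degenerate (constant-texture) GLCM: correlation is flagged undefined
  d <- glcm_stats(diag(c(1, 0)))
  expect_equal(unname(d[c("ASM", "HOM")]), c(1, 1))
  expect_equal(unname(d[c("CON", "DIS", "ENT")]), c(0, 0, 0))
  expect_true(is.na(d["COR"]))

  expect_error(glcm_stats(matrix(1, 2, 2)), "normalized")
})

test_that("angle-averaged GLCM stats are invariant to 180-degree rotation", {
  set.seed(6)
  q <- matrix(sample(0:7, 16 * 16, replace = TRUE), 16, 16)
  rot <- q[rev(seq_len(nrow(q))), rev(seq_len(ncol(q)))]
  s1 <- glcm_stats(glcm(q, levels = 8))
  s2 <- glcm_stats(glcm(rot, levels = 8))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("LBP separates flat from structured texture, deterministically", {
  flat <- matrix(100, 16, 16)
  # constant raster: every neighbour ties the centre, one uniform code
  expect_equal(lbp_mean(flat), 8)

  checker <- 255 * outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_false(isTRUE(all.equal(lbp_mean(checker), lbp_mean(flat))))
  expect_identical(lbp_mean(checker), lbp_mean(checker))

  expect_error(lbp_mean(flat, matrix(0L, 16, 16)), "empty mask")
})

test_that("Gabor responds to gratings at its frequency but not flat fields", {
  flat <- matrix(100, 32, 32)
  g_flat <- gabor_mean(flat)
  expect_lt(g_flat, 1e-6)

  grating <- 100 + 50 * sin(2 * pi * 0.25 * outer(rep(1, 32), 1:32))
  g_grating <- gabor_mean(grating)
  expect_gt(g_grating, g_flat + 1)
  expect_identical(g_grating, gabor_mean(grating))

  expect_error(gabor_mean(flat, matrix(0L, 32, 32)), "empty mask")
})

test_that("the composed vector has the fixed 22-name schema", {
  cfg <- small_scene_config(seed = 13)
  scn <- generate_plot_image(cfg, 17, plot_id = 1)
  fv <- extract_features(scn$image, scn$mask)
  expect_named(fv, feature_names())
  expect_length(fv, 22)
  expect_length(vegetation_index_names(), 5)
  expect_length(color_feature_names(), 9)
  expect_length(texture_feature_names(), 8)
  expect_true(all(is.finite(fv)))

  # a uniform canopy has constant texture: correlation is undefined and the
  # failure names the feature
  expect_error(extract_features(uniform_image(c(80, 120, 60), 16, 16),
                                full_mask(16, 16)), "COR")
})

test_that("yellow-blue chroma rises with the brown fraction", {
  cfg <- scene_config(image_size = c(64, 64), n_plots = 3, seed = 17)
  series <- generate_time_series(cfg)
  tab <- extract_feature_table(series, use_truth_masks = TRUE)
  # Lab_b against realised brown fraction: strongly positive association
  expect_gt(cor(tab$Lab_b, series$true_brown_fraction), 0.8)
})
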