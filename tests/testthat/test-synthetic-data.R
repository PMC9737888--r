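# Synthetic scene and table generators: determinism, phenology structure,
# and the known ground truth they must expose.

test_that("plot images are deterministic and validate their inputs", {
  cfg <- small_scene_config(seed = 3)
  a <- generate_plot_image(cfg, 17, plot_id = 2)
  b <- generate_plot_image(cfg, 17, plot_id = 2)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)

  # a different plot id draws a different field but the same phenology
  c <- generate_plot_image(cfg, 17, plot_id = 3)
  expect_false(identical(a$image, c$image))

  expect_error(generate_plot_image(cfg, -1), "non-negative")
  expect_error(scene_config(image_size = c(16, 16)), "at least 32")
  expect_error(scene_config(n_plots = 0), "positive")
})

test_that("brown fraction follows the colour trajectory", {
  cfg <- small_scene_config(seed = 5)
  early <- generate_plot_image(cfg, 36, plot_id = 1)
  expect_identical(early$brown_fraction, 0)

  # custom trajectory with a fixed brown fraction: the realised fraction is
  # the mean of Bernoulli draws over canopy pixels
  traj <- function(d) list(canopy_rgb = c(60, 110, 40),
                           brown_rgb = c(150, 112, 35), brown_fraction = 0.8)
  cfg2 <- scene_config(image_size = c(96, 96), color_trajectory = traj, seed = 6)
  late <- generate_plot_image(cfg2, 3, plot_id = 1)
  n_canopy <- sum(late$mask)
  tol <- 4 * sqrt(0.8 * 0.2 / n_canopy)
  expect_lt(abs(late$brown_fraction - 0.8), tol)
})

test_that("a campaign has one sample per plot-date with date-only labels", {
  cfg <- small_scene_config(seed = 2)
  series <- generate_time_series(cfg)
  expect_equal(nrow(series), 3 * 3)
  expect_setequal(unique(series$days_to_maturity), c(30, 17, 3))

  # same offset, different plots: different imagery, identical label
  same_date <- series[series$days_to_maturity == 17, ]
  expect_false(identical(same_date$image[[1]], same_date$image[[2]]))
  expect_equal(same_date$days_to_maturity[1], same_date$days_to_maturity[2])

  expect_error(scene_config(capture_offsets = numeric(0)), "non-empty")
  expect_error(scene_config(capture_offsets = c(3, 17)), "decreasing")
})

test_that("brown cover is monotone in maturity and canopy stays ExG-separable", {
  cfg <- scene_config(image_size = c(64, 64), n_plots = 4, seed = 9)
  series <- generate_time_series(cfg)
  by_date <- tapply(series$true_brown_fraction, series$days_to_maturity, mean)
  days <- as.numeric(names(by_date))
  # sort by decreasing days-to-maturity: brown fraction must not decrease
  ord <- order(days, decreasing = TRUE)
  expect_true(all(diff(by_date[ord]) >= 0))

  for (i in seq_len(nrow(series))) {
    exg <- exg_map(series$image[[i]])
    m <- series$mask[[i]]
    expect_gte(mean(exg[m == 1]) - mean(exg[m == 0]), cfg$exg_margin)
  }
})

test_that("synthetic tables expose their construction exactly", {
  cfg <- table_config(n_samples = 500, n_informative = 3, n_redundant = 2,
                      n_noise = 5, seed = 11)
  tab <- generate_feature_table(cfg)
  expect_equal(ncol(tab) - 1, 10)  # 3 + 2 + 5 features, plus the label

  # determinism
  expect_identical(tab, generate_feature_table(cfg))

  # redundant columns track their parents tightly
  parents <- attr(tab, "redundant_parents")
  for (rc in names(parents)) {
    expect_gte(abs(cor(tab[[rc]], tab[[parents[rc]]])), 0.95)
  }

  # noise columns do not correlate with the label beyond sampling error
  for (nc in attr(tab, "noise")) {
    expect_lt(abs(cor(tab[[nc]], tab$label)), 4 / sqrt(nrow(tab)))
  }

  # noiseless limit: the label is an exact linear function of the
  # informative columns
  tab0 <- generate_feature_table(table_config(n_samples = 50, noise_sd = 0,
                                              seed = 12))
  fit <- lm(label ~ inf1 + inf2 + inf3, data = tab0)
  expect_lt(max(abs(residuals(fit))), 1e-10)

  expect_error(table_config(n_samples = 2), "n_samples")
  expect_error(table_config(n_informative = 0), "n_informative")
})
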