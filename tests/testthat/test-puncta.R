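test_that("otsu threshold separates bimodal data and rejects constants", {
  set.seed(3)
  v <- array(c(rep(10, 500), rep(200, 500)), c(10, 10, 10))
  thr <- otsu_threshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 200)

  expect_error(otsu_threshold(array(5, c(4, 4, 4))), "constant")

  # synthetic field: background and punctum cores separate
  cfg <- sted_config(seed = 9)
  f <- make_sted_field(0.23, config = cfg, haze_amplitude = 0)
  thr2 <- otsu_threshold(f$volume)
  bg <- f$volume <= cfg$background_intensity
  core <- array(FALSE, dim(f$volume))
  core[f$truth$core_masks[[1]]] <- TRUE
  expect_gt(mean(f$volume[bg] < thr2), 0.99)
  expect_gt(mean(f$volume[core] > thr2), 0.90)
})

test_that("otsu threshold agrees with the reference implementation", {
  # overlapping modes give a unique between-class-variance maximum (for
  # well-separated modes any threshold on the inter-mode plateau is optimal
  # and implementations tie-break differently)
  set.seed(6)
  v <- array(c(rnorm(2000, 50, 15), rnorm(500, 120, 25)), c(25, 10, 10))
  mine <- otsu_threshold(v)
  ref <- EBImage::otsu(matrix(as.vector(v), ncol = 50), range = range(v),
                       levels = 256)
  bin_width <- diff(range(v)) / 256
  expect_lt(abs(mine - ref), 2 * bin_width)
})

test_that("puncta segmentation splits particles and sizes them", {
  cfg <- sted_config(seed = 5)
  ps <- puncta_params()

  # two spheres fused by a thin neck come apart
  f <- make_sted_field(c(0.23, 0.23), config = cfg,
                       centers = rbind(c(0, 0, 0), c(0.62, 0, 0)))
  st <- segment_puncta(f$volume, ps, axes = f$axes)
  expect_identical(nrow(st$puncta), 2L)
  # oracle: removing the neck by hand leaves two components
  fg <- f$volume > st$threshold
  co <- csmacq:::axes_coords(f$axes)
  neck <- abs(co[, 1] - 0.31) < 0.05
  fg_cut <- fg & !array(neck, dim(fg))
  labs <- csmacq:::label_components_3d(fg_cut, connectivity = 26L)
  expect_identical(max(labs), 2L)

  # an isolated sphere sizes within 10%
  f1 <- make_sted_field(0.23, config = cfg)
  s1 <- segment_puncta(f1$volume, ps, axes = f1$axes)
  expect_identical(nrow(s1$puncta), 1L)
  expect_lt(abs(s1$puncta$volume_um3 - 0.23) / 0.23, 0.10)

  # raising the multiplier never increases total foreground volume
  vols <- vapply(c(1, 2, 3.5, 5), function(m) {
    p <- puncta_params(otsu_multiplier = m)
    sum(segment_puncta(f1$volume, p, axes = f1$axes)$puncta$volume_um3)
  }, numeric(1))
  expect_true(all(diff(vols) <= 1e-12))

  # empty foreground is an empty set, not an error
  dark <- array(rnorm(8^3, 100, 1), c(8, 8, 8))
  s_empty <- segment_puncta(dark, puncta_params(otsu_multiplier = 50))
  expect_identical(nrow(s_empty$puncta), 0L)
})

test_that("punctum volumes conserve the foreground volume", {
  cfg <- sted_config(seed = 13)
  f <- make_sted_field(c(0.23, 0.12, 0.08), config = cfg)
  ps <- puncta_params()
  st <- segment_puncta(f$volume, ps, axes = f$axes)
  fg_vol <- sum(f$volume > st$threshold) * prod(ps$voxel_spacing)
  expect_equal(sum(st$puncta$volume_um3), fg_vol, tolerance = 1e-9)
})

test_that("size calibration interpolates order statistics", {
  # uniform grid of 100 control volumes
  expect_equal(calibrate_size_threshold(seq(0.001, 0.1, by = 0.001)),
               0.09505, tolerance = 1e-9)

  # constant controls give that constant; filtering is >= cutoff
  expect_identical(calibrate_size_threshold(rep(0.04, 10)), 0.04)
  df <- data.frame(volume_um3 = c(0.03, 0.05))
  expect_identical(filter_puncta(df, 0.04)$retained, c(FALSE, TRUE))

  # higher percentile, higher cutoff
  set.seed(2)
  v <- rexp(200, 20)
  expect_gte(calibrate_size_threshold(v, 99), calibrate_size_threshold(v, 95))

  expect_error(calibrate_size_threshold(numeric(0)), "empty")
})

test_that("the retained set is monotone in the cutoff with a hard floor", {
  set.seed(4)
  df <- data.frame(volume_um3 = rexp(100, 10),
                   cell_id = rep(1:10, 10), group = "a")
  cuts <- c(0.02, 0.05, 0.1, 0.2)
  counts <- vapply(cuts, function(ct) sum(filter_puncta(df, ct)$retained),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  for (ct in cuts) {
    kept <- filter_puncta(df, ct)
    expect_true(all(kept$volume_um3[kept$retained] >= ct))
  }
})

test_that("group summaries and the t test behave on known inputs", {
  df <- data.frame(
    volume_um3 = c(0.2, 0.3), cell_id = "c1", group = "cSMAC",
    retained = TRUE
  )
  s <- summarize_puncta(df)
  expect_equal(s$summary$mean_volume, 0.25)
  expect_identical(s$summary$mean_count_per_cell, 2)
  expect_null(s$t_test)

  # identical groups: the test controls its size across seeded replicates
  set.seed(8)
  null_p <- replicate(120, {
    d <- data.frame(
      volume_um3 = rnorm(40, 0.2, 0.05),
      cell_id = rep(1:8, 5),
      group = rep(c("a", "b"), each = 20),
      retained = TRUE
    )
    summarize_puncta(d)$t_test$p.value
  })
  expect_gte(mean(null_p > 0.05), 0.90)

  # an empty frame yields no summary rows
  expect_null(summarize_puncta(df[0, ])$summary)
})
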