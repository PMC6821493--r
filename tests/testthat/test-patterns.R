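test_that("cellular background is the median of masked intensities", {
  vol <- array(100, c(5, 5, 5))
  mask <- array(TRUE, c(5, 5, 5))
  expect_identical(cellular_background(vol, mask), 100)

  # robust to a small bright fraction
  vol2 <- vol
  vol2[1:6] <- 1000
  expect_identical(cellular_background(vol2, mask), 100)

  # synthetic couple: within 3% of the simulated baseline despite the patch
  cc <- make_annotated_couple("central", sim_config(n_frames = 1, seed = 31))
  seg <- segment_t_cell(get_frame(cc$series, 1), cc$series$axes, c(0, 0, 0))
  bg <- cellular_background(get_frame(cc$series, 1), seg$mask)
  expect_lt(abs(bg - 100) / 100, 0.03)

  expect_error(cellular_background(vol, mask & FALSE), "empty")
})

test_that("accumulation detection is strict at 40% above background", {
  cc <- make_annotated_couple("none", quiet_config())
  vol <- get_frame(cc$series, 1)
  mask <- cc$truth$cell_mask
  axes <- cc$series$axes

  # all-background cell: nothing detected
  expect_null(find_accumulation(vol, mask, axes, 100))

  # a patch at exactly 1.4x background does not qualify (strict inequality)
  co <- csmacq:::axes_coords(axes)
  patch <- sqrt(co[, 1]^2 + co[, 2]^2) <= 1.5 & co[, 3] > 3 & as.vector(mask)
  vol_eq <- vol
  vol_eq[patch] <- 140
  expect_null(find_accumulation(vol_eq, mask, axes, 100, smooth = FALSE))

  # just above the criterion it is detected exactly (no detection smoothing)
  vol_hi <- vol
  vol_hi[patch] <- 150
  reg <- find_accumulation(vol_hi, mask, axes, 100, smooth = FALSE)
  expect_false(is.null(reg))
  expect_setequal(reg$indices, which(patch))
})

test_that("scripted geometries produce the expected feature values", {
  thresholds <- pattern_thresholds()
  # central patch filling half the diameter: low radial fraction, ~quarter
  # coverage of the disc it sits in
  cc <- make_annotated_couple(
    "central", quiet_config(), pattern_script("central", patch_fraction = 0.5)
  )
  vol <- get_frame(cc$series, 1)
  axes <- cc$series$axes
  mask <- cc$truth$cell_mask
  reg <- find_accumulation(vol, mask, axes, 100)
  disc <- list(center = cc$truth$interface_center,
               radius = cc$truth$interface_radius)
  f <- extract_geometry(reg, disc, axes, thresholds)
  expect_lt(f$radial_fraction, 0.5)
  expect_lt(abs(f$coverage - 0.25), 0.08)
  expect_lt(f$depth, 1.5)

  # rim arc on one side: high radial fraction, single rim component
  cc2 <- make_annotated_couple("asymmetric", quiet_config())
  reg2 <- find_accumulation(get_frame(cc2$series, 1), cc2$truth$cell_mask,
                            axes, 100)
  f2 <- extract_geometry(reg2, disc, axes, thresholds)
  expect_gt(f2$radial_fraction, 0.5)
  expect_identical(f2$n_rim_components, 1L)
  expect_false(f2$annular)

  # interface-spanning thin slab: full coverage, sub-micrometre depth
  cc3 <- make_annotated_couple("lamellal", quiet_config())
  reg3 <- find_accumulation(get_frame(cc3$series, 1), cc3$truth$cell_mask,
                            axes, 100)
  f3 <- extract_geometry(reg3, disc, axes, thresholds)
  expect_gt(f3$coverage, 0.9)
  expect_lt(f3$depth, 1)
})

test_that("the classifier returns exactly one label on a feature grid", {
  th <- pattern_thresholds()
  grid <- expand.grid(
    coverage = c(0.1, 0.5, 0.7, 1),
    radial_fraction = c(0.2, 0.5, 0.8),
    depth = c(0.5, 1.2, 2.5),
    deep_volume = c(0, 0.5),
    deep_radial = c(0.2, 0.9, NA),
    ext_volume = c(0, 0.5),
    n_rim_components = c(0L, 1L, 2L),
    annular = c(TRUE, FALSE)
  )
  for (i in seq_len(nrow(grid))) {
    lab <- classify_pattern(grid[i, ], th)
    expect_length(lab, 1)
    expect_true(lab %in% pattern_labels())
    expect_true(lab != "none")
  }
  expect_identical(classify_pattern(NULL, th), "none")
})

test_that("noise-free scripted couples round-trip to their labels", {
  for (lab in setdiff(pattern_labels(), "none")) {
    cc <- make_annotated_couple(lab, quiet_config(seed = 17))
    calls <- classify_couple(cc$series, cc$annotation, cell_id = lab)
    expect_identical(calls$label, lab)
  }
})

test_that("raising the detection factor never adds detected cells", {
  cfg <- sim_config(n_frames = 1)
  detected <- function(factor) {
    n <- 0
    for (i in 1:6) {
      cfg$seed <- 300 + i
      cc <- make_annotated_couple("central", cfg)
      th <- pattern_thresholds(background_factor = factor)
      vol <- get_frame(cc$series, 1)
      seg <- segment_t_cell(vol, cc$series$axes, c(0, 0, 0))
      bg <- cellular_background(vol, seg$mask)
      reg <- find_accumulation(vol, seg$mask, cc$series$axes, bg, th)
      n <- n + !is.null(reg)
    }
    n
  }
  counts <- vapply(c(1.4, 1.7, 2.0, 2.5), detected, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("frequency tables respect denominators and the periphery sum", {
  calls <- data.frame(
    cell_id = rep(sprintf("c%02d", 1:10), each = 2),
    time_s = rep(c(0, 20), times = 10),
    label = rep("central", 20)
  )
  freq <- tabulate_frequencies(calls)
  f0 <- freq[freq$time_s == 0 & freq$label == "central", ]
  expect_identical(f0$proportion, 1)
  expect_identical(f0$total, 10L)

  # a cell absent at -40 s is excluded from that denominator
  calls2 <- rbind(calls, data.frame(cell_id = "c01", time_s = -40,
                                    label = "none"))
  freq2 <- tabulate_frequencies(calls2)
  expect_identical(freq2$total[freq2$time_s == -40][1], 1L)
  expect_identical(freq2$total[freq2$time_s == 0][1], 10L)

  # periphery = asymmetric + peripheral
  calls3 <- data.frame(
    cell_id = sprintf("c%02d", 1:10), time_s = 0,
    label = c(rep("asymmetric", 3), rep("peripheral", 2), rep("none", 5))
  )
  freq3 <- tabulate_frequencies(calls3)
  expect_identical(
    freq3$proportion[freq3$label == "periphery"], 0.5
  )
  # proportions over the seven exclusive labels sum to 1
  base <- freq3[freq3$label %in% pattern_labels(), ]
  expect_equal(sum(base$proportion), 1)
})
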