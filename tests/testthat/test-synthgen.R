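test_that("configuration and script validation reject bad inputs", {
  expect_error(sim_config(voxel_spacing = c(0, 0.34, 1)), "voxel_spacing")
  expect_error(sim_config(n_frames = 0), "n_frames")
  expect_error(pattern_script("ring"), "unknown pattern label")
  expect_error(pattern_script("invagination", depth = 0.5), ">= 1 um")
  cfg <- quiet_config(n_frames = 2)
  expect_error(
    make_cell_couple(cfg, pattern_script(rep("none", 5))),
    "exceeds"
  )
  expect_error(
    make_cell_couple(cfg, pattern_script("invagination", depth = 50)),
    "cell diameter"
  )
})

test_that("identical config, script and seed give bit-identical movies", {
  cfg <- sim_config(n_frames = 2, seed = 99)
  a <- make_cell_couple(cfg, pattern_script(c("central", "none")))
  b <- make_cell_couple(cfg, pattern_script(c("central", "none")))
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth$labels, b$truth$labels)
  cfg2 <- sim_config(n_frames = 2, seed = 100)
  c_ <- make_cell_couple(cfg2, pattern_script(c("central", "none")))
  expect_false(identical(a$series$data, c_$series$data))
})

test_that("contrast 1 gives no region above 1.4x background in expectation", {
  cfg <- quiet_config(accumulation_contrast = 1)
  cc <- make_cell_couple(cfg, pattern_script("central"))
  expect_identical(cc$truth$labels, "none")
  vol <- get_frame(cc$series, 1)
  inside <- vol[cc$truth$cell_mask]
  expect_true(all(inside <= 1.4 * cfg$background_intensity))
  expect_length(cc$truth$region_indices[[1]], 0L)
})

test_that("noise-free central script yields one connected central region", {
  cc <- make_annotated_couple("central", quiet_config())
  vol <- get_frame(cc$series, 1)
  above <- vol > 1.4 * 100 & cc$truth$cell_mask
  labs <- csmacq:::label_components_3d(above, connectivity = 26L)
  expect_identical(max(labs), 1L)
  co <- csmacq:::axes_coords(cc$series$axes)
  pts <- co[which(labs == 1L), , drop = FALSE]
  cen <- colMeans(pts)
  # centroid inside the central half of the interface diameter
  r <- sqrt(cen[1]^2 + cen[2]^2)
  expect_lt(r, 0.5 * cc$truth$interface_radius)
  expect_setequal(which(labs == 1L), cc$truth$region_indices[[1]])
})

test_that("cohort draws follow the schedule and handle degenerate cases", {
  cfg <- sim_config(n_frames = 2, seed = 5)
  sched <- matrix(c(0, 1), 1, dimnames = list(NULL, c("none", "central")))
  coh <- make_cohort(4, sched, cfg)
  expect_true(all(coh$labels == "central"))

  empty <- make_cohort(0, sched, cfg)
  expect_length(empty$couples, 0)

  bad <- matrix(c(0.5, 0.6), 1, dimnames = list(NULL, c("none", "central")))
  expect_error(make_cohort(2, bad, cfg), "sum to 1")
  bad2 <- matrix(c(-0.1, 1.1), 1, dimnames = list(NULL, c("none", "central")))
  expect_error(make_cohort(2, bad2, cfg), "\\[0, 1\\]")

  # reproducibility from the seed
  coh2 <- make_cohort(4, sched, cfg)
  expect_identical(coh$labels, coh2$labels)
  expect_identical(coh$couples[[2]]$series$data, coh2$couples[[2]]$series$data)
})

test_that("cohort label frequencies converge to the schedule", {
  # label draws only (rendering-free check at n = 500): the realized
  # frequency of each label stays within 3 standard errors of the schedule
  cfg <- sim_config(n_frames = 1, seed = 21, t_cell_radius = 5)
  p <- c(none = 0.3, central = 0.49, peripheral = 0.21)
  sched <- matrix(p, 1, dimnames = list(NULL, names(p)))
  set.seed(cfg$seed)
  n <- 500
  labs <- sample(names(p), n, replace = TRUE, prob = p)
  for (l in names(p)) {
    se <- sqrt(p[l] * (1 - p[l]) / n)
    expect_lt(abs(mean(labs == l) - p[l]), 3 * se)
  }
  # and the rendering path realizes exactly the drawn labels
  coh <- make_cohort(3, sched, cfg)
  for (i in 1:3) {
    expect_identical(coh$couples[[i]]$truth$labels, unname(coh$labels[i, ]))
  }
})

test_that("sted fields recover scripted volumes at half maximum", {
  cfg <- sted_config(seed = 2)
  f <- make_sted_field(0.23, config = cfg, haze_amplitude = 0)
  rec <- sum(f$volume > f$truth$half_max) * prod(cfg$voxel_spacing)
  expect_lt(abs(rec - 0.23) / 0.23, 0.10)

  # empty volume list: pure background
  f0 <- make_sted_field(numeric(0), config = cfg, haze_amplitude = 0)
  expect_true(all(f0$volume == cfg$background_intensity))

  # punctum below one voxel is rejected
  expect_error(make_sted_field(1e-5, config = cfg), "below one voxel")
  # centres closer than the minimum separation are rejected
  expect_error(
    make_sted_field(c(0.1, 0.1), config = cfg,
                    centers = rbind(c(0, 0, 0), c(0.05, 0, 0))),
    "closer"
  )
})

test_that("puncta at 0.1 um separation split with truth-centre seeding", {
  cfg <- sted_config(seed = 3)
  f <- make_sted_field(c(0.12, 0.12), config = cfg,
                       centers = rbind(c(0, 0, 0), c(0.1, 0, 0)))
  # oracle: seeded growth from the true centres on the noise-free image
  st <- segment_puncta(f$volume, puncta_params(), seeds = f$truth$centers,
                       axes = f$axes)
  expect_identical(nrow(st$puncta), 2L)
})

test_that("membrane traces match the quadrature oracle", {
  flat <- make_membrane_trace(0, 1, 4, sampling = 100)
  expect_equal(flat$truth$arc_length, 4)
  expect_equal(arc_length(flat$trace$points), 4)

  mt <- make_membrane_trace(0.5, 1, 4, sampling = 2000)
  expect_lt(abs(arc_length(mt$trace$points) - mt$truth$arc_length) /
              mt$truth$arc_length, 0.001)

  # sampling convergence: halving density changes arc length by < 1%
  lo <- make_membrane_trace(0.5, 1, 4, sampling = 500)
  hi <- make_membrane_trace(0.5, 1, 4, sampling = 1000)
  expect_lt(
    abs(arc_length(lo$trace$points) - arc_length(hi$trace$points)) /
      arc_length(hi$trace$points), 0.01
  )

  expect_error(make_membrane_trace(0.5, 1, span = -1), "span")
  expect_error(make_membrane_trace(0.5, 1, 4, sampling = 1), "sampling")
})
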