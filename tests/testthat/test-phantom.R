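# Synthetic phantom generator: geometry invariants, temporal model oracles,
# and the motion model.

test_that("phantom geometry satisfies its construction invariants", {
  ph <- small_phantom()
  ids <- unique(ph$vessel_label_map[ph$vessel_label_map > 0])
  expect_gte(length(ids), 9)                       # 8 majors + ring at minimum
  expect_true(all(ids %in% seq_along(ph$vessel_class)))
  expect_true(all(ph$vessel_class[ids] %in% c("arteriole", "venule", "capillary")))

  # centreline truth is a subset of the vessel footprint
  expect_true(all(ph$vessel_label_map[ph$centreline_truth] > 0))

  # FAZ interior is avascular except the terminal ring at its boundary
  h <- ph$shape[1]
  rr <- matrix(seq_len(h), h, ph$shape[2])
  cc <- matrix(seq_len(ph$shape[2]), h, ph$shape[2], byrow = TRUE)
  d <- sqrt((rr - ph$fovea_centre[1])^2 + (cc - ph$fovea_centre[2])^2)
  expect_equal(sum(ph$vessel_label_map[d < ph$faz_radius - 2] > 0), 0)

  # major-vessel masks are disjoint
  tot <- Reduce(`+`, lapply(ph$vessel_masks, function(m) m * 1))
  expect_lte(max(tot), 1)
})

test_that("phantom generation is a pure function of its seed", {
  a <- generate_phantom(shape = c(96, 96), n_arterioles = 3, n_venules = 3,
                        faz_radius = 12, seed = 7)
  b <- generate_phantom(shape = c(96, 96), n_arterioles = 3, n_venules = 3,
                        faz_radius = 12, seed = 7)
  c <- generate_phantom(shape = c(96, 96), n_arterioles = 3, n_venules = 3,
                        faz_radius = 12, seed = 8)
  expect_identical(a$vessel_label_map, b$vessel_label_map)
  expect_identical(a$centreline_truth, b$centreline_truth)
  expect_false(identical(a$vessel_label_map, c$vessel_label_map))
})

test_that("degenerate phantom arguments are rejected", {
  expect_error(generate_phantom(shape = c(40, 40)), "64 px")
  expect_error(generate_phantom(faz_radius = 0), "ring")
  expect_error(generate_phantom(faz_radius = 100, shape = c(160, 160)), "too large")
  expect_error(generate_phantom(n_arterioles = 0), "at least one")
})

test_that("default 304 px phantom has the expected vessel census", {
  ph <- fixture("phantom304", function() generate_phantom(seed = 1))
  ids <- unique(ph$vessel_label_map[ph$vessel_label_map > 0])
  expect_gte(length(ids), 17)
  expect_length(ph$vessel_masks, 16)               # 8 arterioles + 8 venules
  expect_setequal(unique(ph$vessel_class), c("arteriole", "venule", "capillary"))
})

test_that("constant modulation with zero noise gives an exactly constant sequence", {
  ph <- small_phantom()
  m <- temporal_model(vessel_cov = 0, capillary_cov = 0, noise_sd = 0,
                      n_frames = 6, rng_seed = 2)
  m$classes$arteriole$form <- "constant"
  m$classes$venule$form <- "constant"
  m$classes$capillary$form <- "constant"
  sim <- simulate_sequence(ph, m)
  cm <- compute_cov_map(sim$frames, require_aligned = FALSE)
  vess <- ph$vessel_label_map > 0
  expect_true(all(cm$values[vess] == 0))
  expect_true(all(sim$cov_true == 0))
})

test_that("sinusoidal modulation reproduces the a/sqrt(2) closed form", {
  ph <- small_phantom()
  # all classes sinusoidal with relative amplitude a = 0.30, no noise
  m <- temporal_model(noise_sd = 0, n_frames = 20, rng_seed = 3)
  for (cl in names(m$classes)) {
    m$classes[[cl]]$form <- "sinusoid"
    m$classes[[cl]]$amplitude <- 0.30
  }
  sim <- simulate_sequence(ph, m)
  vess <- ph$vessel_label_map > 0
  expect_true(all(abs(sim$cov_true[vess] - 30 / sqrt(2)) < 1e-9))
  cm <- compute_cov_map(sim$frames, require_aligned = FALSE)
  # sample-SD estimate exceeds the population value by sqrt(T/(T-1));
  # agreement within O(1/T) of the closed form 21.2%
  med <- median(cm$values[vess], na.rm = TRUE)
  expect_lt(abs(med - 30 / sqrt(2)), 1.5)
})

test_that("capillary blinking yields higher CoV than arteriole modulation", {
  ph <- small_phantom()
  m <- temporal_model(vessel_cov = 15, capillary_cov = 50, n_frames = 20,
                      noise_sd = 0, rng_seed = 4)
  sim <- simulate_sequence(ph, m)
  cm <- compute_cov_map(sim$frames, require_aligned = FALSE)
  cls <- ph$vessel_class[ph$vessel_label_map[ph$vessel_label_map > 0]]
  cv <- cm$values[ph$vessel_label_map > 0]
  n_cap <- sum(cls == "capillary")
  expect_gte(n_cap, 100)
  expect_gt(median(cv[cls == "capillary"], na.rm = TRUE),
            median(cv[cls == "arteriole"], na.rm = TRUE))
})

test_that("class-separation holds at the generative level with defaults", {
  sim <- small_sequence()
  ph <- small_phantom()
  cls <- ph$vessel_class[ph$vessel_label_map[ph$vessel_label_map > 0]]
  tv <- sim$cov_true[ph$vessel_label_map > 0]
  expect_gt(median(tv[cls == "capillary"]), median(tv[cls == "arteriole"]))
})

test_that("simulation is deterministic and rejects degenerate inputs", {
  ph <- small_phantom()
  a <- simulate_sequence(ph, temporal_model(n_frames = 4, rng_seed = 9))
  b <- simulate_sequence(ph, temporal_model(n_frames = 4, rng_seed = 9))
  expect_identical(a$frames$frames, b$frames$frames)
  expect_error(temporal_model(n_frames = 1), "at least 2")
})

test_that("apply_motion matches the translation definition and inverts", {
  f <- reg_frame()
  expect_pixels_equal(apply_motion(f, 0, 0, 0), f, tol = 1e-9)

  mv <- apply_motion(f, dx = 3, dy = -2)
  # content at (r, c) maps to (r - 2, c + 3): integer shift is exact
  expect_equal(mv[50, 60], f[52, 57], tolerance = 1e-12)
  expect_equal(mv[100, 40], f[102, 37], tolerance = 1e-12)

  # rigid round trip: motion then its exact inverse (-R^{-1} t, -theta).
  # Bilinear interpolation is lossy on single-pixel structures, so the
  # round-trip oracle uses a bandlimited (smoothed) frame.
  fsm <- as.matrix(EBImage::gblur(f, 2))
  th <- 1.5 * pi / 180
  dx <- 2.3; dy <- -1.1
  fwd <- apply_motion(fsm, dx = dx, dy = dy, theta = th)
  dy2 <- -(cos(th) * dy + sin(th) * dx)
  dx2 <- -(-sin(th) * dy + cos(th) * dx)
  back <- apply_motion(fwd, dx = dx2, dy = dy2, theta = -th)
  ok <- is.finite(back) & is.finite(fsm)
  expect_gt(mean(ok), 0.9)
  expect_lt(mean(abs(back[ok] - fsm[ok])), 1)   # interpolation tolerance
})

test_that("apply_motion rejects bad parameters", {
  f <- reg_frame()
  expect_error(apply_motion(f, dx = NA), "finite")
  expect_error(apply_motion(f, dx = 100), "10%")
})

test_that("smooth fields are bounded and reproducible", {
  fl <- make_smooth_field(c(96, 96), max_disp = 2, seed = 5)
  expect_equal(max(sqrt(fl$ur^2 + fl$uc^2)), 2, tolerance = 1e-9)
  fl2 <- make_smooth_field(c(96, 96), max_disp = 2, seed = 5)
  expect_identical(fl, fl2)
})
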