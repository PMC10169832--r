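# Shared fixtures, built once per test run and cached. Sizes are kept small
# (160 px fields, 4+4 major vessels) so the suite stays fast; the geometry
# and temporal model are otherwise the package defaults.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

small_phantom <- function() {
  fixture("phantom", function() {
    generate_phantom(shape = c(160, 160), n_arterioles = 4, n_venules = 4,
                     faz_radius = 18, seed = 1)
  })
}

small_sequence <- function() {
  fixture("sequence", function() {
    simulate_sequence(small_phantom(), temporal_model(n_frames = 20, rng_seed = 11))
  })
}

small_cov_map <- function() {
  fixture("cov_map", function() {
    compute_cov_map(small_sequence()$frames, require_aligned = FALSE)
  })
}

small_skeleton <- function() {
  fixture("skeleton", function() segment_centrelines(small_sequence()$frames))
}

small_segments <- function() {
  fixture("segments", function() {
    segment_mean_cov(small_cov_map(), decompose_segments(small_skeleton()))
  })
}

small_subject <- function() {
  fixture("subject", function() {
    run_subject(analysis_config(
      phantom_shape = c(160, 160), n_arterioles = 4, n_venules = 4,
      faz_radius = 18, phantom_seed = 1, seed = 101,
      registration = "none", upscale_factor = 2L,
      model = temporal_model(n_frames = 20, rng_seed = 1)))
  })
}

# A tiny textured image for registration tests (one noisy phantom frame).
reg_frame <- function() {
  fixture("reg_frame", function() small_sequence()$frames$frames[, , 1])
}

expect_pixels_equal <- function(a, b, tol = 1e-8) {
  expect_true(all(abs(a - b) < tol | (!is.finite(a) & !is.finite(b))))
}
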