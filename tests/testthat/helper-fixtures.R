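# Scaled acquisition used throughout the tests: 180 frames at 1 fps, 4 um/px.
# Same optics and noise as the default camera; the coarser sampling keeps a
# render at a few seconds without affecting what the checks probe.
test_camera <- function(seed = 1L, ...) {
  camera(pixel_size_um = 4, n_frames = 180L, frame_interval_s = 1,
         psf_sigma_um = 6, seed = seed, ...)
}

# Short recording on a short root for cheap structural checks
tiny_camera <- function(seed = 1L, ...) {
  camera(pixel_size_um = 4, n_frames = 60L, frame_interval_s = 1,
         psf_sigma_um = 0, seed = seed, ...)
}
short_geometry <- function(length_um = 800) root_geometry(length_um, 60)

# expensive renders shared between test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, fun) {
  if (is.null(.sim_cache[[key]])) assign(key, fun(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

control_sim <- function() {
  cached_sim("control", function() {
    generate_preset("control", seed = 42, cam = test_camera(42))
  })
}

# replicate-batch recovery run shared by the acceptance tests: renders each
# replicate, analyses it, and keeps only the per-replicate estimates
recover_batch <- function(preset, n, seed = 101, trans_at = NULL) {
  key <- paste("batch", preset, n, seed, is.null(trans_at), sep = "_")
  cached_sim(key, function() {
    res <- generate_replicates(
      preset, n = n, seed = seed, cam = test_camera(),
      map = function(sim, i) {
        an <- analyze_recording(sim$stack, sim$phantom,
                                transverse_at_um = trans_at)
        tibble::tibble(
          speed = abs(an$fit$speed_um_s),
          branch_mean = mean(abs(an$fit$branches$speed_um_s)),
          direction = an$fit$direction,
          fold = an$fold_change_tip,
          trans = if (is.null(an$transverse_fit)) NA_real_
                  else abs(an$transverse_fit$speed_um_s),
          true_speed = abs(sim$truth$scenario$longitudinal_speed_um_s))
      })
    dplyr::bind_rows(res)
  })
}

# small deterministic stack of known integers
toy_stack <- function(H = 6, W = 5, T = 4, seed = 99, maxval = 1000) {
  set.seed(seed)
  frames <- array(sample.int(maxval, H * W * T, replace = TRUE), c(H, W, T))
  image_stack(frames, pixel_size_um = 2, frame_interval_s = 0.5)
}
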