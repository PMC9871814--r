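new_image_stack <- function(frames, pixel_size_um, frame_interval_s, bit_depth) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 2L, all(frames >= 0))
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s, bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' Construct an image stack from an array
#'
#' Wraps a T-frame grayscale recording (ADU counts) with its acquisition
#' metadata. Frames are indexed `[row, column, frame]`, origin top-left.
#'
#' @param frames H x W x T array of non-negative intensities (ADU).
#' @param pixel_size_um Microns per pixel.
#' @param frame_interval_s Seconds between frames.
#' @param bit_depth 8 or 16; values must not exceed `2^bit_depth - 1`.
#' @return An `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um, frame_interval_s,
                        bit_depth = 16L) {
  stopifnot(bit_depth %in% c(8L, 16L), max(frames) <= 2^bit_depth - 1)
  new_image_stack(frames, pixel_size_um, frame_interval_s, bit_depth)
}

#' Frame times of a stack
#' @param stack An `image_stack`.
#' @return Numeric vector of frame times (s), first frame at 0.
#' @export
stack_times <- function(stack) {
  (seq_len(dim(stack$frames)[3]) - 1) * stack$frame_interval_s
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d frames of %d x %d px, %.2f um/px, dt = %.4f s, %d-bit\n",
    d[3], d[1], d[2], x$pixel_size_um, x$frame_interval_s, x$bit_depth))
  invisible(x)
}

#' Render a synthetic fluorescence recording
#'
#' Renders the wave scenario onto the root phantom frame by frame: pixel
#' value = blur(background + mask * baseline * multiplier) + noise, where the
#' multiplier is [wave_multiplier()], blur is a Gaussian PSF and noise is
#' Poisson shot noise plus Gaussian read noise, digitised to the camera bit
#' depth. With both noise terms disabled the stack is returned un-quantised,
#' so analytic identities hold to machine precision.
#'
#' @param phantom A [build_phantom()] result.
#' @param scn A [scenario()].
#' @param cam A [camera()]; its `seed` fixes the noise realisation (identical
#'   seed, identical stack).
#' @return A list with `stack` (an `image_stack`) and `truth` (a
#'   `ground_truth`: the scenario, geometry, camera and per-position
#'   activation times along the midline).
#' @export
render_stack <- function(phantom, scn, cam) {
  stopifnot(inherits(phantom, "root_phantom"), inherits(scn, "scenario"),
            inherits(cam, "camera"))
  set.seed(cam$seed)
  H <- phantom$dim[["H"]]; W <- phantom$dim[["W"]]
  n_t <- cam$n_frames
  times <- (seq_len(n_t) - 1) * cam$frame_interval_s
  R <- phantom$geometry$radius_um

  ta <- activation_time(scn, as.vector(phantom$s_um), as.vector(phantom$r_um), R)
  ta[is.na(ta)] <- Inf
  ta <- matrix(ta, H, W)

  base_img <- cam$background_adu + phantom$mask * cam$baseline_adu
  amp <- phantom$mask * cam$baseline_adu * (scn$amplitude_fold - 1)
  noiseless <- cam$shot_noise_gain == 0 && cam$read_noise_adu == 0
  maxval <- 2^cam$bit_depth - 1
  sigma_px <- cam$psf_sigma_um / cam$pixel_size_um

  frames <- array(0, dim = c(H, W, n_t))
  n_sat <- 0
  for (k in seq_len(n_t)) {
    x <- (times[k] - ta) / scn$rise_time_s
    x[is.infinite(ta)] <- -Inf
    img <- base_img + amp * front_sigmoid(x)
    if (sigma_px > 0) img <- EBImage::gblur(img, sigma = sigma_px)
    if (!noiseless) {
      if (cam$shot_noise_gain > 0) {
        img <- cam$shot_noise_gain *
          rpois(length(img), pmax(img, 0) / cam$shot_noise_gain)
      }
      if (cam$read_noise_adu > 0) {
        img <- img + rnorm(length(img), 0, cam$read_noise_adu)
      }
      img <- round(pmin(pmax(img, 0), maxval))
      n_sat <- n_sat + sum(img == maxval)
    }
    frames[, , k] <- img
  }
  if (!noiseless && n_sat / length(frames) > 0.01) {
    warn(sprintf("%.1f%% of pixels saturated at the %d-bit ceiling.",
                 100 * n_sat / length(frames), cam$bit_depth))
  }

  s_grid <- seq(0, phantom$geometry$length_um, by = cam$pixel_size_um)
  truth <- structure(
    list(scenario = scn, geometry = phantom$geometry, camera = cam,
         activation = tibble(s_um = s_grid,
                             t_a_s = activation_time(scn, s_grid, 0, R)),
         stack_md5 = NA_character_),
    class = "ground_truth"
  )
  list(stack = new_image_stack(frames, cam$pixel_size_um,
                               cam$frame_interval_s, cam$bit_depth),
       truth = truth)
}

#' Generate a preset recording with ground truth
#'
#' One-call front door to the simulator: build the default phantom, look up
#' the preset scenario and render a recording. The returned ground truth
#' carries everything an estimator-recovery test needs.
#'
#' @param preset_name A row of [preset_table()].
#' @param seed RNG seed for the noise realisation.
#' @param cam A [camera()]; defaults to the standard acquisition
#'   (`camera(seed = seed)`). Its seed field is overridden by `seed`.
#' @param geometry Root geometry (default [default_geometry()]).
#' @param noise If `FALSE`, shot and read noise are switched off (blur kept).
#' @param ... Scenario overrides forwarded to [preset_scenario()].
#' @return A list with `stack`, `truth` and `phantom`.
#' @export
generate_preset <- function(preset_name, seed = 1L, cam = NULL,
                            geometry = default_geometry(), noise = TRUE, ...) {
  cam <- cam %||% camera(seed = seed)
  cam$seed <- as.integer(seed)
  if (!noise) {
    cam$shot_noise_gain <- 0
    cam$read_noise_adu <- 0
  }
  scn <- preset_scenario(preset_name, geometry = geometry, ...)
  phantom <- build_phantom(geometry, cam)
  out <- render_stack(phantom, scn, cam)
  out$phantom <- phantom
  out
}

#' Generate a replicate batch of a preset
#'
#' Renders `n` replicate recordings of one preset. Replicate seeds are
#' `seed * 1000 + replicate`. Root-to-root variability of the wave speeds is
#' drawn as stratified normal quantiles `qnorm((i - 0.5) / n)` (assigned to
#' replicates in a seed-dependent permutation), so a batch reproduces the
#' preset's reported speed dispersion with a batch mean equal to the
#' reported mean — a representative cohort rather than a lucky or unlucky
#' random one.
#'
#' @inheritParams generate_preset
#' @param n Number of replicates.
#' @param vary_speed Set `FALSE` to give every replicate the preset mean
#'   speed.
#' @param map Optional `function(sim, replicate)` applied to each recording
#'   as it is rendered; its results are returned instead of the recordings,
#'   so a large batch never has to be held in memory at once.
#' @return A list of `n` [generate_preset()] results (or of `map` results).
#' @export
generate_replicates <- function(preset_name, n, seed = 1L, cam = NULL,
                                geometry = default_geometry(), noise = TRUE,
                                vary_speed = TRUE, map = NULL, ...) {
  set.seed(seed)
  z <- if (vary_speed) stats::qnorm((sample(n) - 0.5) / n) else rep(0, n)
  lapply(seq_len(n), function(i) {
    cam_i <- cam
    if (!is.null(cam_i)) cam_i$seed <- seed * 1000L + i
    sim <- generate_preset(preset_name, seed = seed * 1000L + i, cam = cam_i,
                           geometry = geometry, noise = noise,
                           speed_z = z[i], ...)
    if (is.null(map)) sim else map(sim, i)
  })
}
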