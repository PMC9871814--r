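#' Define the geometry of a root phantom
#'
#' Describes the visible primary root as a capsule around a centerline
#' polyline: an arclength extent, a half-width, and ordered fractional radii
#' separating stele, cortex and epidermis annuli. Coordinates are in microns;
#' the first centerline point is the tip apex and arclength increases
#' shoot-ward.
#'
#' @param length_um Arclength of the visible root (µm), > 0.
#' @param radius_um Half-width of the root (µm), > 0.
#' @param centerline Two-column matrix of (x, y) points in µm, tip first.
#'   Defaults to a straight vertical root from `(0, 0)` to `(0, length_um)`
#'   (image convention: y increases downward, tip at the top).
#' @param tissue_bands Strictly increasing fractional radii delimiting the
#'   stele / cortex / epidermis annuli; the last value must be 1.
#'
#' @return A `root_geometry` object.
#' @export
root_geometry <- function(length_um, radius_um,
                          centerline = NULL,
                          tissue_bands = c(0.35, 0.75, 1.0)) {
  if (!is.numeric(length_um) || length(length_um) != 1L || length_um <= 0) {
    abort("`length_um` must be a single positive number.")
  }
  if (!is.numeric(radius_um) || length(radius_um) != 1L || radius_um <= 0) {
    abort("`radius_um` must be a single positive number.")
  }
  if (is.null(centerline)) {
    centerline <- rbind(c(0, 0), c(0, length_um))
  }
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2L || nrow(centerline) < 2L) {
    abort("`centerline` must be a matrix of >= 2 (x, y) points.")
  }
  seg_len <- sqrt(rowSums(diff(centerline)^2))
  if (any(seg_len <= 0)) abort("`centerline` has zero-length segments.")
  if (any(diff(tissue_bands) <= 0) || tail(tissue_bands, 1) != 1.0) {
    abort("`tissue_bands` must be strictly increasing and end at 1.")
  }
  structure(
    list(length_um = length_um, radius_um = radius_um,
         centerline = centerline, tissue_bands = tissue_bands),
    class = "root_geometry"
  )
}

#' Camera and acquisition model
#'
#' Parameters of the rendered recording: sampling, digitisation, optics and
#' noise. Defaults reproduce the acquisition used throughout: 568 frames over
#' 180 s (frame interval 0.3169 s) on a 16-bit camera. The noise model is
#' Poisson shot noise applied to the photon-equivalent signal (controlled by
#' `shot_noise_gain`, ADU per photon-equivalent) plus additive Gaussian read
#' noise; setting both `shot_noise_gain = 0` and `read_noise_adu = 0` renders
#' a noiseless, unquantised stack.
#'
#' @param pixel_size_um Microns per pixel (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Seconds between frames (> 0).
#' @param bit_depth 8 or 16.
#' @param baseline_adu Baseline fluorescence of root tissue (ADU); must exceed
#'   `background_adu`.
#' @param background_adu Chamber background level (ADU), >= 0.
#' @param psf_sigma_um Gaussian point-spread sigma (µm); 0 disables blur.
#' @param shot_noise_gain ADU per photon-equivalent (0 disables shot noise).
#' @param read_noise_adu Gaussian read-noise sigma (ADU; 0 disables).
#' @param seed RNG seed used by the renderer.
#' @param width_px,height_px Optional fixed frame size; by default the frame
#'   is sized to fit the phantom plus a margin.
#'
#' @return A `camera` object.
#' @export
camera <- function(pixel_size_um = 2.0,
                   n_frames = 568L,
                   frame_interval_s = 180 / 568,
                   bit_depth = 16L,
                   baseline_adu = 2000,
                   background_adu = 200,
                   psf_sigma_um = 4,
                   shot_noise_gain = 1,
                   read_noise_adu = 20,
                   seed = 1L,
                   width_px = NULL, height_px = NULL) {
  stopifnot(pixel_size_um > 0, n_frames >= 2, frame_interval_s > 0,
            bit_depth %in% c(8L, 16L), background_adu >= 0,
            baseline_adu > background_adu,
            psf_sigma_um >= 0, shot_noise_gain >= 0, read_noise_adu >= 0)
  structure(
    list(pixel_size_um = pixel_size_um, n_frames = as.integer(n_frames),
         frame_interval_s = frame_interval_s, bit_depth = as.integer(bit_depth),
         baseline_adu = baseline_adu, background_adu = background_adu,
         psf_sigma_um = psf_sigma_um, shot_noise_gain = shot_noise_gain,
         read_noise_adu = read_noise_adu, seed = as.integer(seed),
         width_px = width_px, height_px = height_px),
    class = "camera"
  )
}

#' Rasterise a root geometry into a phantom
#'
#' Maps every pixel of the image frame to root coordinates: a boolean mask of
#' root pixels, the arclength `s` (µm, 0 at the tip apex, increasing
#' shoot-ward) of the nearest centerline point, and the signed transverse
#' coordinate `r` (µm, positive to the right of the tip-to-shoot direction).
#' The root outline is the capsule of radius `radius_um` around the
#' centerline with a hemispherical cap at the tip and a flat cut at the shoot
#' end.
#'
#' @param geometry A [root_geometry()].
#' @param camera A [camera()]; pixel size and any fixed frame size are used.
#' @param margin_um Margin added around the root bounding box when the frame
#'   size is not fixed by the camera.
#'
#' @return A `root_phantom` with elements `mask`, `s_um`, `r_um` (H×W
#'   matrices), `dim` (H, W), `tip_xy_um` (tip apex in image µm coordinates),
#'   `pixel_size_um`, `geometry`, `camera`.
#' @export
build_phantom <- function(geometry, camera, margin_um = 40) {
  stopifnot(inherits(geometry, "root_geometry"), inherits(camera, "camera"))
  px <- camera$pixel_size_um
  R <- geometry$radius_um
  cl <- geometry$centerline

  # place the root in image coordinates: bounding box + margin, origin top-left
  off <- c(min(cl[, 1]) - R - margin_um, min(cl[, 2]) - R - margin_um)
  cl_img <- sweep(cl, 2, off)
  need_w <- max(cl_img[, 1]) + R + margin_um
  need_h <- max(cl_img[, 2]) + R + margin_um
  W <- camera$width_px %||% as.integer(ceiling(need_w / px))
  H <- camera$height_px %||% as.integer(ceiling(need_h / px))
  if (need_w > W * px + 1e-9 || need_h > H * px + 1e-9) {
    abort(sprintf(
      "Root geometry (needs %.0f x %.0f um) exceeds the %d x %d px frame.",
      need_w, need_h, W, H))
  }

  # pixel-centre coordinates (0-based indices, centre at (i + 0.5) * px)
  xc <- (seq_len(W) - 0.5) * px
  yc <- (seq_len(H) - 0.5) * px
  X <- matrix(rep(xc, each = H), nrow = H)
  Y <- matrix(rep(yc, times = W), nrow = H)

  nseg <- nrow(cl_img) - 1L
  seg_vec <- diff(cl_img)
  seg_len <- sqrt(rowSums(seg_vec^2))
  s0 <- c(0, cumsum(seg_len))

  best_d2 <- matrix(Inf, H, W)
  best_s <- matrix(NA_real_, H, W)
  best_r <- matrix(NA_real_, H, W)
  beyond_end <- matrix(FALSE, H, W)
  for (i in seq_len(nseg)) {
    p <- cl_img[i, ]; v <- seg_vec[i, ]; L <- seg_len[i]
    dx <- X - p[1]; dy <- Y - p[2]
    t_raw <- (dx * v[1] + dy * v[2]) / L^2
    t_cl <- pmin(pmax(t_raw, 0), 1)
    px_ <- p[1] + t_cl * v[1]; py_ <- p[2] + t_cl * v[2]
    d2 <- (X - px_)^2 + (Y - py_)^2
    # signed side: cross product of segment direction with the offset vector
    side <- sign(v[1] * (Y - py_) - v[2] * (X - px_))
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- (s0[i] + t_cl * L)[upd]
    best_r[upd] <- (side * sqrt(d2))[upd]
    be <- upd & (i == nseg) & (t_raw > 1)
    beyond_end[upd] <- FALSE
    beyond_end[be] <- TRUE
  }
  mask <- (best_d2 <= R^2) & !beyond_end
  s_um <- ifelse(mask, best_s, NA_real_)
  r_um <- ifelse(mask, best_r, NA_real_)

  structure(
    list(mask = mask, s_um = s_um, r_um = r_um, dim = c(H = H, W = W),
         tip_xy_um = as.numeric(cl_img[1, ]), pixel_size_um = px,
         geometry = geometry, camera = camera),
    class = "root_phantom"
  )
}

#' @export
print.root_phantom <- function(x, ...) {
  cat(sprintf(
    "<root_phantom> %d x %d px (%.1f um/px), root %.0f um x %.0f um, %d root px\n",
    x$dim[["H"]], x$dim[["W"]], x$pixel_size_um,
    x$geometry$length_um, 2 * x$geometry$radius_um, sum(x$mask)))
  invisible(x)
}

#' Root-axis polyline of a phantom in image coordinates
#'
#' Returns the centerline sampled at its vertices with cumulative arclength,
#' in image µm coordinates (origin top-left), ready for [place_sections()].
#'
#' @param phantom A `root_phantom`.
#' @return A tibble with columns `x_um`, `y_um`, `s_um`.
#' @export
phantom_axis <- function(phantom) {
  stopifnot(inherits(phantom, "root_phantom"))
  cl <- phantom$geometry$centerline
  off <- phantom$tip_xy_um - cl[1, ]
  cl_img <- sweep(cl, 2, -off)
  s <- c(0, cumsum(sqrt(rowSums(diff(cl_img)^2))))
  tibble(x_um = cl_img[, 1], y_um = cl_img[, 2], s_um = s)
}
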