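# centred moving mean; ends filled with the nearest interior value
smooth_series <- function(x, n) {
  if (n <= 1) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / n, n), sides = 2))
  h <- (n - 1) %/% 2
  first <- which(!is.na(sm))[1]
  last <- tail(which(!is.na(sm)), 1)
  sm[seq_len(first - 1)] <- sm[first]
  sm[seq(last + 1, length.out = length(sm) - last)] <- sm[last]
  sm
}

#' Detect wave-front arrival times on a kymograph
#'
#' Per position, the front time is the earliest crossing of the half-maximum
#' level `baseline + f * (peak - baseline)` by the lightly smoothed intensity
#' profile, located to sub-frame precision by linear interpolation. The
#' baseline is the mean over the pre-onset window; positions whose dynamic
#' range stays below `k_sigma` baseline standard deviations are reported as
#' not detected. The half-maximum criterion is amplitude-invariant, so fronts
#' of different local brightness are timed consistently.
#'
#' @param kym A `kymograph`.
#' @param baseline_s Length of the pre-onset baseline window (s), counted
#'   from the first frame; must be shorter than the recording.
#' @param f Fractional rise level of the crossing criterion (default 0.5 =
#'   half-max).
#' @param k_sigma Detection floor: positions whose dynamic range
#'   `peak - baseline` stays below `k_sigma` times the noise scale return no
#'   front. The noise scale is estimated robustly from the first differences
#'   of the whole trace (`mad(diff) / sqrt(2)`), which is stable even when
#'   the baseline window is short and is immune to the slow front rise.
#' @param smooth_frames Width of the temporal moving mean (frames).
#' @return A tibble: `position_um`, `front_time_s` (`NA` where no front),
#'   `baseline_adu`, `peak_adu`, `detected`.
#' @export
detect_front <- function(kym, baseline_s = 10, f = 0.5, k_sigma = 4,
                         smooth_frames = 3) {
  stopifnot(inherits(kym, "kymograph"))
  times <- kym$times_s
  base_idx <- which(times < baseline_s)
  if (length(base_idx) < 2) {
    abort("Baseline window must contain at least 2 frames.")
  }
  if (length(base_idx) >= length(times)) {
    abort("Baseline window covers the whole recording.")
  }
  rows <- purrr::map(seq_len(nrow(kym$matrix)), function(i) {
    y <- kym$matrix[i, ]
    sm <- smooth_series(y, smooth_frames)
    b_mean <- mean(y[base_idx])
    noise_sd <- mad(diff(y)) / sqrt(2)
    peak <- max(sm)
    if (peak - b_mean <= max(k_sigma * noise_sd, 1e-9 * max(abs(b_mean), 1))) {
      return(tibble(position_um = kym$positions_um[i],
                    front_time_s = NA_real_, baseline_adu = b_mean,
                    peak_adu = peak, detected = FALSE))
    }
    thr <- b_mean + f * (peak - b_mean)
    j <- which(sm >= thr)[1]
    t_cross <- if (j == 1L) {
      times[1]
    } else {
      times[j - 1] + (thr - sm[j - 1]) / (sm[j] - sm[j - 1]) *
        (times[j] - times[j - 1])
    }
    tibble(position_um = kym$positions_um[i], front_time_s = t_cross,
           baseline_adu = b_mean, peak_adu = peak, detected = TRUE)
  })
  list_rbind(rows)
}

# median of pairwise slopes (position over time); returns NULL when the
# front-time spread is degenerate (no finite pairwise slope)
theil_sen <- function(t, pos) {
  dt <- outer(t, t, "-")
  dp <- outer(pos, pos, "-")
  keep <- upper.tri(dt) & dt != 0
  slopes <- dp[keep] / dt[keep]
  if (length(slopes) == 0) return(NULL)
  slope <- median(slopes)
  intercept <- median(pos - slope * t)
  res <- pos - (intercept + slope * t)
  scale <- mad(res)
  list(slope = slope, intercept = intercept,
       slope_sd = 1.4826 * mad(slopes) / sqrt(length(t)),
       residual_mad = scale,
       inlier_fraction = if (scale > 0) mean(abs(res) <= 3 * scale) else 1)
}

direction_label <- function(slope, axis) {
  if (axis == "longitudinal") {
    if (slope > 0) "shoot_ward" else "tip_ward"
  } else {
    if (slope > 0) "toward_positive" else "toward_negative"
  }
}

new_wave_fit <- function(branches, front, axis, direction) {
  structure(list(branches = branches, front = front, axis = axis,
                 direction = direction,
                 speed_um_s = branches$speed_um_s[1]),
            class = "wave_fit")
}

#' Robust speed estimate from front times
#'
#' Fits position against front time with the Theil-Sen estimator (median of
#' pairwise slopes), which tolerates positions where detection stalls or the
#' plateau is clipped by the end of the recording. On the longitudinal axis a
#' positive slope is shoot-ward (arclength increasing), a negative slope
#' tip-ward.
#'
#' @param front_times_s Front times (s); `NA`s are dropped.
#' @param positions_um Matching positions (µm).
#' @param axis `"longitudinal"` or `"transverse"` (controls the direction
#'   label).
#' @param min_speed_um_s Speeds below this magnitude are labelled `none`
#'   (unresolved).
#' @return A `wave_fit` with one branch: signed `speed_um_s`, `speed_sd`,
#'   direction label, number of positions used and fit quality (inlier
#'   fraction, median absolute residual).
#' @export
estimate_speed <- function(front_times_s, positions_um,
                           axis = "longitudinal", min_speed_um_s = 1) {
  keep <- !is.na(front_times_s)
  t <- front_times_s[keep]
  pos <- positions_um[keep]
  if (length(t) < 3) {
    abort("Insufficient front coverage: need >= 3 positions with detected fronts.")
  }
  ts <- theil_sen(t, pos)
  front <- tibble(position_um = pos, front_time_s = t)
  if (is.null(ts) || abs(ts$slope) < min_speed_um_s) {
    br <- tibble(branch = "full", speed_um_s = if (is.null(ts)) NA_real_ else ts$slope,
                 speed_sd = NA_real_, n_positions = length(t),
                 residual_mad = NA_real_, inlier_fraction = NA_real_,
                 direction = "none")
    return(new_wave_fit(br, front, axis, "none"))
  }
  dir <- direction_label(ts$slope, axis)
  br <- tibble(branch = "full", speed_um_s = ts$slope, speed_sd = ts$slope_sd,
               n_positions = length(t), residual_mad = ts$residual_mad,
               inlier_fraction = ts$inlier_fraction, direction = dir)
  new_wave_fit(br, front, axis, dir)
}

#' Classify propagation direction, including bidirectional waves
#'
#' If the detected front times form a V with their minimum at an interior
#' position — the signature of a front leaving an interior initiation locus
#' in both directions — the positions are split at the minimum and each
#' branch is fitted separately; the wave is `bidirectional` when the branch
#' slopes have opposite signs and both magnitudes exceed `min_speed_um_s`.
#' Otherwise a single Theil-Sen fit determines `shoot_ward` / `tip_ward`
#' (longitudinal axis), or `none` for flat (unresolved) front times.
#'
#' @inheritParams estimate_speed
#' @param interior_margin Fraction of the position range the minimum must be
#'   away from either end to count as interior.
#' @return A `wave_fit`; bidirectional fits carry two branches (`tip_side`,
#'   `shoot_side`) with signed speeds of opposite sign.
#' @export
classify_direction <- function(front_times_s, positions_um,
                               axis = "longitudinal", min_speed_um_s = 1,
                               interior_margin = 0.1) {
  keep <- !is.na(front_times_s)
  t <- front_times_s[keep]
  pos <- positions_um[keep]
  if (length(t) < 3) {
    abort("Insufficient front coverage: need >= 3 positions with detected fronts.")
  }
  o <- order(pos)
  t <- t[o]; pos <- pos[o]
  # smooth the time profile over positions before locating the minimum, so a
  # noisy early detection does not masquerade as an initiation locus
  t_sm <- smooth_series(t, max(3L, length(t) %/% 20))
  i_min <- which.min(t_sm)
  rng <- range(pos)
  interior <- (pos[i_min] - rng[1]) > interior_margin * diff(rng) &&
    (rng[2] - pos[i_min]) > interior_margin * diff(rng)
  if (interior) {
    left <- seq_len(i_min)
    right <- seq(i_min, length(pos))
    if (length(left) >= 3 && length(right) >= 3) {
      ts_l <- theil_sen(t[left], pos[left])
      ts_r <- theil_sen(t[right], pos[right])
      if (!is.null(ts_l) && !is.null(ts_r) &&
          sign(ts_l$slope) != sign(ts_r$slope) &&
          abs(ts_l$slope) >= min_speed_um_s &&
          abs(ts_r$slope) >= min_speed_um_s) {
        br <- tibble(
          branch = c("tip_side", "shoot_side"),
          speed_um_s = c(ts_l$slope, ts_r$slope),
          speed_sd = c(ts_l$slope_sd, ts_r$slope_sd),
          n_positions = c(length(left), length(right)),
          residual_mad = c(ts_l$residual_mad, ts_r$residual_mad),
          inlier_fraction = c(ts_l$inlier_fraction, ts_r$inlier_fraction),
          direction = vapply(c(ts_l$slope, ts_r$slope), direction_label,
                             "", axis = axis)
        )
        return(new_wave_fit(br, tibble(position_um = pos, front_time_s = t),
                            axis, "bidirectional"))
      }
    }
  }
  estimate_speed(t, pos, axis = axis, min_speed_um_s = min_speed_um_s)
}

#' Detect fronts and fit wave kinematics on a kymograph
#'
#' Convenience wrapper: [detect_front()] followed by [classify_direction()]
#' (or plain [estimate_speed()] when `bidirectional_check = FALSE`).
#'
#' @inheritParams detect_front
#' @inheritParams classify_direction
#' @param bidirectional_check Look for a V-shaped (bidirectional) front-time
#'   profile.
#' @return A `wave_fit`.
#' @export
fit_wavefront <- function(kym, baseline_s = 10, f = 0.5, k_sigma = 4,
                          smooth_frames = 3, min_speed_um_s = 1,
                          bidirectional_check = TRUE) {
  fr <- detect_front(kym, baseline_s = baseline_s, f = f, k_sigma = k_sigma,
                     smooth_frames = smooth_frames)
  if (sum(fr$detected) < 3) {
    br <- tibble(branch = "full", speed_um_s = NA_real_, speed_sd = NA_real_,
                 n_positions = sum(fr$detected), residual_mad = NA_real_,
                 inlier_fraction = NA_real_, direction = "none")
    return(new_wave_fit(br, fr[fr$detected, c("position_um", "front_time_s")],
                        kym$axis, "none"))
  }
  if (bidirectional_check) {
    classify_direction(fr$front_time_s, fr$position_um, axis = kym$axis,
                       min_speed_um_s = min_speed_um_s)
  } else {
    estimate_speed(fr$front_time_s, fr$position_um, axis = kym$axis,
                   min_speed_um_s = min_speed_um_s)
  }
}

#' Transverse wave speed across the root width
#'
#' [fit_wavefront()] applied to a transverse kymograph: positions are the
#' signed transverse coordinate, so the recovered slope is the speed at which
#' the front crosses from one flank to the other.
#'
#' @inheritParams fit_wavefront
#' @return A `wave_fit`.
#' @export
transverse_speed <- function(kym, baseline_s = 10, f = 0.5, k_sigma = 4,
                             smooth_frames = 3, min_speed_um_s = 1) {
  stopifnot(identical(kym$axis, "transverse"))
  fit_wavefront(kym, baseline_s = baseline_s, f = f, k_sigma = k_sigma,
                smooth_frames = smooth_frames,
                min_speed_um_s = min_speed_um_s, bidirectional_check = FALSE)
}

#' @export
print.wave_fit <- function(x, ...) {
  cat(sprintf("<wave_fit> %s axis, direction: %s\n", x$axis, x$direction))
  print(x$branches)
  invisible(x)
}

#' @export
tidy.wave_fit <- function(x, ...) x$branches

#' @export
glance.wave_fit <- function(x, ...) {
  tibble(direction = x$direction,
         speed_um_s = x$speed_um_s,
         n_branches = nrow(x$branches),
         n_positions = sum(x$branches$n_positions))
}

#' Front-time plot with the fitted branches
#' @param object A `wave_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wave_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$front,
                       ggplot2::aes(.data$front_time_s, .data$position_um)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "front time (s)", y = "position (µm)",
                  title = sprintf("direction: %s", object$direction)) +
    ggplot2::theme_minimal()
  p
}

#' Background level of a recording
#'
#' Robust estimate of the chamber background: the median of the per-pixel
#' temporal mean (over the first `n_frames` frames) among pixels below the
#' given quantile — i.e. the dim, root-free part of the frame.
#'
#' @param stack An `image_stack`.
#' @param n_frames Frames averaged (from the start of the recording).
#' @param q Quantile below which pixels are treated as background.
#' @return Background level (ADU).
#' @export
estimate_background <- function(stack, n_frames = 10, q = 0.25) {
  n_frames <- min(n_frames, dim(stack$frames)[3])
  m <- apply(stack$frames[, , seq_len(n_frames), drop = FALSE], c(1, 2), mean)
  median(m[m <= quantile(m, q)])
}

#' Fold change of a section trace
#'
#' Background-corrected peak-to-baseline ratio:
#' `(max(smoothed) - background) / (mean(baseline) - background)`, with the
#' baseline taken over the pre-onset window. Invariant under rescaling of the
#' (background-corrected) intensities.
#'
#' @param trace Tibble with `time_s`, `intensity_adu` (a single section).
#' @param baseline_s Pre-onset baseline window (s from the first frame).
#' @param background_adu Background level subtracted from both terms (see
#'   [estimate_background()]).
#' @param smooth_frames Temporal moving-mean width for the peak.
#' @return Unitless fold change (>= 1 for a rising trace; 1 for a constant
#'   one).
#' @export
fold_change <- function(trace, baseline_s = 10, background_adu = 0,
                        smooth_frames = 3) {
  stopifnot(all(c("time_s", "intensity_adu") %in% names(trace)))
  base_idx <- trace$time_s < baseline_s
  if (sum(base_idx) < 1) abort("Baseline window contains no frames.")
  baseline <- mean(trace$intensity_adu[base_idx]) - background_adu
  if (baseline <= 0) {
    abort("Non-positive background-corrected baseline; check `background_adu`.")
  }
  peak <- max(smooth_series(trace$intensity_adu, smooth_frames)) - background_adu
  peak / baseline
}

#' Replicate summary in the reporting style mean (SD, n)
#'
#' @param values Per-replicate values.
#' @return A tibble: `mean`, `sd` (n-1 denominator; `NA` when n = 1), `n`,
#'   and the per-replicate values as a list column.
#' @export
summarize_replicates <- function(values) {
  stopifnot(length(values) >= 1)
  tibble(mean = mean(values),
         sd = if (length(values) > 1) sd(values) else NA_real_,
         n = length(values),
         values = list(values))
}
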