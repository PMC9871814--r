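#' Microfluidic channel specification
#'
#' Geometry and operating point of the observation channel for the
#' closed-form transit model. The default cross-section is back-calculated
#' (the chamber drawings give no printed cross-section) so that the default
#' operating point — 20 µL/min through a 12-mm channel with half the
#' cross-section occupied by the root — reproduces the observed solution
#' front speed of roughly 6.8 x 10^3 µm/s.
#'
#' @param length_um Channel length L (µm).
#' @param flow_rate_ul_min Volumetric flow rate Q (µL/min).
#' @param cross_section_um2 Full channel cross-section A_chan (µm²).
#' @param root_occlusion_fraction Effective fraction of the cross-section
#'   occupied by the root, in `[0, 1)`; the free area is
#'   `A_chan * (1 - fraction)`.
#' @return A `channel_spec`.
#' @export
channel_spec <- function(length_um = 12000, flow_rate_ul_min = 20,
                         cross_section_um2 = 97800,
                         root_occlusion_fraction = 0.5) {
  stopifnot(length_um > 0, flow_rate_ul_min > 0, cross_section_um2 > 0,
            root_occlusion_fraction >= 0, root_occlusion_fraction < 1)
  structure(list(length_um = length_um, flow_rate_ul_min = flow_rate_ul_min,
                 cross_section_um2 = cross_section_um2,
                 root_occlusion_fraction = root_occlusion_fraction),
            class = "channel_spec")
}

#' Solution transit velocity in the channel
#'
#' `v = Q / A_free` with Q converted to µm³/s (1 µL = 1e9 µm³) and
#' `A_free = A_chan * (1 - occlusion)`.
#'
#' @param spec A [channel_spec()].
#' @return Velocity (µm/s).
#' @export
transit_velocity <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  a_free <- spec$cross_section_um2 * (1 - spec$root_occlusion_fraction)
  if (a_free <= 0) abort("Free cross-section is non-positive.")
  q_um3_s <- spec$flow_rate_ul_min * 1e9 / 60
  q_um3_s / a_free
}

#' Time for the solution front to fill a channel
#'
#' @param length_um Channel length (µm).
#' @param velocity_um_s Front velocity (µm/s).
#' @return Fill time (s); satisfies `t * v = L`.
#' @export
fill_time <- function(length_um, velocity_um_s) {
  stopifnot(length_um > 0, velocity_um_s > 0)
  length_um / velocity_um_s
}

#' Advection-decoupling ratio
#'
#' Ratio of the solution front speed to the measured tissue signal speed. A
#' large ratio (default threshold 100) excludes advection of the solution as
#' the carrier of the signal.
#'
#' @param v_flow_um_s Solution front speed (µm/s).
#' @param v_signal_um_s Measured signal speed magnitude (µm/s), > 0.
#' @param threshold Ratio above which the signal counts as
#'   advection-decoupled.
#' @return A tibble: `ratio`, `decoupled`.
#' @export
decoupling_ratio <- function(v_flow_um_s, v_signal_um_s, threshold = 100) {
  if (any(v_signal_um_s <= 0)) abort("Signal speed must be positive.")
  tibble(ratio = v_flow_um_s / v_signal_um_s,
         decoupled = v_flow_um_s / v_signal_um_s > threshold)
}

#' Flow report for a channel spec
#'
#' @param spec A [channel_spec()].
#' @param v_signal_um_s Optional signal speeds to compare against.
#' @return A one-row tibble with `velocity_um_s` and `fill_time_s`, plus one
#'   row per supplied signal speed with its decoupling ratio when
#'   `v_signal_um_s` is given.
#' @export
flow_report <- function(spec, v_signal_um_s = NULL) {
  v <- transit_velocity(spec)
  out <- tibble(velocity_um_s = v,
                fill_time_s = fill_time(spec$length_um, v))
  if (!is.null(v_signal_um_s)) {
    out <- tidyr::crossing(out, signal_um_s = v_signal_um_s) |>
      mutate(decoupling_ratio(.data$velocity_um_s, .data$signal_um_s))
  }
  out
}
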