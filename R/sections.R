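#' Layout of the five standard sampling sections
#'
#' Five linear transects placed along the root axis: `Tip` at the columella
#' (anchor, default arclength 0), `ME1`/`ME2` over the meristem-elongation
#' zones and `ED1`/`ED2` over the elongation-differentiation zones, spaced
#' 290, 290, 290 and 580 µm apart (total span 1450 µm). Each transect is
#' perpendicular to the local root axis.
#'
#' @param anchor_um Arclength of the first (Tip) section, µm from the apex.
#' @param spacings_um Four centre-to-centre gaps (µm).
#' @param section_length_um Transect length (µm); default spans a 120-µm-wide
#'   root.
#' @return A `section_layout`.
#' @export
section_layout <- function(anchor_um = 0,
                           spacings_um = c(290, 290, 290, 580),
                           section_length_um = 120) {
  stopifnot(length(spacings_um) == 4L, all(spacings_um > 0),
            anchor_um >= 0, section_length_um > 0)
  structure(list(labels = c("Tip", "ME1", "ME2", "ED1", "ED2"),
                 anchor_um = anchor_um, spacings_um = spacings_um,
                 section_length_um = section_length_um),
            class = "section_layout")
}

# point and unit tangent at arclength s on a polyline tibble (x_um, y_um, s_um)
point_at_arclength <- function(axis, s) {
  total <- max(axis$s_um)
  i <- findInterval(s, axis$s_um, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(axis) - 1L)
  f <- (s - axis$s_um[i]) / (axis$s_um[i + 1] - axis$s_um[i])
  tx <- axis$x_um[i + 1] - axis$x_um[i]
  ty <- axis$y_um[i + 1] - axis$y_um[i]
  len <- sqrt(tx^2 + ty^2)
  list(x = axis$x_um[i] + f * tx, y = axis$y_um[i] + f * ty,
       tx = tx / len, ty = ty / len, total = total)
}

#' Place the five sampling sections on a root axis
#'
#' @param axis A root axis: either a `root_phantom` (its centerline is used)
#'   or a tibble with columns `x_um`, `y_um`, `s_um` (image µm coordinates,
#'   cumulative arclength, tip first).
#' @param layout A [section_layout()].
#' @return A tibble with one row per section: `section`, `s_um` (arclength of
#'   the centre), centre coordinates `cx_um`, `cy_um`, unit normal
#'   `nx`, `ny`, and `length_um`. Gaps between successive centres, measured
#'   along the axis arclength, equal the layout spacings.
#' @export
place_sections <- function(axis, layout = section_layout()) {
  if (inherits(axis, "root_phantom")) axis <- phantom_axis(axis)
  stopifnot(all(c("x_um", "y_um", "s_um") %in% names(axis)))
  s_centres <- layout$anchor_um + c(0, cumsum(layout$spacings_um))
  total <- max(axis$s_um)
  if (tail(s_centres, 1) > total) {
    abort(sprintf(
      "Root axis too short: %.0f um available, %.0f um required (anchor %.0f + span %.0f).",
      total, tail(s_centres, 1), layout$anchor_um, sum(layout$spacings_um)))
  }
  p <- point_at_arclength(axis, s_centres)
  tibble(
    section = factor(layout$labels, levels = layout$labels),
    s_um = s_centres,
    cx_um = p$x, cy_um = p$y,
    nx = -p$ty, ny = p$tx,          # perpendicular to the local tangent
    length_um = layout$section_length_um
  )
}

#' Extract per-section intensity traces
#'
#' For every frame, the mean intensity (ADU) of the pixels lying within
#' `half_width_px` pixels of each transect segment — the plot-profile
#' semantics of a straight-line ROI of finite width.
#'
#' @param stack An `image_stack`.
#' @param sections A [place_sections()] tibble.
#' @param half_width_px Half-width of the band around each transect (pixels).
#' @param phantom Optional `root_phantom`; when given, a warning is issued
#'   for any transect whose band contains no root pixel (the trace is still
#'   computed).
#' @return A `section_traces` tibble: `time_s`, `section`, `intensity_adu`,
#'   with the half-width recorded as an attribute.
#' @export
extract_traces <- function(stack, sections, half_width_px = 2, phantom = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixel_size_um
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]
  xc <- (seq_len(W) - 0.5) * px
  yc <- (seq_len(H) - 0.5) * px
  X <- matrix(rep(xc, each = H), nrow = H)
  Y <- matrix(rep(yc, times = W), nrow = H)
  hw_um <- half_width_px * px
  flat <- matrix(stack$frames, nrow = H * W)
  times <- stack_times(stack)

  traces <- purrr::pmap(sections, function(section, s_um, cx_um, cy_um,
                                           nx, ny, length_um, ...) {
    a <- c(cx_um - nx * length_um / 2, cy_um - ny * length_um / 2)
    b <- c(cx_um + nx * length_um / 2, cy_um + ny * length_um / 2)
    v <- b - a
    L2 <- sum(v^2)
    t_cl <- pmin(pmax(((X - a[1]) * v[1] + (Y - a[2]) * v[2]) / L2, 0), 1)
    d2 <- (X - (a[1] + t_cl * v[1]))^2 + (Y - (a[2] + t_cl * v[2]))^2
    idx <- which(d2 <= hw_um^2)
    if (length(idx) == 0) {
      abort(sprintf("Section %s lies outside the image frame.", section))
    }
    if (!is.null(phantom) && !any(phantom$mask[idx])) {
      warn(sprintf("Section %s does not overlap the root mask.", section))
    }
    tibble(time_s = times, section = section,
           intensity_adu = colMeans(flat[idx, , drop = FALSE]))
  })
  out <- list_rbind(traces)
  attr(out, "half_width_px") <- half_width_px
  class(out) <- c("section_traces", class(out))
  out
}

#' Resample a trace onto an evenly spaced grid
#'
#' Linear interpolation onto grid nodes; identity on the native grid,
#' endpoints preserved. Extrapolation outside the trace's time span is an
#' error.
#'
#' @param trace Tibble with `time_s` and `intensity_adu` (one section).
#' @param grid Target time points (s), inside the trace span.
#' @return Tibble `time_s`, `intensity_adu` at the grid nodes.
#' @export
resample_trace <- function(trace, grid) {
  stopifnot(all(c("time_s", "intensity_adu") %in% names(trace)))
  if (min(grid) < min(trace$time_s) - 1e-9 ||
      max(grid) > max(trace$time_s) + 1e-9) {
    abort("Resampling grid extends beyond the trace time span (extrapolation).")
  }
  out <- approx(trace$time_s, trace$intensity_adu, xout = grid, ties = "ordered")
  tibble(time_s = out$x, intensity_adu = out$y)
}

#' Line plot of section traces
#' @param object A `section_traces` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.section_traces <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s, .data$intensity_adu,
                                       colour = .data$section)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean intensity (ADU)",
                  colour = "section") +
    ggplot2::theme_minimal()
}
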