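new_kymograph <- function(matrix, positions_um, times_s, axis, roi) {
  stopifnot(nrow(matrix) == length(positions_um),
            ncol(matrix) == length(times_s),
            all(diff(positions_um) > 0))
  structure(list(matrix = matrix, positions_um = positions_um,
                 times_s = times_s, axis = axis, roi = roi),
            class = "kymograph")
}

#' Build a kymograph by in-ROI summation
#'
#' For every frame, pixel intensities inside the ROI are summed within bins
#' along the chosen axis: `longitudinal` bins by the image y coordinate
#' (along the root, tip at the top), `transverse` bins by x (across the
#' root). Bin membership is by pixel centre, so every ROI pixel contributes
#' to exactly one bin and the per-frame total over bins equals the per-frame
#' ROI sum exactly.
#'
#' @param stack An `image_stack`.
#' @param roi An `roi_spec` inside the frame.
#' @param axis `"longitudinal"` or `"transverse"`.
#' @param bin_um Bin width (µm); default one pixel. Must be >= the pixel
#'   size.
#' @return A `kymograph`: positions x times matrix of summed ADU, bin-centre
#'   positions (µm, image coordinates) and frame times (s).
#' @export
build_kymograph <- function(stack, roi,
                            axis = c("longitudinal", "transverse"),
                            bin_um = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi_spec"))
  axis <- match.arg(axis)
  px <- stack$pixel_size_um
  bin_um <- bin_um %||% px
  if (bin_um < px) {
    abort(sprintf("bin_um (%.3g) must be at least one pixel (%.3g um).",
                  bin_um, px))
  }
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; n_t <- d[3]
  mask <- roi_mask(roi, H, W)
  idx <- which(mask)
  rows0 <- (idx - 1) %% H        # 0-based row
  cols0 <- (idx - 1) %/% H       # 0-based col
  coord <- if (axis == "longitudinal") (rows0 + 0.5) * px else (cols0 + 0.5) * px
  bin <- floor(coord / bin_um)

  flat <- matrix(stack$frames, nrow = H * W)[idx, , drop = FALSE]
  m <- rowsum(flat, group = bin, reorder = TRUE)
  bins <- sort(unique(bin))
  new_kymograph(unname(m), positions_um = (bins + 0.5) * bin_um,
                times_s = stack_times(stack), axis = axis, roi = roi)
}

#' Display-normalise kymographs to [0, 1]
#'
#' `global` mode maps one shared min/max across all inputs to 0/1 (so
#' intensities remain comparable between samples); `per_sample` rescales each
#' kymograph independently. Optionally clips at quantiles before rescaling.
#' A constant-valued kymograph normalises to all zeros (with a warning in
#' `per_sample` mode).
#'
#' @param kyms A `kymograph` or list of them.
#' @param mode `"global"` or `"per_sample"`.
#' @param clip_quantiles Optional length-2 vector, e.g. `c(0.01, 0.99)`, of
#'   quantiles clipped before min/max scaling.
#' @return Same shape as the input, matrices rescaled to `[0, 1]`.
#' @export
normalize_kymograph <- function(kyms, mode = c("global", "per_sample"),
                                clip_quantiles = NULL) {
  mode <- match.arg(mode)
  single <- inherits(kyms, "kymograph")
  lst <- if (single) list(kyms) else kyms
  stopifnot(length(lst) >= 1, all(vapply(lst, inherits, TRUE, "kymograph")))

  rescale <- function(m, lo, hi) {
    if (hi <= lo) return(matrix(0, nrow(m), ncol(m)))
    pmin(pmax((m - lo) / (hi - lo), 0), 1)
  }
  rng <- function(vals) {
    if (!is.null(clip_quantiles)) {
      quantile(vals, clip_quantiles, names = FALSE)
    } else {
      range(vals)
    }
  }
  if (mode == "global") {
    r <- rng(unlist(lapply(lst, function(k) k$matrix)))
    out <- lapply(lst, function(k) { k$matrix <- rescale(k$matrix, r[1], r[2]); k })
  } else {
    out <- lapply(lst, function(k) {
      r <- rng(k$matrix)
      if (r[2] <= r[1]) warn("Constant-valued kymograph normalised to zeros.")
      k$matrix <- rescale(k$matrix, r[1], r[2])
      k
    })
  }
  if (single) out[[1]] else out
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %s, %d positions x %d frames, %.1f-%.1f um\n",
              x$axis, nrow(x$matrix), ncol(x$matrix),
              min(x$positions_um), max(x$positions_um)))
  invisible(x)
}

#' @export
as_tibble.kymograph <- function(x, ...) {
  tibble(
    position_um = rep(x$positions_um, times = length(x$times_s)),
    time_s = rep(x$times_s, each = length(x$positions_um)),
    intensity_adu = as.vector(x$matrix)
  )
}

#' Heat-map plot of a kymograph
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$position_um,
                                   fill = .data$intensity_adu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "ADU") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s position (µm)", object$axis)) +
    ggplot2::theme_minimal()
}
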