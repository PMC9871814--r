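meta_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.json")
truth_path <- function(path) paste0(tools::file_path_sans_ext(path), ".truth.json")

#' Write an image stack as multi-page TIFF
#'
#' Writes one grayscale page per frame at the stack's bit depth, plus a JSON
#' metadata sidecar (`<basename>.meta.json`) holding pixel size, frame
#' interval and bit depth. Values are rounded to integer ADU on write.
#'
#' @param stack An `image_stack`.
#' @param path Output `.tif` path.
#' @param truth Optional `ground_truth`; when given it is written next to the
#'   stack as `<basename>.truth.json` with the stack's MD5 digest filled in.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, truth = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  maxval <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(k) {
    pmin(pmax(round(stack$frames[, , k]), 0), maxval) / maxval
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s,
         bit_depth = stack$bit_depth,
         n_frames = dim(stack$frames)[3]),
    meta_path(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    truth$stack_md5 <- unname(tools::md5sum(path))
    write_truth(truth, truth_path(path))
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Lossless load of a grayscale multi-page TIFF. Pixel size and frame
#' interval are taken from the `<basename>.meta.json` sidecar when present,
#' else from the arguments (with a warning when a default is used).
#'
#' @param path A `.tif` path.
#' @param pixel_size_um,frame_interval_s Metadata fallbacks when no sidecar
#'   exists.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("Ragged TIFF: pages have differing sizes.")
  }
  bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
  frames <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]

  mp <- meta_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um
    frame_interval_s <- meta$frame_interval_s
    bits <- meta$bit_depth %||% bits
  } else {
    if (is.null(pixel_size_um) || is.null(frame_interval_s)) {
      warn("No metadata sidecar; filling missing pixel size / frame interval with 1.")
      pixel_size_um <- pixel_size_um %||% 1
      frame_interval_s <- frame_interval_s %||% 1
    }
  }
  new_image_stack(frames, pixel_size_um, frame_interval_s, bits)
}

write_truth <- function(truth, path) {
  x <- list(
    scenario = unclass(truth$scenario),
    geometry = list(length_um = truth$geometry$length_um,
                    radius_um = truth$geometry$radius_um,
                    centerline = unclass(truth$geometry$centerline),
                    tissue_bands = truth$geometry$tissue_bands),
    camera = unclass(truth$camera),
    activation = as.list(truth$activation),
    stack_md5 = truth$stack_md5
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path A `.truth.json` path written by [write_stack()].
#' @return A `ground_truth` object.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scn <- x$scenario
  scn$transverse_speed_um_s <- scn$transverse_speed_um_s %||% NA_real_
  scn$preset_name <- scn$preset_name %||% NA_character_
  structure(
    list(scenario = structure(scn, class = "scenario"),
         geometry = root_geometry(x$geometry$length_um, x$geometry$radius_um,
                                  x$geometry$centerline, x$geometry$tissue_bands),
         camera = structure(x$camera, class = "camera"),
         # JSON has no Inf: null marks positions the front never reaches
         activation = tibble(
           s_um = x$activation$s_um,
           t_a_s = {
             ta <- as.numeric(unlist(lapply(x$activation$t_a_s,
                                            function(v) v %||% Inf)))
             ta[is.na(ta)] <- Inf
             ta
           }),
         stack_md5 = x$stack_md5),
    class = "ground_truth"
  )
}

# ---- ROI --------------------------------------------------------------------

#' Region-of-interest specifications
#'
#' Pixel coordinates are 0-based, origin top-left, y down, referring to pixel
#' centres. `roi_rect` takes inclusive corner pixels; `roi_polygon` a simple
#' (non-self-intersecting) polygon.
#'
#' @param x0,y0,x1,y1 Inclusive rectangle corners (0-based pixel indices).
#' @param label Optional name.
#' @return An `roi_spec`.
#' @export
roi_rect <- function(x0, y0, x1, y1, label = NULL) {
  stopifnot(x1 >= x0, y1 >= y0, x0 >= 0, y0 >= 0)
  structure(list(kind = "rectangle",
                 vertices = rbind(c(x0, y0), c(x1, y1)),
                 label = label),
            class = "roi_spec")
}

#' @rdname roi_rect
#' @param vertices n x 2 matrix of polygon vertices (0-based pixel coords).
#' @export
roi_polygon <- function(vertices, label = NULL) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 3L)
  structure(list(kind = "polygon", vertices = vertices, label = label),
            class = "roi_spec")
}

#' Write / read an ROI specification as JSON
#'
#' @param roi An `roi_spec`.
#' @param path JSON path.
#' @return `path` invisibly; `read_roi()` returns the `roi_spec`.
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_spec"))
  jsonlite::write_json(
    list(kind = roi$kind, vertices = unclass(roi$vertices), label = roi$label),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = x$kind, vertices = as.matrix(x$vertices),
                 label = x$label),
            class = "roi_spec")
}

# even-odd point-in-polygon, vectorised over points
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# logical H x W membership matrix for an ROI, validated against frame bounds
roi_mask <- function(roi, H, W) {
  v <- roi$vertices
  if (any(v[, 1] < 0) || any(v[, 1] > W - 1) ||
      any(v[, 2] < 0) || any(v[, 2] > H - 1)) {
    abort("ROI extends outside the image frame.")
  }
  if (roi$kind == "rectangle") {
    m <- matrix(FALSE, H, W)
    m[(v[1, 2]:v[2, 2]) + 1, (v[1, 1]:v[2, 1]) + 1] <- TRUE
    m
  } else {
    xs <- rep(0:(W - 1), each = H)
    ys <- rep(0:(H - 1), times = W)
    matrix(points_in_polygon(xs, ys, v[, 1], v[, 2]), H, W)
  }
}

# ---- tabular dialects -------------------------------------------------------

#' Write / read the kymograph CSV dialect
#'
#' Long format with fixed header `position_um, time_s, intensity_adu`, full
#' numeric precision; the reader reconstructs the position x time matrix.
#'
#' @param kym A `kymograph`.
#' @param path CSV path.
#' @return `path` invisibly; `read_kymograph_csv()` returns a `kymograph`.
#' @export
write_kymograph_csv <- function(kym, path) {
  stopifnot(inherits(kym, "kymograph"))
  readr::write_csv(as_tibble(kym), path)
  invisible(path)
}

#' @rdname write_kymograph_csv
#' @param axis Axis label to record on the reconstructed kymograph.
#' @export
read_kymograph_csv <- function(path, axis = "longitudinal") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("position_um", "time_s", "intensity_adu") %in% names(df)))
  pos <- sort(unique(df$position_um))
  tim <- sort(unique(df$time_s))
  m <- matrix(NA_real_, length(pos), length(tim))
  m[cbind(match(df$position_um, pos), match(df$time_s, tim))] <- df$intensity_adu
  new_kymograph(m, pos, tim, axis = axis, roi = NULL)
}

#' Write section traces as CSV
#'
#' Long format with fixed header `time_s, section, intensity_adu`.
#'
#' @param traces A `section_traces` tibble (from [extract_traces()]).
#' @param path CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(all(c("time_s", "section", "intensity_adu") %in% names(traces)))
  readr::write_csv(traces[, c("time_s", "section", "intensity_adu")], path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("time_s", "section", "intensity_adu") %in% names(df)))
  df
}
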