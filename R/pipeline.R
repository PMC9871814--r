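#' Whole-root ROI of a phantom
#'
#' Rectangle ROI covering the root mask bounding box (0-based pixel
#' coordinates), for kymograph construction.
#'
#' @param phantom A `root_phantom`.
#' @param pad_px Pixels of padding around the bounding box (clipped to the
#'   frame).
#' @return An `roi_spec`.
#' @export
root_roi <- function(phantom, pad_px = 0) {
  rc <- which(phantom$mask, arr.ind = TRUE)
  H <- phantom$dim[["H"]]; W <- phantom$dim[["W"]]
  roi_rect(max(min(rc[, 2]) - 1 - pad_px, 0),
           max(min(rc[, 1]) - 1 - pad_px, 0),
           min(max(rc[, 2]) - 1 + pad_px, W - 1),
           min(max(rc[, 1]) - 1 + pad_px, H - 1))
}

#' Analyse one recording end to end
#'
#' Builds the longitudinal kymograph over the root ROI (positions re-based to
#' arclength from the tip apex), fits the wave front, extracts the five
#' section traces and the Tip-section fold change, and — for one-sided
#' differentiation-zone scenarios — fits the transverse speed on a
#' kymograph across the root width near the contact site.
#'
#' @param stack An `image_stack`.
#' @param phantom The `root_phantom` the recording was rendered on (or one
#'   matching the real root's geometry).
#' @param baseline_s,f,k_sigma,smooth_frames Front-detection settings, see
#'   [detect_front()].
#' @param transverse_at_um Arclength (µm) of the transverse analysis window,
#'   or `NULL` to skip the transverse fit.
#' @param transverse_halfspan_um Half-length of the window along the root.
#' @param sections Optional [place_sections()] tibble; defaults to the
#'   standard five-section layout anchored at the tip.
#' @return A list: `fit` (`wave_fit`), `kymograph`, `traces`,
#'   `fold_change_tip`, `background_adu`, and `transverse_fit` (or `NULL`).
#' @export
analyze_recording <- function(stack, phantom, baseline_s = 10, f = 0.5,
                              k_sigma = 4, smooth_frames = 3,
                              transverse_at_um = NULL,
                              transverse_halfspan_um = 150,
                              sections = NULL) {
  tip_y <- phantom$tip_xy_um[2]
  kym <- build_kymograph(stack, root_roi(phantom), axis = "longitudinal")
  kym$positions_um <- kym$positions_um - tip_y
  fit <- fit_wavefront(kym, baseline_s = baseline_s, f = f, k_sigma = k_sigma,
                       smooth_frames = smooth_frames)

  sections <- sections %||% place_sections(phantom)
  traces <- extract_traces(stack, sections, phantom = phantom)
  bg <- estimate_background(stack)
  tip_trace <- traces[traces$section == "Tip", ]
  fold_tip <- fold_change(tip_trace, baseline_s = baseline_s,
                          background_adu = bg, smooth_frames = smooth_frames)

  trans_fit <- NULL
  if (!is.null(transverse_at_um)) {
    px <- stack$pixel_size_um
    H <- dim(stack$frames)[1]; W <- dim(stack$frames)[2]
    y0 <- max(floor((tip_y + transverse_at_um - transverse_halfspan_um) / px), 0)
    y1 <- min(ceiling((tip_y + transverse_at_um + transverse_halfspan_um) / px),
              H - 1)
    rc <- which(phantom$mask, arr.ind = TRUE)
    roi_t <- roi_rect(min(rc[, 2]) - 1, y0, max(rc[, 2]) - 1, y1)
    kym_t <- build_kymograph(stack, roi_t, axis = "transverse")
    trans_fit <- transverse_speed(kym_t, baseline_s = baseline_s, f = f,
                                  k_sigma = k_sigma,
                                  smooth_frames = smooth_frames)
  }
  list(fit = fit, kymograph = kym, traces = traces,
       fold_change_tip = fold_tip, background_adu = bg,
       transverse_fit = trans_fit)
}

default_run_config <- function() {
  list(
    presets = list(list(preset = "control", n = 3)),
    seed = 1L,
    camera = list(),
    geometry = list(),
    dz_arclength_um = 2000,
    analysis = list(baseline_s = 10, f = 0.5, k_sigma = 4, smooth_frames = 3),
    keep_stacks = FALSE
  )
}

#' Run the simulate-to-summary pipeline
#'
#' For every preset in the config, renders `n` replicate recordings
#' (replicate seeds are `seed * 1000 + replicate`), analyses each with
#' [analyze_recording()], and writes `summary.csv`, the resolved config and a
#' log into the output directory. Deterministic given the config: rerunning
#' reproduces the summary byte for byte. On error a `FAILED` marker naming
#' the stage is left in the directory.
#'
#' @param config A config list (see Details) or a path to a JSON config.
#'   Recognised keys: `presets` (list of `{preset, n}`), `seed`, `camera`
#'   and `geometry` (argument overrides for [camera()] / [default_geometry()]),
#'   `dz_arclength_um`, `analysis` (front-detection settings), `keep_stacks`.
#' @param out_dir Output directory (created if needed).
#' @return The summary tibble, invisibly: one row per replicate with
#'   `preset`, `replicate`, `seed`, `direction`, signed `speed_um_s`,
#'   `speed_abs_um_s`, `fold_change_tip`, `transverse_speed_um_s`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = FALSE)
  cfg <- default_run_config()
  for (nm in names(config)) {
    # parameter sub-lists merge; everything else (incl. presets) replaces
    if (nm %in% c("camera", "geometry", "analysis")) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], config[[nm]])
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                           append = TRUE)
  unlink(file.path(out_dir, c("run.log", "FAILED")))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log("rootwave pipeline; base seed %d", cfg$seed)
  log("defaults: %s", jsonlite::toJSON(cfg$analysis, auto_unbox = TRUE))

  stage <- "setup"
  result <- tryCatch({
    geometry <- do.call(default_geometry, cfg$geometry)
    rows <- list()
    for (p in cfg$presets) {
      stage <- sprintf("simulate/analyze %s", p$preset)
      cam <- do.call(camera, cfg$camera)
      preset_rows <- generate_replicates(
        p$preset, n = p$n, seed = cfg$seed, cam = cam, geometry = geometry,
        dz_arclength_um = cfg$dz_arclength_um,
        map = function(sim, rep_i) {
          seed_i <- cfg$seed * 1000L + rep_i
          if (isTRUE(cfg$keep_stacks)) {
            write_stack(sim$stack,
                        file.path(out_dir,
                                  sprintf("%s_r%02d.tif", p$preset, rep_i)),
                        truth = sim$truth)
          }
          scn <- sim$truth$scenario
          trans_at <- if (scn$sidedness == "one_sided" &&
                          scn$treatment_site == "differentiation_zone") {
            cfg$dz_arclength_um
          } else NULL
          an <- do.call(analyze_recording,
                        c(list(stack = sim$stack, phantom = sim$phantom,
                               transverse_at_um = trans_at), cfg$analysis))
          log("%s r%d: direction=%s speed=%.3f fold=%.3f", p$preset, rep_i,
              an$fit$direction, an$fit$speed_um_s, an$fold_change_tip)
          tibble(
            preset = p$preset, replicate = rep_i, seed = seed_i,
            direction = an$fit$direction,
            speed_um_s = an$fit$speed_um_s,
            speed_abs_um_s = mean(abs(an$fit$branches$speed_um_s)),
            fold_change_tip = an$fold_change_tip,
            transverse_speed_um_s = if (is.null(an$transverse_fit)) NA_real_
                                    else abs(an$transverse_fit$speed_um_s)
          )
        })
      rows <- c(rows, preset_rows)
    }
    summary <- list_rbind(rows)
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    log("wrote summary.csv (%d rows)", nrow(summary))
    summary
  }, error = function(e) {
    writeLines(sprintf("stage: %s\n%s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("Pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  invisible(result)
}
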