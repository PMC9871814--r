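# Smoothstep front: exactly 0 below -W_SIGMOID, exactly 1 above +W_SIGMOID,
# half-rise at 0, 10-90% rise width = 1 (in units of tau). The polynomial
# 6u^5 - 15u^4 + 10u^3 ("smootherstep") gives a C2 front with compact support,
# so baseline and plateau are attained exactly, not asymptotically.
W_SIGMOID <- local({
  f <- function(u) 6 * u^5 - 15 * u^4 + 10 * u^3
  u10 <- stats::uniroot(function(u) f(u) - 0.1, c(0, 0.5))$root
  1 / (2 * (1 - 2 * u10))
})

front_sigmoid <- function(x) {
  u <- pmin(pmax((x + W_SIGMOID) / (2 * W_SIGMOID), 0), 1)
  6 * u^5 - 15 * u^4 + 10 * u^3
}

#' Define a wave scenario
#'
#' Ground-truth kinematics of a treatment-triggered calcium front: where it
#' initiates, how fast and in which direction(s) it travels, how much the
#' fluorescence rises, and whether the treatment contacts one flank or the
#' whole root. The front at a position is a smooth sigmoidal rise from 1 to
#' the plateau fold `amplitude_fold`, with its half-rise at the position's
#' activation time and a 10-90% rise time of `rise_time_s`.
#'
#' Activation time at arclength `s` (µm from the tip apex) is
#' `t0 + (s - s0) / u` on the propagation side of the initiation locus `s0`
#' (both sides at rate `1/|u|` when `bidirectional`); positions on the
#' non-propagating side never activate. One-sided scenarios add a transverse
#' delay `|r - r_treated| / v_T` from the treated flank, clamped at the
#' midline when `crosses_midline` is `FALSE`.
#'
#' @param treatment_site `"tip"` or `"differentiation_zone"`.
#' @param sidedness `"full"` (both flanks) or `"one_sided"`.
#' @param init_arclength_um Front origin s0, µm from the tip apex.
#' @param longitudinal_speed_um_s Signed speed u (µm/s); positive is
#'   shoot-ward (arclength increasing). Use 0 with `amplitude_fold = 1` for a
#'   control (no front).
#' @param bidirectional If `TRUE`, two fronts leave s0 at ±|u|.
#' @param transverse_speed_um_s Transverse speed v_T (µm/s) or `NA` (no
#'   transverse structure; only meaningful for one-sided scenarios).
#' @param amplitude_fold Plateau / baseline ratio A (>= 1).
#' @param rise_time_s 10-90% rise time tau (s, > 0).
#' @param onset_time_s Treatment onset t0 (s, >= 0).
#' @param crosses_midline For one-sided scenarios, whether the transverse
#'   transmission reaches the untreated flank.
#' @param treated_flank `"positive"` or `"negative"` transverse side.
#' @param preset_name Optional identifier.
#'
#' @return A `scenario` object.
#' @export
scenario <- function(treatment_site = c("tip", "differentiation_zone"),
                     sidedness = c("full", "one_sided"),
                     init_arclength_um = 0,
                     longitudinal_speed_um_s = 5.9,
                     bidirectional = FALSE,
                     transverse_speed_um_s = NA_real_,
                     amplitude_fold = 2.5,
                     rise_time_s = 5,
                     onset_time_s = 20,
                     crosses_midline = TRUE,
                     treated_flank = c("positive", "negative"),
                     preset_name = NA_character_) {
  treatment_site <- match.arg(treatment_site)
  sidedness <- match.arg(sidedness)
  treated_flank <- match.arg(treated_flank)
  stopifnot(amplitude_fold >= 1, rise_time_s > 0, onset_time_s >= 0,
            init_arclength_um >= 0)
  if (amplitude_fold > 1 && longitudinal_speed_um_s == 0 && !bidirectional) {
    abort("A propagating scenario needs a non-zero longitudinal speed.")
  }
  if (sidedness == "one_sided" && is.na(transverse_speed_um_s)) {
    abort("One-sided scenarios require `transverse_speed_um_s`.")
  }
  structure(
    list(preset_name = preset_name, treatment_site = treatment_site,
         sidedness = sidedness, init_arclength_um = init_arclength_um,
         longitudinal_speed_um_s = longitudinal_speed_um_s,
         bidirectional = bidirectional,
         transverse_speed_um_s = transverse_speed_um_s,
         amplitude_fold = amplitude_fold, rise_time_s = rise_time_s,
         onset_time_s = onset_time_s, crosses_midline = crosses_midline,
         treated_flank = treated_flank),
    class = "scenario"
  )
}

#' Activation time of the front at root coordinates
#'
#' Vectorised over positions. Returns `Inf` for positions the front never
#' reaches (non-propagating side; untreated flank of a non-crossing one-sided
#' scenario; any position of a control scenario).
#'
#' @param scn A [scenario()].
#' @param s_um Arclength positions (µm from tip apex).
#' @param r_um Signed transverse coordinates (µm); ignored for full-contact
#'   scenarios.
#' @param radius_um Root half-width, needed to locate the treated flank
#'   surface for one-sided scenarios.
#' @return Activation times (s), same length as `s_um`.
#' @export
activation_time <- function(scn, s_um, r_um = 0, radius_um = 60) {
  stopifnot(inherits(scn, "scenario"))
  if (scn$amplitude_fold == 1) return(rep(Inf, length(s_um)))
  u <- scn$longitudinal_speed_um_s
  ds <- s_um - scn$init_arclength_um
  t_long <- if (scn$bidirectional) {
    abs(ds) / abs(u)
  } else {
    ifelse(ds / u >= 0, ds / u, Inf)
  }
  t_trans <- 0
  if (scn$sidedness == "one_sided") {
    r_tr <- if (scn$treated_flank == "positive") radius_um else -radius_um
    r <- rep_len(r_um, length(s_um))
    t_trans <- abs(r - r_tr) / scn$transverse_speed_um_s
    if (!scn$crosses_midline) {
      off_side <- if (scn$treated_flank == "positive") r < 0 else r > 0
      t_trans[off_side] <- Inf
    }
  }
  scn$onset_time_s + t_long + t_trans
}

#' Intensity multiplier of the wave at a point in space-time
#'
#' The unitless factor applied to baseline fluorescence:
#' `1 + (A - 1) * S((t - t_a(s, r)) / tau)` with `S` a compact-support
#' sigmoid that is exactly 0 before the rise, 1/2 at the activation time and
#' exactly 1 on the plateau. Monotone non-decreasing in `t`.
#'
#' @inheritParams activation_time
#' @param t_s Time (s), scalar or same length as `s_um`.
#' @return Multipliers in `[1, A]`.
#' @export
wave_multiplier <- function(scn, s_um, r_um = 0, t_s, radius_um = 60) {
  t_a <- activation_time(scn, s_um, r_um, radius_um)
  x <- (t_s - t_a) / scn$rise_time_s
  x[is.infinite(t_a)] <- -Inf
  1 + (scn$amplitude_fold - 1) * front_sigmoid(x)
}

# ---- presets ----------------------------------------------------------------

preset_rows <- function() {
  tibble::tribble(
    ~preset,            ~site,                  ~sidedness,  ~u,     ~u_sd, ~bidir, ~v_t,  ~v_t_sd, ~crosses, ~fold,
    "control",          "tip",                  "full",       0,     0,     FALSE,  NA,    NA,      TRUE,     1.0,
    "nacl_dz_full",     "differentiation_zone", "full",      -6.8,   0.9,   FALSE,  NA,    NA,      TRUE,     1.5,
    "peg_dz_full",      "differentiation_zone", "full",      -11.6,  1.6,   FALSE,  NA,    NA,      TRUE,     1.5,
    "nacl_tip_full",    "tip",                  "full",       5.9,   0.4,   FALSE,  NA,    NA,      TRUE,     2.5,
    "peg_tip_full",     "tip",                  "full",       10.5,  1.6,   FALSE,  NA,    NA,      TRUE,     4.0,
    "nacl_dz_oneside",  "differentiation_zone", "one_sided", -5.2,   0.57,  FALSE,  9.4,   0.94,    TRUE,     1.5,
    "peg_dz_oneside",   "differentiation_zone", "one_sided",  11,    1.4,   TRUE,   14,    1.4,     FALSE,    1.5,
    "nacl_tip_oneside", "tip",                  "one_sided",  4.2,   0.51,  FALSE,  10,    1.0,     FALSE,    2.5,
    "peg_tip_oneside",  "tip",                  "one_sided",  14.2,  1.9,   FALSE,  10,    1.0,     FALSE,    3.0
  )
}

#' Table of scenario presets
#'
#' The eight treatment configurations studied on the dual-flow chip (NaCl or
#' PEG, applied at the tip or the differentiation zone, full or one-sided)
#' plus an untreated control. Longitudinal speeds are signed (positive =
#' shoot-ward), amplitude folds are plateau/baseline ratios. `u_sd` and
#' `v_t_sd` are the root-to-root standard deviations of the speeds; where no
#' dispersion is reported, a 10% coefficient of variation (the typical
#' relative spread of the reported speeds) is used. Transverse speeds for the
#' `peg_dz_oneside` and tip one-sided presets are documented placeholder
#' values (the corresponding experiments report none).
#'
#' @return A tibble with one row per preset: `preset`, `site`, `sidedness`,
#'   signed longitudinal speed `u` and its SD `u_sd`, `bidir`, transverse
#'   speed `v_t` and `v_t_sd`, `crosses`, amplitude `fold`.
#' @export
preset_table <- function() preset_rows()

#' Scenario for a named preset
#'
#' @param preset_name One of `preset_table()$preset`.
#' @param geometry Root geometry used to place the initiation locus: tip
#'   presets initiate at the columella (s0 = 0), differentiation-zone presets
#'   at `dz_arclength_um`.
#' @param dz_arclength_um Arclength of the differentiation-zone contact site.
#' @param speed_z Root-to-root variability as a standard normal deviate: the
#'   scenario's speeds are `mean + z * sd` (one shared `z`, so a fast root is
#'   fast both longitudinally and transversely). 0 gives the preset means.
#' @param ... Overrides passed to [scenario()] (e.g. `onset_time_s`).
#' @return A `scenario`.
#' @export
preset_scenario <- function(preset_name, geometry = default_geometry(),
                            dz_arclength_um = 2000, speed_z = 0, ...) {
  tab <- preset_rows()
  if (!preset_name %in% tab$preset) {
    abort(sprintf("Unknown preset '%s'. Valid presets: %s.",
                  preset_name, paste(tab$preset, collapse = ", ")))
  }
  row <- tab[tab$preset == preset_name, ]
  s0 <- if (row$site == "tip") 0 else dz_arclength_um
  u <- row$u + speed_z * row$u_sd * sign(row$u)
  v_t <- if (is.na(row$v_t)) NA_real_ else row$v_t + speed_z * row$v_t_sd
  args <- list(
    treatment_site = row$site, sidedness = row$sidedness,
    init_arclength_um = s0, longitudinal_speed_um_s = u,
    bidirectional = row$bidir, transverse_speed_um_s = v_t,
    amplitude_fold = row$fold, crosses_midline = row$crosses,
    preset_name = preset_name
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario, args)
}

#' Default root geometry for simulated recordings
#'
#' A straight vertical root, 2400 µm visible arclength, 60 µm half-width:
#' long enough to hold the five standard sections (span 1450 µm) and a
#' differentiation-zone contact site at 2000 µm.
#'
#' @inheritParams root_geometry
#' @return A `root_geometry`.
#' @export
default_geometry <- function(length_um = 2400, radius_um = 60) {
  root_geometry(length_um = length_um, radius_um = radius_um)
}
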