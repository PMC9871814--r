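test_that("wave multiplier obeys baseline, half-rise and plateau identities", {
  scn <- scenario(treatment_site = "tip", init_arclength_um = 0,
                  longitudinal_speed_um_s = 10, amplitude_fold = 3,
                  rise_time_s = 5, onset_time_s = 0)
  # half-rise exactly at the activation time: s = s0 + 100, u = 10 => t_a = 10
  expect_equal(wave_multiplier(scn, s_um = 100, t_s = 10), 1 + (3 - 1) / 2)
  # plateau reached exactly
  expect_identical(wave_multiplier(scn, s_um = 100, t_s = 1e4), 3)
  # baseline before the rise anywhere
  expect_identical(wave_multiplier(scn, s_um = 500, t_s = 20), 1)
  # monotone non-decreasing in t
  ts <- seq(0, 60, by = 0.25)
  m <- wave_multiplier(scn, s_um = rep(200, length(ts)), t_s = ts)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 1 & m <= 3))
})

test_that("activation times are linear in arclength on the propagation side", {
  scn <- scenario(treatment_site = "differentiation_zone",
                  init_arclength_um = 1500, longitudinal_speed_um_s = -6.8,
                  amplitude_fold = 1.5)
  s <- seq(0, 1500, by = 50)
  ta <- activation_time(scn, s)
  expect_equal(diff(ta), diff(s) / -6.8)
  # shoot-ward of the locus: never activated for a tip-ward wave
  expect_identical(activation_time(scn, 1600), Inf)
  # bidirectional: V with both branches at rate 1/|u|
  scn_bi <- scenario(treatment_site = "differentiation_zone",
                     init_arclength_um = 1000, longitudinal_speed_um_s = 11,
                     bidirectional = TRUE, amplitude_fold = 1.5)
  expect_equal(activation_time(scn_bi, c(890, 1110)) -
                 activation_time(scn_bi, 1000),
               c(10, 10))
})

test_that("one-sided transverse delay is mirror-symmetric and midline-clamped", {
  mk <- function(flank, crosses) {
    scenario(treatment_site = "differentiation_zone", sidedness = "one_sided",
             init_arclength_um = 1000, longitudinal_speed_um_s = -5.2,
             transverse_speed_um_s = 9.4, amplitude_fold = 1.5,
             crosses_midline = crosses, treated_flank = flank)
  }
  r <- seq(-60, 60, by = 5)
  t_pos <- activation_time(mk("positive", TRUE), rep(900, length(r)), r, 60)
  t_neg <- activation_time(mk("negative", TRUE), rep(900, length(r)), -r, 60)
  expect_equal(t_pos, t_neg)  # flipping the flank mirrors the delay field
  # crossing: delay grows linearly from the treated flank at rate 1/v_T
  expect_equal(t_pos - min(t_pos), (60 - r) / 9.4)
  # non-crossing: untreated side never activates
  t_nc <- activation_time(mk("positive", FALSE), rep(900, length(r)), r, 60)
  expect_true(all(is.infinite(t_nc[r < 0])))
  expect_equal(t_nc[r >= 0], t_pos[r >= 0])
})

test_that("preset table encodes the reported kinematics", {
  tab <- preset_table()
  s <- function(p, col) tab[[col]][tab$preset == p]
  expect_equal(s("nacl_tip_full", "u"), 5.9)
  expect_equal(s("nacl_tip_full", "fold"), 2.5)
  expect_equal(s("nacl_dz_full", "u"), -6.8)
  expect_equal(s("peg_dz_full", "u"), -11.6)
  expect_equal(s("peg_tip_full", "fold"), 4.0)
  expect_equal(s("nacl_dz_oneside", "v_t"), 9.4)
  expect_equal(s("nacl_dz_oneside", "u"), -5.2)
  expect_true(s("peg_dz_oneside", "bidir"))
  expect_equal(abs(s("peg_dz_oneside", "u")), 11)
  expect_equal(s("peg_tip_oneside", "u"), 14.2)
  expect_equal(s("peg_tip_oneside", "fold"), 3.0)

  scn <- preset_scenario("nacl_tip_full")
  expect_equal(scn$longitudinal_speed_um_s, 5.9)
  expect_identical(scn$treatment_site, "tip")
  expect_equal(scn$init_arclength_um, 0)

  scn1 <- preset_scenario("peg_tip_oneside")
  expect_identical(scn1$sidedness, "one_sided")
  expect_equal(scn1$longitudinal_speed_um_s, 14.2)

  expect_error(preset_scenario("does_not_exist"), "Valid presets")
})

test_that("speed_z shifts speed magnitudes by z standard deviations", {
  scn <- preset_scenario("nacl_dz_full", speed_z = 1)
  expect_equal(abs(scn$longitudinal_speed_um_s), 6.8 + 0.9)
  expect_lt(scn$longitudinal_speed_um_s, 0)  # still tip-ward
  scn2 <- preset_scenario("nacl_dz_oneside", speed_z = -1)
  expect_equal(abs(scn2$longitudinal_speed_um_s), 5.2 - 0.57)
  expect_equal(scn2$transverse_speed_um_s, 9.4 - 0.94)
})
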