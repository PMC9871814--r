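test_that("Theil-Sen recovers exact synthetic front times", {
  s <- seq(100, 800, by = 20)
  t <- 12 + (s - 100) / 6.8   # shoot-ward wave at 6.8 um/s
  fit <- estimate_speed(t, s)
  expect_equal(fit$speed_um_s, 6.8, tolerance = 1e-12)
  expect_identical(fit$direction, "shoot_ward")
  expect_equal(fit$branches$inlier_fraction, 1)

  # robust to a third of the positions stalling at a common late time
  t_bad <- t
  t_bad[1:12] <- max(t) + 5
  fit_r <- estimate_speed(t_bad[13:36], s[13:36])
  expect_equal(fit_r$speed_um_s, 6.8, tolerance = 1e-12)
})

test_that("speed estimation is antisymmetric under time reversal", {
  s <- seq(0, 500, by = 25)
  t <- 8 + s / 9.4
  fwd <- estimate_speed(t, s)
  rev <- estimate_speed(max(t) - t, s)
  expect_equal(rev$speed_um_s, -fwd$speed_um_s, tolerance = 1e-12)
  expect_identical(fwd$direction, "shoot_ward")
  expect_identical(rev$direction, "tip_ward")
})

test_that("insufficient or degenerate front coverage is handled", {
  expect_error(estimate_speed(c(1, 2), c(0, 10)), "Insufficient")
  expect_error(estimate_speed(c(1, 2, NA, NA), c(0, 10, 20, 30)),
               "Insufficient")
  # flat (instantaneous) front times: unresolved, direction none
  fit <- estimate_speed(rep(5, 10), seq(0, 90, by = 10))
  expect_identical(fit$direction, "none")
  expect_true(is.na(fit$speed_um_s))
})

test_that("V-shaped front times classify as bidirectional with opposite branches", {
  s <- seq(0, 1000, by = 10)
  s0 <- 600
  t <- 15 + abs(s - s0) / 11
  fit <- classify_direction(t, s)
  expect_identical(fit$direction, "bidirectional")
  expect_identical(nrow(fit$branches), 2L)
  expect_equal(sort(fit$branches$speed_um_s), c(-11, 11), tolerance = 1e-6)
  # monotone times stay single-branch
  mono <- classify_direction(15 + s / 5.2, s)
  expect_identical(mono$direction, "shoot_ward")
  expect_identical(nrow(mono$branches), 1L)
})

test_that("front detection recovers activation times on a noiseless preset", {
  sim <- cached_sim("nacl_tip_full_noiseless", function() {
    generate_preset("nacl_tip_full", seed = 1, cam = test_camera(1),
                    noise = FALSE)
  })
  kym <- build_kymograph(sim$stack, root_roi(sim$phantom))
  kym$positions_um <- kym$positions_um - sim$phantom$tip_xy_um[2]
  fr <- detect_front(kym)
  det <- fr[fr$detected & fr$position_um > 50 & fr$position_um < 800, ]
  truth <- sim$truth
  t_exp <- approx(truth$activation$s_um, truth$activation$t_a_s,
                  xout = det$position_um)$y
  # detected half-max times match the analytic activation times
  expect_lt(max(abs(det$front_time_s - t_exp)), 1)
  expect_gt(nrow(det), 100)
})

test_that("control recordings yield no front anywhere", {
  sim <- control_sim()
  kym <- build_kymograph(sim$stack, root_roi(sim$phantom))
  fr <- detect_front(kym)
  expect_false(any(fr$detected))
  fit <- fit_wavefront(kym)
  expect_identical(fit$direction, "none")
  # constant (noise-free flat) profiles are none as well
  flat <- kym
  flat$matrix[] <- 1234
  expect_false(any(detect_front(flat)$detected))
})

test_that("baseline-window misuse is an error", {
  sim <- control_sim()
  kym <- build_kymograph(sim$stack, root_roi(sim$phantom))
  expect_error(detect_front(kym, baseline_s = 1e6), "whole recording")
  expect_error(detect_front(kym, baseline_s = 0.5), "at least 2 frames")
})

test_that("fold change is exact, scale-invariant and guards its baseline", {
  tr <- tibble::tibble(time_s = 0:59,
                       intensity_adu = rep(800, 60))
  expect_equal(fold_change(tr), 1.0)
  # sigmoidal rise from 500 to 1250 over a 200-ADU background
  rise <- 500 + 750 * stats::plogis((0:59 - 30) / 3)
  tr2 <- tibble::tibble(time_s = 0:59, intensity_adu = 200 + rise)
  f1 <- fold_change(tr2, background_adu = 200)
  expect_equal(f1, 1250 / 500, tolerance = 0.01)
  # doubling the background-corrected signal leaves the ratio unchanged
  tr3 <- tibble::tibble(time_s = 0:59, intensity_adu = 200 + 2 * rise)
  expect_equal(fold_change(tr3, background_adu = 200), f1, tolerance = 1e-9)
  expect_error(fold_change(tr2, background_adu = 5000), "baseline")
})

test_that("replicate summaries follow the mean (SD, n) convention", {
  s <- summarize_replicates(c(6, 7, 8))
  expect_equal(s$mean, 7)
  expect_equal(s$sd, 1)
  expect_identical(s$n, 3L)
  expect_identical(summarize_replicates(c(8, 7, 6))[, 1:3], s[, 1:3])
  one <- summarize_replicates(5)
  expect_identical(one$n, 1L)
  expect_true(is.na(one$sd))
})

test_that("tidy and glance expose the fit in broom style", {
  s <- seq(0, 500, by = 25)
  fit <- estimate_speed(10 + s / 4.2, s)
  td <- tidy(fit)
  expect_true(all(c("branch", "speed_um_s", "speed_sd", "direction")
                  %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$speed_um_s, 4.2, tolerance = 1e-9)
  expect_s3_class(autoplot(fit), "ggplot")
})
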