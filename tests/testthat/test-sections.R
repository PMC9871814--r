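test_that("sections sit at the standard spacings on a straight root", {
  geom <- root_geometry(1600, 60)
  ph <- build_phantom(geom, tiny_camera())
  sec <- place_sections(ph)
  expect_identical(as.character(sec$section),
                   c("Tip", "ME1", "ME2", "ED1", "ED2"))
  gaps <- diff(sec$s_um)
  expect_equal(gaps, c(290, 290, 290, 580))
  expect_equal(max(sec$s_um) - min(sec$s_um), 1450)
  # centre-to-centre pixel distance matches arclength for a straight axis
  d <- sqrt(diff(sec$cx_um)^2 + diff(sec$cy_um)^2)
  expect_equal(d, c(290, 290, 290, 580), tolerance = 1e-9)
  # transects perpendicular to a vertical axis are horizontal
  expect_equal(sec$nx, rep(1, 5) * sec$nx[1], tolerance = 1e-12)
  expect_equal(sec$ny, rep(0, 5), tolerance = 1e-12)
})

test_that("curved-axis spacings are arclength, not chord", {
  # quarter arc of radius 1200 um, arclength 1885 um
  theta <- seq(0, pi / 2, length.out = 2001)
  rc <- 1200
  x <- rc * sin(theta); y <- rc * (1 - cos(theta))
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  axis <- tibble::tibble(x_um = x, y_um = y, s_um = s)
  sec <- place_sections(axis)
  # oracle: positions on the arc are at angles theta = s_true / rc; the
  # arclength between consecutive sections is rc * delta(theta)
  ang <- atan2(sec$cx_um, rc - sec$cy_um)
  arc_gaps <- rc * diff(ang)
  expect_equal(arc_gaps, c(290, 290, 290, 580), tolerance = 0.05)
  # chord distances are strictly shorter than the arclength gaps
  chords <- sqrt(diff(sec$cx_um)^2 + diff(sec$cy_um)^2)
  expect_true(all(chords < arc_gaps))
  # normals are unit length and perpendicular to the local tangent
  expect_equal(sec$nx^2 + sec$ny^2, rep(1, 5), tolerance = 1e-9)
})

test_that("too-short axes are rejected with the required length", {
  ph <- build_phantom(short_geometry(1000), tiny_camera())
  expect_error(place_sections(ph), "1450")
})

test_that("uniform stacks give constant traces at the uniform value", {
  geom <- root_geometry(1600, 60)
  ph <- build_phantom(geom, tiny_camera())
  st <- image_stack(array(500, c(ph$dim[["H"]], ph$dim[["W"]], 5)), 4, 1)
  tr <- extract_traces(st, place_sections(ph))
  expect_true(all(tr$intensity_adu == 500))
  expect_equal(sort(unique(tr$time_s)), 0:4)
})

test_that("noiseless tip trace plateaus at baseline times the amplitude fold", {
  geom <- root_geometry(1600, 60)
  cam <- camera(pixel_size_um = 4, n_frames = 80L, frame_interval_s = 1,
                psf_sigma_um = 0, background_adu = 0, seed = 1)
  sim <- generate_preset("nacl_tip_full", seed = 1, cam = cam,
                         geometry = geom, noise = FALSE)
  tr <- extract_traces(sim$stack, place_sections(sim$phantom))
  tip <- tr[tr$section == "Tip", ]
  pre <- mean(tip$intensity_adu[tip$time_s < 10])
  plateau <- max(tip$intensity_adu)
  expect_equal(plateau / pre, 2.5, tolerance = 1e-9)
})

test_that("a transect outside the root warns but still yields a trace", {
  geom <- root_geometry(1600, 60)
  ph <- build_phantom(geom, tiny_camera())
  st <- image_stack(array(100, c(ph$dim[["H"]], ph$dim[["W"]], 3)), 4, 1)
  sec <- place_sections(ph)
  sec$cx_um[1] <- 6  # move the Tip transect into the empty margin
  sec$length_um[1] <- 8
  expect_warning(tr <- extract_traces(st, sec, phantom = ph), "Tip")
  expect_identical(nrow(tr), 15L)
})

test_that("resampling is exact on ramps and bounded on smooth signals", {
  tr <- tibble::tibble(time_s = 0:10, intensity_adu = 5 * (0:10) + 2)
  # identity on the native grid
  expect_equal(resample_trace(tr, 0:10)$intensity_adu, tr$intensity_adu)
  # exact midpoint values on a linear ramp
  mid <- resample_trace(tr, seq(0.5, 9.5, by = 1))
  expect_equal(mid$intensity_adu, 5 * mid$time_s + 2)
  expect_error(resample_trace(tr, seq(0, 12, by = 1)), "extrapolation")

  # band-limited signal: downsample-then-upsample error bounded by h^2/8 * max|f''|
  t_fine <- seq(0, 80, by = 1)
  sig <- tibble::tibble(time_s = t_fine, intensity_adu = sin(2 * pi * t_fine / 40))
  coarse <- resample_trace(sig, seq(0, 80, by = 4))
  back <- resample_trace(coarse, t_fine)
  bound <- 4^2 / 8 * (2 * pi / 40)^2
  expect_lt(max(abs(back$intensity_adu - sig$intensity_adu)), bound * 1.05)
})
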