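test_that("degenerate scene configurations behave as specified", {
  cfg0 <- scene_config(field_size_um = 10, density_per_um2 = 0,
                       oligomer_fractions = 1)
  sc0 <- generate_scene(cfg0, seed = 1)
  expect_equal(nrow(sc0$emitters), 0)

  # full labeling: every subunit carries a fluorophore
  cfg1 <- scene_config(field_size_um = 15, n_emitters = 200,
                       oligomer_fractions = c(0.2, 0.3, 0.5),
                       labeling_p = 1, min_separation_nm = 0)
  sc1 <- generate_scene(cfg1, seed = 2)
  expect_identical(sc1$emitters$k, sc1$emitters$n)

  expect_error(scene_config(n_emitters = 10, oligomer_fractions = c(-1, 2)),
               "nonnegative")
  expect_error(scene_config(n_emitters = 10, oligomer_fractions = numeric(0)))
  expect_error(scene_config(n_emitters = 10, oligomer_fractions = 1,
                            labeling_p = 0))
})

test_that("dark-emitter fraction matches the binomial labeling law", {
  n_em <- 1e5
  cfg <- scene_config(field_size_um = 100, n_emitters = n_em,
                      oligomer_fractions = c(0, 0, 1), labeling_p = 0.7,
                      min_separation_nm = 0)
  sc <- generate_scene(cfg, seed = 3)
  p_dark <- 0.3^3                         # binomial enumeration oracle
  frac <- mean(sc$emitters$k == 0)
  expect_lt(abs(frac - p_dark), 3 * sqrt(p_dark * (1 - p_dark) / n_em))
})

test_that("positions respect the field, margin and minimum separation", {
  cfg <- scene_config(field_size_um = 10, n_emitters = 60,
                      oligomer_fractions = 1, min_separation_nm = 700,
                      border_margin_nm = 500)
  sc <- generate_scene(cfg, seed = 4)
  em <- sc$emitters
  expect_true(all(em$x_nm >= 500 & em$x_nm <= 9500))
  expect_true(all(em$y_nm >= 500 & em$y_nm <= 9500))
  d <- stats::dist(cbind(em$x_nm, em$y_nm))
  expect_gte(min(d), 700)
})

test_that("background-only movies sit at the camera baseline", {
  cfg <- scene_config(field_size_um = 6.4, n_emitters = 0,
                      oligomer_fractions = 1)
  sc <- generate_scene(cfg, seed = 5)
  mv <- render_movie(sc, n_frames = 50, seed = 6, bg_photons_per_px = 0)
  cam <- mv$camera
  pixel_means <- average_frames(mv)
  # max over 64^2 independent pixel means: expected extreme z ~ 3.6, so a
  # 4.5 sd bound (+0.5 rounding slack) holds with high probability
  tol <- 4.5 * cam$read_noise_sd / sqrt(50) + 0.5
  expect_true(all(abs(pixel_means - cam$offset) <= tol))
  expect_lt(abs(mean(pixel_means) - cam$offset), 0.6)
})

test_that("expected photons are conserved and linear in the label count", {
  # noiseless render: total background-corrected counts = gain x total rate
  for (k in c(1, 2)) {
    sc <- one_emitter_scene(n = k)
    mv <- render_movie(sc, n_frames = 1, seed = 7, noise = FALSE,
                       brightness_cv = 0, bg_photons_per_px = 0)
    fr <- get_frame(mv, 1)
    tot <- sum(fr - mv$camera$offset)
    expected <- k * 300 * 65.4
    expect_lt(abs(tot - expected) / expected, 0.002)  # edge + rounding < 0.2%
  }
})

test_that("noisy integrated brightness matches the EMCCD mean model", {
  # one immobile k = 1 emitter; average over many frames approaches
  # photons_per_fluorophore x em_gain / sensitivity counts
  sc <- one_emitter_scene(n = 1)
  mv <- render_movie(sc, n_frames = 1000, seed = 8, brightness_cv = 0,
                    bg_photons_per_px = 0)
  avg <- average_frames(mv)
  e <- sc$emitters
  ic <- floor(e$y_nm / 100) + 1; jc <- floor(e$x_nm / 100) + 1
  roi <- avg[(ic - 5):(ic + 5), (jc - 5):(jc + 5)]
  tot <- sum(roi - mv$camera$offset)
  expected <- 300 * 65.4
  # EMCCD excess noise: var of the frame-summed signal ~ 2 N g^2
  se <- sqrt(2 * 300 * 65.4^2 / 1000)
  expect_lt(abs(tot - expected), 4 * se + 5)
})

test_that("the same seed reproduces a bit-identical movie", {
  sc <- one_emitter_scene(n = 2)
  m1 <- render_movie(sc, n_frames = 5, seed = 11)
  m2 <- render_movie(sc, n_frames = 5, seed = 11)
  expect_identical(m1$frames, m2$frames)
  m3 <- render_movie(sc, n_frames = 5, seed = 12)
  expect_false(identical(m1$frames, m3$frames))
})

test_that("movies round-trip losslessly through 16-bit TIFF", {
  sc <- one_emitter_scene(n = 3)
  mv <- render_movie(sc, n_frames = 3, seed = 13)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_identical(back$frames, mv$frames)
})

test_that("mobile emitters take Brownian steps of the configured variance", {
  cfg <- scene_config(field_size_um = 30, n_emitters = 40,
                      oligomer_fractions = c(0, 1), labeling_p = 1,
                      mobile_fraction = 1, diffusion_um2s = 0.5,
                      min_separation_nm = 0, border_margin_nm = 5000)
  sc <- generate_scene(cfg, seed = 14)
  mv <- render_movie(sc, n_frames = 40, seed = 15)
  gt <- mv$ground_truth
  steps <- unlist(lapply(split(gt, gt$emitter_id), function(g)
    diff(g$x_nm[order(g$frame)])))
  # per-axis step sd = sqrt(2 D dt) = sqrt(2 * 0.5 um^2/s * 0.03 s) = 173 nm
  expect_lt(abs(stats::sd(steps) - 173.2) / 173.2, 0.1)
  # reflection keeps every position inside the field
  expect_true(all(gt$x_nm >= 0 & gt$x_nm <= 30000))
})

test_that("a field smaller than the PSF support is rejected", {
  cfg <- scene_config(field_size_um = 0.5, n_emitters = 1,
                      oligomer_fractions = 1, min_separation_nm = 0,
                      border_margin_nm = 0)
  sc <- generate_scene(cfg, seed = 16)
  expect_error(render_movie(sc, psf_sigma_nm = 150, n_frames = 1),
               "too small")
})
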