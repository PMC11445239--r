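test_that("flat and background-only images yield no candidates", {
  expect_equal(nrow(detect_spots(matrix(100, 64, 64))), 0)
  expect_error(detect_spots(array(0, c(4, 4, 4))), "2D")

  cfg <- scene_config(field_size_um = 12.8, n_emitters = 0,
                      oligomer_fractions = 1)
  sc <- generate_scene(cfg, seed = 1)
  n_cand <- vapply(1:30, function(s) {
    fr <- get_frame(render_movie(sc, n_frames = 1, seed = s,
                                 bg_photons_per_px = 0), 1)
    nrow(detect_spots(fr))
  }, numeric(1))
  expect_gte(mean(n_cand == 0), 0.95)
})

test_that("a rendered emitter is detected once, at its true position", {
  sc <- one_emitter_scene(n = 2, seed = 3)
  fr <- get_frame(render_movie(sc, n_frames = 1, seed = 4), 1)
  cand <- detect_spots(fr)
  expect_equal(nrow(cand), 1)
  e <- sc$emitters
  expect_lt(abs(cand$row - (floor(e$y_nm / 100) + 1)), 1.5)
  expect_lt(abs(cand$col - (floor(e$x_nm / 100) + 1)), 1.5)
})

test_that("noiseless fits recover volume and width to within 1%", {
  for (k in c(1, 3)) {
    sc <- one_emitter_scene(n = k, seed = 5)
    mv <- render_movie(sc, n_frames = 1, seed = 6, noise = FALSE,
                       brightness_cv = 0)
    fr <- get_frame(mv, 1)
    cand <- detect_spots(fr)
    loc <- fit_spot(fr, c(cand$row[1], cand$col[1]), mv$camera)
    expect_true(loc$fit_ok)
    expect_lt(abs(loc$brightness_photons - k * 300) / (k * 300), 0.01)
    expect_lt(abs(loc$sigma_nm - 150) / 150, 0.01)
  }
})

test_that("brightness is linear in the label count on noiseless renders", {
  ks <- 1:6
  vols <- vapply(ks, function(k) {
    sc <- one_emitter_scene(n = k, seed = 10 + k)
    mv <- render_movie(sc, n_frames = 1, seed = 20 + k, noise = FALSE,
                       brightness_cv = 0)
    fr <- get_frame(mv, 1)
    cand <- detect_spots(fr)
    fit_spot(fr, c(cand$row[1], cand$col[1]), mv$camera)$brightness_photons
  }, numeric(1))
  slope <- stats::coef(stats::lm(vols ~ ks))[["ks"]]
  expect_lt(abs(slope - 300) / 300, 0.02)
})

test_that("fits on structureless background are never accepted bright spots", {
  # after filtering, a fit at an arbitrary noise position either fails, is
  # rejected, or reports a brightness far below one fluorophore (300 photons)
  for (s in c(7, 42, 99)) {
    fr <- withr::with_seed(s, matrix(170 + stats::rnorm(64 * 64, 0, 10),
                                     64, 64))
    loc <- filter_localizations(fit_spot(fr, c(32, 32), test_camera()))
    accepted_bright <- loc$fit_ok & loc$reject_reason == "none" &
      !is.na(loc$brightness_photons) & loc$brightness_photons > 30
    expect_false(accepted_bright)
  }
  # ROI touching the border fails cleanly
  fr <- withr::with_seed(99, matrix(170 + stats::rnorm(64 * 64, 0, 10),
                                    64, 64))
  edge <- fit_spot(fr, c(2, 2), test_camera())
  expect_false(edge$fit_ok)
  expect_equal(edge$reject_reason, "fit_failed")
})

test_that("localization error stays below 0.3 px RMS at ~1000 photons", {
  sc <- one_emitter_scene(n = 1, seed = 30)
  e <- sc$emitters
  errs <- vapply(1:150, function(s) {
    mv <- render_movie(sc, n_frames = 1, seed = 100 + s,
                       photons_per_fluorophore = 1000, brightness_cv = 0,
                       bg_photons_per_px = 20)
    fr <- get_frame(mv, 1)
    cand <- detect_spots(fr)
    if (nrow(cand) == 0) return(NA_real_)
    loc <- fit_spot(fr, c(cand$row[1], cand$col[1]), mv$camera)
    sqrt((loc$x_nm - e$x_nm)^2 + (loc$y_nm - e$y_nm)^2) / 100
  }, numeric(1))
  errs <- errs[!is.na(errs)]
  expect_gt(length(errs), 140)
  expect_lt(sqrt(mean(errs^2)), 0.3)
})

test_that("overlap, width and multi-peak filters reject as specified", {
  base <- data.frame(
    frame = NA_integer_, x_px = c(10, 16, 40), y_px = c(10, 10, 40),
    x_nm = c(1000, 1600, 4000), y_nm = c(1000, 1000, 4000),
    brightness_photons = c(500, 400, 600), sigma_nm = c(150, 150, 150),
    background_photons = 0.1, fit_ok = TRUE, reject_reason = "none",
    stringsAsFactors = FALSE)
  out <- filter_localizations(base, min_roi_distance_px = 7)
  # pair at distance 6 px: both rejected; isolated one survives
  expect_equal(out$reject_reason, c("overlap", "overlap", "none"))

  wide <- base[3, ]; wide$sigma_nm <- 230
  expect_equal(filter_localizations(wide)$reject_reason, "sigma_too_large")
  ok <- base[3, ]
  expect_equal(filter_localizations(ok, max_sigma_nm = 200)$reject_reason,
               "none")

  empty <- base[0, ]
  expect_equal(nrow(filter_localizations(empty)), 0)

  # idempotency
  once <- filter_localizations(base)
  expect_identical(filter_localizations(once), once)
})

test_that("two particles in one ROI raise the multi-peak flag", {
  # two trimers exactly 4 px apart: secondary peak inside the 7x7 ROI
  sc <- one_emitter_scene(n = 3, seed = 42, field_um = 6.4)
  sc$emitters <- rbind(sc$emitters, sc$emitters)
  sc$emitters$emitter_id <- 1:2
  sc$emitters$x_nm[2] <- sc$emitters$x_nm[2] + 400
  mv <- render_movie(sc, n_frames = 30, seed = 43)
  avg <- average_frames(mv)
  cand <- detect_spots(avg)
  locs <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_spot(avg, c(cand$row[i], cand$col[i]), test_camera(),
             n_frames_averaged = 30)))
  expect_true(any(locs$reject_reason == "multi_peak"))
})

test_that("photon conversion inverts the renderer's mean model", {
  sc <- one_emitter_scene(n = 2, seed = 50)
  mv <- render_movie(sc, n_frames = 400, seed = 51, brightness_cv = 0,
                     photons_per_fluorophore = 2000, bg_photons_per_px = 0)
  avg <- average_frames(mv)
  e <- sc$emitters
  ic <- floor(e$y_nm / 100) + 1; jc <- floor(e$x_nm / 100) + 1
  roi_sum <- sum(avg[(ic - 6):(ic + 6), (jc - 6):(jc + 6)] - mv$camera$offset)
  ph <- as.numeric(counts_to_photons(roi_sum, mv$camera,
                                     subtract_offset = FALSE))
  expect_lt(abs(ph - 4000) / 4000, 0.01)
})

test_that("net gradient scores spots positively and dark spots negatively", {
  expect_true(all(net_gradient(matrix(5, 32, 32), 7) == 0))
  expect_error(net_gradient(matrix(0, 8, 8), box = 4), "odd")

  sc <- one_emitter_scene(n = 3, seed = 60)
  mv <- render_movie(sc, n_frames = 20, seed = 61)
  avg <- average_frames(mv)
  ng <- net_gradient(avg, 7)
  e <- sc$emitters
  ic <- floor(e$y_nm / 100) + 1; jc <- floor(e$x_nm / 100) + 1
  expect_gt(ng[ic, jc], ng[ic, jc + 6])
  expect_gt(ng[ic, jc], 0)
  # intensity inversion flips the score's sign
  inv <- max(avg) + min(avg) - avg
  expect_lt(net_gradient(inv, 7)[ic, jc], 0)
})

test_that("detection has high recall and precision on a sparse field", {
  cfg <- scene_config(field_size_um = 25.6, n_emitters = 60,
                      oligomer_fractions = c(0, 1), labeling_p = 1,
                      min_separation_nm = 1500)
  sc <- generate_scene(cfg, seed = 70)
  mv <- render_movie(sc, n_frames = 40, seed = 71)
  locs <- accepted_localizations(detect_frame(average_frames(mv), mv$camera))
  em <- sc$emitters
  d <- sqrt(outer(em$x_nm, locs$x_nm, "-")^2 + outer(em$y_nm, locs$y_nm, "-")^2)
  recall <- mean(apply(d, 1, min) < 150)
  precision <- mean(apply(d, 2, min) < 150)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})
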