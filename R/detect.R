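#' @importFrom EBImage filter2 makeBrush
NULL

# shift a matrix by (di, dj), padding with `fill`
shift_mat <- function(m, di, dj, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
  ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

# strict 8-neighbourhood local maxima
local_maxima <- function(m) {
  nb <- matrix(-Inf, nrow(m), ncol(m))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pmax(nb, shift_mat(m, di, dj))
  }
  m > nb
}

gaussian_brush <- function(sigma_px) {
  size <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
}

#' Detect diffraction-limited spots by difference of Gaussians
#'
#' Band-pass filters the image with the difference of two Gaussian blurs and
#' returns the strict local maxima of the response that exceed
#' \code{threshold} times the robust noise level (MAD) of the response.
#'
#' @param frame 2D numeric matrix of camera counts.
#' @param dog_sigmas_px the two blur standard deviations in pixels,
#'   narrow first. Default (1.2, 2.4) px = (0.8, 1.6) x a 1.5 px PSF.
#' @param threshold detection threshold in units of the robust response noise.
#' @return data.frame with columns \code{row}, \code{col} (1-based pixel
#'   indices) and \code{response}, ordered by decreasing response.
#' @export
detect_spots <- function(frame, dog_sigmas_px = c(1.2, 2.4), threshold = 5) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("`frame` must be a 2D numeric matrix")
  stopifnot(length(dog_sigmas_px) == 2, dog_sigmas_px[1] < dog_sigmas_px[2],
            all(dog_sigmas_px > 0), threshold >= 0)
  b1 <- EBImage::filter2(frame, gaussian_brush(dog_sigmas_px[1]),
                         boundary = "replicate")
  b2 <- EBImage::filter2(frame, gaussian_brush(dog_sigmas_px[2]),
                         boundary = "replicate")
  resp <- b1 - b2
  # background noise floor by iterative sigma clipping: a plain global MAD is
  # inflated at high spot densities (cores and DoG rings can cover most pixels)
  noise <- stats::mad(resp)
  v <- as.vector(resp)
  for (i in 1:5) {
    if (noise <= 0) break
    keep <- abs(v - stats::median(v)) < 4 * noise
    if (sum(keep) < 100) break
    v <- v[keep]
    new_noise <- stats::mad(v)
    if (new_noise >= noise * 0.95) { noise <- new_noise; break }
    noise <- new_noise
  }
  cand <- local_maxima(resp) & (resp > threshold * noise)
  idx <- which(cand, arr.ind = TRUE)
  out <- data.frame(row = idx[, 1], col = idx[, 2],
                    response = resp[cand])
  out[order(-out$response), , drop = FALSE]
}

# integrated 2D Gaussian + constant evaluated on a pixel grid (pixel units;
# pixel j spans [j-1, j), centre at j - 0.5)
integrated_gauss <- function(par, rows, cols) {
  V <- par[1]; x0 <- par[2]; y0 <- par[3]; s <- par[4]; c0 <- par[5]
  fx <- stats::pnorm((cols - x0) / s) - stats::pnorm((cols - 1 - x0) / s)
  fy <- stats::pnorm((rows - y0) / s) - stats::pnorm((rows - 1 - y0) / s)
  V * outer(fy, fx) + c0
}

#' Fit one spot with an integrated 2D Gaussian and local background
#'
#' Estimates the local background as the median of the annulus between the
#' inner fit ROI and a larger outer ROI, subtracts it, and least-squares fits
#' a circularly symmetric 2D Gaussian (integrated over pixel areas) plus a
#' residual constant. The spot brightness is the fitted Gaussian volume
#' converted to photoelectrons/photons via \code{\link{counts_to_photons}}.
#'
#' @param frame 2D numeric matrix of camera counts.
#' @param candidate integer vector \code{c(row, col)} near the spot centre.
#' @param camera a \code{\link{camera_model}}.
#' @param roi_halfwidth inner ROI half-width in pixels (7x7 default box).
#' @param bg_halfwidth outer ROI half-width in pixels (11x11 default box).
#' @param multi_peak_frac after subtracting the fitted primary Gaussian, a
#'   residual maximum above this fraction of the fitted peak amplitude (and
#'   above 4x the model-predicted per-pixel noise) flags the ROI as
#'   multi-particle.
#' @param n_frames_averaged number of raw frames averaged into \code{frame};
#'   scales the per-pixel noise model by 1/sqrt(n) in the multi-peak check.
#' @param photon_units passed to \code{\link{counts_to_photons}}.
#' @return one-row data.frame (a localization): \code{frame}, \code{x_px},
#'   \code{y_px}, \code{x_nm}, \code{y_nm}, \code{brightness_photons},
#'   \code{sigma_nm}, \code{background_photons}, \code{fit_ok},
#'   \code{reject_reason} in \{none, overlap, multi_peak, sigma_too_large,
#'   sigma_too_small, fit_failed\}.
#' @export
fit_spot <- function(frame, candidate, camera, roi_halfwidth = 3,
                     bg_halfwidth = 5, multi_peak_frac = 0.3,
                     n_frames_averaged = 1,
                     photon_units = "photoelectrons") {
  stopifnot(is.matrix(frame), inherits(camera, "camera_model"),
            length(candidate) >= 2, bg_halfwidth > roi_halfwidth)
  r0 <- as.integer(candidate[1]); c0 <- as.integer(candidate[2])
  nr <- nrow(frame); nc <- ncol(frame)
  px <- camera$pixel_size_nm
  fail <- function(reason) data.frame(
    frame = NA_integer_, x_px = c0 - 0.5, y_px = r0 - 0.5,
    x_nm = (c0 - 0.5) * px, y_nm = (r0 - 0.5) * px,
    brightness_photons = NA_real_, sigma_nm = NA_real_,
    background_photons = NA_real_, fit_ok = FALSE,
    reject_reason = reason, stringsAsFactors = FALSE)
  if (r0 - bg_halfwidth < 1 || r0 + bg_halfwidth > nr ||
      c0 - bg_halfwidth < 1 || c0 + bg_halfwidth > nc)
    return(fail("fit_failed"))

  rows_in <- (r0 - roi_halfwidth):(r0 + roi_halfwidth)
  cols_in <- (c0 - roi_halfwidth):(c0 + roi_halfwidth)
  rows_out <- (r0 - bg_halfwidth):(r0 + bg_halfwidth)
  cols_out <- (c0 - bg_halfwidth):(c0 + bg_halfwidth)
  outer_roi <- frame[rows_out, cols_out]
  inner_mask <- matrix(FALSE, length(rows_out), length(cols_out))
  inner_mask[(bg_halfwidth - roi_halfwidth + 1):(bg_halfwidth + roi_halfwidth + 1),
             (bg_halfwidth - roi_halfwidth + 1):(bg_halfwidth + roi_halfwidth + 1)] <- TRUE
  annulus <- outer_roi[!inner_mask]
  bg_med <- stats::median(annulus)

  z <- frame[rows_in, cols_in] - bg_med

  # start values: peak amplitude -> volume, centroid on positive part
  zp <- pmax(z, 0)
  tot <- sum(zp)
  s0 <- 1.5
  if (tot > 0) {
    x0 <- sum(t(zp) * (cols_in - 0.5)) / tot
    y0 <- sum(zp * (rows_in - 0.5)) / tot
  } else {
    x0 <- c0 - 0.5; y0 <- r0 - 0.5
  }
  V0 <- max(max(z), 1e-6) * 2 * pi * s0^2

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(V = V0, x0 = x0, y0 = y0, s = s0, c0 = 0),
      lower = c(0, min(cols_in) - 1, min(rows_in) - 1, 0.3, -Inf),
      upper = c(Inf, max(cols_in) + 1, max(rows_in) + 1,
                2 * roi_halfwidth, Inf),
      fn = function(p) as.vector(z - integrated_gauss(p, rows_in, cols_in)),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9))
    return(fail("fit_failed"))
  p <- fit$par
  if (p[["V"]] <= 0 || p[["s"]] <= 0) return(fail("fit_failed"))

  # multi-particle check on the fit residual: after subtracting the fitted
  # primary Gaussian, a remaining non-adjacent maximum above multi_peak_frac
  # of the primary amplitude indicates a second particle. Raw-ROI maxima are
  # not used because the PSF's own shoulder plus pixel noise routinely forms
  # spurious secondary maxima; the significance guard uses the EMCCD noise
  # model (excess-noise factor 2) at each pixel's expected intensity, scaled
  # for frame averaging, because the annulus MAD underestimates the
  # signal-dependent noise on the spot itself.
  reason <- "none"
  model <- integrated_gauss(p, rows_in, cols_in)
  resid <- z - model
  amp <- p[["V"]] / (2 * pi * p[["s"]]^2)
  lm_res <- local_maxima(resid)
  if (any(lm_res)) {
    peaks <- which(lm_res, arr.ind = TRUE)
    vals <- resid[lm_res]
    pr <- round(p[["y0"]] + 0.5) - min(rows_in) + 1
    pc <- round(p[["x0"]] + 0.5) - min(cols_in) + 1
    g <- gain_counts_per_pe(camera)
    lam_counts <- pmax(model, 0) + max(bg_med - camera$offset, 0)
    sd_px <- sqrt((2 * g * lam_counts + camera$read_noise_sd^2) /
                    max(n_frames_averaged, 1))
    sec <- vals > multi_peak_frac * amp &
      vals > 4 * pmax(sd_px[lm_res], .Machine$double.eps) &
      (abs(peaks[, 1] - pr) > 1 | abs(peaks[, 2] - pc) > 1)
    if (any(sec)) reason <- "multi_peak"
  }

  brightness <- counts_to_photons(p[["V"]], camera, photon_units,
                                  subtract_offset = FALSE)
  background <- counts_to_photons(max(bg_med, camera$offset), camera,
                                  photon_units, subtract_offset = TRUE)
  data.frame(
    frame = NA_integer_,
    x_px = p[["x0"]], y_px = p[["y0"]],
    x_nm = p[["x0"]] * px, y_nm = p[["y0"]] * px,
    brightness_photons = as.numeric(brightness),
    sigma_nm = p[["s"]] * px,
    background_photons = as.numeric(background),
    fit_ok = TRUE, reject_reason = reason, stringsAsFactors = FALSE)
}

#' Filter localizations by ROI overlap, multi-peak flags and PSF width
#'
#' Applies, in order: width filtering (fitted sigma above \code{max_sigma_nm}
#' or below \code{min_sigma_nm} is rejected; sub-diffraction widths are noise
#' spikes, not particles), then pairwise overlap (both members of any accepted
#' pair closer than \code{min_roi_distance_px} are rejected, so the brightness
#' distribution is never contaminated by blended spots). Multi-peak flags set
#' at fit time are kept. The input order is preserved and the full annotated
#' table is returned; filtering is idempotent.
#'
#' @param locs localization data.frame as returned by \code{\link{fit_spot}}.
#' @param min_roi_distance_px minimum centre-to-centre distance in pixels.
#' @param max_sigma_nm maximum accepted fitted PSF sigma in nm.
#' @param min_sigma_nm minimum accepted fitted PSF sigma in nm (default 100,
#'   two-thirds of the 150 nm diffraction-limited PSF).
#' @return the annotated localization data.frame.
#' @export
filter_localizations <- function(locs, min_roi_distance_px = 7,
                                 max_sigma_nm = 200, min_sigma_nm = 100) {
  if (nrow(locs) == 0) return(locs)
  ok <- locs$fit_ok & locs$reject_reason == "none"
  wide <- ok & !is.na(locs$sigma_nm) & locs$sigma_nm > max_sigma_nm
  locs$reject_reason[wide] <- "sigma_too_large"
  narrow <- ok & !is.na(locs$sigma_nm) & locs$sigma_nm < min_sigma_nm
  locs$reject_reason[narrow] <- "sigma_too_small"
  ok <- locs$fit_ok & locs$reject_reason == "none"
  idx <- which(ok)
  if (length(idx) > 1) {
    # overlap is evaluated per frame (NA frames treated as one frame)
    fr <- locs$frame[idx]
    fr[is.na(fr)] <- -1L
    for (f in unique(fr)) {
      sub <- idx[fr == f]
      if (length(sub) < 2) next
      d <- as.matrix(stats::dist(cbind(locs$x_px[sub], locs$y_px[sub])))
      diag(d) <- Inf
      clash <- apply(d < min_roi_distance_px, 1, any)
      locs$reject_reason[sub[clash]] <- "overlap"
    }
  }
  locs
}

#' Accepted localizations
#' @param locs annotated localization data.frame.
#' @return the subset with \code{fit_ok} and no rejection reason.
#' @export
accepted_localizations <- function(locs) {
  locs[locs$fit_ok & locs$reject_reason == "none", , drop = FALSE]
}

#' Net-gradient spot score
#'
#' For every pixel, sums over a square box the image-gradient component
#' pointing toward the box centre. Bright spots give large positive scores,
#' dark (inverted) spots negative scores, flat regions zero; thresholding the
#' score ("minimum net gradient") is an alternative detection statistic.
#'
#' @param frame 2D numeric matrix.
#' @param box odd box size in pixels, >= 3 (default 7).
#' @return numeric matrix of scores, same size as \code{frame}.
#' @export
net_gradient <- function(frame, box = 7) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("`frame` must be a 2D numeric matrix")
  box <- as.integer(box)
  if (box %% 2L == 0L || box < 3L) stop("`box` must be odd and >= 3")
  # central-difference gradients with replicated edges
  gx <- (shift_mat(frame, 0, -1, fill = NA) - shift_mat(frame, 0, 1, fill = NA)) / 2
  gy <- (shift_mat(frame, -1, 0, fill = NA) - shift_mat(frame, 1, 0, fill = NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  h <- (box - 1L) / 2L
  d <- -h:h
  rr <- matrix(rep(d, times = box), box, box)          # row offsets di
  cc <- t(rr)                                          # col offsets dj
  r <- sqrt(rr^2 + cc^2); r[r == 0] <- Inf
  # score(p) = sum_d [gx(p+d), gy(p+d)] . (-d)/|d|
  # (filter2 correlates with the mirrored kernel, hence the positive signs)
  kx <- cc / r
  ky <- rr / r
  EBImage::filter2(gx, kx, boundary = "replicate") +
    EBImage::filter2(gy, ky, boundary = "replicate")
}

#' Detect and fit all spots in a single frame
#'
#' Convenience wrapper: \code{\link{detect_spots}}, \code{\link{fit_spot}} on
#' every candidate, then \code{\link{filter_localizations}}.
#'
#' @param frame 2D counts matrix.
#' @param camera a \code{\link{camera_model}}.
#' @param psf_sigma_nm expected PSF sigma; sets the DoG scales to
#'   (0.8, 1.6) x sigma.
#' @param threshold DoG detection threshold (robust noise units).
#' @param roi_halfwidth,bg_halfwidth,min_roi_distance_px,max_sigma_nm,min_sigma_nm,n_frames_averaged
#'   see \code{\link{fit_spot}} and \code{\link{filter_localizations}}.
#' @param frame_index value stored in the \code{frame} column.
#' @param photon_units passed to \code{\link{counts_to_photons}}.
#' @return annotated localization data.frame.
#' @export
detect_frame <- function(frame, camera, psf_sigma_nm = 150, threshold = 5,
                         roi_halfwidth = 3, bg_halfwidth = 5,
                         min_roi_distance_px = 7, max_sigma_nm = 200,
                         min_sigma_nm = 100, n_frames_averaged = 1,
                         frame_index = NA_integer_,
                         photon_units = "photoelectrons") {
  sig_px <- psf_sigma_nm / camera$pixel_size_nm
  cand <- detect_spots(frame, dog_sigmas_px = c(0.8, 1.6) * sig_px,
                       threshold = threshold)
  if (nrow(cand) == 0) {
    return(data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      brightness_photons = numeric(0), sigma_nm = numeric(0),
                      background_photons = numeric(0), fit_ok = logical(0),
                      reject_reason = character(0), stringsAsFactors = FALSE))
  }
  locs <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_spot(frame, c(cand$row[i], cand$col[i]), camera,
             roi_halfwidth = roi_halfwidth, bg_halfwidth = bg_halfwidth,
             n_frames_averaged = n_frames_averaged,
             photon_units = photon_units)))
  locs$frame <- frame_index
  filter_localizations(locs, min_roi_distance_px = min_roi_distance_px,
                       max_sigma_nm = max_sigma_nm,
                       min_sigma_nm = min_sigma_nm)
}

#' Detect and fit spots across movie frames
#'
#' Runs \code{\link{detect_frame}} on each requested frame and stacks the
#' localization tables (used for tracking; for stoichiometry of immobile
#' particles prefer photometry on \code{\link{average_frames}}).
#'
#' @param stack a \code{frame_stack}.
#' @param frames frame indices to analyze (default: all).
#' @param ... passed to \code{\link{detect_frame}}.
#' @inheritParams detect_frame
#' @return localization data.frame with the \code{frame} column set.
#' @export
detect_movie <- function(stack, frames = NULL, camera = stack$camera, ...) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(frames)) frames <- seq_len(dim(stack$frames)[3])
  do.call(rbind, lapply(frames, function(f)
    detect_frame(get_frame(stack, f), camera = camera, frame_index = f, ...)))
}

#' Write / read localization tables as CSV
#' @param locs localization data.frame.
#' @param path CSV path.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(locs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
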