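#' Scene configuration for the synthetic TIRF simulator
#'
#' Collects the ground-truth parameters of a simulated field of membrane
#' oligomers. Defaults emulate reconstituted oligomers in a supported lipid
#' bilayer: a population built purely from dimers and trimers, 70% fluorophore
#' labeling efficiency, immobile (membrane-inserted) particles.
#'
#' @param field_size_um side length of the square field of view, micrometres.
#' @param n_emitters number of emitters to place. Alternatively give
#'   \code{density_per_um2}; exactly one of the two must be supplied.
#' @param density_per_um2 emitter density; \code{n_emitters} is then
#'   \code{round(density * area)}.
#' @param oligomer_fractions numeric vector of occurrence fractions indexed by
#'   oligomer order n = 1, 2, ... (must be nonnegative, nonempty support, and
#'   is normalized to sum to 1).
#' @param labeling_p probability that a subunit carries a fluorescent (mature)
#'   fluorophore, in (0, 1].
#' @param mobile_fraction fraction of emitters diffusing laterally; the rest
#'   are immobile.
#' @param diffusion_um2s lateral diffusion coefficient of mobile emitters.
#' @param min_separation_nm minimum pairwise distance between emitters.
#'   Set to 0 to allow overlapping scenes (for testing the overlap filters).
#' @param border_margin_nm emitters are kept at least this far from the field
#'   edges so their PSF is fully contained.
#' @return A list of class \code{scene_config}.
#' @export
scene_config <- function(field_size_um = 20,
                         n_emitters = NULL,
                         density_per_um2 = NULL,
                         oligomer_fractions = c(0, 0.5, 0.5),
                         labeling_p = 0.7,
                         mobile_fraction = 0,
                         diffusion_um2s = 0.5,
                         min_separation_nm = 600,
                         border_margin_nm = 600) {
  if (is.null(n_emitters) == is.null(density_per_um2))
    stop("supply exactly one of `n_emitters` or `density_per_um2`")
  if (!is.numeric(oligomer_fractions) || length(oligomer_fractions) == 0 ||
      any(oligomer_fractions < 0) || sum(oligomer_fractions) <= 0)
    stop("`oligomer_fractions` must be nonnegative with nonempty support")
  stopifnot(labeling_p > 0, labeling_p <= 1,
            mobile_fraction >= 0, mobile_fraction <= 1,
            diffusion_um2s >= 0, field_size_um > 0,
            min_separation_nm >= 0, border_margin_nm >= 0)
  if (!is.null(density_per_um2)) {
    stopifnot(density_per_um2 >= 0)
    n_emitters <- round(density_per_um2 * field_size_um^2)
  }
  stopifnot(n_emitters >= 0)
  structure(list(
    field_size_um = field_size_um,
    n_emitters = as.integer(n_emitters),
    oligomer_fractions = oligomer_fractions / sum(oligomer_fractions),
    labeling_p = labeling_p,
    mobile_fraction = mobile_fraction,
    diffusion_um2s = diffusion_um2s,
    min_separation_nm = min_separation_nm,
    border_margin_nm = border_margin_nm
  ), class = "scene_config")
}

#' Generate a ground-truth scene of membrane oligomers
#'
#' Places emitters uniformly at random on the field subject to a minimum
#' pairwise separation (dart throwing), draws each emitter's oligomer order n
#' from the configured occurrence distribution, its number of labeled subunits
#' k from Binomial(n, labeling_p), and assigns mobility classes. Emitters with
#' k = 0 are dark: they carry no fluorophore and contribute no signal.
#'
#' @param config a \code{\link{scene_config}}.
#' @param seed integer seed; the same seed reproduces the same scene.
#' @return An object of class \code{synthetic_scene}: list with
#'   \code{emitters} (data.frame: emitter_id, x_nm, y_nm, n, k, mobility,
#'   diffusion_um2s), \code{field_size_nm}, \code{labeling_p}, \code{config}.
#' @export
generate_scene <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(seed, {
    L <- config$field_size_um * 1000
    ne <- config$n_emitters
    lo <- config$border_margin_nm
    hi <- L - config$border_margin_nm
    if (ne > 0 && hi <= lo)
      stop("field too small for the requested border margin")
    xs <- numeric(0); ys <- numeric(0)
    if (ne > 0) {
      min2 <- config$min_separation_nm^2
      max_tries <- 500L * ne
      tries <- 0L
      while (length(xs) < ne) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("could not place emitters at the requested density and separation")
        x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
        if (min2 == 0 || length(xs) == 0 ||
            min((xs - x)^2 + (ys - y)^2) >= min2) {
          xs <- c(xs, x); ys <- c(ys, y)
        }
      }
    }
    supp <- seq_along(config$oligomer_fractions)
    n <- if (ne > 0) sample(supp, ne, replace = TRUE,
                            prob = config$oligomer_fractions) else integer(0)
    k <- if (ne > 0) stats::rbinom(ne, size = n, prob = config$labeling_p)
         else integer(0)
    mobile <- if (ne > 0) stats::runif(ne) < config$mobile_fraction
              else logical(0)
    emitters <- data.frame(
      emitter_id = seq_len(ne),
      x_nm = xs, y_nm = ys,
      n = as.integer(n), k = as.integer(k),
      mobility = ifelse(mobile, "mobile", "immobile"),
      diffusion_um2s = ifelse(mobile, config$diffusion_um2s, 0),
      stringsAsFactors = FALSE
    )
    structure(list(emitters = emitters,
                   field_size_nm = c(L, L),
                   labeling_p = config$labeling_p,
                   config = config),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d emitters on %.1f x %.1f um, labeling p = %.2f\n",
              nrow(x$emitters), x$field_size_nm[1] / 1000,
              x$field_size_nm[2] / 1000, x$labeling_p))
  if (nrow(x$emitters) > 0) {
    tb <- table(x$emitters$n)
    cat("  oligomer orders:", paste(sprintf("n=%s:%d", names(tb), tb),
                                    collapse = ", "), "\n")
    cat(sprintf("  dark (k = 0): %d | mobile: %d\n",
                sum(x$emitters$k == 0),
                sum(x$emitters$mobility == "mobile")))
  }
  invisible(x)
}

# integrated-Gaussian PSF contribution of one emitter to a pixel window.
# Pixel (i, j) (1-based row/col) spans [(j-1)*px, j*px) x [(i-1)*px, i*px) nm;
# the Gaussian is integrated over pixel areas, not centre-sampled.
psf_window <- function(x_nm, y_nm, sigma_nm, px_nm, nr, nc, halfwidth_px) {
  jc <- floor(x_nm / px_nm) + 1
  ic <- floor(y_nm / px_nm) + 1
  js <- max(1, jc - halfwidth_px):min(nc, jc + halfwidth_px)
  is <- max(1, ic - halfwidth_px):min(nr, ic + halfwidth_px)
  # fraction of photons falling in each column/row strip
  fx <- stats::pnorm((js * px_nm - x_nm) / sigma_nm) -
        stats::pnorm(((js - 1) * px_nm - x_nm) / sigma_nm)
  fy <- stats::pnorm((is * px_nm - y_nm) / sigma_nm) -
        stats::pnorm(((is - 1) * px_nm - y_nm) / sigma_nm)
  list(rows = is, cols = js, weights = outer(fy, fx))
}

#' Render a synthetic TIRF movie with an EMCCD noise model
#'
#' Forward model of single-molecule TIRF imaging. Each labeled subunit emits a
#' fixed (per-movie) photoelectron rate drawn from a log-normal law with mean
#' \code{photons_per_fluorophore} and coefficient of variation
#' \code{brightness_cv}; an emitter with k labeled subunits contributes the
#' sum of its k rates, spread over pixels as a 2D Gaussian PSF integrated over
#' pixel areas. Per pixel and frame, photoelectrons are Poisson distributed,
#' electron multiplication follows the standard Gamma approximation
#' (shape = photoelectrons, scale = EM gain), and Gaussian read noise plus the
#' camera baseline are added before rounding to 16-bit counts. Mobile emitters
#' perform isotropic Brownian steps of per-axis variance 2 D dt each frame,
#' reflected at the field boundaries.
#'
#' @param scene a \code{\link{generate_scene}} result.
#' @param camera a \code{\link{camera_model}}; default \code{\link{camera_slb}}.
#' @param psf_sigma_nm PSF standard deviation in nm.
#' @param photons_per_fluorophore mean detected photoelectrons per labeled
#'   subunit per frame.
#' @param n_frames number of frames to render.
#' @param seed integer seed; same seed and inputs give a bit-identical movie.
#' @param exposure_ms exposure time per frame (the Brownian time step).
#' @param brightness_cv log-normal coefficient of variation of per-fluorophore
#'   brightness (0 disables the variability).
#' @param bg_photons_per_px uniform optical background (residual membrane /
#'   buffer autofluorescence), photoelectrons per pixel per frame.
#' @param noise if \code{FALSE}, render the noiseless expected counts
#'   (baseline + mean signal), still rounded to integer counts.
#' @return An object of class \code{frame_stack}: list with \code{frames}
#'   (integer array, dim = rows x cols x frames), \code{camera},
#'   \code{exposure_ms}, \code{psf_sigma_nm} and \code{ground_truth}
#'   (data.frame: emitter_id, frame, x_nm, y_nm, n, k, mobility; immobile
#'   emitters are listed once at frame 1, mobile emitters once per frame).
#' @export
render_movie <- function(scene, camera = camera_slb(), psf_sigma_nm = 150,
                         photons_per_fluorophore = 300, n_frames = 1500,
                         seed = 1L, exposure_ms = 30, brightness_cv = 0.25,
                         bg_photons_per_px = 2, noise = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(camera, "camera_model"),
            psf_sigma_nm > 0, photons_per_fluorophore > 0, n_frames >= 1,
            brightness_cv >= 0, bg_photons_per_px >= 0)
  px <- camera$pixel_size_nm
  nr <- floor(scene$field_size_nm[2] / px)
  nc <- floor(scene$field_size_nm[1] / px)
  if (min(nr, nc) * px < 6 * psf_sigma_nm)
    stop("field too small for the PSF support (need >= 6 sigma per side)")
  hw <- as.integer(ceiling(4 * psf_sigma_nm / px))
  g <- gain_counts_per_pe(camera)
  em <- scene$emitters
  lit <- em[em$k > 0, , drop = FALSE]

  withr::with_seed(seed, {
    # one fixed emission rate per labeled fluorophore, summed per emitter
    rates <- numeric(nrow(lit))
    if (nrow(lit) > 0) {
      if (brightness_cv > 0) {
        sdlog <- sqrt(log(1 + brightness_cv^2))
        mulog <- log(photons_per_fluorophore) - sdlog^2 / 2
        rates <- vapply(lit$k, function(k)
          sum(stats::rlnorm(k, mulog, sdlog)), numeric(1))
      } else {
        rates <- lit$k * photons_per_fluorophore
      }
    }

    mob <- lit$mobility == "mobile"
    # static emitters: expected photoelectron image computed once
    lambda_static <- matrix(bg_photons_per_px, nr, nc)
    for (e in which(!mob)) {
      w <- psf_window(lit$x_nm[e], lit$y_nm[e], psf_sigma_nm, px, nr, nc, hw)
      lambda_static[w$rows, w$cols] <- lambda_static[w$rows, w$cols] +
        rates[e] * w$weights
    }
    # Brownian paths for mobile emitters, reflected into [0, L)
    paths <- NULL
    if (any(mob)) {
      step_sd <- sqrt(2 * lit$diffusion_um2s[mob] * exposure_ms / 1000) * 1000
      nm_ <- sum(mob)
      paths <- list(x = matrix(0, n_frames, nm_), y = matrix(0, n_frames, nm_))
      paths$x[1, ] <- lit$x_nm[mob]; paths$y[1, ] <- lit$y_nm[mob]
      if (n_frames > 1) {
        for (f in 2:n_frames) {
          paths$x[f, ] <- reflect01(paths$x[f - 1, ] +
                                      stats::rnorm(nm_, 0, step_sd),
                                    scene$field_size_nm[1])
          paths$y[f, ] <- reflect01(paths$y[f - 1, ] +
                                      stats::rnorm(nm_, 0, step_sd),
                                    scene$field_size_nm[2])
        }
      }
    }

    frames <- array(0L, dim = c(nr, nc, n_frames))
    npx <- nr * nc
    for (f in seq_len(n_frames)) {
      lambda <- lambda_static
      if (any(mob)) {
        for (m in seq_len(sum(mob))) {
          w <- psf_window(paths$x[f, m], paths$y[f, m],
                          psf_sigma_nm, px, nr, nc, hw)
          lambda[w$rows, w$cols] <- lambda[w$rows, w$cols] +
            rates[mob][m] * w$weights
        }
      }
      if (noise) {
        counts <- camera$offset + stats::rnorm(npx, 0, camera$read_noise_sd)
        idx <- which(lambda > 1e-12)
        if (length(idx) > 0) {
          ne <- stats::rpois(length(idx), lambda[idx])
          pos <- ne > 0
          amp <- numeric(length(idx))
          amp[pos] <- stats::rgamma(sum(pos), shape = ne[pos], scale = g)
          counts[idx] <- counts[idx] + amp
        }
      } else {
        counts <- camera$offset + lambda * g
      }
      frames[, , f] <- as.integer(pmin.int(pmax.int(round(counts), 0), 65535L))
    }

    gt_static <- lit[!mob, , drop = FALSE]
    gt <- data.frame(emitter_id = gt_static$emitter_id,
                     frame = rep(1L, nrow(gt_static)),
                     x_nm = gt_static$x_nm, y_nm = gt_static$y_nm,
                     n = gt_static$n, k = gt_static$k,
                     mobility = gt_static$mobility, stringsAsFactors = FALSE)
    if (any(mob)) {
      idm <- lit$emitter_id[mob]
      gt_mob <- data.frame(
        emitter_id = rep(idm, each = n_frames),
        frame = rep(seq_len(n_frames), times = sum(mob)),
        x_nm = as.vector(paths$x), y_nm = as.vector(paths$y),
        n = rep(lit$n[mob], each = n_frames),
        k = rep(lit$k[mob], each = n_frames),
        mobility = "mobile", stringsAsFactors = FALSE)
      gt <- rbind(gt, gt_mob)
    }

    structure(list(frames = frames, camera = camera,
                   exposure_ms = exposure_ms, psf_sigma_nm = psf_sigma_nm,
                   photons_per_fluorophore = photons_per_fluorophore,
                   ground_truth = gt),
              class = "frame_stack")
  })
}

reflect01 <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%g nm/px), %g ms exposure\n",
              d[3], d[1], d[2], x$camera$pixel_size_nm, x$exposure_ms))
  invisible(x)
}

#' Extract one frame from a stack
#' @param stack a \code{frame_stack}.
#' @param frame frame index (1-based).
#' @return numeric matrix of counts.
#' @export
get_frame <- function(stack, frame) {
  stopifnot(inherits(stack, "frame_stack"),
            frame >= 1, frame <= dim(stack$frames)[3])
  matrix(as.numeric(stack$frames[, , frame]), dim(stack$frames)[1])
}

#' Pixelwise mean image of a stack
#'
#' Time-averaging suppresses shot and read noise by 1/sqrt(frames) and is the
#' photometry substrate for immobile particles.
#'
#' @param stack a \code{frame_stack}.
#' @param frames optional subset of frame indices.
#' @return numeric matrix of mean counts.
#' @export
average_frames <- function(stack, frames = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(frames)) frames <- seq_len(dim(stack$frames)[3])
  out <- matrix(0, dim(stack$frames)[1], dim(stack$frames)[2])
  for (f in frames) out <- out + stack$frames[, , f]
  out / length(frames)
}

#' Write / read a movie as a 16-bit multi-page TIFF
#'
#' Counts are stored losslessly as unsigned 16-bit samples. Camera metadata is
#' not embedded in the file; keep it in the pipeline configuration.
#'
#' @param stack a \code{frame_stack}.
#' @param path output TIFF path.
#' @return \code{write_movie}: the path, invisibly. \code{read_movie}: a
#'   \code{frame_stack} (with the supplied camera and exposure metadata).
#' @export
write_movie <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(f)
    matrix(stack$frames[, , f] / 65535, dim(stack$frames)[1]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_movie
#' @param camera,exposure_ms metadata to attach to the stack read back.
#' @export
read_movie <- function(path, camera = camera_slb(), exposure_ms = 30) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- as.integer(pages[[f]])
  structure(list(frames = frames, camera = camera, exposure_ms = exposure_ms,
                 psf_sigma_nm = NA_real_, photons_per_fluorophore = NA_real_,
                 ground_truth = NULL),
            class = "frame_stack")
}

#' Write the ground-truth emitter table to CSV
#'
#' Columns: emitter_id, frame, x_nm, y_nm, n, k, mobility. Immobile emitters
#' are written once (frame 1); pass \code{expand = TRUE} to repeat them for
#' every frame.
#'
#' @param stack a \code{frame_stack} produced by \code{\link{render_movie}}.
#' @param path output CSV path.
#' @param expand repeat immobile emitters for every frame.
#' @export
write_ground_truth <- function(stack, path, expand = FALSE) {
  stopifnot(inherits(stack, "frame_stack"), !is.null(stack$ground_truth))
  gt <- stack$ground_truth
  if (expand) {
    nf <- dim(stack$frames)[3]
    im <- gt[gt$mobility == "immobile", , drop = FALSE]
    if (nrow(im) > 0) {
      im_exp <- im[rep(seq_len(nrow(im)), each = nf), ]
      im_exp$frame <- rep(seq_len(nf), times = nrow(im))
      gt <- rbind(im_exp, gt[gt$mobility == "mobile", , drop = FALSE])
      gt <- gt[order(gt$emitter_id, gt$frame), ]
    }
  }
  utils::write.csv(gt, path, row.names = FALSE)
  invisible(path)
}
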