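#' Calibrate the single-fluorophore brightness
#'
#' Fits the calibration brightness sample (e.g. surface-immobilized monomeric
#' fluorophore) with a Gaussian mixture and returns the mean and standard
#' deviation of the dominant lowest-mean mode, which is robust against a
#' minority of pre-formed dimers or aggregates in the calibration sample.
#'
#' @param brightness numeric vector of calibration brightness values
#'   (photoelectrons or photons, consistent with the analysis sample).
#' @param min_particles minimum sample size (default 50).
#' @param max_components maximum number of mixture components considered.
#' @param min_weight smallest mixing proportion for a component to qualify as
#'   the monomer mode.
#' @return An object of class \code{monomer_calibration}: list with
#'   \code{mu1}, \code{sigma1}, \code{n_particles}.
#' @export
calibrate_monomer <- function(brightness, min_particles = 50,
                              max_components = 4, min_weight = 0.1) {
  brightness <- brightness[is.finite(brightness)]
  if (length(brightness) < min_particles)
    stop(sprintf("need at least %d calibration particles, got %d",
                 min_particles, length(brightness)))
  if (stats::sd(brightness) <= .Machine$double.eps * abs(mean(brightness)))
    stop("degenerate calibration sample: zero variance")
  fit <- mclust::Mclust(brightness, G = 1:max_components,
                        modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("no resolvable monomer mode in the calibration sample")
  w <- fit$parameters$pro
  mu <- fit$parameters$mean
  sd_ <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd_) == 1) sd_ <- rep(sd_, length(mu))
  eligible <- which(w >= min_weight)
  if (length(eligible) == 0) stop("no resolvable monomer mode in the calibration sample")
  j <- eligible[which.min(mu[eligible])]
  # components within 2.5 sd of the selected one describe the same (possibly
  # skewed) mode, not a distinct oligomeric species: merge their moments
  grp <- which(abs(mu - mu[j]) < 2.5 * sd_[j])
  wg <- w[grp] / sum(w[grp])
  m1 <- sum(wg * mu[grp])
  v1 <- sum(wg * (sd_[grp]^2 + mu[grp]^2)) - m1^2
  if (m1 <= 0) stop("monomer mode has nonpositive mean")
  structure(list(mu1 = m1, sigma1 = sqrt(v1),
                 n_particles = length(brightness)),
            class = "monomer_calibration")
}

#' @export
print.monomer_calibration <- function(x, ...) {
  cat(sprintf("<monomer_calibration> mu1 = %.1f, sigma1 = %.1f (n = %d)\n",
              x$mu1, x$sigma1, x$n_particles))
  invisible(x)
}

#' Kernel probability density of spot brightnesses
#'
#' Gaussian-kernel density estimate on a uniform grid from 0 to
#' max(brightness) + 3 bandwidths, renormalized to unit trapezoidal integral.
#'
#' @param brightness numeric vector (>= 2 values).
#' @param bandwidth kernel bandwidth in brightness units, or \code{"auto"} for
#'   Silverman's rule of thumb.
#' @param n_grid number of grid points.
#' @return An object of class \code{brightness_pdf}: list with \code{grid},
#'   \code{density}, \code{bandwidth}, \code{n_particles}.
#' @export
build_pdf <- function(brightness, bandwidth = "auto", n_grid = 1024) {
  brightness <- brightness[is.finite(brightness)]
  if (length(brightness) < 2)
    stop("need at least 2 brightness values to build a density")
  h <- if (identical(bandwidth, "auto")) {
    bw <- tryCatch(stats::bw.nrd0(brightness), error = function(e) NA_real_)
    if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(brightness), 1e-8,
                                             0.01 * abs(mean(brightness)))
    bw
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  d <- stats::density(brightness, bw = h, from = 0,
                      to = max(brightness) + 3 * h, n = n_grid)
  area <- pracma::trapz(d$x, d$y)
  structure(list(grid = d$x, density = d$y / area, bandwidth = h,
                 n_particles = length(brightness)),
            class = "brightness_pdf")
}

#' @export
print.brightness_pdf <- function(x, ...) {
  cat(sprintf("<brightness_pdf> n = %d, bandwidth = %.3g, grid [0, %.3g]\n",
              x$n_particles, x$bandwidth, max(x$grid)))
  invisible(x)
}

#' Decompose a brightness density into calibrated Gaussian components
#'
#' Models the brightness density as a nonnegative linear combination of
#' unit-area Gaussians whose means are fixed at n * mu1 and whose standard
#' deviations are sqrt(n) * sigma1 (independent fluorophores), for
#' n = 1..max_n. Because the fit target is a kernel density estimate, i.e.
#' the data distribution convolved with a Gaussian kernel of bandwidth h, the
#' components are by default broadened to sqrt(n * sigma1^2 + h^2)
#' (\code{kernel_broadening}). Weights are found by nonnegative least squares
#' on the density grid and renormalized to sum to 1; since each component has
#' unit area, the weight of species n is its occurrence fraction.
#'
#' @param pdf a \code{\link{build_pdf}} result.
#' @param cal a \code{\link{calibrate_monomer}} result (or list with
#'   \code{mu1}, \code{sigma1}).
#' @param max_n largest oligomer order considered (<= 30).
#' @param kernel_broadening add the KDE bandwidth to the component widths.
#' @param sd_model \code{"sqrt_n"} (independent-fluorophore variance addition,
#'   default) or \code{"linear"} (sd proportional to n).
#' @param min_fraction weights below this are reported as exactly 0 (and the
#'   rest renormalized).
#' @return list with \code{fractions} (named numeric, n = 1..max_n, sums to
#'   1), \code{residual} (root-mean-square misfit on the grid),
#'   \code{fitted} (fitted density on the grid), \code{components}
#'   (grid x max_n matrix of weighted component densities).
#' @export
fit_mixture <- function(pdf, cal, max_n = 30, kernel_broadening = TRUE,
                        sd_model = c("sqrt_n", "linear"),
                        min_fraction = 1e-3) {
  stopifnot(inherits(pdf, "brightness_pdf"), max_n >= 1, max_n <= 30,
            cal$mu1 > 0, cal$sigma1 > 0)
  sd_model <- match.arg(sd_model)
  ns <- seq_len(max_n)
  sds <- switch(sd_model,
                sqrt_n = sqrt(ns) * cal$sigma1,
                linear = ns * cal$sigma1)
  if (kernel_broadening) sds <- sqrt(sds^2 + pdf$bandwidth^2)
  G <- vapply(ns, function(n) stats::dnorm(pdf$grid, n * cal$mu1, sds[n]),
              numeric(length(pdf$grid)))
  sol <- pracma::lsqnonneg(G, pdf$density)
  w <- sol$x
  if (sum(w) <= 0) stop("ill-conditioned mixture fit: all weights zero")
  frac <- w / sum(w)
  frac[frac < min_fraction] <- 0
  if (sum(frac) == 0) stop("ill-conditioned mixture fit: all weights zero")
  frac <- frac / sum(frac)
  fitted <- as.vector(G %*% w)
  names(frac) <- ns
  list(fractions = frac,
       residual = sqrt(mean((fitted - pdf$density)^2)),
       fitted = fitted,
       components = sweep(G, 2, w, `*`))
}

# binomial mixing matrix M[k, n] = P(k labeled | n subunits), k, n = 1..max_n
labeling_matrix <- function(p, max_n) {
  stopifnot(p > 0, p <= 1, max_n >= 1)
  outer(seq_len(max_n), seq_len(max_n),
        function(k, n) stats::dbinom(k, size = n, prob = p))
}

#' Observed label-count distribution under partial labeling
#'
#' Given true oligomer-order fractions f(n) and a per-subunit labeling
#' probability p, returns the distribution of the number k of labeled subunits
#' among detectable particles (k >= 1):
#' P(k) = sum_n f(n) C(n, k) p^k (1-p)^(n-k), renormalized over k >= 1.
#' This is the forward model inverted by \code{\link{correct_labeling}}.
#'
#' @param true_fractions numeric vector of fractions indexed by n = 1..length;
#'   must be nonnegative and sum to 1 (tolerance 1e-6).
#' @param p labeling probability in (0, 1].
#' @param max_n length of the returned k-distribution (default: length of
#'   \code{true_fractions}).
#' @return named numeric vector over k = 1..max_n summing to 1.
#' @export
forward_labeling <- function(true_fractions, p, max_n = length(true_fractions)) {
  if (!(p > 0 && p <= 1)) stop("labeling probability must be in (0, 1]")
  stopifnot(all(true_fractions >= 0),
            abs(sum(true_fractions) - 1) < 1e-6,
            max_n >= length(true_fractions))
  f <- c(true_fractions, rep(0, max_n - length(true_fractions)))
  M <- labeling_matrix(p, max_n)
  obs <- as.vector(M %*% f)
  detectable <- sum(obs)            # = 1 - sum_n f(n) (1-p)^n
  if (detectable <= 0) stop("no detectable particles under this labeling probability")
  out <- obs / detectable
  names(out) <- seq_len(max_n)
  out
}

#' Correct observed label-count fractions for partial labeling
#'
#' Inverts the binomial mixing of \code{\link{forward_labeling}}: finds the
#' nonnegative true oligomer-order fractions f(n), summing to 1, whose
#' predicted label-count distribution best matches the observed one
#' (nonnegative least squares, then renormalization). With exact input the
#' round trip forward-then-invert is exact to machine precision; with noisy
#' input the nearest nonnegative solution is returned together with its
#' residual, and a warning is raised when the misfit is substantial.
#'
#' @param observed_fractions numeric vector over k = 1..length: fraction of
#'   detected particles carrying k labeled subunits (sums to 1).
#' @param p labeling probability in (0, 1].
#' @param max_n largest oligomer order allowed in the solution (default:
#'   length of \code{observed_fractions}).
#' @param residual_warn warn when the relative forward-model misfit of the
#'   solution exceeds this.
#' @return named numeric vector over n = 1..max_n summing to 1, with attribute
#'   \code{residual} (L2 misfit between the observed fractions and the forward
#'   model of the solution).
#' @export
correct_labeling <- function(observed_fractions, p,
                             max_n = length(observed_fractions),
                             residual_warn = 0.05) {
  if (!(p > 0 && p <= 1)) stop("labeling probability must be in (0, 1]")
  stopifnot(all(observed_fractions >= 0),
            abs(sum(observed_fractions) - 1) < 1e-6,
            max_n >= length(observed_fractions))
  o <- c(observed_fractions, rep(0, max_n - length(observed_fractions)))
  if (p == 1) {
    out <- o / sum(o)
    names(out) <- seq_len(max_n)
    attr(out, "residual") <- 0
    return(out)
  }
  M <- labeling_matrix(p, max_n)
  # the unnormalized solution of M f = o is f_true / (1 - dark fraction);
  # renormalizing recovers the true fractions
  sol <- pracma::lsqnonneg(M, o)
  f <- sol$x
  if (sum(f) <= 0) stop("labeling correction infeasible: all-zero solution")
  f <- f / sum(f)
  res <- sqrt(sum((forward_labeling(f, p, max_n) - o)^2))
  if (res > residual_warn)
    warning(sprintf("labeling correction misfit %.3g: observed fractions are not fully consistent with the binomial model", res))
  names(f) <- seq_len(max_n)
  attr(f, "residual") <- res
  f
}

#' Particle density
#'
#' Number of accepted particles per unit membrane area, optionally corrected
#' for a sample dilution factor (diluted samples underestimate the density of
#' the undiluted preparation by exactly that factor).
#'
#' @param n_particles accepted particle count (>= 0).
#' @param area_um2 field-of-view or cell-mask area in square micrometres (> 0).
#' @param dilution_factor multiplicative correction (default 1).
#' @return particles per square micrometre.
#' @export
particle_density <- function(n_particles, area_um2, dilution_factor = 1) {
  stopifnot(n_particles >= 0, dilution_factor > 0)
  if (!is.numeric(area_um2) || length(area_um2) != 1 || area_um2 <= 0)
    stop("`area_um2` must be a single positive number")
  n_particles / area_um2 * dilution_factor
}

#' Full stoichiometry inference from spot brightnesses
#'
#' Builds the kernel density of the brightness sample, decomposes it into
#' calibrated Gaussian components (\code{\link{fit_mixture}}), interprets the
#' component fractions as the distribution of visible labeled subunits k, and
#' inverts the binomial partial-labeling model (\code{\link{correct_labeling}})
#' to obtain the true oligomer-order fractions.
#'
#' @param brightness numeric vector of accepted spot brightnesses.
#' @param cal a \code{\link{monomer_calibration}}.
#' @param labeling_p fluorophore labeling efficiency in (0, 1] (default 0.7).
#' @param max_n largest oligomer order (default 30).
#' @param bandwidth KDE bandwidth, or \code{"auto"}.
#' @param ... passed to \code{\link{fit_mixture}}.
#' @return An object of class \code{stoich_result}: list with
#'   \code{observed_fractions} (by label count k), \code{corrected_fractions}
#'   (by oligomer order n), \code{labeling_p}, \code{max_n}, \code{residual}
#'   (mixture-fit rms misfit), \code{correction_residual},
#'   \code{n_particles}, \code{pdf}, \code{mixture}, \code{calibration}.
#' @export
stoichiometry <- function(brightness, cal, labeling_p = 0.7, max_n = 30,
                          bandwidth = "auto", ...) {
  stopifnot(inherits(cal, "monomer_calibration") ||
              (is.list(cal) && !is.null(cal$mu1) && !is.null(cal$sigma1)))
  pdf <- build_pdf(brightness, bandwidth = bandwidth)
  mix <- fit_mixture(pdf, cal, max_n = max_n, ...)
  corrected <- correct_labeling(mix$fractions, p = labeling_p, max_n = max_n)
  structure(list(
    observed_fractions = mix$fractions,
    corrected_fractions = corrected,
    labeling_p = labeling_p, max_n = max_n,
    residual = mix$residual,
    correction_residual = attr(corrected, "residual"),
    n_particles = length(brightness),
    pdf = pdf, mixture = mix, calibration = cal
  ), class = "stoich_result")
}

#' @export
print.stoich_result <- function(x, digits = 3, ...) {
  cat(sprintf("<stoich_result> n = %d particles, labeling p = %.2f\n",
              x$n_particles, x$labeling_p))
  nz <- which(x$corrected_fractions > 0)
  cat("  corrected occurrence (%):",
      paste(sprintf("n=%s: %.1f", names(x$corrected_fractions)[nz],
                    100 * x$corrected_fractions[nz]), collapse = ", "), "\n")
  cat(sprintf("  mixture rms misfit: %.3g\n", x$residual))
  invisible(x)
}
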