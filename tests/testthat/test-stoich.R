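test_that("monomer calibration recovers the single-fluorophore brightness", {
  set.seed(1)
  b <- stats::rnorm(5000, 1000, 150)
  cal <- calibrate_monomer(b)
  expect_lt(abs(cal$mu1 - 1000) / 1000, 0.02)
  expect_lt(abs(cal$sigma1 - 150) / 150, 0.05)
  expect_equal(cal$n_particles, 5000)
})

test_that("calibration tracks the lower mode of a contaminated sample", {
  set.seed(2)
  b <- c(stats::rnorm(4000, 1000, 150), stats::rnorm(1000, 2000, 212))
  cal <- calibrate_monomer(b)
  expect_lt(abs(cal$mu1 - 1000) / 1000, 0.03)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(calibrate_monomer(rep(5, 100)), "zero variance")
  expect_error(calibrate_monomer(stats::rnorm(10)), "at least")
})

test_that("the brightness density integrates to one on its grid", {
  set.seed(3)
  for (b in list(stats::rnorm(500, 800, 100), stats::rexp(300, 1 / 500))) {
    pdf <- build_pdf(b)
    expect_lt(abs(pracma::trapz(pdf$grid, pdf$density) - 1), 1e-3)
    expect_true(all(pdf$density >= 0))
  }
  expect_error(build_pdf(numeric(0)))
  expect_error(build_pdf(5))
  # two identical values: a single peak at that value
  pdf2 <- build_pdf(c(400, 400))
  expect_lt(abs(pdf2$grid[which.max(pdf2$density)] - 400),
            diff(pdf2$grid[1:2]) * 2)
})

test_that("the KDE is consistent with the generating density", {
  set.seed(4)
  x <- stats::rnorm(2e4, 10, 1)  # shifted so the [0, max] grid covers it
  pdf <- build_pdf(x)
  expect_lt(max(abs(pdf$density - stats::dnorm(pdf$grid, 10, 1))), 0.02)
})

test_that("the calibrated mixture fit resolves known compositions", {
  cal <- fixed_calibration(mu1 = 600, sigma1 = 150)
  set.seed(5)
  # pure monomer
  b1 <- stats::rnorm(2000, 600, 150)
  f1 <- fit_mixture(build_pdf(b1), cal, max_n = 10)$fractions
  expect_gte(f1[["1"]], 0.95)
  # 50/50 dimer/trimer at the minimum per-experiment particle count
  k <- sample(2:3, 1500, replace = TRUE)
  b23 <- stats::rnorm(1500, k * 600, sqrt(k) * 150)
  f23 <- fit_mixture(build_pdf(b23), cal, max_n = 10)$fractions
  expect_lt(abs(f23[["2"]] - 0.5), 0.05)
  expect_lt(abs(f23[["3"]] - 0.5), 0.05)
  expect_lte(f23[["1"]], 0.05)
  # no mass below 1.5 mu1: monomer fraction ~ 0
  expect_lte(f23[["1"]], 0.02)
  # fractions sum to one, never negative
  expect_equal(sum(f23), 1, tolerance = 1e-9)
  expect_true(all(f23 >= 0))
})

test_that("mixture weights are invariant to a common brightness rescaling", {
  cal <- fixed_calibration(mu1 = 600, sigma1 = 150)
  set.seed(6)
  k <- sample(1:3, 2000, replace = TRUE)
  b <- stats::rnorm(2000, k * 600, sqrt(k) * 150)
  f <- fit_mixture(build_pdf(b), cal, max_n = 8)$fractions
  scl <- 3.7
  cal2 <- fixed_calibration(mu1 = 600 * scl, sigma1 = 150 * scl)
  f2 <- fit_mixture(build_pdf(b * scl), cal2, max_n = 8)$fractions
  expect_equal(unname(f), unname(f2), tolerance = 1e-6)
})

test_that("forward labeling reproduces the binomial enumeration", {
  # identity cases
  f <- c(0.2, 0.5, 0.3)
  expect_equal(unname(forward_labeling(f, 1)), f)
  expect_equal(unname(forward_labeling(c(1, 0, 0), 0.37)), c(1, 0, 0))
  # pure trimers at p = 0.7: enumeration oracle
  oracle <- stats::dbinom(1:3, 3, 0.7) / (1 - stats::dbinom(0, 3, 0.7))
  expect_equal(unname(forward_labeling(c(0, 0, 1), 0.7)), oracle,
               tolerance = 1e-12)
  expect_error(forward_labeling(f, 1.2), "probability")
  expect_error(forward_labeling(f, 0))
})

test_that("labeling correction inverts the forward model", {
  expect_equal(unname(correct_labeling(c(0.2, 0.5, 0.3), 1))[1:3],
               c(0.2, 0.5, 0.3))
  o <- forward_labeling(c(0, 0, 1), 0.7)
  f <- correct_labeling(o, 0.7)
  expect_gte(f[["3"]], 0.98)
  # round trip over random true distributions, n <= 6
  set.seed(7)
  for (i in 1:20) {
    x <- stats::runif(6); x <- x / sum(x)
    err <- max(abs(correct_labeling(forward_labeling(x, 0.7), 0.7) - x))
    expect_lt(err, 1e-6)
  }
  # inconsistent observations come back with a warning and a residual:
  # all mass at k = 6 under p = 0.3 cannot arise from any n-mixture, since
  # every column of the binomial matrix with mass at k = 6 also puts most
  # of its mass at k < 6
  expect_warning(correct_labeling(c(0, 0, 0, 0, 0, 1), 0.3), "misfit")
})

test_that("uncorrected fractions are biased toward lower oligomer orders", {
  # mean observed label count E[K | K >= 1] = p E[N] / (1 - dark) <= E[N],
  # with equality only for pure monomers; and once the dark (k = 0) class
  # is restored, the observed distribution stochastically dominates the
  # true one downward at every order (K <= N pathwise)
  set.seed(8)
  for (i in 1:10) {
    x <- stats::runif(5); x <- x / sum(x)
    o <- forward_labeling(x, 0.7)
    expect_lte(sum(seq_along(o) * o), sum(seq_along(x) * x) + 1e-12)
    dark <- sum(x * 0.3^seq_along(x))
    o_full <- c(dark, o * (1 - dark))
    expect_true(all(cumsum(o_full)[1:5] >= cumsum(c(0, x))[1:5] - 1e-12))
  }
})

test_that("particle density normalizes counts by area and dilution", {
  expect_equal(particle_density(0, 100), 0)
  expect_equal(particle_density(500, 50 * 50), 0.2)
  expect_equal(particle_density(500, 2500, dilution_factor = 10), 2)
  expect_error(particle_density(10, 0), "positive")
  expect_error(particle_density(10, -5), "positive")
})

test_that("the full stoichiometry wrapper corrects partial labeling", {
  cal <- fixed_calibration(mu1 = 600, sigma1 = 150)
  set.seed(9)
  # dimers and trimers observed through p = 0.7 labeling
  n_true <- sample(2:3, 4000, replace = TRUE)
  k <- stats::rbinom(4000, n_true, 0.7)
  k <- k[k > 0]
  b <- stats::rnorm(length(k), k * 600, sqrt(k) * 150)
  res <- stoichiometry(b, cal, labeling_p = 0.7, max_n = 10)
  expect_s3_class(res, "stoich_result")
  expect_equal(sum(res$observed_fractions), 1, tolerance = 1e-6)
  expect_equal(sum(res$corrected_fractions), 1, tolerance = 1e-6)
  expect_lt(abs(res$corrected_fractions[["2"]] - 0.5), 0.07)
  expect_lt(abs(res$corrected_fractions[["3"]] - 0.5), 0.07)
  expect_lte(res$corrected_fractions[["1"]], 0.05)
})
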