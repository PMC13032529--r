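make_spec <- function(y, nu = toy_axis(length(y))) spectrum(nu, y)

test_that("truncation keeps exactly the enumerated grid points, inclusive bounds", {
  nu <- default_axis("HTSFTIR")
  sp <- spectrum(nu, seq_along(nu))
  full <- truncate_regions(sp, list(range(nu)))
  expect_equal(full$intensity, sp$intensity)
  regs <- list(c(3200, 2600), c(2000, 600))
  tr <- truncate_regions(sp, regs)
  brute <- sum((nu >= 2600 & nu <= 3200) | (nu >= 600 & nu <= 2000))
  expect_equal(length(tr$wavenumber), brute)
  expect_true(all(tr$wavenumber %in% nu))
  expect_error(truncate_regions(sp, list(c(10, 20))), "empty")
  expect_error(truncate_regions(sp, list(c(600, 2000), c(1900, 3000))), "overlap")
})

test_that("Savitzky-Golay is exact on quadratics and matches the per-point LS oracle", {
  n <- 60
  y <- (seq_len(n))^2
  d2 <- savgol(make_spec(y), window = 15, polyorder = 2, deriv = 2)
  expect_equal(d2$intensity, rep(2, n), tolerance = 1e-9)
  expect_equal(d2$derivative_order, 2L)
  sm <- savgol(make_spec(y), window = 5, polyorder = 2, deriv = 0)
  expect_equal(sm$intensity, y, tolerance = 1e-9)
  set.seed(11)
  yr <- stats::rnorm(50)
  for (cfg in list(c(15, 2, 2), c(11, 3, 1), c(9, 4, 0))) {
    got <- savgol(make_spec(yr), cfg[1], cfg[2], cfg[3])$intensity
    expect_equal(got, sg_oracle(yr, cfg[1], cfg[2], cfg[3]), tolerance = 1e-10)
  }
  expect_error(savgol(spectrum(c(1, 2, 4, 8, 16, 32), stats::rnorm(6)), 5, 2, 2),
               "uniform")
})

test_that("second derivative is negative at a raw band maximum", {
  nu <- toy_axis(200, 1000, 1400)
  y <- lineshape(nu, 1200, 20)
  d2 <- savgol(spectrum(nu, y), 15, 2, 2)
  expect_lt(d2$intensity[which.max(y)], 0)
})

test_that("rubberband baseline equals the lower convex hull and is shift invariant", {
  set.seed(21)
  nu <- toy_axis(12)
  y <- stats::rnorm(12)
  sp <- spectrum(nu, y)
  res <- rubberband_baseline(sp, return_baseline = TRUE)
  verts <- hull_oracle(nu, y)
  expect_equal(res$baseline$intensity[verts], y[verts], tolerance = 1e-12)
  hull_interp <- stats::approx(nu[verts], y[verts], xout = nu)$y
  expect_equal(res$baseline$intensity, hull_interp, tolerance = 1e-12)
  expect_true(all(res$corrected$intensity >= -1e-12))
  # straight line corrects to zero; adding any affine function changes nothing
  line <- spectrum(nu, 3 - 0.01 * nu)
  expect_equal(rubberband_baseline(line)$intensity, rep(0, 12), tolerance = 1e-12)
  nu2 <- toy_axis(80)
  y2 <- lineshape(nu2, 1400, 40) + lineshape(nu2, 1650, 30)
  c1 <- rubberband_baseline(spectrum(nu2, y2))$intensity
  c2 <- rubberband_baseline(spectrum(nu2, y2 + 5 + 0.02 * nu2))$intensity
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("linear baseline zeroes the endpoints and recovers a peak on a tilted line", {
  nu <- toy_axis(101)
  peak <- lineshape(nu, 1400, 30)
  tilted <- spectrum(nu, peak + 2 + 0.005 * nu)
  corr <- linear_baseline(tilted)
  # the pure peak is itself nonzero at the endpoints; compare to its own
  # two-point-detrended version
  w <- (nu - nu[1]) / (nu[101] - nu[1])
  peak_detrended <- peak - (peak[1] * (1 - w) + peak[101] * w)
  expect_equal(corr$intensity, peak_detrended, tolerance = 1e-12)
  expect_equal(corr$intensity[c(1, 101)], c(0, 0))
  expect_equal(linear_baseline(spectrum(nu, 7 - 0.3 * nu))$intensity,
               rep(0, 101), tolerance = 1e-9)
})

test_that("iterative polynomial baseline removes polynomial backgrounds, preserves peaks", {
  nu <- toy_axis(300)
  bg <- 2 + 0.003 * (nu - 1400) + 2e-6 * (nu - 1400)^2
  expect_equal(polynomial_baseline(spectrum(nu, bg), 2)$intensity,
               rep(0, 300), tolerance = 1e-8)
  expect_equal(polynomial_baseline(spectrum(nu, rep(4, 300)), 0)$intensity,
               rep(0, 300), tolerance = 1e-12)
  peak <- lineshape(nu, 1500, 14, shape = "gaussian")
  corr <- polynomial_baseline(spectrum(nu, peak + bg), 2)
  a_true <- sum(diff(nu) * (peak[-1] + peak[-300]) / 2)
  keep <- abs(nu - 1500) < 40
  a_got <- sum(diff(nu[keep]) * (corr$intensity[keep][-1] +
                                 corr$intensity[keep][-sum(keep)]) / 2)
  expect_lt(abs(a_got - a_true) / a_true, 0.05)
})

test_that("MSC recovers affine distortions and matches the normal-equations oracle", {
  nu <- toy_axis(120)
  ref <- lineshape(nu, 1300, 40) + lineshape(nu, 1650, 25)
  Y <- rbind(ref, 2 * ref + 3, 0.5 * ref - 1)
  ds <- spectral_dataset(nu, Y)
  out <- msc(ds, reference = ref)
  cf <- attr(out, "msc_coefficients")
  expect_equal(cf$a, c(0, 3, -1), tolerance = 1e-10)
  expect_equal(cf$b, c(1, 2, 0.5), tolerance = 1e-10)
  for (i in 1:3) expect_equal(out$intensity[i, ], ref, tolerance = 1e-9)
  set.seed(5)
  yrand <- stats::rnorm(120)
  cf2 <- attr(msc(spectral_dataset(nu, rbind(yrand)), reference = ref),
              "msc_coefficients")
  oracle <- msc_oracle(yrand, ref)
  expect_equal(unname(unlist(cf2)), unname(oracle), tolerance = 1e-10)
})

test_that("EMSC separates multiplicative and polynomial effects", {
  nu <- toy_axis(150)
  ref <- lineshape(nu, 1300, 40) + 0.7 * lineshape(nu, 1600, 25)
  xs <- 2 * (nu - min(nu)) / (max(nu) - min(nu)) - 1
  y <- 1.5 * ref + 0.3 * xs^2
  out <- emsc(spectral_dataset(nu, rbind(ref, y)), reference = ref,
              poly_degree = 2)
  expect_equal(out$intensity[1, ], ref, tolerance = 1e-9)
  expect_equal(out$intensity[2, ], ref, tolerance = 1e-9)
  cf <- attr(out, "emsc_coefficients")
  expect_equal(cf$b, c(1, 1.5), tolerance = 1e-9)
  expect_equal(unlist(cf[1, -1]), c(c0 = 0, c1 = 0, c2 = 0), tolerance = 1e-9)
  # coefficients equal the generic least-squares solution on the explicit
  # design matrix
  set.seed(9)
  yr <- stats::rnorm(150)
  cf2 <- attr(emsc(spectral_dataset(nu, rbind(yr)), reference = ref,
                   poly_degree = 3), "emsc_coefficients")
  D <- cbind(ref, outer(xs, 0:3, "^"))
  ls <- drop(qr.solve(D, yr))
  expect_equal(unname(unlist(cf2)), unname(ls), tolerance = 1e-10)
  # EMSC restores the reference up to noise for generated spectra
  set.seed(10)
  Y <- t(replicate(8, stats::runif(1, 0.5, 2) * ref + 0.2 * stats::rnorm(1) +
                      0.3 * stats::rnorm(1) * xs + 0.01 * stats::rnorm(150)))
  rec <- emsc(spectral_dataset(nu, Y), reference = ref, poly_degree = 2)
  rmse <- sqrt(rowMeans((rec$intensity - matrix(ref, 8, 150, byrow = TRUE))^2))
  expect_true(all(rmse <= 2 * 0.01))
})

test_that("normalisations are scale invariant with the stated divisors", {
  nu <- toy_axis(100)
  y <- lineshape(nu, 1300, 30) + 0.2
  for (fn in list(vector_normalize, area_normalize)) {
    a <- fn(spectrum(nu, y))$intensity
    b <- fn(spectrum(nu, 7.3 * y))$intensity
    expect_equal(a, b, tolerance = 1e-12)
  }
  expect_equal(sqrt(sum(vector_normalize(spectrum(nu, y))$intensity^2)), 1,
               tolerance = 1e-12)
  # unit-height triangle spanning the amide I region: analytic area 35
  nut <- seq(1560, 1710, 1)
  tri <- pmax(0, 1 - abs(nut - 1635) / 35)
  got <- band_area_normalize(spectrum(nut, tri), region = c(1600, 1670))
  expect_equal(got$intensity, tri / 35, tolerance = 1e-10)
  expect_error(vector_normalize(spectrum(nu, rep(0, 100))), "zero")
})

test_that("cosmic ray removal deletes spikes and leaves smooth spectra untouched", {
  nu <- toy_axis(400, 400, 1800)
  smooth <- lineshape(nu, 800, 20) + 0.5 * lineshape(nu, 1400, 16)
  # a smooth flat spectrum is returned verbatim
  flat <- 1 + 0.0005 * nu
  expect_equal(cosmic_ray_remove(spectrum(nu, flat))$intensity, flat)
  # a smooth banded spectrum at typical noise: no point is modified
  set.seed(31)
  noisy <- smooth + stats::rnorm(400, 0, 0.001)
  expect_equal(cosmic_ray_remove(spectrum(nu, noisy))$intensity, noisy)
  spiked <- noisy
  spiked[150] <- spiked[150] + 50 * 0.001 * 50
  out <- cosmic_ray_remove(spectrum(nu, spiked))
  expect_lt(abs(out$intensity[150] - noisy[150]), 3 * 0.001 + 0.002)
  spiked2 <- noisy
  spiked2[200:201] <- spiked2[200:201] + c(2, 1.5)
  out2 <- cosmic_ray_remove(spectrum(nu, spiked2))
  expect_lt(max(abs(out2$intensity[200:201] - noisy[200:201])), 0.01)
})

test_that("packaged recipes apply the printed steps in order", {
  des <- default_design(media = c("nGlu", "iGlu"), timepoints = c(24, 120),
                        replicates = 2)
  sim <- simulate_design_dataset(des, seed = 5)
  br <- apply_recipe(sim$HTSFTIR, "htsftir_bandratio")
  expect_equal(br$derivative_order, 2L)
  expect_true(all(br$wavenumber >= 800 & br$wavenumber <= 1800))
  expect_identical(attr(br, "recipe"), "htsftir_bandratio")
  mva <- apply_recipe(sim$FTRaman, "ftraman_mva")
  expect_equal(unname(sqrt(rowSums(mva$intensity^2))),
               rep(1, n_spectra(mva)), tolerance = 1e-9)
  expect_true(all(mva$wavenumber >= 400 & mva$wavenumber <= 1800))
  # truncated-to-two-regions recipe keeps both windows
  m2 <- apply_recipe(sim$HTSFTIR, "htsftir_mva")
  expect_true(any(m2$wavenumber > 2600) && any(m2$wavenumber < 2000))
  expect_false(any(m2$wavenumber > 2000 & m2$wavenumber < 2600))
  # a second application is rejected on derivative state
  expect_error(apply_recipe(br, "htsftir_bandratio"), "derivative")
  expect_error(apply_recipe(sim$HTSFTIR, "noSuchRecipe"), "unknown recipe")
})

test_that("recipes serialize to a text config and back", {
  rec <- packaged_recipes()$ftraman_plsr
  path <- tempfile(fileext = ".yml")
  write_recipe(rec, path)
  back <- read_recipe(path)
  expect_equal(back$name, rec$name)
  expect_equal(length(back$steps), length(rec$steps))
  expect_equal(back$steps[[4]]$poly_degree, 3)
  sim <- simulate_design_dataset(default_design(media = "nGlu",
                                                timepoints = c(24),
                                                replicates = 1,
                                                modalities = "FTRaman"),
                                 seed = 2)
  expect_equal(apply_recipe(sim$FTRaman, back)$intensity,
               apply_recipe(sim$FTRaman, rec)$intensity)
})
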