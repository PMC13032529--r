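# small truncated infrared axis keeps cubes light
img_axis <- function() {
  nu <- default_axis("FTIRMicro")
  nu[nu >= 900 & nu <= 1900]
}

test_that("scene masks nest correctly and images have one spectrum per pixel", {
  sc <- make_scene(shape = c(64, 64), seed = 2)
  expect_true(validate_scene(sc))
  expect_true(all(sc$lipid_body_mask | !sc$lipid_body_mask))
  expect_false(any(sc$lipid_body_mask & !sc$hyphae_mask))
  expect_false(any(sc$polyp_granule_mask & !sc$hyphae_mask))
  img <- simulate_hyperspectral_image(sc, "FTIRMicro", seed = 3,
                                      axis = img_axis())
  expect_equal(dim(img$cube)[1:2], c(64L, 64L))
  expect_equal(dim(img$cube)[3], length(img_axis()))
  # all-background scene: biomass signal is zero before noise
  bg <- sc; bg$hyphae_mask[] <- FALSE; bg$lipid_body_mask[] <- FALSE
  bg$polyp_granule_mask[] <- FALSE
  bimg <- simulate_hyperspectral_image(bg, "FTIRMicro", noise_sd = 0,
                                       baseline_rel = 0, seed = 3,
                                       axis = img_axis())
  expect_equal(max(abs(bimg$cube)), 0)
  # lipid-body pixels outshine background at the ester C=O wavenumber
  nimg <- simulate_hyperspectral_image(sc, "FTIRMicro", noise_sd = 0,
                                       baseline_rel = 0, seed = 3,
                                       axis = img_axis())
  amap <- absorbance_map(nimg, 1745)
  if (any(sc$lipid_body_mask)) {
    expect_gt(min(amap[sc$lipid_body_mask]), max(amap[!sc$hyphae_mask]))
  }
})

test_that("pixel quality control removes background and keeps biomass", {
  sc <- make_scene(shape = c(64, 64), seed = 5)
  img <- simulate_hyperspectral_image(sc, "FTIRMicro", seed = 5,
                                      axis = img_axis())
  vm <- remove_empty_pixels(img)
  bg_truth <- !sc$hyphae_mask
  sens <- mean(!vm[bg_truth])          # background removed
  loss <- mean(!vm[sc$hyphae_mask])    # biomass wrongly removed
  expect_gte(sens, 0.95)
  expect_lte(loss, 0.05)
  # zero image: everything invalid
  z <- img; z$cube[] <- 0
  expect_false(any(remove_empty_pixels(z)))
  # uniform noise-free biomass: nothing removed
  u <- img
  u$cube <- array(rep(1, prod(dim(img$cube))), dim(img$cube))
  expect_true(all(remove_empty_pixels(u)))
})

test_that("binning follows the published block layout and conserves mass", {
  g <- block_grid(c(128, 128), 10)
  widths <- table((g$row1 - g$row0 + 1)[!duplicated(g$row0)])
  expect_equal(as.integer(widths[c("10", "8")]), c(12L, 1L))
  # fully valid 128 x 128 image -> 13 x 13 = 169 blocks
  nu <- img_axis()[1:3]
  ones <- structure(list(cube = array(1, c(128, 128, 3)), wavenumber = nu,
                         valid_mask = matrix(TRUE, 128, 128), pixel_size = 2.7,
                         modality = "FTIRMicro", truth = NULL),
                    class = "hyper_image")
  binned <- bin_image(ones)
  expect_equal(n_spectra(binned), 169)
  # block of identical pixels reproduces the pixel spectrum
  expect_equal(unname(binned$intensity[1, ]), rep(1, 3))
  # blocks with fewer than 5 valid pixels are dropped
  vm <- matrix(FALSE, 128, 128); vm[1:2, 1:2] <- TRUE   # 4 pixels in block 1
  vm[1:5, 11:15] <- TRUE                                 # 25 in block 2
  few <- ones; few$valid_mask <- vm
  b2 <- bin_image(few)
  expect_equal(n_spectra(b2), 1)
  expect_equal(b2$meta$n_pixels, 25)
  # mass conservation: count-weighted block mean equals valid-pixel mean
  sc <- make_scene(shape = c(64, 64), seed = 6)
  img <- simulate_hyperspectral_image(sc, "FTIRMicro", seed = 6,
                                      axis = img_axis())
  img$valid_mask <- remove_empty_pixels(img)
  bb <- bin_image(img, min_pixels = 1)
  wmean <- colSums(bb$intensity * bb$meta$n_pixels) / sum(bb$meta$n_pixels)
  pmean <- colMeans(cube_matrix(img, valid_only = TRUE))
  expect_equal(unname(wmean), unname(pmean), tolerance = 1e-10)
})

test_that("NNLS basis fitting matches the subset-enumeration oracle", {
  set.seed(61)
  nwn <- 12
  for (rep in 1:30) {
    B <- matrix(stats::rexp(nwn * 3), nwn, 3)
    y <- stats::rnorm(nwn)
    x_pkg <- drop(isoflux:::nnls_batch(B, matrix(y, ncol = 1)))
    x_orc <- nnls_oracle(B, y)
    expect_equal(drop(x_pkg), x_orc, tolerance = 1e-8)
  }
})

test_that("basis analysis recovers exact mixtures and spatial truth", {
  nu <- img_axis()
  b1 <- component_spectrum("TAG", nu, 0, "FTIRMicro")$intensity
  b2 <- component_spectrum("protein", nu, 0, "FTIRMicro")$intensity
  b3 <- component_spectrum("polyphosphate", nu, 0, "FTIRMicro")$intensity
  bs <- basis_set(rbind(b1, b2, b3), c("TAG", "protein", "polyP"),
                  wavenumber = nu)
  mini <- structure(list(
    cube = array(t(cbind(b2, 0.3 * b1 + 0.7 * b2, b3)), c(1, 3, length(nu))),
    wavenumber = nu, valid_mask = matrix(TRUE, 1, 3), pixel_size = 2.7,
    modality = "FTIRMicro", truth = NULL), class = "hyper_image")
  fit <- basis_fit(mini, bs)
  expect_equal(fit$factors[1, 1, ], c(0, 1, 0), tolerance = 1e-9)
  expect_lt(fit$residual_norm[1, 1], 1e-9)
  expect_equal(fit$factors[1, 2, ], c(0.3, 0.7, 0), tolerance = 1e-9)
  expect_equal(fit$factors[1, 3, ], c(0, 0, 1), tolerance = 1e-9)
  # component maps track the generating masks (AUC vs truth)
  sc <- make_scene(shape = c(64, 64), seed = 7)
  img <- simulate_hyperspectral_image(sc, "FTIRMicro", seed = 7, axis = nu)
  hyph <- clean_region_spectrum(sc, "hyphae", nu)
  lip <- clean_region_spectrum(sc, "lipid_body", nu)
  pol <- clean_region_spectrum(sc, "polyp_granule", nu)
  bs2 <- basis_set(rbind(hyph, lip, pol), c("hyphae", "lipid", "polyp"),
                   wavenumber = nu)
  fit2 <- basis_fit(img, bs2)
  lipid_truth <- as.vector(sc$lipid_body_mask)
  auc <- auc_score(as.vector(fit2$factors[, , 2]), lipid_truth)
  expect_gte(auc, 0.9)
})

test_that("k-means basis derivation finds the pure components", {
  nu <- img_axis()
  # two spatially separated pure components: hyphae vs lipid bodies
  sc <- make_scene(shape = c(48, 48), n_lipid_bodies = 8, n_granules = 0,
                   seed = 8)
  img <- simulate_hyperspectral_image(sc, "FTIRMicro", seed = 8, axis = nu,
                                      baseline_rel = 0)
  img$valid_mask <- sc$hyphae_mask  # biomass pixels only
  bs <- derive_basis(img, k = 2, seed = 9)
  # identical seed, identical basis
  bs_again <- derive_basis(img, k = 2, seed = 9)
  expect_identical(bs$spectra, bs_again$spectra)
  cosd <- function(a, b) 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  lip <- clean_region_spectrum(sc, "lipid_body", nu)
  hyp <- clean_region_spectrum(sc, "hyphae", nu)
  d_lip <- min(apply(bs$spectra, 1, cosd, b = lip))
  d_hyp <- min(apply(bs$spectra, 1, cosd, b = hyp))
  expect_lt(d_lip, 0.02)
  expect_lt(d_hyp, 0.02)
  # manual basis takes the pixel spectra verbatim
  mb <- derive_basis(img, k = 2, method = "manual",
                     coords = rbind(c(1, 1), c(2, 2)))
  expect_equal(mb$spectra[1, ], img$cube[1, 1, ])
})

test_that("absorbance maps localise lipid bodies; zero cubes map to zero", {
  nu <- img_axis()
  sc <- make_scene(shape = c(64, 64), seed = 10)
  img <- simulate_hyperspectral_image(sc, "FTIRMicro", seed = 10, axis = nu)
  amap <- absorbance_map(img, 1745)
  hyph_only <- sc$hyphae_mask & !sc$lipid_body_mask
  expect_gt(mean(amap[sc$lipid_body_mask]), mean(amap[hyph_only]))
  z <- img; z$cube[] <- 0
  expect_equal(max(abs(absorbance_map(z, 1745))), 0)
  expect_error(absorbance_map(img, 5000), "outside")
})

test_that("a common PCA space overlaps early scenes and separates late isotope scenes", {
  nu <- img_axis()
  imgs <- list()
  conds <- list(list(m = "nGlu", t = 8), list(m = "iGlu", t = 8),
                list(m = "nGlu", t = 120), list(m = "iGlu", t = 120))
  for (i in seq_along(conds)) {
    sc <- make_scene(shape = c(48, 48), medium = conds[[i]]$m,
                     t_hours = conds[[i]]$t, seed = 20 + i)
    img <- simulate_hyperspectral_image(sc, "FTIRMicro", seed = 20 + i,
                                        axis = nu)
    img$valid_mask <- remove_empty_pixels(img)
    imgs[[i]] <- apply_recipe(bin_image(img), "ftirmicro_mva")
  }
  union <- do.call(rbind, lapply(imgs, function(b) b$intensity))
  grp <- rep(seq_along(imgs), vapply(imgs, n_spectra, integer(1)))
  m <- pca_fit(union, 3)
  centd <- function(a, b) {
    ca <- colMeans(m$scores[grp == a, , drop = FALSE])
    cb <- colMeans(m$scores[grp == b, , drop = FALSE])
    sqrt(sum((ca - cb)^2)) /
      mean(c(stats::sd(m$scores[grp == a, 1]), stats::sd(m$scores[grp == b, 1])))
  }
  expect_gt(centd(3, 4), 2 * centd(1, 2))
})
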