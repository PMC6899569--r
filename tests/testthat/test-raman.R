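bands_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], center = r[[2]], area = r[[3]],
               width = r[[4]], eta = r[[5]])))
}

test_that("generator reproduces a pure polynomial baseline exactly", {
  spec <- raman_phantom_spec(
    bands = bands_df(list("phe", 1004, 0, 7, 0.3)),
    baseline_coef = c(2, -1, 0.5), noise_sd = 0, n_spectra = 1, seed = 1)
  ds <- generate_raman_dataset(spec)
  x <- ds$spectra[[1]]$wavenumber
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)
  expect_equal(ds$spectra[[1]]$intensity, 2 - u + 0.5 * u^2)
})

test_that("a generated band integrates to its specified area", {
  spec <- raman_phantom_spec(
    bands = bands_df(list("g", 1100, 12, 8, 0)), # pure Gaussian
    noise_sd = 0, n_spectra = 1, seed = 2)
  ds <- generate_raman_dataset(spec)
  s <- ds$spectra[[1]]
  expect_equal(trapz(s$wavenumber, s$intensity), 12, tolerance = 0.01)
})

test_that("generation is reproducible and truth folds are by construction", {
  mk <- function(area, seed) raman_phantom_spec(
    bands = bands_df(list("ACP", 950, area, 6, 0.3)),
    noise_sd = 0.01, n_spectra = 5, area_cv = 0, seed = seed)
  a <- generate_raman_dataset(mk(4, 5))
  b <- generate_raman_dataset(mk(4, 5))
  expect_identical(a$spectra[[3]]$intensity, b$spectra[[3]]$intensity)
  hi <- generate_raman_dataset(mk(8, 6))
  expect_equal(mean(hi$truth$area) / mean(a$truth$area), 2)
})

test_that("preprocessing flattens a pure 9th-order polynomial", {
  x <- seq(600, 1750, by = 1)
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)
  y <- 3 + 2 * u - u^2 + 0.5 * u^3 + 0.2 * u^9
  sp <- raman_preprocess(raman_spectrum(x, y), despike = FALSE,
                         denoise = FALSE)
  expect_lt(max(abs(sp$intensity)), 0.01 * max(abs(y)))
  expect_true(sp$baseline_corrected)
})

test_that("band heights survive baseline, noise and denoising within 5%", {
  spec <- raman_phantom_spec(
    bands = bands_df(list("b1", 950, 40, 8, 0), list("b2", 1450, 60, 12, 0),
                     list("phe", 1004, 30, 7, 0)),
    baseline_coef = c(5, 1.5, -0.8), noise_sd = 0.05, # 1% of tallest peak
    n_spectra = 6, seed = 7)
  ds <- generate_raman_dataset(spec)
  for (i in 1:6) {
    sp <- raman_preprocess(ds$spectra[[i]])
    x <- sp$wavenumber
    for (b in 1:2) {
      ctr <- c(950, 1450)[b]
      h_true <- pv_height(ds$truth$area[ds$truth$spectrum == i][b],
                          c(8, 12)[b], 0)
      h_rec <- max(sp$intensity[abs(x - ctr) <= 3])
      expect_lt(abs(h_rec - h_true) / h_true, 0.05)
    }
  }
})

test_that("a cosmic spike is removed without disturbing its neighbours", {
  spec <- raman_phantom_spec(
    bands = bands_df(list("b1", 1100, 40, 10, 0.2)),
    noise_sd = 0.02, spike_count = 0, n_spectra = 1, seed = 9)
  ds <- generate_raman_dataset(spec)
  clean <- ds$spectra[[1]]
  spiked <- clean
  k <- 400
  spiked$intensity[k] <- spiked$intensity[k] + 50 * 0.02
  a <- raman_preprocess(clean, denoise = FALSE)
  b <- raman_preprocess(spiked, denoise = FALSE)
  expect_lt(abs(b$intensity[k] - a$intensity[k]), 6 * 0.02)
  nb <- c(k - 3, k - 2, k + 2, k + 3)
  expect_lt(max(abs(b$intensity[nb] - a$intensity[nb])), 3 * 0.02)
})

test_that("normalisation pins the 1004 peak to one and is scale-free", {
  spec <- raman_phantom_spec(
    bands = bands_df(list("phe", 1004, 30, 7, 0.3),
                     list("CAP", 961, 20, 5, 0.3)),
    noise_sd = 0, n_spectra = 1, seed = 11)
  ds <- generate_raman_dataset(spec)
  sp <- ds$spectra[[1]]
  sp$baseline_corrected <- TRUE
  n1 <- raman_normalize(sp)
  w <- n1$wavenumber >= 999 & n1$wavenumber <= 1009
  expect_equal(max(n1$intensity[w]), 1)
  doubled <- sp
  doubled$intensity <- doubled$intensity * 2
  n2 <- raman_normalize(doubled)
  expect_equal(n1$intensity, n2$intensity)
  zero <- sp; zero$intensity <- -abs(zero$intensity)
  expect_error(raman_normalize(zero), "non-positive")
})

test_that("doubling phenylalanine halves every normalised band area", {
  mk <- function(phe_area) raman_phantom_spec(
    bands = bands_df(list("phe", 1004, phe_area, 7, 0.3),
                     list("CAP", 961, 20, 5, 0.3)),
    noise_sd = 0, n_spectra = 1, seed = 13)
  fit_area <- function(spec) {
    ds <- generate_raman_dataset(spec)
    sp <- raman_normalize(raman_preprocess(ds$spectra[[1]],
                                           despike = FALSE, denoise = FALSE))
    deconvolve_phosphate(sp)$species_areas[["CAP"]]
  }
  expect_equal(fit_area(mk(60)) / fit_area(mk(30)), 0.5, tolerance = 0.02)
})

test_that("deconvolution of a zero spectrum returns zero areas", {
  x <- seq(600, 1750, by = 1)
  sp <- raman_spectrum(x, rep(0, length(x)))
  sp$baseline_corrected <- TRUE; sp$normalized <- TRUE
  fit <- deconvolve_phosphate(sp)
  expect_equal(unname(fit$species_areas), c(0, 0, 0))
  expect_error(mineral_matrix_ratio(fit), "amide I")
})

test_that("overlapping sub-bands with 1:3 areas are resolved within 5%", {
  spec <- raman_phantom_spec(
    bands = bands_df(list("ACP", 950, 5, 6, 0), list("CAP", 959.5, 15, 6, 0),
                     list("phe", 1004, 30, 7, 0)),
    noise_sd = 0, n_spectra = 1, seed = 15)
  ds <- generate_raman_dataset(spec)
  sp <- raman_normalize(raman_preprocess(ds$spectra[[1]], despike = FALSE,
                                         denoise = FALSE))
  cfg <- phosphate_band_config(phosphate_centers = c(ACP = 950, OCP = 955,
                                                     CAP = 959.5))
  fit <- deconvolve_phosphate(sp, cfg)
  phe_h <- pv_height(30, 7, 0)
  expect_equal(fit$species_areas[["ACP"]], 5 / phe_h, tolerance = 0.05)
  expect_equal(fit$species_areas[["CAP"]], 15 / phe_h, tolerance = 0.05)
  expect_equal(fit$species_areas[["CAP"]] / fit$species_areas[["ACP"]], 3,
               tolerance = 0.05)
})

test_that("fitted envelope area conserves the integrated envelope", {
  groups <- load_raman_fixture("raman_female")
  ds <- generate_raman_dataset(groups$wt)
  sp <- raman_normalize(raman_preprocess(ds$spectra[[1]]))
  fit <- deconvolve_phosphate(sp)
  w <- sp$wavenumber >= 935 & sp$wavenumber <= 985
  direct <- trapz(sp$wavenumber[w], pmax(sp$intensity[w], 0))
  expect_equal(fit$phosphate_envelope_area, direct, tolerance = 0.10)
})

test_that("preprocessing an already-processed spectrum is a near-no-op", {
  groups <- load_raman_fixture("raman_male")
  ds <- generate_raman_dataset(groups$wt)
  p1 <- raman_preprocess(ds$spectra[[1]])
  p2 <- raman_preprocess(p1)
  scale <- diff(range(p1$intensity))
  expect_lt(max(abs(p2$intensity - p1$intensity)) / scale, 0.01)
})

test_that("mineral-to-matrix ratio reflects the phosphate/amide-I balance", {
  spec <- raman_phantom_spec(
    bands = bands_df(list("CAP", 961, 40, 5, 0.3),
                     list("phe", 1004, 30, 7, 0.3),
                     list("amide_I", 1660, 20, 26, 0.4)),
    noise_sd = 0, n_spectra = 1, seed = 17)
  ds <- generate_raman_dataset(spec)
  sp <- raman_normalize(raman_preprocess(ds$spectra[[1]], despike = FALSE,
                                         denoise = FALSE))
  fit <- deconvolve_phosphate(sp)
  expect_equal(mineral_matrix_ratio(fit), 2, tolerance = 0.05)
})

test_that("signed fold change follows the reciprocal convention", {
  expect_equal(signed_fold_change(1, 1), 1)
  expect_equal(signed_fold_change(3, 2), 1.5)
  expect_equal(signed_fold_change(2, 3), -1.5)
  expect_error(signed_fold_change(0, 1), "positive")
  set.seed(19)
  a <- runif(200, 0.1, 10); b <- runif(200, 0.1, 10)
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a))
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
})
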