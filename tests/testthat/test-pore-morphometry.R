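make_porosity <- function(voxels, h = 1) binary_mask(voxels, h, "porosity")

test_that("an empty mask yields an empty catalog, not an error", {
  catalog <- label_pores(make_porosity(array(FALSE, c(6, 6, 6))))
  expect_equal(nrow(catalog$pores), 0)
  expect_error(select_separation_threshold(catalog), "empty")
})

test_that("disjoint spheres are labeled with voxel-count volumes and diameters", {
  d <- c(40, 24, 24)
  s1 <- ball_mask(d, c(10, 12, 12), 3)
  s2 <- ball_mask(d, c(28, 12, 12), 5)
  catalog <- label_pores(make_porosity(s1 | s2))
  expect_equal(nrow(catalog$pores), 2)
  expect_setequal(catalog$pores$n_voxels, c(sum(s1), sum(s2)))
  expect_equal(catalog$pores$diameter_um,
               (6 * catalog$pores$volume_um3 / pi)^(1 / 3))
})

test_that("corner-sharing voxels form one pore under 26-connectivity", {
  m <- array(FALSE, c(5, 5, 5))
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE
  catalog <- label_pores(make_porosity(m))
  expect_equal(nrow(catalog$pores), 1)
  expect_equal(catalog$pores$n_voxels, 2L)
})

test_that("elongation and extent separate tubes from blobs", {
  d <- c(30, 30, 60)
  tube <- array(FALSE, d)
  tube[14:16, 14:16, 5:54] <- TRUE   # 50 um long, ~3 um wide
  blob <- ball_mask(d, c(7, 7, 10), 4)
  catalog <- label_pores(make_porosity(tube | blob))
  p <- catalog$pores[order(catalog$pores$volume_um3), ]
  expect_lt(p$elongation[1], 1.3)    # blob
  expect_gt(p$elongation[2], 3)      # tube
  expect_gt(p$extent_um[2], 45)
})

test_that("separation threshold sits 1% below the smallest canal candidate", {
  # catalog built directly: two tubes (2000, 2600 um^3) and blobs < 1500
  catalog <- structure(list(
    pores = data.frame(
      id = 1:5,
      n_voxels = c(2000L, 2600L, 900L, 1200L, 400L),
      volume_um3 = c(2000, 2600, 900, 1200, 400),
      diameter_um = 1, elongation = c(8, 9, 1.5, 1.8, 1.2),
      extent_um = c(60, 70, 12, 14, 9),
      centroid_x_um = 0, centroid_y_um = 0, centroid_z_um = 0,
      class = NA_character_),
    cortical_solid_volume_um3 = 1e6, voxel_size_um = 1,
    separation_threshold_um3 = NA_real_, noise_floor_um3 = NA_real_),
    class = "pore_catalog")
  expect_equal(select_separation_threshold(catalog), 0.99 * 2000)
  # no elongated pores: threshold is +Inf and no pore is a canal
  round_only <- catalog
  round_only$pores$elongation <- 1.4
  expect_identical(select_separation_threshold(round_only), Inf)
  cls <- classify_pores(round_only, Inf, noise_floor_um3 = 8)
  expect_false(any(cls$pores$class == "canal"))
})

test_that("classification boundaries are inclusive and validated", {
  catalog <- structure(list(
    pores = data.frame(
      id = 1:3, n_voxels = c(5L, 500L, 2000L),
      volume_um3 = c(5, 500, 2000), diameter_um = 1,
      elongation = 1.5, extent_um = 10,
      centroid_x_um = 0, centroid_y_um = 0, centroid_z_um = 0,
      class = NA_character_),
    cortical_solid_volume_um3 = 1e6, voxel_size_um = 1,
    separation_threshold_um3 = NA_real_, noise_floor_um3 = NA_real_),
    class = "pore_catalog")
  cls <- classify_pores(catalog, threshold_um3 = 2000, noise_floor_um3 = 8)
  expect_equal(cls$pores$class, c("noise", "lacuna", "canal"))
  expect_error(classify_pores(catalog, threshold_um3 = 5,
                              noise_floor_um3 = 8), "exceed")
})

test_that("summary indices use the documented unit conversions", {
  # 10 lacunae in a 1e6 um^3 cortex: Lc.Dn = 1e4 per mm^3
  catalog <- structure(list(
    pores = data.frame(
      id = 1:10, n_voxels = 300L, volume_um3 = 300, diameter_um = 8.3,
      elongation = 1.5, extent_um = 9,
      centroid_x_um = 0, centroid_y_um = 0, centroid_z_um = 0,
      class = "lacuna"),
    cortical_solid_volume_um3 = 1e6, voxel_size_um = 1,
    separation_threshold_um3 = Inf, noise_floor_um3 = 8),
    class = "pore_catalog")
  s <- summarize_pores(catalog)
  expect_equal(s$Lc.Dn_mm3, 1e4)
  expect_equal(s$lacunar_pct, 100)
  expect_equal(s$Ca.Dn_mm3, 0)
  expect_true(is.na(s$Ca.V_um3)) # empty class mean is missing, not 0
  expect_equal(s$lacunar_pct + s$canal_pct + s$noise_pct, 100,
               tolerance = 1e-4)
})

test_that("raising the threshold weakly decreases canal count and fraction", {
  ph <- generate_cortex_volume(small_cortex_spec(seed = 41))
  bone <- binarize(ph$volume, 80)
  out <- extract_cortical_porosity(bone, 8)
  catalog <- label_pores(out$porosity, out$cortex_solid)
  thr0 <- select_separation_threshold(catalog)
  prev_n <- Inf; prev_frac <- Inf
  for (thr in c(thr0, thr0 * 2, thr0 * 8)) {
    cls <- classify_pores(catalog, thr)
    s <- summarize_pores(cls)
    n_can <- sum(cls$pores$class == "canal")
    expect_lte(n_can, prev_n)
    expect_lte(s$canal_pct, prev_frac + 1e-12)
    prev_n <- n_can; prev_frac <- s$canal_pct
  }
})

test_that("full pipeline classification matches generator ground truth", {
  ph <- generate_cortex_volume(small_cortex_spec(seed = 43))
  bone <- binarize(ph$volume, 80)
  out <- extract_cortical_porosity(bone, 8)
  catalog <- label_pores(out$porosity, out$cortex_solid)
  thr <- select_separation_threshold(catalog)
  cls <- classify_pores(catalog, thr)
  expect_equal(sum(cls$pores$class == "canal"),
               sum(ph$truth$pores$class == "canal"))
  s <- summarize_pores(cls)
  expect_equal(s$lacunar_pct, ph$truth$lacunar_pct, tolerance = 1e-6)
  expect_equal(s$canal_pct, ph$truth$canal_pct, tolerance = 1e-6)
})

test_that("halving the voxel size changes mean lacunar volume by < 5%", {
  base <- list(outer_radius_um = 36, inner_radius_um = 16,
               length_slices = 40,
               lacunae = list(count = 15, meanlog = log(250), sdlog = 0.3,
                              min_volume_um3 = 80, max_volume_um3 = 1200),
               seed = 77)
  run <- function(h) {
    spec <- cortex_phantom_spec(
      outer_radius_um = base$outer_radius_um,
      inner_radius_um = base$inner_radius_um,
      length_slices = as.integer(base$length_slices / h),
      voxel_size_um = h, lacunae = base$lacunae,
      padding_vox = as.integer(10 / h), seed = base$seed)
    ph <- generate_cortex_volume(spec)
    bone <- binarize(ph$volume, 80)
    out <- extract_cortical_porosity(bone, as.integer(8 / h))
    catalog <- label_pores(out$porosity, out$cortex_solid)
    cls <- classify_pores(catalog, Inf)
    summarize_pores(cls)$Lc.V_um3
  }
  v1 <- run(1); v05 <- run(0.5)
  expect_lt(abs(v05 - v1) / v1, 0.05)
})
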