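# Second moments of area of one binary cross-section.
# Adds the per-pixel self-moment (p^2/12 per axis) so coarse rasterisations
# stay consistent with the continuum limit.
section_moments <- function(mask2d, pixel_size_um) {
  idx <- which(mask2d, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(NULL)
  p <- pixel_size_um
  A_px <- p^2
  x <- idx[, 1] * p; y <- idx[, 2] * p
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  Ixx <- sum(dy^2) * A_px + n * A_px * p^2 / 12
  Iyy <- sum(dx^2) * A_px + n * A_px * p^2 / 12
  Ixy <- -sum(dx * dy) * A_px
  M <- matrix(c(Ixx, Ixy, Ixy, Iyy), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  i_max <- ev$values[1]; i_min <- ev$values[2]
  # principal-axis angle of the moment-equivalent ellipse (major axis)
  v <- ev$vectors[, 2]
  theta <- atan2(v[2], v[1]) %% pi
  list(csa = n * A_px, centroid = c(cx, cy), i_min = i_min, i_max = i_max,
       j = i_min + i_max, ellipticity = sqrt(i_max / i_min),
       theta_deg = theta * 180 / pi)
}

# Mean cortical thickness of one section: twice the distance-transform
# value averaged over ridge pixels (local maxima of the distance map), the
# medial-axis approximation of local half-thickness. The half-voxel offset
# converts centre-to-centre distances to boundary distances.
ct_thickness_2d <- function(mask2d, pixel_size_um) {
  if (!any(mask2d)) return(NA_real_)
  d <- dim(mask2d)
  m3 <- array(!mask2d, dim = c(d, 1L))
  edt <- sqrt(array(.edt_squared_cpp(as.vector(m3), dim(m3)), dim = d))
  pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- edt
  ridge <- matrix(TRUE, d[1], d[2])
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(d[1] + 1) + di, 2:(d[2] + 1) + dj]
    ridge <- ridge & (edt >= nb)
  }
  ridge <- ridge & mask2d & edt > 0
  if (!any(ridge)) return(NA_real_)
  (2 * mean(edt[ridge]) - 1) * pixel_size_um
}

#' Cross-sectional geometry profile along the bone axis
#'
#' For each requested axial position (% of bone length, measured over the
#' slices that contain bone): cross-sectional area, principal second
#' moments of area I_min and I_max about the section centroid, polar moment
#' J = I_min + I_max, mean cortical thickness (medial-axis distance), and
#' ellipticity `sqrt(I_max/I_min)` — the axis ratio of the
#' moment-equivalent ellipse. If a calibrated grayscale volume is supplied,
#' mean BMD over the bone pixels of each section is added.
#'
#' @param bone A [binary_mask] labelled `"bone"`; the bone axis is the
#'   third array dimension.
#' @param positions Axial positions as percentages of bone length.
#' @param volume Optional [volume_image] aligned with `bone`, for BMD.
#' @param calibration Optional [density_calibration], required with
#'   `volume`.
#' @return A data frame (class `cross_section_profile`) with one row per
#'   position: `position_pct`, `slice`, `csa_um2`, `i_min_um4`,
#'   `i_max_um4`, `j_um4`, `ct_th_um`, `ellipticity`, `theta_deg`, and
#'   `bmd_mgHA_cm3` when calibrated. Positions with an empty slice are
#'   reported as `NA`.
#' @export
cross_section_profile <- function(bone, positions = seq(10, 90, by = 10),
                                  volume = NULL, calibration = NULL) {
  stopifnot(inherits(bone, "binary_mask"))
  if (!is.null(volume) && is.null(calibration))
    stop("supply `calibration` together with `volume`")
  h <- bone$voxel_size_um
  has_bone <- apply(bone$voxels, 3, any)
  if (!any(has_bone)) stop("bone mask is empty")
  z0 <- which(has_bone)[1]; z1 <- tail(which(has_bone), 1)
  rows <- lapply(positions, function(pct) {
    k <- as.integer(round(z0 + pct / 100 * (z1 - z0)))
    k <- min(max(k, 1L), dim(bone$voxels)[3])
    m <- bone$voxels[, , k]
    sm <- section_moments(m, h)
    if (is.null(sm))
      return(data.frame(position_pct = pct, slice = k, csa_um2 = NA_real_,
                        i_min_um4 = NA_real_, i_max_um4 = NA_real_,
                        j_um4 = NA_real_, ct_th_um = NA_real_,
                        ellipticity = NA_real_, theta_deg = NA_real_,
                        bmd_mgHA_cm3 = NA_real_))
    bmd <- NA_real_
    if (!is.null(volume)) {
      att <- volume$voxels[, , k][m]
      bmd <- mean(calibrate_bmd(att, calibration))
    }
    data.frame(position_pct = pct, slice = k, csa_um2 = sm$csa,
               i_min_um4 = sm$i_min, i_max_um4 = sm$i_max, j_um4 = sm$j,
               ct_th_um = ct_thickness_2d(m, h),
               ellipticity = sm$ellipticity, theta_deg = sm$theta_deg,
               bmd_mgHA_cm3 = bmd)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cross_section_profile", "data.frame")
  out
}

#' Attenuation-to-density calibration from a hydroxyapatite phantom
#'
#' Affine map fitted through phantom reference points of known
#' hydroxyapatite density scanned under the same conditions as the
#' specimens. With two points the map reproduces them exactly; with more,
#' it is the least-squares line.
#'
#' @param attenuations X-ray attenuation values of the phantom inserts.
#' @param densities_mgHA_cm3 Their known densities (mg HA/cm^3).
#' @return Object of class `density_calibration` with `slope`,
#'   `intercept` and the reference points.
#' @export
density_calibration <- function(attenuations, densities_mgHA_cm3) {
  if (length(attenuations) < 2L || length(attenuations) != length(densities_mgHA_cm3))
    stop("at least two phantom points are required")
  if (diff(range(attenuations)) == 0)
    stop("degenerate phantom: all attenuations are equal")
  fit <- lm(densities_mgHA_cm3 ~ attenuations)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 points = data.frame(attenuation = attenuations,
                                     density = densities_mgHA_cm3)),
            class = "density_calibration")
}

#' Apply a density calibration to attenuation values
#'
#' Voxelwise affine map; negative mapped densities are clamped to zero
#' with a warning (they indicate attenuation below the calibration range).
#'
#' @param attenuations Numeric attenuation values.
#' @param calibration A [density_calibration].
#' @return Densities in mg HA/cm^3.
#' @export
calibrate_bmd <- function(attenuations, calibration) {
  stopifnot(inherits(calibration, "density_calibration"))
  d <- calibration$intercept + calibration$slope * attenuations
  if (any(d < 0, na.rm = TRUE)) {
    warning("negative mapped densities clamped to 0")
    d[d < 0] <- 0
  }
  d
}

#' Bin 8-bit threshold-density values for heat-map rendering
#'
#' Deterministic equal-width binning of the 0-255 intensity scale used for
#' longitudinal-section density renderings (low-density bins rendered
#' brown through to high-density blue).
#'
#' @param values Numeric values in `[0, 255]`.
#' @param n_bins Number of equal-width bins.
#' @return Data frame with `value`, `bin` (1 = lowest), and `color`.
#' @export
density_heatmap_bins <- function(values, n_bins = 8L) {
  if (any(is.na(values)) || any(values < 0 | values > 255))
    stop("values must lie in [0, 255]")
  breaks <- seq(0, 255, length.out = n_bins + 1L)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  pal <- grDevices::colorRampPalette(c("brown", "blue"))(n_bins)
  data.frame(value = values, bin = bin, color = pal[bin])
}

#' Generate a tibia-like elliptical-annulus stack with analytic geometry
#'
#' Rasterises a stack whose cross-section at each slice is a concentric
#' rotated elliptical annulus; outer/inner semi-axes, centre and rotation
#' may vary smoothly along the axis (pass scalars or per-slice vectors).
#' The analytic section properties of every slice are returned alongside,
#' to serve as ground truth: CSA `pi(a_o b_o - a_i b_i)` and principal
#' moments `pi/4 (a b^3 - ...)` of the annulus.
#'
#' @param n_slices Number of slices.
#' @param pixel_size_um Pixel size in micrometres.
#' @param outer_a_um,outer_b_um,inner_a_um,inner_b_um Semi-axes (scalar or
#'   length-`n_slices`); the inner ellipse must be strictly inside the
#'   outer one.
#' @param center_x_um,center_y_um Section centre relative to the stack
#'   centre.
#' @param rotation_deg Rotation of the major axis from the x axis.
#' @param nx,ny Grid size in pixels (default: sized to fit).
#' @return List with `mask` (a [binary_mask]) and `truth` (data frame:
#'   `slice`, `csa_um2`, `i_min_um4`, `i_max_um4`, `j_um4`, `ellipticity`,
#'   `theta_deg`).
#' @export
generate_tibia_stack <- function(n_slices, pixel_size_um,
                                 outer_a_um, outer_b_um,
                                 inner_a_um, inner_b_um,
                                 center_x_um = 0, center_y_um = 0,
                                 rotation_deg = 0, nx = NULL, ny = NULL) {
  rep_n <- function(x) if (length(x) == 1L) rep(x, n_slices) else x
  oa <- rep_n(outer_a_um); ob <- rep_n(outer_b_um)
  ia <- rep_n(inner_a_um); ib <- rep_n(inner_b_um)
  cx <- rep_n(center_x_um); cy <- rep_n(center_y_um)
  rot <- rep_n(rotation_deg)
  lens <- c(length(oa), length(ob), length(ia), length(ib), length(cx),
            length(cy), length(rot))
  if (any(lens != n_slices))
    stop("per-slice parameters must be scalars or length n_slices")
  if (any(ia >= oa | ib >= ob))
    stop("inner ellipse must be strictly inside the outer ellipse")
  p <- pixel_size_um
  reach <- max(abs(cx) + pmax(oa, ob), abs(cy) + pmax(oa, ob))
  if (is.null(nx)) nx <- 2L * (ceiling(reach / p) + 3L)
  if (is.null(ny)) ny <- nx
  xs <- (seq_len(nx) - (nx + 1) / 2) * p
  ys <- (seq_len(ny) - (ny + 1) / 2) * p
  vox <- array(FALSE, dim = c(nx, ny, n_slices))
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  for (k in seq_len(n_slices)) {
    th <- rot[k] * pi / 180
    dx <- X - cx[k]; dy <- Y - cy[k]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside_out <- (u / oa[k])^2 + (v / ob[k])^2 <= 1
    inside_in <- (u / ia[k])^2 + (v / ib[k])^2 < 1
    vox[, , k] <- inside_out & !inside_in
  }
  i1 <- pi / 4 * (oa * ob^3 - ia * ib^3) # about the major (a) axis
  i2 <- pi / 4 * (oa^3 * ob - ia^3 * ib)
  truth <- data.frame(
    slice = seq_len(n_slices),
    csa_um2 = pi * (oa * ob - ia * ib),
    i_min_um4 = pmin(i1, i2), i_max_um4 = pmax(i1, i2),
    j_um4 = i1 + i2,
    ellipticity = sqrt(pmax(i1, i2) / pmin(i1, i2)),
    theta_deg = rot %% 180)
  list(mask = binary_mask(vox, p, "bone"), truth = truth)
}
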