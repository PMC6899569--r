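#' Label pores and compute per-pore descriptors
#'
#' One pore per 26-connected component of the porosity mask ("particle
#' analysis"). Per pore: volume (voxel count x voxel volume), equivalent
#' spherical diameter `(6V/pi)^(1/3)`, centroid, elongation
#' `sqrt(lambda_1/lambda_3)` (largest over smallest principal second
#' moment of the voxel cloud; a voxel self-moment of 1/12 voxel^2 is added
#' to each principal direction so single-voxel and planar components stay
#' finite), and maximum extent (largest voxel-cloud range along the three
#' principal axes, an inscribed approximation to the maximum Feret
#' diameter).
#'
#' @param porosity A [binary_mask] labelled `"porosity"`.
#' @param cortex_solid Optional [binary_mask] giving the solid cortex; its
#'   volume is the denominator for number densities.
#' @return An object of class `pore_catalog`: list with `pores` (data
#'   frame: `id`, `n_voxels`, `volume_um3`, `diameter_um`, `elongation`,
#'   `extent_um`, `centroid_*_um`, `class`), `cortical_solid_volume_um3`,
#'   `voxel_size_um`, `separation_threshold_um3` (NA until classified),
#'   `noise_floor_um3` (NA until classified).
#' @export
label_pores <- function(porosity, cortex_solid = NULL) {
  stopifnot(inherits(porosity, "binary_mask"))
  h <- porosity$voxel_size_um
  lab <- label_components(porosity$voxels, 26L)
  idx <- which(lab > 0L)
  csv_um3 <- if (!is.null(cortex_solid))
    sum(cortex_solid$voxels) * cortex_solid$voxel_size_um^3 else NA_real_

  if (length(idx) == 0L) {
    pores <- data.frame(id = integer(0), n_voxels = integer(0),
                        volume_um3 = numeric(0), diameter_um = numeric(0),
                        elongation = numeric(0), extent_um = numeric(0),
                        centroid_x_um = numeric(0),
                        centroid_y_um = numeric(0),
                        centroid_z_um = numeric(0),
                        class = character(0), stringsAsFactors = FALSE)
    return(structure(list(pores = pores,
                          cortical_solid_volume_um3 = csv_um3,
                          voxel_size_um = h,
                          separation_threshold_um3 = NA_real_,
                          noise_floor_um3 = NA_real_),
                     class = "pore_catalog"))
  }

  d <- dim(lab)
  labv <- lab[idx]
  i <- (idx - 1L) %% d[1] + 1L
  j <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  coords <- cbind(i, j, k) * h
  ord <- order(labv)
  labv <- labv[ord]; coords <- coords[ord, , drop = FALSE]
  n_per <- tabulate(labv)
  ends <- cumsum(n_per); starts <- c(1L, head(ends, -1L) + 1L)
  n_pores <- length(n_per)

  vol <- n_per * h^3
  diam <- (6 * vol / pi)^(1 / 3)
  cent <- matrix(0, n_pores, 3)
  elong <- numeric(n_pores)
  extent <- numeric(n_pores)
  self_mom <- h^2 / 12
  for (p in seq_len(n_pores)) {
    pc <- coords[starts[p]:ends[p], , drop = FALSE]
    mu <- colMeans(pc)
    cent[p, ] <- mu
    pc <- sweep(pc, 2, mu)
    S <- crossprod(pc) / nrow(pc) + diag(self_mom, 3)
    ev <- eigen(S, symmetric = TRUE)
    elong[p] <- sqrt(ev$values[1] / ev$values[3])
    proj <- pc %*% ev$vectors
    extent[p] <- max(apply(proj, 2, function(x) diff(range(x)))) + h
  }

  pores <- data.frame(id = seq_len(n_pores), n_voxels = n_per,
                      volume_um3 = vol, diameter_um = diam,
                      elongation = elong, extent_um = extent,
                      centroid_x_um = cent[, 1], centroid_y_um = cent[, 2],
                      centroid_z_um = cent[, 3],
                      class = NA_character_, stringsAsFactors = FALSE)
  structure(list(pores = pores, cortical_solid_volume_um3 = csv_um3,
                 voxel_size_um = h, separation_threshold_um3 = NA_real_,
                 noise_floor_um3 = NA_real_),
            class = "pore_catalog")
}

#' @export
print.pore_catalog <- function(x, ...) {
  cat(sprintf("<pore_catalog> %d pores", nrow(x$pores)))
  if (!all(is.na(x$pores$class))) {
    tb <- table(x$pores$class)
    cat(" (", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Animal-specific lacuna/canal separation threshold
#'
#' Canal candidates are pores that look like canals by shape and size:
#' elongation at least `elongation_min` and maximum extent at least
#' `extent_min_um`. The separation threshold is set just below the volume
#' of the smallest candidate — `(1 - epsilon)` times it — so that every
#' candidate ends up at or above the threshold. With no candidates the
#' threshold is `+Inf` (no pore is large enough to be a canal). Thresholds
#' are per-specimen: compute one per input volume, never pooled.
#'
#' @param catalog A `pore_catalog`.
#' @param elongation_min,extent_min_um Shape/size criterion defining a
#'   canal candidate. Defaults (3, 30 um) suit murine cortical canals.
#' @param epsilon Relative margin below the smallest candidate volume.
#' @return Threshold volume in um^3 (possibly `Inf`).
#' @export
select_separation_threshold <- function(catalog, elongation_min = 3,
                                        extent_min_um = 30,
                                        epsilon = 0.01) {
  stopifnot(inherits(catalog, "pore_catalog"))
  if (nrow(catalog$pores) == 0L) stop("catalog is empty")
  p <- catalog$pores
  cand <- p$elongation >= elongation_min & p$extent_um >= extent_min_um
  if (!any(cand)) return(Inf)
  (1 - epsilon) * min(p$volume_um3[cand])
}

#' Classify pores into lacunae, canals and noise
#'
#' Volume below the noise floor: noise. Volume at or above the separation
#' threshold: canal (the boundary is inclusive). Everything between:
#' lacuna.
#'
#' @param catalog A `pore_catalog`.
#' @param threshold_um3 Separation threshold (e.g. from
#'   [select_separation_threshold]).
#' @param noise_floor_um3 Volume below which a component is sub-resolution
#'   noise. Default 8 voxels at the catalog's voxel size.
#' @return The catalog with `class` filled in and the thresholds recorded.
#' @export
classify_pores <- function(catalog, threshold_um3,
                           noise_floor_um3 = 8 * catalog$voxel_size_um^3) {
  stopifnot(inherits(catalog, "pore_catalog"))
  if (threshold_um3 <= noise_floor_um3)
    stop("separation threshold must exceed the noise floor")
  v <- catalog$pores$volume_um3
  cls <- ifelse(v < noise_floor_um3, "noise",
                ifelse(v >= threshold_um3, "canal", "lacuna"))
  catalog$pores$class <- cls
  catalog$separation_threshold_um3 <- threshold_um3
  catalog$noise_floor_um3 <- noise_floor_um3
  catalog
}

#' Morphometric summary indices
#'
#' Standard nomenclature: Lc.Dn / Ca.Dn are number densities (per mm^3 of
#' solid cortex), Lc.V / Ca.V mean volumes (um^3), Lc.Dm / Ca.Dm mean
#' equivalent spherical diameters (um). Class fractions are percentages of
#' total pore volume and sum to 100. Ct.Po is total pore volume as a
#' percentage of the solid cortex volume.
#'
#' @param catalog A classified `pore_catalog` with
#'   `cortical_solid_volume_um3` set.
#' @return A one-row data frame with columns `Lc.Dn_mm3`, `Lc.V_um3`,
#'   `Lc.Dm_um`, `Ca.Dn_mm3`, `Ca.V_um3`, `Ca.Dm_um`, `lacunar_pct`,
#'   `canal_pct`, `noise_pct`, `Ct.Po_pct`. Means over an empty class are
#'   reported as `NA`, densities as 0.
#' @export
summarize_pores <- function(catalog) {
  stopifnot(inherits(catalog, "pore_catalog"))
  csv <- catalog$cortical_solid_volume_um3
  if (is.na(csv) || csv <= 0)
    stop("cortical solid volume must be positive; pass `cortex_solid` to label_pores()")
  p <- catalog$pores
  if (nrow(p) > 0 && all(is.na(p$class)))
    stop("classify_pores() must be run before summarising")
  cls_stats <- function(cl) {
    s <- p[p$class == cl, , drop = FALSE]
    list(dn = nrow(s) / csv * 1e9, # per mm^3; 1 mm^3 = 1e9 um^3
         v = if (nrow(s)) mean(s$volume_um3) else NA_real_,
         dm = if (nrow(s)) mean(s$diameter_um) else NA_real_,
         vol = sum(s$volume_um3))
  }
  lc <- cls_stats("lacuna"); ca <- cls_stats("canal"); no <- cls_stats("noise")
  tot <- lc$vol + ca$vol + no$vol
  pct <- function(x) if (tot > 0) 100 * x / tot else NA_real_
  data.frame(Lc.Dn_mm3 = lc$dn, Lc.V_um3 = lc$v, Lc.Dm_um = lc$dm,
             Ca.Dn_mm3 = ca$dn, Ca.V_um3 = ca$v, Ca.Dm_um = ca$dm,
             lacunar_pct = pct(lc$vol), canal_pct = pct(ca$vol),
             noise_pct = pct(no$vol),
             Ct.Po_pct = 100 * tot / csv)
}
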