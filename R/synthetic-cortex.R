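#' Specification of a synthetic cortical-bone phantom
#'
#' Describes a hollow-cylinder cortex (annulus cross-section, axis along the
#' third array dimension) populated with ellipsoidal osteocyte lacunae and
#' elongated tubular vascular canals, the substrate emulated being a
#' sub-micron CT scan of cortical bone. Pores are placed by rejection
#' sampling so they never overlap, giving unambiguous ground-truth labels.
#'
#' @param outer_radius_um,inner_radius_um Cortex annulus radii in
#'   micrometres (`inner < outer`).
#' @param length_slices Number of slices along the bone axis.
#' @param voxel_size_um Isotropic voxel size in micrometres.
#' @param lacunae List describing the lacuna population:
#'   `count`; `meanlog`/`sdlog` of the (natural-log) volume distribution in
#'   um^3; optional second mode `mode2_weight`, `mode2_meanlog`,
#'   `mode2_sdlog`; truncation bounds `min_volume_um3`, `max_volume_um3`;
#'   `max_elongation` (axis ratio of the prolate ellipsoids, sampled
#'   uniformly in `[1.2, max_elongation]`).
#' @param canals List describing the canal population: `count`;
#'   `radius_um`; `length_um` (nominal); `length_jitter` (relative sd of a
#'   uniform length jitter); `orientation_sd_deg` (tilt away from the bone
#'   axis); optional `target_canal_ratio`, the desired ratio of total canal
#'   to total lacunar rasterised volume — when set, canals are added until
#'   the ratio is met and the final canal's length is trimmed to hit it,
#'   and `count` is ignored.
#' @param osteoid List: `enabled`, `thickness_um`, `intensity_fraction`
#'   (halo intensity as a fraction of the bone mean). Halos emulate
#'   unmineralised osteoid seams around pores.
#' @param intensity List: `bone_mean`, `background_mean`, `noise_sd`
#'   (additive Gaussian, in intensity units), `bit_depth` (8 or 16).
#' @param padding_vox Background padding between the outer cortex surface
#'   and the array edge, in voxels. Must exceed the closing radius used
#'   downstream so the morphological mask construction is unaffected by
#'   the array border (default 20).
#' @param seed Mandatory RNG seed; generation is bit-reproducible given the
#'   spec.
#' @return An object of class `cortex_phantom_spec`.
#' @export
cortex_phantom_spec <- function(outer_radius_um, inner_radius_um,
                                length_slices, voxel_size_um,
                                lacunae = list(), canals = list(),
                                osteoid = list(), intensity = list(),
                                padding_vox = 20L, seed) {
  lac_def <- list(count = 0L, meanlog = log(250), sdlog = 0.45,
                  mode2_weight = 0, mode2_meanlog = NA_real_,
                  mode2_sdlog = NA_real_, min_volume_um3 = 60,
                  max_volume_um3 = 2000, max_elongation = 2.2)
  can_def <- list(count = 0L, radius_um = 4, length_um = 90,
                  length_jitter = 0.15, orientation_sd_deg = 5,
                  target_canal_ratio = NULL)
  ost_def <- list(enabled = FALSE, thickness_um = 3, intensity_fraction = 0.35)
  int_def <- list(bone_mean = 180, background_mean = 40, noise_sd = 5,
                  bit_depth = 8L)
  lacunae <- utils::modifyList(lac_def, lacunae)
  canals <- utils::modifyList(can_def, canals)
  osteoid <- utils::modifyList(ost_def, osteoid)
  intensity <- utils::modifyList(int_def, intensity)

  if (inner_radius_um >= outer_radius_um)
    stop("inner_radius_um must be smaller than outer_radius_um")
  if (voxel_size_um <= 0) stop("voxel_size_um must be > 0")
  if (length_slices < 1) stop("length_slices must be >= 1")
  if (lacunae$count < 0 || canals$count < 0) stop("counts must be >= 0")
  if (intensity$noise_sd < 0) stop("noise_sd must be >= 0")
  if (lacunae$max_elongation < 1.2)
    stop("max_elongation must be >= 1.2")
  if (missing(seed)) stop("a seed is mandatory in every phantom spec")

  structure(
    list(outer_radius_um = outer_radius_um,
         inner_radius_um = inner_radius_um,
         length_slices = as.integer(length_slices),
         voxel_size_um = voxel_size_um, lacunae = lacunae, canals = canals,
         osteoid = osteoid, intensity = intensity,
         padding_vox = as.integer(padding_vox),
         seed = as.integer(seed)),
    class = "cortex_phantom_spec")
}

# minimum distance between two 3D segments (p1,p2) and (q1,q2)
segment_segment_distance <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * cc - b * b
  if (D < 1e-12) { sN <- 0; sD <- 1; tN <- e; tD <- cc } else {
    sN <- b * e - cc * d; sD <- D
    tN <- a * e - b * d; tD <- D
    if (sN < 0) { sN <- 0; tN <- e; tD <- cc }
    else if (sN > sD) { sN <- sD; tN <- e + b; tD <- cc }
  }
  if (tN < 0) { tN <- 0; sN <- min(max(-d, 0), a); sD <- a; if (a < 1e-12) { sN <- 0; sD <- 1 } }
  else if (tN > tD) { tN <- tD; sN <- min(max(-d + b, 0), a); sD <- a; if (a < 1e-12) { sN <- 0; sD <- 1 } }
  s <- if (abs(sD) < 1e-12) 0 else sN / sD
  t <- if (abs(tD) < 1e-12) 0 else tN / tD
  dp <- w + s * u - t * v
  sqrt(sum(dp * dp))
}

# distance from points (matrix nx3) to segment (q1,q2)
point_segment_distance <- function(pts, q1, q2) {
  v <- q2 - q1
  L2 <- sum(v * v)
  w <- sweep(pts, 2, q1)
  t <- if (L2 < 1e-12) rep(0, nrow(pts)) else
    pmin(pmax((w %*% v) / L2, 0), 1)
  d <- w - outer(as.vector(t), v)
  sqrt(rowSums(d * d))
}

# orthonormal frame whose third axis is u
frame_from_axis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  rbind(v, w, u) # rows: two transverse axes then the main axis
}

# Rasterise an ellipsoid (semi-axes a >= b = c, main axis `axis`) centred at
# `centre` (um) into the label array; returns linear voxel indices.
rasterise_ellipsoid <- function(centre, a, b, axis, grid) {
  fr <- frame_from_axis(axis)
  rb <- a
  ir <- lapply(1:3, function(k) {
    lo <- max(1L, floor((centre[k] - rb) / grid$h - grid$off[k]) )
    hi <- min(grid$dim[k], ceiling((centre[k] + rb) / grid$h - grid$off[k]) + 1L)
    seq.int(lo, hi)
  })
  cx <- (ir[[1]] + grid$off[1]) * grid$h - centre[1]
  cy <- (ir[[2]] + grid$off[2]) * grid$h - centre[2]
  cz <- (ir[[3]] + grid$off[3]) * grid$h - centre[3]
  nxl <- length(cx); nyl <- length(cy); nzl <- length(cz)
  X <- rep(cx, times = nyl * nzl)
  Y <- rep(rep(cy, each = nxl), times = nzl)
  Z <- rep(cz, each = nxl * nyl)
  P <- cbind(X, Y, Z)
  q1 <- P %*% fr[3, ]; q2 <- P %*% fr[1, ]; q3 <- P %*% fr[2, ]
  inside <- (q1 / a)^2 + (q2 / b)^2 + (q3 / b)^2 <= 1
  if (!any(inside)) return(integer(0))
  li <- rep(ir[[1]], times = nyl * nzl) +
    grid$dim[1] * (rep(rep(ir[[2]] - 1L, each = nxl), times = nzl)) +
    grid$dim[1] * grid$dim[2] * (rep(ir[[3]] - 1L, each = nxl * nyl))
  li[inside]
}

# Rasterise a capsule (cylinder radius r with hemispherical caps) with axis
# segment from e1 to e2 (um); returns linear voxel indices.
rasterise_capsule <- function(e1, e2, r, grid) {
  lo <- pmin(e1, e2) - r; hi <- pmax(e1, e2) + r
  ir <- lapply(1:3, function(k) {
    a <- max(1L, floor(lo[k] / grid$h - grid$off[k]))
    b <- min(grid$dim[k], ceiling(hi[k] / grid$h - grid$off[k]) + 1L)
    seq.int(a, b)
  })
  cx <- (ir[[1]] + grid$off[1]) * grid$h
  cy <- (ir[[2]] + grid$off[2]) * grid$h
  cz <- (ir[[3]] + grid$off[3]) * grid$h
  nxl <- length(cx); nyl <- length(cy); nzl <- length(cz)
  P <- cbind(rep(cx, times = nyl * nzl),
             rep(rep(cy, each = nxl), times = nzl),
             rep(cz, each = nxl * nyl))
  d <- point_segment_distance(P, e1, e2)
  inside <- d <= r
  if (!any(inside)) return(integer(0))
  li <- rep(ir[[1]], times = nyl * nzl) +
    grid$dim[1] * (rep(rep(ir[[2]] - 1L, each = nxl), times = nzl)) +
    grid$dim[1] * grid$dim[2] * (rep(ir[[3]] - 1L, each = nxl * nyl))
  li[inside]
}

sample_lacuna_volumes <- function(lac, n) {
  if (n == 0L) return(numeric(0))
  v <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      if (lac$mode2_weight > 0 && runif(1) < lac$mode2_weight)
        x <- rlnorm(1, lac$mode2_meanlog, lac$mode2_sdlog)
      else
        x <- rlnorm(1, lac$meanlog, lac$sdlog)
      if (x >= lac$min_volume_um3 && x <= lac$max_volume_um3) break
    }
    v[i] <- x
  }
  v
}

#' Generate a ground-truthed cortical phantom volume
#'
#' Builds the grayscale volume (bone at `bone_mean`, pores and exterior at
#' `background_mean`, optional osteoid halos at
#' `intensity_fraction * bone_mean`, additive Gaussian noise, clamped and
#' rounded to the bit depth) together with per-pore ground truth: class,
#' rasterised voxel volume and centroid, plus the true cortex mask and the
#' class partition of total pore volume.
#'
#' @param spec A [cortex_phantom_spec].
#' @param keep_labels Keep the integer pore-label array in the ground truth
#'   (large; needed for voxel-exact comparisons).
#' @param max_retries Placement attempts allowed per pore before giving up.
#' @return A list with elements `volume` (a [volume_image]) and `truth`
#'   (list: `pores` data frame with `id`, `class`, `volume_um3`,
#'   `n_voxels`, `centroid_x/y/z_um`; `lacunar_pct`; `canal_pct`;
#'   `cortex_mask`; `labels` if kept).
#' @export
generate_cortex_volume <- function(spec, keep_labels = TRUE,
                                   max_retries = 2000L) {
  stopifnot(inherits(spec, "cortex_phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$voxel_size_um
    Ro <- spec$outer_radius_um; Ri <- spec$inner_radius_um
    half <- ceiling(Ro / h) + spec$padding_vox
    nx <- ny <- 2L * half
    nz <- spec$length_slices
    # voxel centre k has coordinate (k + off) * h; centre of array at 0
    offxy <- -(nx + 1) / 2
    grid <- list(h = h, dim = c(nx, ny, nz), off = c(offxy, offxy, -0.5))

    xs <- (seq_len(nx) + offxy) * h
    r2d <- outer(xs^2, xs^2, "+")
    cortex2d <- r2d <= Ro^2 & r2d >= Ri^2

    gap <- 2 * h
    lac <- spec$lacunae; can <- spec$canals
    pore_lab <- array(0L, dim = c(nx, ny, nz))
    zlen <- nz * h

    place_centre <- function(rb) {
      rmin <- Ri + rb + gap; rmax <- Ro - rb - gap
      if (rmin >= rmax) return(NULL)
      rad <- sqrt(runif(1, rmin^2, rmax^2))
      th <- runif(1, 0, 2 * pi)
      zmin <- rb + gap; zmax <- zlen - rb - gap
      if (zmin >= zmax) return(NULL)
      c(rad * cos(th), rad * sin(th), runif(1, zmin, zmax))
    }

    # --- pore populations -------------------------------------------------
    # Lacuna volumes are sampled up front: their analytic total fixes the
    # canal volume budget when a target partition is requested. Canals are
    # placed first (long corridors are hard to thread through a seeded
    # annulus); lacunae then dodge the canals. The last canal is
    # fine-trimmed once the lacunae are rasterised, so the voxel partition
    # hits the requested ratio exactly.
    vols <- sort(sample_lacuna_volumes(lac, lac$count), decreasing = TRUE)
    n_lac <- length(vols)

    rc <- can$radius_um
    canal_segs <- list()
    canal_idx <- list()
    canal_len <- numeric(0)
    vox_per_um3 <- 1 / h^3

    # collision checks and margins use a 25% longer segment than is
    # rasterised, leaving room to extend the final canal when trimming the
    # partition to a target ratio
    place_canal <- function(len) {
      len_chk <- 1.25 * len
      for (try in seq_len(max_retries)) {
        tilt <- abs(rnorm(1, 0, can$orientation_sd_deg)) * pi / 180
        phi <- runif(1, 0, 2 * pi)
        u <- c(sin(tilt) * cos(phi), sin(tilt) * sin(phi), cos(tilt))
        lat <- len_chk / 2 * sin(tilt) # lateral reach of the endpoints
        rmin <- Ri + rc + lat + gap; rmax <- Ro - rc - lat - gap
        if (rmin >= rmax) next # too tilted for the annulus; redraw
        rad <- sqrt(runif(1, rmin^2, rmax^2)); th <- runif(1, 0, 2 * pi)
        zmin <- len_chk / 2 + rc + gap; zmax <- zlen - len_chk / 2 - rc - gap
        if (zmin >= zmax)
          stop("canal length exceeds the phantom length")
        ctr <- c(rad * cos(th), rad * sin(th), runif(1, zmin, zmax))
        e1c <- ctr - len_chk / 2 * u; e2c <- ctr + len_chk / 2 * u
        clash <- FALSE
        for (sg in canal_segs)
          if (segment_segment_distance(sg$e1c, sg$e2c, e1c, e2c) <
              sg$r + rc + gap) { clash <- TRUE; break }
        if (clash) next
        return(list(e1 = ctr - len / 2 * u, e2 = ctr + len / 2 * u,
                    e1c = e1c, e2c = e2c, r = rc))
      }
      stop("placement failed for the canal population after max retries")
    }

    add_canal <- function(len) {
      sg <- place_canal(len)
      canal_segs[[length(canal_segs) + 1L]] <<- sg
      idx <- rasterise_capsule(sg$e1, sg$e2, sg$r, grid)
      canal_idx[[length(canal_idx) + 1L]] <<- idx
      canal_len <<- c(canal_len, len)
      length(idx)
    }

    nominal_vol <- pi * rc^2 * can$length_um + 4 / 3 * pi * rc^3
    use_target <- !is.null(can$target_canal_ratio) && n_lac > 0
    if (use_target) {
      # canal count and lengths from the analytic lacunar volume total
      target_um3 <- can$target_canal_ratio * sum(vols)
      nC <- max(1L, as.integer(round(target_um3 / nominal_vol)))
      cap_um3 <- 4 / 3 * pi * rc^3
      total_len <- (target_um3 - nC * cap_um3) / (pi * rc^2)
      f <- runif(nC, 1 - can$length_jitter, 1 + can$length_jitter)
      lens <- f / sum(f) * total_len
      for (len in lens) add_canal(len)
    } else {
      for (i in seq_len(can$count)) {
        len <- can$length_um *
          runif(1, 1 - can$length_jitter, 1 + can$length_jitter)
        add_canal(len)
      }
    }
    n_can <- length(canal_idx)

    # --- lacunae (largest first, avoiding the canals) ---------------------
    cent <- matrix(numeric(0), ncol = 3)
    brad <- numeric(0)
    lac_idx <- vector("list", n_lac)
    for (i in seq_len(n_lac)) {
      e <- runif(1, 1.2, lac$max_elongation)
      b <- (3 * vols[i] / (4 * pi * e))^(1 / 3)
      a <- e * b
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        ctr <- place_centre(a)
        if (is.null(ctr))
          stop("lacuna population does not fit the cortex annulus")
        if (nrow(cent) > 0) {
          dd <- sqrt(rowSums(sweep(cent, 2, ctr)^2))
          if (any(dd < brad + a + gap)) next
        }
        clash <- FALSE
        for (sg in canal_segs)
          if (point_segment_distance(matrix(ctr, 1, 3), sg$e1c, sg$e2c) <
              sg$r + a + gap) { clash <- TRUE; break }
        if (clash) next
        ok <- TRUE; break
      }
      if (!ok)
        stop("placement failed for the lacuna population after max retries")
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cent <- rbind(cent, ctr); brad <- c(brad, a)
      lac_idx[[i]] <- rasterise_ellipsoid(ctr, a, b, u, grid)
    }
    for (i in seq_len(n_lac)) pore_lab[lac_idx[[i]]] <- i
    total_lac_vox <- sum(vapply(lac_idx, length, integer(1)))

    # --- fine-trim the last canal to the measured lacunar total -----------
    if (use_target && n_can > 0) {
      target_vox <- can$target_canal_ratio * total_lac_vox
      delta <- target_vox - sum(vapply(canal_idx, length, integer(1)))
      nC <- n_can
      apl <- length(canal_idx[[nC]]) / canal_len[nC] # voxels per um length
      new_len <- max(2 * rc, canal_len[nC] + delta / apl)
      new_len <- min(new_len, 1.2 * canal_len[nC]) # stay in collision margin
      sg <- canal_segs[[nC]]
      ctr <- (sg$e1 + sg$e2) / 2
      u <- (sg$e2 - sg$e1) / sqrt(sum((sg$e2 - sg$e1)^2))
      e1 <- ctr - new_len / 2 * u; e2 <- ctr + new_len / 2 * u
      canal_idx[[nC]] <- rasterise_capsule(e1, e2, sg$r, grid)
      canal_len[nC] <- new_len
    }
    for (i in seq_len(n_can)) pore_lab[canal_idx[[i]]] <- n_lac + i

    # --- assemble intensity ----------------------------------------------
    cortex3d <- array(cortex2d, dim = c(nx, ny, nz))
    ints <- spec$intensity
    vol <- array(ints$background_mean, dim = c(nx, ny, nz))
    vol[cortex3d & pore_lab == 0L] <- ints$bone_mean
    if (spec$osteoid$enabled && (n_lac + n_can) > 0) {
      d2 <- .edt_squared_cpp(as.vector(pore_lab > 0L), dim(pore_lab))
      halo <- array(d2 <= (spec$osteoid$thickness_um / h)^2,
                    dim = dim(pore_lab)) & cortex3d & pore_lab == 0L
      vol[halo] <- spec$osteoid$intensity_fraction * ints$bone_mean
      rm(d2, halo)
    }
    if (ints$noise_sd > 0)
      vol <- vol + rnorm(length(vol), 0, ints$noise_sd)
    top <- 2^ints$bit_depth - 1
    vol <- round(pmin(pmax(vol, 0), top))
    dim(vol) <- c(nx, ny, nz)

    # --- ground truth -----------------------------------------------------
    all_idx <- c(lac_idx, canal_idx)
    n_pores <- length(all_idx)
    nvox <- vapply(all_idx, length, integer(1))
    centroid <- t(vapply(all_idx, function(ii) {
      if (length(ii) == 0) return(c(NA_real_, NA_real_, NA_real_))
      i0 <- (ii - 1L) %% nx + 1L
      j0 <- ((ii - 1L) %/% nx) %% ny + 1L
      k0 <- (ii - 1L) %/% (nx * ny) + 1L
      c(mean((i0 + offxy) * h), mean((j0 + offxy) * h), mean((k0 - 0.5) * h))
    }, numeric(3)))
    pores <- data.frame(
      id = seq_len(n_pores),
      class = rep(c("lacuna", "canal"), c(n_lac, n_can)),
      n_voxels = nvox,
      volume_um3 = nvox * h^3,
      centroid_x_um = if (n_pores) centroid[, 1] else numeric(0),
      centroid_y_um = if (n_pores) centroid[, 2] else numeric(0),
      centroid_z_um = if (n_pores) centroid[, 3] else numeric(0),
      stringsAsFactors = FALSE)
    tot <- sum(pores$volume_um3)
    truth <- list(
      pores = pores,
      lacunar_pct = if (tot > 0) 100 * sum(pores$volume_um3[pores$class == "lacuna"]) / tot else NA_real_,
      canal_pct = if (tot > 0) 100 * sum(pores$volume_um3[pores$class == "canal"]) / tot else NA_real_,
      cortex_mask = cortex3d,
      labels = if (keep_labels) pore_lab else NULL)

    list(volume = volume_image(vol, h, ints$bit_depth), truth = truth)
  })
}
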