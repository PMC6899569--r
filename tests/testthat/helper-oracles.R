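# Small phantom spec used across tests: quick to generate, all pore radii
# well below the closing radius used with it (8).
small_cortex_spec <- function(seed, n_lac = 25, n_can = 3, noise_sd = 0,
                              ...) {
  cortex_phantom_spec(
    outer_radius_um = 50, inner_radius_um = 22, length_slices = 70,
    voxel_size_um = 1,
    lacunae = list(count = n_lac, meanlog = log(220), sdlog = 0.35,
                   min_volume_um3 = 60, max_volume_um3 = 1500),
    canals = list(count = n_can, radius_um = 3, length_um = 40),
    intensity = list(noise_sd = noise_sd),
    padding_vox = 12L, seed = seed, ...)
}

# Independent connected-component oracle: iterative label propagation.
# Every voxel starts with its own label; labels relax to the minimum over
# the 26-neighbourhood until a fixed point. Shares no code or algorithm
# with the package's flood fill.
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- which(mask)
  shifts <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0 & shifts$dk == 0), ]
  pad <- function(a) {
    out <- array(.Machine$integer.max, d + 2L)
    out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
    out
  }
  repeat {
    work <- lab
    work[!mask] <- .Machine$integer.max
    p <- pad(work)
    mn <- work
    for (s in seq_len(nrow(shifts))) {
      nb <- p[2:(d[1] + 1) + shifts$di[s],
              2:(d[2] + 1) + shifts$dj[s],
              2:(d[3] + 1) + shifts$dk[s]]
      mn <- pmin(mn, nb)
    }
    new <- lab
    new[mask] <- mn[mask]
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0L
  lab
}

# TRUE when two labelings induce the same partition of the foreground.
same_partition <- function(a, b) {
  fa <- a[a > 0L]; fb <- b[b > 0L]
  if (length(fa) != length(fb)) return(FALSE)
  key <- paste(fa, fb)
  u <- !duplicated(key)
  # bijection: each label of one maps to exactly one label of the other
  !any(duplicated(fa[u])) && !any(duplicated(fb[u]))
}

# Voxelised ball mask around a centre (voxel indices), for insertion-mask
# voxel-count oracles.
ball_mask <- function(dim, centre, radius) {
  i <- slice.index(array(0, dim), 1)
  j <- slice.index(array(0, dim), 2)
  k <- slice.index(array(0, dim), 3)
  (i - centre[1])^2 + (j - centre[2])^2 + (k - centre[3])^2 <= radius^2
}

# trapezoid integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
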