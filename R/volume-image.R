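#' 3D grayscale volume with physical voxel size
#'
#' The raw CT substrate: a 3D array of intensities on an isotropic voxel
#' grid. Slices are indexed along the third array dimension (the scan/bone
#' axis).
#'
#' @param voxels 3D numeric array of intensities.
#' @param voxel_size_um Isotropic voxel edge length in micrometres (> 0).
#' @param bit_depth Intensity bit depth, 8 or 16. Determines the
#'   representable range `[0, 2^bit_depth - 1]` used for threshold checks.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size_um, bit_depth = 8L) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  structure(
    list(voxels = voxels, voxel_size_um = voxel_size_um,
         bit_depth = as.integer(bit_depth)),
    class = "volume_image")
}

#' Binary 3D mask aligned with a source volume
#'
#' @param voxels 3D logical array.
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @param label Semantic label: what the TRUE voxels represent.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, voxel_size_um,
                        label = c("bone", "cortex_solid", "porosity")) {
  label <- match.arg(label)
  if (!is.array(voxels) || length(dim(voxels)) != 3L || !is.logical(voxels))
    stop("`voxels` must be a 3D logical array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(
    list(voxels = voxels, voxel_size_um = voxel_size_um, label = label),
    class = "binary_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d x %d x %d voxels, %.3g um/voxel, %d-bit\n",
              d[1], d[2], d[3], x$voxel_size_um, x$bit_depth))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask:%s> %d x %d x %d voxels, %.3g um/voxel, %d TRUE\n",
              x$label, d[1], d[2], d[3], x$voxel_size_um, sum(x$voxels)))
  invisible(x)
}

# voxel volume in um^3
voxel_volume <- function(x) x$voxel_size_um^3

#' Write a volume as a multi-page TIFF
#'
#' One page per slice (third array dimension), stored at the volume's bit
#' depth. The voxel size is not embedded; keep it in the accompanying config.
#'
#' @param volume A [volume_image].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "volume_image"))
  scale <- 2^volume$bit_depth - 1
  pages <- lapply(seq_len(dim(volume$voxels)[3]), function(k) {
    m <- volume$voxels[, , k] / scale
    m[m < 0] <- 0; m[m > 1] <- 1
    # TIFF rows are the first array index
    t(m)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = volume$bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF as a volume
#'
#' @param path TIFF file path.
#' @param voxel_size_um Isotropic voxel size in micrometres (from the scan
#'   config; TIFF files do not carry it).
#' @param bit_depth Intensity bit depth of the stored data.
#' @return A [volume_image].
#' @export
read_volume_tiff <- function(path, voxel_size_um, bit_depth = 8L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 2^bit_depth - 1
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    t(p) * scale
  })
  vox <- array(unlist(slices, use.names = FALSE),
               dim = c(dim(slices[[1]]), length(slices)))
  volume_image(vox, voxel_size_um, bit_depth)
}
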