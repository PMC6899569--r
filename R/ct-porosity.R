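#' Separate bone from non-bone by a lower intensity threshold
#'
#' A voxel is bone iff its intensity is greater than or equal to the
#' threshold ("lower threshold" convention: bone sits at or above it). The
#' value 80 used for 8-bit lab-CT reconstructions is a common choice, but
#' the threshold is a required, per-dataset parameter.
#'
#' @param volume A [volume_image].
#' @param threshold Intensity threshold; must lie within the volume's
#'   representable intensity range.
#' @return A [binary_mask] labelled `"bone"`.
#' @export
binarize <- function(volume, threshold) {
  stopifnot(inherits(volume, "volume_image"))
  top <- 2^volume$bit_depth - 1
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > top)
    stop(sprintf("threshold must lie within [0, %d] for %d-bit data",
                 top, volume$bit_depth))
  binary_mask(volume$voxels >= threshold, volume$voxel_size_um, "bone")
}

#' Extract intracortical porosity as the negative imprint of bone
#'
#' Reproduces the mask-construction recipe used for high-resolution CT
#' stacks: keep the largest 26-connected bone region, close it with a
#' Euclidean ball to obtain a solid cortex mask, then intersect the closed
#' mask with the inverted bone image. Pores smaller than the closing radius
#' are swallowed by the closing and so reappear in the intersection; the
#' marrow cavity and the exterior are not filled and stay excluded.
#'
#' @param bone A [binary_mask] labelled `"bone"` (from [binarize]).
#' @param closing_radius_vox Ball radius of the morphological closing, in
#'   voxels (>= 1). Must exceed the radius of the largest pore to be
#'   recovered; default 15 suits sub-micron scans of murine cortex.
#' @param order Order of the morphological operations; `"dilate_erode"`
#'   (closing) is the default, see [close_ball].
#' @param exclude_border_pores Drop pore components touching the first or
#'   last slice (the default keeps them, matching analysis of a fixed
#'   slice window).
#' @param drop_surface_pores Drop void components that open onto the
#'   cortex surface (voxels 26-adjacent to the outside of the closed
#'   cortex mask). Intracortical porosity is enclosed by definition;
#'   surface-connected voids belong to the exterior or the marrow cavity.
#'   This also suppresses the shallow pockets that a discrete closing
#'   leaves in sub-voxel nicks of the rasterised bone surface.
#' @return A list with [binary_mask] elements `porosity` and
#'   `cortex_solid`.
#' @export
extract_cortical_porosity <- function(bone, closing_radius_vox = 15L,
                                      order = "dilate_erode",
                                      exclude_border_pores = FALSE,
                                      drop_surface_pores = TRUE) {
  stopifnot(inherits(bone, "binary_mask"))
  if (!any(bone$voxels)) stop("bone mask is empty")
  if (closing_radius_vox < 1) stop("closing_radius_vox must be >= 1")
  largest <- keep_largest_region(bone$voxels, 26L)
  cortex <- close_ball(largest, closing_radius_vox, order = order)
  if (sum(cortex) > 2 * sum(largest))
    warning("closing more than doubled the solid volume; the closing ",
            "radius may have filled the marrow cavity")
  porosity <- cortex & !bone$voxels
  if ((drop_surface_pores || exclude_border_pores) && any(porosity)) {
    lab <- label_components(porosity, 26L)
    drop_labs <- integer(0)
    if (drop_surface_pores) {
      surface <- dilate_ball(!cortex, 1.75) # 26-neighbourhood of outside
      drop_labs <- unique(lab[porosity & surface])
    }
    if (exclude_border_pores) {
      nz <- dim(lab)[3]
      drop_labs <- c(drop_labs, unique(c(lab[, , 1], lab[, , nz])))
    }
    drop_labs <- unique(drop_labs[drop_labs > 0L])
    if (length(drop_labs))
      porosity[lab %in% drop_labs] <- FALSE
  }
  list(porosity = binary_mask(porosity, bone$voxel_size_um, "porosity"),
       cortex_solid = binary_mask(cortex, bone$voxel_size_um,
                                  "cortex_solid"))
}

#' Total volume porosity
#'
#' Ct.Po (%) = 100 x porosity voxels / cortex-solid voxels.
#'
#' @param porosity,cortex_solid [binary_mask] objects from
#'   [extract_cortical_porosity].
#' @return Percentage of the solid cortex volume occupied by pores.
#' @export
total_porosity <- function(porosity, cortex_solid) {
  stopifnot(inherits(porosity, "binary_mask"),
            inherits(cortex_solid, "binary_mask"))
  n_cortex <- sum(cortex_solid$voxels)
  if (n_cortex == 0) stop("cortex_solid mask is empty")
  100 * sum(porosity$voxels) / n_cortex
}
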