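#' Euclidean distance transform of a 3D logical array
#'
#' Distance, in voxel units, from every voxel to the nearest TRUE voxel.
#' Computed with the separable lower-envelope algorithm, exact for the
#' Euclidean metric. Voxels outside the array carry no sites, so a mask
#' touching the array border is not influenced by anything beyond it.
#'
#' @param sites 3D logical array marking site voxels.
#' @param squared Return squared distances (avoids the final `sqrt`).
#' @return 3D numeric array of (squared) distances. Voxels with no site
#'   anywhere in the array get a very large finite value.
#' @export
distance_transform <- function(sites, squared = FALSE) {
  stopifnot(is.array(sites), length(dim(sites)) == 3L, is.logical(sites))
  d2 <- .edt_squared_cpp(as.vector(sites), dim(sites))
  out <- array(if (squared) d2 else sqrt(d2), dim = dim(sites))
  out
}

ball_op <- function(mask, radius_vox, op = c("dilate", "erode")) {
  op <- match.arg(op)
  stopifnot(is.array(mask), is.logical(mask), radius_vox >= 0)
  if (radius_vox == 0) return(mask)
  r2 <- radius_vox^2 + 1e-9
  if (op == "dilate") {
    d2 <- .edt_squared_cpp(as.vector(mask), dim(mask))
    array(d2 <= r2, dim = dim(mask))
  } else {
    d2 <- .edt_squared_cpp(as.vector(!mask), dim(mask))
    array(d2 > r2, dim = dim(mask))
  }
}

#' Morphological dilation/erosion/closing with a Euclidean ball
#'
#' Implemented via the exact distance transform: dilation keeps voxels
#' within `radius_vox` of the mask; erosion keeps voxels farther than
#' `radius_vox` from the complement. At array borders the outside is
#' treated as complement-free, so erosion does not eat into structures
#' truncated by the scan window.
#'
#' @param mask 3D logical array.
#' @param radius_vox Ball radius in voxels (>= 0).
#' @param order For `close_ball`, `"dilate_erode"` (a true closing, the
#'   default) or `"erode_dilate"` (an opening, available because scanner
#'   protocols sometimes state the operations in that order).
#' @return 3D logical array.
#' @export
dilate_ball <- function(mask, radius_vox) ball_op(mask, radius_vox, "dilate")

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius_vox) ball_op(mask, radius_vox, "erode")

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, radius_vox,
                       order = c("dilate_erode", "erode_dilate")) {
  order <- match.arg(order)
  if (order == "dilate_erode")
    erode_ball(dilate_ball(mask, radius_vox), radius_vox)
  else
    dilate_ball(erode_ball(mask, radius_vox), radius_vox)
}

#' Label connected components of a 3D logical array
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (faces, edges and corners; the particle-analysis
#'   default) or 6 (faces only).
#' @return 3D integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  lab <- .label_components_cpp(as.vector(mask), dim(mask),
                               as.integer(connectivity))
  array(lab, dim = dim(mask))
}

#' Keep only the largest connected component
#'
#' The "keep largest region" step: everything but the largest (by voxel
#' count) 26-connected component is discarded.
#'
#' @inheritParams label_components
#' @return 3D logical array.
#' @export
keep_largest_region <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim = dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim = dim(mask))
}
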