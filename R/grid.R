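#' Construct a voxel grid
#'
#' @param shape integer(3): voxels along x, y, z.
#' @param spacing numeric(3) or scalar: voxel spacing in mm.
#' @param origin numeric(3): world position (mm, RAS+) of the first voxel
#'   center.
#' @return a [VoxelGrid-class].
#' @examples
#' g <- VoxelGrid(c(10L, 10L, 10L), spacing = 2)
#' voxelVolume(g)  # 0.008 cm3
#' @export
VoxelGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("VoxelGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "VoxelGrid",
          function(object) prod(object@spacing) / 1000)

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "PETVolume", function(object) voxelVolume(object@grid))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "MaskVolume",
          function(object) voxelVolume(object@grid))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ComponentSet",
          function(object) voxelVolume(object@mask@grid))

#' @rdname imageGrid
#' @export
setMethod("imageGrid", "PETVolume", function(object) object@grid)

#' @rdname imageGrid
#' @export
setMethod("imageGrid", "MaskVolume", function(object) object@grid)

#' @rdname imageGrid
#' @export
setMethod("imageGrid", "ComponentSet", function(object) object@mask@grid)

#' Grid accessors
#'
#' @param grid a [VoxelGrid-class].
#' @return shape (integer(3)), spacing or origin (numeric(3), mm).
#' @export
gridShape <- function(grid) grid@shape

#' @rdname gridShape
#' @export
gridSpacing <- function(grid) grid@spacing

#' @rdname gridShape
#' @export
gridOrigin <- function(grid) grid@origin

#' Convert between world coordinates (mm) and voxel indices
#'
#' World points map to the voxel whose center is nearest (rounding half up
#' along each axis); indices are 1-based.
#'
#' @param grid a [VoxelGrid-class].
#' @param point_mm numeric(3) world point in mm.
#' @param index integer(3) 1-based voxel index.
#' @return `worldToVoxel`: integer(3) voxel index, or an error if the point
#'   falls outside the grid; `voxelToWorld`: numeric(3) mm.
#' @export
worldToVoxel <- function(grid, point_mm) {
    idx <- as.integer(round((as.numeric(point_mm) - grid@origin) /
                            grid@spacing)) + 1L
    if (any(idx < 1L) || any(idx > grid@shape))
        stop("point (", paste(signif(point_mm, 6), collapse = ", "),
             ") mm falls outside the image grid", call. = FALSE)
    idx
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(grid, index)
    grid@origin + (as.numeric(index) - 1) * grid@spacing

setMethod("show", "VoxelGrid", function(object) {
    cat(sprintf("VoxelGrid %d x %d x %d voxels, spacing (%g, %g, %g) mm, voxel %g cm3\n",
                object@shape[1], object@shape[2], object@shape[3],
                object@spacing[1], object@spacing[2], object@spacing[3],
                voxelVolume(object)))
})
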