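#' SUV thresholding
#'
#' Marks every voxel whose SUV is greater than or equal to the threshold
#' ("at least 4" is inclusive).
#'
#' @param pet a [PETVolume-class].
#' @param suvMin SUV threshold (> 0); default 4.0, the benchmark value.
#' @return a binary [MaskVolume-class] (1 where SUV >= \code{suvMin}).
#' @export
thresholdMask <- function(pet, suvMin = 4.0) {
    stopifnot(is(pet, "PETVolume"))
    if (!isTRUE(suvMin > 0)) stop("suvMin must be > 0", call. = FALSE)
    MaskVolume(pet@values >= suvMin, pet@grid)
}

# Label statistics + relabeling in decreasing volume order (ties broken by
# original scan-order label), shared by every operation that rebuilds a
# ComponentSet from a label array.
.component_set <- function(labels_arr, pet, suvMin, connectivity) {
    grid <- pet@grid
    dims <- grid@shape
    idx <- which(labels_arr > 0L)
    if (length(idx) == 0L) {
        comp <- data.frame(label = integer(), voxel_count = integer(),
                           volume_cm3 = numeric(), suv_max = numeric(),
                           centroid_x = numeric(), centroid_y = numeric(),
                           centroid_z = numeric(),
                           x0 = integer(), x1 = integer(), y0 = integer(),
                           y1 = integer(), z0 = integer(), z1 = integer())
        return(new("ComponentSet",
                   mask = MaskVolume(array(0L, dims), grid),
                   components = comp, source = pet,
                   suvMin = suvMin, connectivity = as.integer(connectivity)))
    }
    lab <- labels_arr[idx]
    k <- max(lab)
    counts <- tabulate(lab, nbins = k)
    keep <- which(counts > 0L)
    # order: decreasing voxel count, then original label
    ord <- keep[order(-counts[keep], keep)]
    newlab <- integer(k)
    newlab[ord] <- seq_along(ord)

    i0 <- idx - 1L
    ix <- i0 %% dims[1] + 1L
    iy <- (i0 %/% dims[1]) %% dims[2] + 1L
    iz <- i0 %/% (dims[1] * dims[2]) + 1L
    vals <- pet@values[idx]
    lab2 <- newlab[lab]

    n <- length(ord)
    f <- factor(lab2, levels = seq_len(n))
    vc <- as.integer(table(f))
    suv_max <- as.numeric(tapply(vals, f, max))
    cx <- as.numeric(tapply(ix, f, mean))
    cy <- as.numeric(tapply(iy, f, mean))
    cz <- as.numeric(tapply(iz, f, mean))
    comp <- data.frame(
        label = seq_len(n),
        voxel_count = vc,
        volume_cm3 = vc * voxelVolume(grid),
        suv_max = suv_max,
        centroid_x = grid@origin[1] + (cx - 1) * grid@spacing[1],
        centroid_y = grid@origin[2] + (cy - 1) * grid@spacing[2],
        centroid_z = grid@origin[3] + (cz - 1) * grid@spacing[3],
        x0 = as.integer(tapply(ix, f, min)),
        x1 = as.integer(tapply(ix, f, max)),
        y0 = as.integer(tapply(iy, f, min)),
        y1 = as.integer(tapply(iy, f, max)),
        z0 = as.integer(tapply(iz, f, min)),
        z1 = as.integer(tapply(iz, f, max)))

    out <- array(0L, dims)
    out[idx] <- lab2
    new("ComponentSet", mask = MaskVolume(out, grid), components = comp,
        source = pet, suvMin = suvMin,
        connectivity = as.integer(connectivity))
}

# Raw 3-D labeling of a binary array; returns an integer array.
.label_array <- function(bin_arr, dims, connectivity) {
    labs <- .cc_label_cpp(as.integer(bin_arr), as.integer(dims),
                          as.integer(connectivity))
    array(labs, dims)
}

#' 3-D connected-component labeling
#'
#' Partitions the foreground of a binary mask into maximal connected
#' regions under 6- (face), 18- (face+edge) or 26- (face+edge+corner)
#' neighbor adjacency and computes per-component statistics from the paired
#' PET volume. Components are labeled in decreasing volume order.
#'
#' @param mask a binary [MaskVolume-class].
#' @param pet the [PETVolume-class] the mask was derived from (same grid).
#' @param connectivity 6, 18 or 26 (default 26, the common choice in
#'   SUV-threshold MTV tools).
#' @param suvMin the threshold that produced \code{mask} (recorded on the
#'   result).
#' @return a [ComponentSet-class].
#' @export
labelComponents <- function(mask, pet, connectivity = 26, suvMin = 4.0) {
    stopifnot(is(mask, "MaskVolume"), is(pet, "PETVolume"))
    if (!connectivity %in% c(6, 18, 26))
        stop("connectivity must be 6, 18 or 26", call. = FALSE)
    if (!identical(mask@grid@shape, pet@grid@shape))
        stop("mask and PET grids differ", call. = FALSE)
    if (any(mask@labels > 1L))
        stop("labelComponents expects a binary mask", call. = FALSE)
    labs <- .label_array(mask@labels, mask@grid@shape, connectivity)
    .component_set(labs, pet, suvMin, connectivity)
}

#' Minimum-volume filtering of components
#'
#' Retains exactly the components whose volume is at least
#' \code{minVolume} cm3 (inclusive, matching the "volume of at least 3 cm3"
#' rule); survivors keep their voxel regions and are relabeled in
#' decreasing volume order.
#'
#' @param cs a [ComponentSet-class].
#' @param minVolume minimum volume in cm3 (default 3.0, the benchmark
#'   value); 0 is the identity.
#' @return a filtered [ComponentSet-class].
#' @export
filterComponents <- function(cs, minVolume = 3.0) {
    stopifnot(is(cs, "ComponentSet"))
    if (!isTRUE(minVolume >= 0)) stop("minVolume must be >= 0", call. = FALSE)
    comp <- cs@components
    drop <- comp$label[comp$volume_cm3 < minVolume]
    if (!length(drop)) return(cs)
    labs <- cs@mask@labels
    labs[labs %in% drop] <- 0L
    .component_set(labs, cs@source, cs@suvMin, cs@connectivity)
}

#' Automated lesion preselection
#'
#' The benchmark's automated first step: threshold at SUV >= \code{suvMin},
#' label connected components, and keep those of at least
#' \code{minVolume} cm3. Physiologic uptake (brain, bladder, ...) is *not*
#' excluded here — removal is a later, interactive workflow step.
#'
#' @param pet a [PETVolume-class].
#' @param suvMin SUV threshold (default 4.0).
#' @param minVolume minimum component volume in cm3 (default 3.0).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return a [ComponentSet-class] of candidate lesions.
#' @seealso [runWorkflow()] for the full four-stage protocol.
#' @export
preselect <- function(pet, suvMin = 4.0, minVolume = 3.0, connectivity = 26) {
    filterComponents(
        labelComponents(thresholdMask(pet, suvMin), pet,
                        connectivity = connectivity, suvMin = suvMin),
        minVolume)
}

#' @rdname tmtv
#' @export
setMethod("tmtv", "ComponentSet", function(object, ...)
    sum(object@components$volume_cm3))

#' @rdname componentTable
#' @export
setMethod("componentTable", "ComponentSet", function(object)
    object@components)

#' Segmentation parameters of a component set
#' @param cs a [ComponentSet-class].
#' @return named list with suv_min and connectivity.
#' @export
segmentationParams <- function(cs)
    list(suv_min = cs@suvMin, connectivity = cs@connectivity)

setMethod("show", "ComponentSet", function(object) {
    cat(sprintf("ComponentSet: %d component(s), TMTV %.1f cm3 (SUV >= %g, %d-connectivity)\n",
                nrow(object@components), tmtv(object), object@suvMin,
                object@connectivity))
    if (nrow(object@components)) {
        tab <- utils::head(object@components[, c("label", "voxel_count",
                                                 "volume_cm3", "suv_max")], 8)
        print(tab, row.names = FALSE)
        if (nrow(object@components) > 8) cat("  ...\n")
    }
})
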