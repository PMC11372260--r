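#' Construct a PET volume
#'
#' @param values 3-D numeric array of SUV values. Negative values are
#'   clamped to 0 with a warning (negative SUV is reconstruction noise).
#' @param grid a [VoxelGrid-class] matching \code{dim(values)}.
#' @param meta optional named list of provenance metadata (\code{case_id},
#'   \code{subtype} in HL/FL/DLBCL, \code{reader_id}).
#' @return a [PETVolume-class].
#' @export
PETVolume <- function(values, grid, meta = list()) {
    values <- as.array(values)
    storage.mode(values) <- "double"
    if (any(values < 0, na.rm = TRUE)) {
        warning("clamping ", sum(values < 0), " negative SUV values to 0")
        values[values < 0] <- 0
    }
    new("PETVolume", grid = grid, values = values, meta = meta)
}

#' Construct a mask volume
#'
#' @param labels 3-D array of non-negative integer labels (0 = background);
#'   logical arrays are accepted and converted to 0/1.
#' @param grid a [VoxelGrid-class] matching \code{dim(labels)}.
#' @return a [MaskVolume-class].
#' @export
MaskVolume <- function(labels, grid) {
    labels <- as.array(labels)
    storage.mode(labels) <- "integer"
    new("MaskVolume", grid = grid, labels = labels)
}

#' SUV values / mask labels accessors
#' @param x a [PETVolume-class] or [MaskVolume-class].
#' @return the underlying 3-D array.
#' @export
suvValues <- function(x) {
    stopifnot(is(x, "PETVolume"))
    x@values
}

#' @rdname suvValues
#' @export
maskLabels <- function(x) {
    stopifnot(is(x, "MaskVolume"))
    x@labels
}

#' Provenance metadata accessor
#' @param x a [PETVolume-class].
#' @return named list.
#' @export
volumeMeta <- function(x) x@meta

.grid_from_nifti <- function(img) {
    sp <- unname(RNifti::pixdim(img))[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
        stop("non-positive voxel spacing in NIfTI header", call. = FALSE)
    xf <- RNifti::xform(img)
    VoxelGrid(dim(img)[1:3], sp, unname(xf[1:3, 4]))
}

#' Read a PET or mask volume from a NIfTI-1 file
#'
#' Volumes are reoriented to the internal RAS+ axis convention on load;
#' spacing and origin are taken from the file header. PET values are
#' interpreted as SUV; negative values are clamped to 0 with a warning.
#'
#' @param path a readable .nii or .nii.gz file with 3 spatial dimensions.
#' @param mask logical; read as an integer label mask instead of SUV.
#' @return a [PETVolume-class] or [MaskVolume-class]. If a JSON sidecar
#'   \code{<path minus extension>.json} exists, its fields are attached as
#'   metadata (PET only).
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, mask = FALSE) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
        stop("expected a 3-D volume, got ", length(d), " dimensions",
             call. = FALSE)
    if (!is.na(RNifti::orientation(img)) &&
        RNifti::orientation(img) != "RAS")
        RNifti::orientation(img) <- "RAS"
    grid <- .grid_from_nifti(img)
    arr <- array(as.numeric(img), dim = d)
    if (mask)
        return(MaskVolume(arr, grid))
    meta <- list()
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (side != path && file.exists(side))
        meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    PETVolume(arr, grid, meta = meta)
}

#' Write a PET or mask volume to a NIfTI-1 file
#'
#' PET volumes are stored as float32, masks as unsigned 16-bit integers;
#' the header carries the grid geometry (RAS+ sform/qform).
#'
#' @param vol a [PETVolume-class] or [MaskVolume-class].
#' @param path output .nii or .nii.gz path.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
    is_mask <- is(vol, "MaskVolume")
    arr <- if (is_mask) vol@labels else vol@values
    grid <- vol@grid
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- grid@spacing
    xf <- diag(4)
    diag(xf)[1:3] <- grid@spacing
    xf[1:3, 4] <- grid@origin
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::sform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint16" else "float")
    invisible(path)
}

#' Body-weight SUV from activity concentration
#'
#' Converts an activity concentration to a body-weight standardized uptake
#' value, decay-correcting the net injected dose to scan time:
#' \deqn{SUV = c \cdot w \cdot 1000 / (D_{net} \cdot 2^{-t/T_{1/2}})}
#' with \eqn{c} in kBq/mL, \eqn{w} body weight in kg, \eqn{D_{net}} the net
#' dose (injected minus residual) in kBq, \eqn{t} the uptake time and
#' \eqn{T_{1/2}} the isotope half-life in minutes (109.77 for 18F).
#'
#' @param conc activity concentration in kBq/mL; scalar or array (an array
#'   in yields an array out).
#' @param injectedDoseMBq,residualDoseMBq injected and residual dose, MBq.
#' @param uptakeMin minutes between injection and acquisition.
#' @param halfLifeMin isotope half-life in minutes (default 18F).
#' @param weightKg patient body weight in kg.
#' @return SUV (dimensionless), same shape as \code{conc}.
#' @examples
#' suvFromActivity(5, 185, 0, uptakeMin = 60, weightKg = 70)  # ~2.76
#' @export
suvFromActivity <- function(conc, injectedDoseMBq, residualDoseMBq = 0,
                            uptakeMin, halfLifeMin = 109.77, weightKg) {
    net <- injectedDoseMBq - residualDoseMBq
    if (!isTRUE(weightKg > 0)) stop("weight must be > 0", call. = FALSE)
    if (!isTRUE(net > 0)) stop("net dose must be > 0", call. = FALSE)
    if (!isTRUE(halfLifeMin > 0)) stop("half-life must be > 0", call. = FALSE)
    decayed_kBq <- net * 1000 * 2^(-uptakeMin / halfLifeMin)
    conc * (weightKg * 1000) / decayed_kBq
}

setMethod("show", "PETVolume", function(object) {
    cat("PETVolume (SUV)\n")
    show(object@grid)
    cat(sprintf("  SUV range [%.3g, %.3g]\n", min(object@values),
                max(object@values)))
    if (length(object@meta))
        cat("  meta:", paste(names(object@meta), unlist(object@meta),
                             sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MaskVolume", function(object) {
    labs <- unique(as.vector(object@labels))
    cat("MaskVolume\n")
    show(object@grid)
    cat(sprintf("  %d distinct non-zero labels, %d foreground voxels\n",
                length(setdiff(labs, 0L)), sum(object@labels != 0L)))
})
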