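#' @import methods
NULL

#' Voxel grid geometry
#'
#' Describes the geometry shared by a PET volume and any mask paired with
#' it: array shape, voxel spacing and the world-space position of the first
#' voxel center. World coordinates are in millimetres in a fixed RAS+ frame
#' (x increases to the patient's right, y anterior, z superior); voxel
#' \code{(i, j, k)} (1-based) has its center at
#' \code{origin + (c(i, j, k) - 1) * spacing}.
#'
#' @slot shape integer(3), number of voxels along x, y, z (each >= 1).
#' @slot spacing numeric(3), voxel spacing in mm (each > 0).
#' @slot origin numeric(3), world coordinates (mm) of the first voxel center.
#'
#' @seealso [VoxelGrid()], [voxelVolume()], [worldToVoxel()]
#' @export
setClass("VoxelGrid",
    representation(shape = "integer", spacing = "numeric", origin = "numeric"),
    prototype(shape = c(1L, 1L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("VoxelGrid", function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(is.na(object@shape)))
        msg <- c(msg, "shape must be an integer triple")
    else if (any(object@shape < 1L))
        msg <- c(msg, "all shape components must be >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)))
        msg <- c(msg, "spacing must be a finite numeric triple")
    else if (any(object@spacing <= 0))
        msg <- c(msg, "all spacing components must be > 0")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be a finite numeric triple")
    if (length(msg)) msg else TRUE
})

#' PET volume in SUV units
#'
#' A 3-D scalar field of body-weight-normalized standardized uptake values
#' (SUV, dimensionless) with its voxel geometry. Values are finite and
#' non-negative; negative reconstruction noise is clamped on load.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot values 3-D numeric array, one SUV per voxel.
#' @slot meta named list of optional provenance metadata
#'   (\code{case_id}, \code{subtype}, \code{reader_id}).
#'
#' @seealso [PETVolume()], [readVolume()], [preselect()]
#' @export
setClass("PETVolume",
    representation(grid = "VoxelGrid", values = "array", meta = "list"))

setValidity("PETVolume", function(object) {
    msg <- character()
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
        msg <- c(msg, "values array dimensions must equal grid shape")
    if (anyNA(object@values) || any(!is.finite(object@values)))
        msg <- c(msg, "SUV values must be finite")
    else if (any(object@values < 0))
        msg <- c(msg, "SUV values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Label / binary mask volume
#'
#' Non-negative integer labels over a voxel grid; 0 is background. A binary
#' mask uses labels {0, 1}; a component mask uses 1..K.
#'
#' @slot grid a [VoxelGrid-class]; must equal the paired PET volume's grid.
#' @slot labels 3-D integer array of non-negative labels.
#'
#' @seealso [MaskVolume()], [thresholdMask()], [labelComponents()]
#' @export
setClass("MaskVolume",
    representation(grid = "VoxelGrid", labels = "array"))

setValidity("MaskVolume", function(object) {
    msg <- character()
    if (!identical(dim(object@labels), as.integer(object@grid@shape)))
        msg <- c(msg, "labels array dimensions must equal grid shape")
    if (!is.integer(object@labels))
        msg <- c(msg, "labels must be stored as integers")
    else if (anyNA(object@labels) || any(object@labels < 0L))
        msg <- c(msg, "labels must be non-negative and non-missing")
    if (length(msg)) msg else TRUE
})

#' Set of labeled connected components
#'
#' The result of thresholding a PET volume and labeling its connected
#' regions: a label mask plus one row of summary statistics per component
#' (voxel count, volume in cm3, SUVmax, world-space centroid, bounding box).
#' Components are labeled in decreasing volume order.
#'
#' @slot mask a [MaskVolume-class] whose labels index the component table.
#' @slot components data.frame with columns \code{label}, \code{voxel_count},
#'   \code{volume_cm3}, \code{suv_max}, \code{centroid_x/y/z} (mm) and
#'   integer bounding-box columns \code{x0,x1,y0,y1,z0,z1}.
#' @slot source the [PETVolume-class] the components were measured on.
#' @slot suvMin SUV threshold that produced the segmentation.
#' @slot connectivity 6, 18 or 26.
#'
#' @seealso [preselect()], [tmtv()], [componentTable()]
#' @export
setClass("ComponentSet",
    representation(mask = "MaskVolume", components = "data.frame",
                   source = "PETVolume", suvMin = "numeric",
                   connectivity = "integer"))

setValidity("ComponentSet", function(object) {
    msg <- character()
    labs <- sort(unique(as.vector(object@mask@labels)))
    labs <- labs[labs != 0L]
    if (!identical(labs, sort(as.integer(object@components$label))))
        msg <- c(msg, "mask labels must be exactly {0} union component labels")
    if (!object@connectivity %in% c(6L, 18L, 26L))
        msg <- c(msg, "connectivity must be 6, 18 or 26")
    if (nrow(object@components)) {
        counts <- tabulate(object@mask@labels, nbins = max(labs))
        if (!all(object@components$voxel_count ==
                 counts[object@components$label]))
            msg <- c(msg, "component voxel counts inconsistent with mask")
    }
    if (length(msg)) msg else TRUE
})

#' Reader interaction session
#'
#' An ordered, staged list of reader interactions that makes a TMTV
#' measurement reproducible: single-click removals of physiologic uptake
#' (stage 1) and reactive spleen/marrow uptake (stage 2), manual edit masks
#' (stage 3) and seed clicks adding lesions (stage 4), together with the
#' segmentation parameters.
#'
#' @slot caseId,readerId character identifiers.
#' @slot suvMin,minVolume numeric segmentation parameters (SUV threshold,
#'   minimum component volume in cm3).
#' @slot connectivity integer, 6/18/26.
#' @slot interactions list of interactions as built by [removeClick()],
#'   [editMask()] and [addSeed()].
#'
#' @seealso [Session()], [runWorkflow()], [readSession()]
#' @export
setClass("Session",
    representation(caseId = "character", readerId = "character",
                   suvMin = "numeric", minVolume = "numeric",
                   connectivity = "integer", interactions = "list"))

.INTERACTION_KINDS <- c("remove_click", "edit_mask", "add_seed")
.KIND_STAGES <- list(remove_click = c(1L, 2L), edit_mask = 3L, add_seed = 4L)

setValidity("Session", function(object) {
    msg <- character()
    for (ia in object@interactions) {
        if (!is.list(ia) || is.null(ia$kind) || is.null(ia$stage)) {
            msg <- c(msg, "each interaction needs a kind and a stage")
            break
        }
        if (!ia$kind %in% .INTERACTION_KINDS)
            msg <- c(msg, sprintf("unknown interaction kind '%s'", ia$kind))
        else if (!ia$stage %in% .KIND_STAGES[[ia$kind]])
            msg <- c(msg, sprintf("kind '%s' is not allowed at stage %d",
                                  ia$kind, ia$stage))
        if (ia$kind %in% c("remove_click", "add_seed") &&
            (is.null(ia$point_mm) || length(ia$point_mm) != 3L))
            msg <- c(msg, "clicks and seeds need a point_mm triple")
        if (identical(ia$kind, "edit_mask") &&
            is.null(ia$mask) && is.null(ia$mask_path))
            msg <- c(msg, "edit_mask needs a mask or a mask_path")
    }
    stages <- vapply(object@interactions, function(x) as.integer(x$stage), 1L)
    if (length(stages) && is.unsorted(stages))
        msg <- c(msg, "interactions must be sorted by stage")
    if (length(msg)) msg else TRUE
})

#' Result of the four-stage TMTV workflow
#'
#' Holds the TMTV recorded after each stage (TMTV1..TMTV4, cm3), the
#' component set after each stage (stage 0 is the raw preselection), and a
#' log of applied and failed interactions. Stage semantics guarantee
#' TMTV3 <= TMTV2 <= TMTV1 and TMTV4 >= TMTV3.
#'
#' @slot tmtvByStage named numeric(4): TMTV1..TMTV4 in cm3.
#' @slot stageSets list of five [ComponentSet-class]s (preselection then
#'   stages 1-4).
#' @slot log data.frame of interactions with columns \code{stage},
#'   \code{kind}, \code{status}, \code{message}.
#' @slot session the [Session-class] that was replayed.
#'
#' @seealso [runWorkflow()], [tmtvByStage()]
#' @export
setClass("WorkflowResult",
    representation(tmtvByStage = "numeric", stageSets = "list",
                   log = "data.frame", session = "Session"))

setValidity("WorkflowResult", function(object) {
    v <- object@tmtvByStage
    msg <- character()
    if (length(v) != 4L ||
        !identical(names(v), c("TMTV1", "TMTV2", "TMTV3", "TMTV4")))
        msg <- c(msg, "tmtvByStage must be named TMTV1..TMTV4")
    else {
        eps <- 1e-9
        if (v["TMTV2"] > v["TMTV1"] + eps || v["TMTV3"] > v["TMTV2"] + eps)
            msg <- c(msg, "stages 2-3 may only remove volume")
        if (v["TMTV4"] < v["TMTV3"] - eps)
            msg <- c(msg, "stage 4 may only add volume")
    }
    if (length(msg)) msg else TRUE
})

#' Organ specification for the digital phantom
#'
#' One analytic shape painted into the phantom with a uniform SUV. Roles
#' mirror how a reader treats the structure: \code{lesion} (tumor),
#' \code{physiologic} (brain, bladder, kidney, myocardium...),
#' \code{reference_tissue} (liver) or \code{background}.
#'
#' @slot name character organ name (unique within a phantom).
#' @slot role one of lesion / physiologic / reference_tissue / background.
#' @slot shape sphere, ellipsoid, box or tube.
#' @slot center numeric(3) mm (for tube: first endpoint).
#' @slot radii numeric, shape parameters in mm: sphere radius (1), ellipsoid
#'   semi-axes (3), box half-widths (3), tube radius (1).
#' @slot end numeric(3) mm, second endpoint (tube only; NA otherwise).
#' @slot suv uniform SUV painted inside the shape.
#' @slot paintOrder integer; where shapes overlap the higher order wins.
#'
#' @seealso [organSpec()], [phantomSpec()], [rasterizePhantom()]
#' @export
setClass("OrganSpec",
    representation(name = "character", role = "character", shape = "character",
                   center = "numeric", radii = "numeric", end = "numeric",
                   suv = "numeric", paintOrder = "integer"))

setValidity("OrganSpec", function(object) {
    msg <- character()
    if (!object@role %in% c("lesion", "physiologic", "reference_tissue",
                            "background"))
        msg <- c(msg, "invalid organ role")
    if (!object@shape %in% c("sphere", "ellipsoid", "box", "tube"))
        msg <- c(msg, "invalid organ shape")
    if (any(object@radii <= 0)) msg <- c(msg, "radii must be > 0")
    if (object@suv < 0) msg <- c(msg, "suv must be >= 0")
    nrad <- c(sphere = 1L, ellipsoid = 3L, box = 3L, tube = 1L)
    if (object@shape %in% names(nrad) &&
        length(object@radii) != nrad[[object@shape]])
        msg <- c(msg, sprintf("shape '%s' needs %d radii", object@shape,
                              nrad[[object@shape]]))
    if (identical(object@shape, "tube") && any(is.na(object@end)))
        msg <- c(msg, "tube needs an end point")
    if (length(msg)) msg else TRUE
})

#' Digital phantom specification
#'
#' A voxel grid, a uniform background SUV, a list of organs, and optional
#' image degradation (Gaussian point-spread blur and additive Gaussian
#' noise) applied after the ground-truth masks are recorded.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot backgroundSuv uniform SUV outside all organs.
#' @slot organs list of [OrganSpec-class].
#' @slot psfFwhm Gaussian PSF full width at half maximum, mm (0 = none).
#' @slot noiseSd additive Gaussian noise standard deviation, SUV (0 = none).
#' @slot seed integer random seed for the noise.
#'
#' @seealso [phantomSpec()], [rasterizePhantom()], [phantomScenario()]
#' @export
setClass("PhantomSpec",
    representation(grid = "VoxelGrid", backgroundSuv = "numeric",
                   organs = "list", psfFwhm = "numeric", noiseSd = "numeric",
                   seed = "integer"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (object@backgroundSuv < 0) msg <- c(msg, "backgroundSuv must be >= 0")
    if (object@psfFwhm < 0) msg <- c(msg, "psfFwhm must be >= 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (!all(vapply(object@organs, is, TRUE, class2 = "OrganSpec")))
        msg <- c(msg, "organs must be OrganSpec objects")
    nm <- vapply(object@organs, function(o) o@name, "")
    if (anyDuplicated(nm)) msg <- c(msg, "organ names must be unique")
    if (length(msg)) msg else TRUE
})

#' Maximum-intensity projection image
#'
#' A 2-D projection of a PET volume (or mask) along one anatomical axis:
#' each pixel is the maximum voxel value along the collapsed axis.
#'
#' @slot values numeric matrix (first retained axis by second retained axis).
#' @slot plane "coronal" (collapse y), "sagittal" (collapse x) or
#'   "axial" (collapse z).
#' @slot pixelSpacing numeric(2), mm spacing of the retained axes.
#'
#' @seealso [mip()], [renderMip()]
#' @export
setClass("ProjectionImage",
    representation(values = "matrix", plane = "character",
                   pixelSpacing = "numeric"))

setValidity("ProjectionImage", function(object) {
    msg <- character()
    if (!object@plane %in% c("coronal", "sagittal", "axial"))
        msg <- c(msg, "plane must be coronal, sagittal or axial")
    if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
        msg <- c(msg, "pixelSpacing must be two positive numbers")
    if (length(msg)) msg else TRUE
})
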