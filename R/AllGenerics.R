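#' Total metabolic tumor volume
#'
#' Sum of the volumes (cm3) of all segmented components. For a
#' [WorkflowResult-class], returns the stage-4 (final) TMTV by default.
#'
#' @param object a [ComponentSet-class] or [WorkflowResult-class].
#' @param ... further arguments; for workflow results, \code{stage}
#'   (1-4) selects the stage.
#' @return TMTV in cm3 (0 for an empty set).
#' @examples
#' pet <- PETVolume(array(5, c(4, 4, 4)), VoxelGrid(c(4L, 4L, 4L), c(10, 10, 10)))
#' tmtv(preselect(pet))  # whole 4x4x4 cm volume = 64 cm3... at 1 cm voxels
#' @export
setGeneric("tmtv", function(object, ...) standardGeneric("tmtv"))

#' Component summary table
#'
#' @param object a [ComponentSet-class].
#' @return data.frame with one row per component: \code{label},
#'   \code{voxel_count}, \code{volume_cm3}, \code{suv_max},
#'   \code{centroid_x/y/z}, bounding box columns.
#' @export
setGeneric("componentTable",
           function(object) standardGeneric("componentTable"))

#' Voxel grid accessor
#' @param object an object carrying a [VoxelGrid-class].
#' @return the grid.
#' @export
setGeneric("imageGrid", function(object) standardGeneric("imageGrid"))

#' Volume of one voxel in cm3
#' @param object a [VoxelGrid-class] or an object carrying one.
#' @return voxel volume in cm3.
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))

#' TMTV recorded after each workflow stage
#' @param object a [WorkflowResult-class].
#' @return named numeric(4): TMTV1..TMTV4 in cm3.
#' @export
setGeneric("tmtvByStage", function(object) standardGeneric("tmtvByStage"))

#' Component set after a workflow stage
#' @param object a [WorkflowResult-class].
#' @param stage 0 (raw preselection) to 4.
#' @return a [ComponentSet-class].
#' @export
setGeneric("stageComponents",
           function(object, stage) standardGeneric("stageComponents"))

#' Log of applied and failed interactions
#' @param object a [WorkflowResult-class].
#' @return data.frame with columns stage, kind, status, message.
#' @export
setGeneric("interactionLog",
           function(object) standardGeneric("interactionLog"))
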