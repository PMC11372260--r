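#' Reader interactions
#'
#' Builders for the three interaction kinds of the four-stage protocol:
#' \describe{
#'   \item{removeClick}{stage 1 or 2; a single click deleting the whole
#'     component under the point (physiologic uptake at stage 1, reactive
#'     spleen/bone marrow at stage 2).}
#'   \item{editMask}{stage 3; a binary mask of voxels to erase from the
#'     segmentation (physiologic uptake fused with tumor, e.g. ureter and
#'     retroperitoneal nodes).}
#'   \item{addSeed}{stage 4; a click adding the full connected SUV >=
#'     threshold region under the point, with no minimum volume.}
#' }
#'
#' @param stage workflow stage (removeClick only: 1 or 2).
#' @param point_mm numeric(3) world coordinates of the click/seed in mm.
#' @param mask a binary [MaskVolume-class] of voxels to remove (editMask).
#' @param mask_path path to a NIfTI mask, used when \code{mask} is NULL.
#' @param note free-text annotation.
#' @return a list describing the interaction, for use in [Session()].
#' @export
removeClick <- function(point_mm, stage = 1, note = "")
    list(kind = "remove_click", stage = as.integer(stage),
         point_mm = as.numeric(point_mm), note = note)

#' @rdname removeClick
#' @export
editMask <- function(mask = NULL, mask_path = NULL, note = "")
    list(kind = "edit_mask", stage = 3L, mask = mask, mask_path = mask_path,
         note = note)

#' @rdname removeClick
#' @export
addSeed <- function(point_mm, note = "")
    list(kind = "add_seed", stage = 4L, point_mm = as.numeric(point_mm),
         note = note)

#' Construct a reader session
#'
#' @param caseId,readerId character identifiers.
#' @param interactions list of interactions from [removeClick()],
#'   [editMask()], [addSeed()]; must be ordered by stage.
#' @param suvMin,minVolume,connectivity segmentation parameters; the
#'   defaults (4.0 SUV, 3.0 cm3, 26) are the benchmark method's.
#' @return a [Session-class].
#' @export
Session <- function(caseId = "case", readerId = "reader",
                    interactions = list(), suvMin = 4.0, minVolume = 3.0,
                    connectivity = 26) {
    new("Session", caseId = caseId, readerId = readerId,
        suvMin = suvMin, minVolume = minVolume,
        connectivity = as.integer(connectivity),
        interactions = interactions)
}

#' Session accessors
#' @param session a [Session-class].
#' @return interactions list / parameter list.
#' @export
sessionInteractions <- function(session) session@interactions

#' @rdname sessionInteractions
#' @export
sessionParams <- function(session)
    list(suv_min = session@suvMin, min_volume_cm3 = session@minVolume,
         connectivity = session@connectivity)

setMethod("show", "Session", function(object) {
    stages <- vapply(object@interactions, function(x) x$stage, 1L)
    cat(sprintf("Session %s / %s: %d interaction(s) [stages: %s]; SUV >= %g, >= %g cm3, %d-conn\n",
                object@caseId, object@readerId, length(object@interactions),
                if (length(stages)) paste(stages, collapse = ",") else "-",
                object@suvMin, object@minVolume, object@connectivity))
})

#' Write / read a session as JSON
#'
#' The on-disk schema is
#' \preformatted{{"case_id", "reader_id",
#'   "params": {"suv_min", "min_volume_cm3", "connectivity"},
#'   "interactions": [{"kind", "stage", "point_mm" | "mask_path", "note"}]}}
#' In-memory edit masks are written as NIfTI files next to the JSON
#' (\code{<case_id>_edit<k>.nii.gz}) and referenced by relative path;
#' relative \code{mask_path}s are resolved against the JSON's directory on
#' read.
#'
#' @param session a [Session-class].
#' @param path JSON file path.
#' @return `writeSession`: \code{path} invisibly; `readSession`: a
#'   [Session-class].
#' @export
writeSession <- function(session, path) {
    dir <- dirname(path)
    k <- 0L
    ias <- lapply(session@interactions, function(ia) {
        if (identical(ia$kind, "edit_mask") && !is.null(ia$mask)) {
            k <<- k + 1L
            fn <- sprintf("%s_edit%d.nii.gz", session@caseId, k)
            writeVolume(ia$mask, file.path(dir, fn))
            ia$mask_path <- fn
            ia$mask <- NULL
        }
        ia[!vapply(ia, is.null, TRUE)]
    })
    obj <- list(case_id = session@caseId, reader_id = session@readerId,
                params = sessionParams(session), interactions = ias)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    dir <- dirname(path)
    ias <- lapply(obj$interactions, function(ia) {
        ia$stage <- as.integer(ia$stage)
        if (!is.null(ia$point_mm)) ia$point_mm <- as.numeric(unlist(ia$point_mm))
        if (!is.null(ia$mask_path) && !file.exists(ia$mask_path) &&
            file.exists(file.path(dir, ia$mask_path)))
            ia$mask_path <- file.path(dir, ia$mask_path)
        if (is.null(ia$note)) ia$note <- ""
        ia
    })
    p <- obj$params
    Session(caseId = obj$case_id, readerId = obj$reader_id,
            interactions = ias,
            suvMin = if (is.null(p$suv_min)) 4.0 else p$suv_min,
            minVolume = if (is.null(p$min_volume_cm3)) 3.0 else p$min_volume_cm3,
            connectivity = if (is.null(p$connectivity)) 26L else p$connectivity)
}

#' Remove the component under a click
#'
#' Deletes the entire connected component containing the clicked world
#' point; the TMTV decreases by exactly that component's volume. Exact
#' containment is required — a click on background is an error, never
#' snapped to the nearest component.
#'
#' @param cs a [ComponentSet-class].
#' @param point_mm numeric(3) world click position in mm.
#' @return the [ComponentSet-class] without that component.
#' @export
removeComponentAt <- function(cs, point_mm) {
    idx <- worldToVoxel(cs@mask@grid, point_mm)
    lab <- cs@mask@labels[idx[1], idx[2], idx[3]]
    if (lab == 0L)
        stop("no component at click (", paste(signif(point_mm, 6),
             collapse = ", "), ") mm", call. = FALSE)
    labs <- cs@mask@labels
    labs[labs == lab] <- 0L
    .component_set(labs, cs@source, cs@suvMin, cs@connectivity)
}

#' Erase voxels with a manual edit mask
#'
#' Deletes every segmented voxel marked in \code{remove}; remaining voxels
#' are relabeled, so a component cut in two becomes two components.
#' Remaining fragments are retained regardless of size: the 3 cm3 minimum
#' applies only at automated preselection, and re-filtering here would
#' silently delete tumor the reader chose to keep.
#'
#' @param cs a [ComponentSet-class].
#' @param remove a binary [MaskVolume-class] on the same grid.
#' @return the edited [ComponentSet-class].
#' @export
applyEditMask <- function(cs, remove) {
    stopifnot(is(remove, "MaskVolume"))
    if (!identical(remove@grid@shape, cs@mask@grid@shape))
        stop("edit mask grid does not match the segmentation grid",
             call. = FALSE)
    keep <- (cs@mask@labels > 0L) & (remove@labels == 0L)
    labs <- .label_array(keep, cs@mask@grid@shape, cs@connectivity)
    .component_set(labs, cs@source, cs@suvMin, cs@connectivity)
}

#' Add a lesion with a seed click
#'
#' Adds the full connected region of SUV >= threshold voxels containing the
#' seed (same connectivity as preselection), with no minimum volume. A
#' region that overlaps the existing segmentation is merged by union; a
#' seed on a voxel below the threshold is an error.
#'
#' @param cs a [ComponentSet-class].
#' @param point_mm numeric(3) world seed position in mm.
#' @param pet the source [PETVolume-class]; defaults to the volume the set
#'   was segmented from.
#' @return the [ComponentSet-class] including the added region.
#' @export
addLesionAt <- function(cs, point_mm, pet = NULL) {
    if (is.null(pet)) pet <- cs@source
    idx <- worldToVoxel(pet@grid, point_mm)
    if (pet@values[idx[1], idx[2], idx[3]] < cs@suvMin)
        stop(sprintf("seed below threshold: SUV %.2f < %.2f at (%s) mm",
                     pet@values[idx[1], idx[2], idx[3]], cs@suvMin,
                     paste(signif(point_mm, 6), collapse = ", ")),
             call. = FALSE)
    thr <- .label_array(pet@values >= cs@suvMin, pet@grid@shape,
                        cs@connectivity)
    region <- thr == thr[idx[1], idx[2], idx[3]]
    merged <- region | (cs@mask@labels > 0L)
    labs <- .label_array(merged, pet@grid@shape, cs@connectivity)
    .component_set(labs, pet, cs@suvMin, cs@connectivity)
}

#' Run the four-stage TMTV measurement workflow
#'
#' Replays a reader session on a PET volume: automated preselection
#' (SUV >= \code{suvMin}, volume >= \code{minVolume} cm3), then
#' \describe{
#'   \item{TMTV1}{after stage-1 single-click removal of physiologic uptake
#'     (brain, bladder, ...).}
#'   \item{TMTV2}{after stage-2 removal of reactive bone marrow and spleen
#'     uptake.}
#'   \item{TMTV3}{after stage-3 manual edit masks.}
#'   \item{TMTV4}{after stage-4 seed-click lesion additions (final TMTV).}
#' }
#' Replaying a session is deterministic: the same session on the same
#' volume always yields identical results.
#'
#' @param pet a [PETVolume-class].
#' @param session a [Session-class].
#' @param strict logical; if TRUE the first failed interaction aborts the
#'   run, otherwise failures are logged and skipped (default).
#' @return a [WorkflowResult-class].
#' @export
runWorkflow <- function(pet, session, strict = FALSE) {
    validObject(session)
    cs <- preselect(pet, suvMin = session@suvMin,
                    minVolume = session@minVolume,
                    connectivity = session@connectivity)
    sets <- list(preselection = cs)
    tmtvs <- numeric(4)
    log <- list()
    for (stage in 1:4) {
        for (ia in session@interactions) {
            if (ia$stage != stage) next
            res <- tryCatch({
                cs <- switch(ia$kind,
                    remove_click = removeComponentAt(cs, ia$point_mm),
                    edit_mask = {
                        m <- ia$mask
                        if (is.null(m)) m <- readVolume(ia$mask_path,
                                                        mask = TRUE)
                        applyEditMask(cs, m)
                    },
                    add_seed = addLesionAt(cs, ia$point_mm, pet))
                "applied"
            }, error = function(e) {
                if (strict) stop(e)
                conditionMessage(e)
            })
            log[[length(log) + 1L]] <- data.frame(
                stage = stage, kind = ia$kind,
                status = if (identical(res, "applied")) "applied" else "failed",
                message = if (identical(res, "applied")) "" else res)
        }
        tmtvs[stage] <- tmtv(cs)
        sets[[sprintf("stage%d", stage)]] <- cs
    }
    names(tmtvs) <- paste0("TMTV", 1:4)
    log <- if (length(log)) do.call(rbind, log) else
        data.frame(stage = integer(), kind = character(),
                   status = character(), message = character())
    new("WorkflowResult", tmtvByStage = tmtvs, stageSets = sets, log = log,
        session = session)
}

#' @rdname tmtvByStage
#' @export
setMethod("tmtvByStage", "WorkflowResult", function(object)
    object@tmtvByStage)

#' @rdname tmtv
#' @export
setMethod("tmtv", "WorkflowResult", function(object, stage = 4, ...)
    unname(object@tmtvByStage[paste0("TMTV", stage)]))

#' @rdname stageComponents
#' @export
setMethod("stageComponents", "WorkflowResult", function(object, stage) {
    stopifnot(stage %in% 0:4)
    object@stageSets[[if (stage == 0) "preselection" else
                      sprintf("stage%d", stage)]]
})

#' @rdname interactionLog
#' @export
setMethod("interactionLog", "WorkflowResult", function(object) object@log)

setMethod("show", "WorkflowResult", function(object) {
    v <- object@tmtvByStage
    cat(sprintf("WorkflowResult [%s / %s]\n", object@session@caseId,
                object@session@readerId))
    cat(sprintf("  TMTV1 %.1f | TMTV2 %.1f | TMTV3 %.1f | TMTV4 %.1f cm3\n",
                v[1], v[2], v[3], v[4]))
    nf <- sum(object@log$status == "failed")
    cat(sprintf("  %d interaction(s) applied, %d failed\n",
                sum(object@log$status == "applied"), nf))
})
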