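# Shared organ catalog for the scenario library. All positions are world mm
# on the default 128 x 128 x 160 grid at 4 mm spacing (x 0-508, y 0-508,
# z 0-636; head at large z). Organ centers sit on voxel centers so scripted
# clicks hit the intended structure exactly. Paint orders: liver 3,
# spleen/marrow 4, brain/bladder 5, lesions 10, kidneys/myocardium 11
# (physiologic wins where a lesion is deliberately fused to it, so the
# stage-3 edit mask equals the physiologic organ's painted region).
.organ_catalog <- function() list(
    brain = organSpec("brain", "physiologic", "sphere",
                      c(256, 256, 560), 60, suv = 10, paintOrder = 5L),
    bladder = organSpec("bladder", "physiologic", "sphere",
                        c(256, 256, 64), 28, suv = 15, paintOrder = 5L),
    liver = organSpec("liver", "reference_tissue", "ellipsoid",
                      c(330, 230, 330), c(70, 55, 45), suv = 3.0,
                      paintOrder = 3L),
    spleen_normal = organSpec("spleen", "physiologic", "ellipsoid",
                              c(150, 250, 340), c(35, 30, 50), suv = 1.8,
                              paintOrder = 4L),
    spleen_reactive = organSpec("spleen", "physiologic", "ellipsoid",
                                c(150, 250, 340), c(35, 30, 50), suv = 4.5,
                                paintOrder = 4L),
    spleen_diffuse = organSpec("spleen", "physiologic", "ellipsoid",
                               c(150, 250, 340), c(35, 30, 50), suv = 4.8,
                               paintOrder = 4L),
    marrow_normal = organSpec("marrow", "physiologic", "tube",
                              c(256, 180, 120), 12, suv = 1.5,
                              paintOrder = 4L, end = c(256, 180, 480)),
    marrow_reactive = organSpec("marrow", "physiologic", "tube",
                                c(256, 180, 120), 12, suv = 4.5,
                                paintOrder = 4L, end = c(256, 180, 480)),
    marrow_involved = organSpec("marrow", "lesion", "tube",
                                c(256, 180, 120), 12, suv = 5.0,
                                paintOrder = 4L, end = c(256, 180, 480)),
    kidney_right = organSpec("kidney_right", "physiologic", "ellipsoid",
                             c(330, 190, 260), c(22, 28, 42), suv = 8,
                             paintOrder = 11L),
    kidney_left = organSpec("kidney_left", "physiologic", "ellipsoid",
                            c(180, 190, 260), c(22, 28, 42), suv = 8,
                            paintOrder = 11L),
    myocardium = organSpec("myocardium", "physiologic", "ellipsoid",
                           c(215, 275, 430), c(38, 33, 28), suv = 7,
                           paintOrder = 11L),
    neck_node = organSpec("neck_node", "lesion", "sphere",
                          c(256, 256, 470), 14, suv = 9, paintOrder = 10L),
    axillary_node = organSpec("axillary_node", "lesion", "sphere",
                              c(350, 280, 450), 18, suv = 8, paintOrder = 10L),
    para_aortic_node = organSpec("para_aortic_node", "lesion", "sphere",
                                 c(256, 230, 300), 15, suv = 10,
                                 paintOrder = 10L),
    iliac_node = organSpec("iliac_node", "lesion", "sphere",
                           c(300, 240, 150), 12, suv = 7, paintOrder = 10L),
    inguinal_node = organSpec("inguinal_node", "lesion", "sphere",
                              c(220, 250, 110), 10, suv = 8, paintOrder = 10L),
    mediastinal_bulk = organSpec("mediastinal_bulk", "lesion", "ellipsoid",
                                 c(256, 260, 430), c(62, 52, 62), suv = 9,
                                 paintOrder = 10L),
    abdominal_bulk = organSpec("abdominal_bulk", "lesion", "ellipsoid",
                               c(230, 260, 240), c(60, 50, 55), suv = 8,
                               paintOrder = 10L),
    renal_fused_node = organSpec("renal_fused_node", "lesion", "sphere",
                                 c(330, 232, 260), 16, suv = 7,
                                 paintOrder = 10L),
    paracardiac_node = organSpec("paracardiac_node", "lesion", "sphere",
                                 c(245, 300, 445), 15, suv = 9,
                                 paintOrder = 10L),
    small_node_a = organSpec("small_node_a", "lesion", "sphere",
                             c(190, 300, 200), 7.8, suv = 8, paintOrder = 10L),
    small_node_b = organSpec("small_node_b", "lesion", "sphere",
                             c(320, 300, 200), 6, suv = 9, paintOrder = 10L))

# Scenario definitions: organ picks plus the scripted reader decisions.
# `fused` declares organs that form one connected component by construction
# (a lesion painted against a physiologic structure).
.scenario_defs <- function() list(
    multifocal_nodal = list(
        desc = "Multifocal nodal disease; brain and bladder removed at stage 1.",
        organs = c("brain", "bladder", "liver", "spleen_normal",
                   "marrow_normal", "neck_node", "axillary_node",
                   "para_aortic_node", "iliac_node", "inguinal_node"),
        stage1 = c("brain", "bladder")),
    bulky_disease = list(
        desc = "Bulky mediastinal and abdominal masses with diffuse marrow involvement (kept in the TMTV).",
        organs = c("brain", "bladder", "liver", "marrow_involved",
                   "mediastinal_bulk", "abdominal_bulk", "axillary_node"),
        stage1 = c("brain", "bladder")),
    reactive_spleen_marrow = list(
        desc = "Reactive (non-tumoral) spleen and bone-marrow uptake removed with single clicks at stage 2.",
        organs = c("brain", "bladder", "liver", "spleen_reactive",
                   "marrow_reactive", "neck_node", "axillary_node",
                   "para_aortic_node"),
        stage1 = c("brain", "bladder"),
        stage2 = c("spleen", "marrow")),
    diffuse_spleen_included = list(
        desc = "Diffuse splenic uptake at 1.6 x liver without reactive marrow changes: spleen kept in the TMTV per reader instructions.",
        organs = c("brain", "bladder", "liver", "spleen_diffuse",
                   "marrow_normal", "neck_node", "para_aortic_node",
                   "iliac_node"),
        stage1 = c("brain", "bladder")),
    diffuse_spleen_reactive_marrow = list(
        desc = "Diffuse splenic uptake at 1.6 x liver with similar reactive marrow changes: both removed at stage 2.",
        organs = c("brain", "bladder", "liver", "spleen_diffuse",
                   "marrow_reactive", "neck_node", "para_aortic_node",
                   "iliac_node"),
        stage1 = c("brain", "bladder"),
        stage2 = c("spleen", "marrow")),
    kidney_fused_node = list(
        desc = "Retroperitoneal node fused with the right kidney: the kidney voxels are erased with a stage-3 edit mask; the isolated left kidney is removed with a stage-1 click.",
        organs = c("brain", "bladder", "liver", "kidney_right",
                   "kidney_left", "renal_fused_node", "axillary_node"),
        stage1 = c("brain", "bladder", "kidney_left"),
        edits3 = "kidney_right",
        fused = list(c("kidney_right", "renal_fused_node"))),
    myocardium_edit = list(
        desc = "Paracardiac node fused with myocardial uptake: myocardium erased with a stage-3 edit mask.",
        organs = c("brain", "bladder", "liver", "myocardium",
                   "paracardiac_node", "axillary_node", "para_aortic_node"),
        stage1 = c("brain", "bladder"),
        edits3 = "myocardium",
        fused = list(c("myocardium", "paracardiac_node"))),
    small_lesion_addition = list(
        desc = "Two sub-3 cm3 lesions excluded by preselection and added back with stage-4 seed clicks.",
        organs = c("brain", "bladder", "liver", "iliac_node",
                   "small_node_a", "small_node_b"),
        stage1 = c("brain", "bladder"),
        adds4 = c("small_node_a", "small_node_b")))

#' Names of the shipped phantom scenarios
#' @return character vector of scenario names for [phantomScenario()].
#' @export
scenarioNames <- function() names(.scenario_defs())

# Click point for an organ: its center (tube: axis midpoint), which by
# construction lies on a voxel center painted by that organ.
.organ_click <- function(o)
    if (o@shape == "tube") (o@center + o@end) / 2 else o@center

#' Build a ready-made phantom case with session script and expected TMTVs
#'
#' Returns one case from the shipped scenario library: a phantom emulating
#' one of the benchmark's uptake patterns (multifocal nodal disease, bulky
#' masses, reactive or diffuse splenic/marrow uptake, lesions fused with
#' kidney or myocardium, sub-3 cm3 lesions for stage-4 addition), the
#' scripted reader session encoding the intended clinical decisions, and
#' the stage TMTVs expected in clean (blur- and noise-free) mode, derived
#' purely from the rasterizer's per-organ ground truth.
#'
#' @param name one of [scenarioNames()].
#' @param seed integer seed recorded on the spec (used only when the
#'   phantom is later degraded with blur/noise).
#' @return list with elements \code{spec} ([PhantomSpec-class]),
#'   \code{session} ([Session-class]), \code{expected} (named numeric,
#'   TMTV1..TMTV4 in cm3), \code{truth} (per-organ truth table),
#'   \code{organMasks}, \code{pet} (clean [PETVolume-class]),
#'   \code{spleenLiverRatio} and \code{description}.
#' @examples
#' sc <- phantomScenario("small_lesion_addition")
#' sc$expected  # TMTV1..TMTV4 in cm3
#' @export
phantomScenario <- function(name, seed = 1L) {
    defs <- .scenario_defs()
    if (!name %in% names(defs))
        stop("unknown scenario '", name, "'; see scenarioNames()",
             call. = FALSE)
    def <- defs[[name]]
    cat_ <- .organ_catalog()
    organs <- unname(cat_[def$organs])
    spec <- phantomSpec(organs, seed = seed)
    ras <- rasterizePhantom(spec, degrade = FALSE)
    truth <- ras$truth
    vol <- voxelVolume(spec@grid)
    cnt <- stats::setNames(truth$voxel_count, truth$name)
    suv <- stats::setNames(truth$suv, truth$name)

    suvMin <- 4.0; minVolume <- 3.0
    seg <- truth$name[truth$suv >= suvMin & truth$voxel_count > 0L]
    # group fused organs into components; everything else is its own group
    groups <- as.list(seg)
    for (fg in def$fused) {
        fg <- intersect(fg, seg)
        if (length(fg) < 2) next
        groups <- groups[!vapply(groups, function(g) any(g %in% fg), TRUE)]
        groups <- c(groups, list(fg))
    }
    kept <- unlist(groups[vapply(groups,
        function(g) sum(cnt[g]) * vol >= minVolume, TRUE)])

    s1 <- intersect(def$stage1, kept)
    t1 <- setdiff(kept, s1)
    t2 <- setdiff(t1, def$stage2)
    t3 <- setdiff(t2, def$edits3)
    t4 <- union(t3, intersect(def$adds4, seg))
    expected <- c(TMTV1 = sum(cnt[t1]) * vol, TMTV2 = sum(cnt[t2]) * vol,
                  TMTV3 = sum(cnt[t3]) * vol, TMTV4 = sum(cnt[t4]) * vol)

    organ_idx <- stats::setNames(seq_along(organs), truth$name)
    ias <- list()
    for (nm in def$stage1)
        ias <- c(ias, list(removeClick(.organ_click(organs[[organ_idx[nm]]]),
                                       stage = 1, note = nm)))
    for (nm in def$stage2)
        ias <- c(ias, list(removeClick(.organ_click(organs[[organ_idx[nm]]]),
                                       stage = 2, note = nm)))
    for (nm in def$edits3) {
        m <- MaskVolume(ras$organMasks@labels == organ_idx[nm], spec@grid)
        ias <- c(ias, list(editMask(mask = m, note = nm)))
    }
    for (nm in def$adds4)
        ias <- c(ias, list(addSeed(.organ_click(organs[[organ_idx[nm]]]),
                                   note = nm)))
    session <- Session(caseId = name, readerId = "script",
                       interactions = ias, suvMin = suvMin,
                       minVolume = minVolume, connectivity = 26)

    list(spec = spec, session = session, expected = expected, truth = truth,
         organMasks = ras$organMasks, pet = ras$pet,
         spleenLiverRatio = ras$spleenLiverRatio,
         description = def$desc)
}

#' Random lesion-only phantom for property testing
#'
#' A small phantom (64^3 voxels at 4 mm) with a seeded random number of
#' spherical lesions at random positions, sizes and uptake levels, for
#' fuzz-testing segmentation and workflow invariants.
#'
#' @param seed integer seed.
#' @param nLesions range to draw the lesion count from.
#' @return a [PhantomSpec-class].
#' @export
randomPhantomSpec <- function(seed = 1L, nLesions = 3:8) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    n <- sample(nLesions, 1)
    organs <- lapply(seq_len(n), function(i)
        organSpec(sprintf("lesion_%02d", i), "lesion", "sphere",
                  center = stats::runif(3, 40, 216),
                  radii = stats::runif(1, 6, 24),
                  suv = stats::runif(1, 2, 12),
                  paintOrder = as.integer(10L + i)))
    phantomSpec(organs, grid = VoxelGrid(c(64L, 64L, 64L), spacing = 4),
                backgroundSuv = 0.8, seed = seed)
}
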