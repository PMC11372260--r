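# Two well-separated lesions plus a "physiologic" hot sphere on a small
# grid, built in code for the interaction tests.
toy_case <- function() {
    g <- VoxelGrid(c(20L, 20L, 20L), spacing = 4)
    a <- array(0.5, c(20, 20, 20))
    a[3:7, 3:7, 3:7] <- 8        # lesion A: 125 voxels, 8 cm3
    a[14:18, 14:18, 3:7] <- 6    # lesion B: 125 voxels, 8 cm3
    a[14:18, 3:7, 14:18] <- 12   # "brain": 125 voxels
    a[3, 3, 14] <- 9             # sub-3 cm3 lesion: 1 voxel
    PETVolume(a, g)
}

test_that("remove_click deletes the whole component; background clicks error", {
    pet <- toy_case()
    cs <- preselect(pet)
    expect_equal(nrow(componentTable(cs)), 3L)
    brain_pt <- voxelToWorld(imageGrid(pet), c(16, 5, 16))
    cs2 <- removeComponentAt(cs, brain_pt)
    expect_equal(tmtv(cs2), tmtv(cs) - 8)
    expect_equal(nrow(componentTable(cs2)), 2L)
    expect_error(removeComponentAt(cs2, brain_pt), "no component")
    # removing the remaining two in either order empties the set
    pA <- voxelToWorld(imageGrid(pet), c(5, 5, 5))
    pB <- voxelToWorld(imageGrid(pet), c(16, 16, 5))
    e1 <- removeComponentAt(removeComponentAt(cs2, pA), pB)
    e2 <- removeComponentAt(removeComponentAt(cs2, pB), pA)
    expect_equal(tmtv(e1), 0)
    expect_identical(maskLabels(e1@mask), maskLabels(e2@mask))
})

test_that("edit masks erase voxels, split components and keep sub-3 cm3 fragments", {
    g <- VoxelGrid(c(20L, 8L, 8L), spacing = 4)
    a <- array(0, c(20, 8, 8))
    a[2:18, 4, 4] <- 8                       # a 17-voxel rod
    pet <- PETVolume(a, g)
    cs <- preselect(pet, minVolume = 0)
    expect_equal(nrow(componentTable(cs)), 1L)
    cut <- array(0L, c(20, 8, 8)); cut[9:11, , ] <- 1L
    cs2 <- applyEditMask(cs, MaskVolume(cut, g))
    tab <- componentTable(cs2)
    expect_equal(nrow(tab), 2L)              # dumbbell cut through the neck
    expect_equal(sum(tab$voxel_count), 17L - 3L)
    expect_equal(tmtv(cs2), tmtv(cs) - 3 * voxelVolume(g))
    # fragments far below 3 cm3 are retained: no re-filtering after edits
    expect_true(all(tab$volume_cm3 < 3))
    # disjoint mask is the identity
    far <- array(0L, c(20, 8, 8)); far[1, 1, 1] <- 1L
    expect_identical(maskLabels(applyEditMask(cs, MaskVolume(far, g))@mask),
                     maskLabels(cs@mask))
    expect_error(applyEditMask(cs, MaskVolume(array(0L, c(4, 4, 4)),
                                              VoxelGrid(c(4L, 4L, 4L)))),
                 "grid")
})

test_that("add_seed grows the full connected region, merging by union", {
    pet <- toy_case()
    grid <- imageGrid(pet)
    cs <- preselect(pet)
    small_pt <- voxelToWorld(grid, c(3, 3, 14))
    cs2 <- addLesionAt(cs, small_pt)
    expect_equal(tmtv(cs2), tmtv(cs) + voxelVolume(grid))
    # idempotent union: seeding an included component changes nothing
    cs3 <- addLesionAt(cs2, small_pt)
    expect_identical(maskLabels(cs3@mask), maskLabels(cs2@mask))
    # a seed below the threshold is an error
    expect_error(addLesionAt(cs, voxelToWorld(grid, c(10, 10, 10))),
                 "below threshold")
})

test_that("remove then re-add restores the removed voxel set exactly", {
    pet <- toy_case()
    cs <- preselect(pet)
    pA <- voxelToWorld(imageGrid(pet), c(5, 5, 5))
    cs_removed <- removeComponentAt(cs, pA)
    cs_back <- addLesionAt(cs_removed, pA)
    expect_identical(maskLabels(cs_back@mask) > 0L,
                     maskLabels(cs@mask) > 0L)
    expect_equal(tmtv(cs_back), tmtv(cs))
})

test_that("sessions validate interaction kinds against stages", {
    expect_error(Session(interactions = list(removeClick(c(0, 0, 0),
                                                         stage = 3))),
                 "not allowed")
    expect_error(Session(interactions = list(
        list(kind = "add_seed", stage = 2, point_mm = c(0, 0, 0)))),
        "not allowed")
    expect_error(Session(interactions = list(addSeed(c(0, 0, 0)),
                                             removeClick(c(0, 0, 0), 1))),
                 "sorted by stage")
    expect_error(Session(interactions = list(editMask())), "mask")
    expect_silent(validObject(Session(interactions = list(
        removeClick(c(0, 0, 0), 1), removeClick(c(0, 0, 0), 2),
        addSeed(c(0, 0, 0))))))
})

test_that("an empty session leaves all four stage TMTVs at the preselection value", {
    pet <- toy_case()
    wr <- runWorkflow(pet, Session())
    expect_equal(unname(tmtvByStage(wr)), rep(tmtv(preselect(pet)), 4))
    expect_equal(nrow(interactionLog(wr)), 0L)
})

test_that("the four-stage workflow applies interactions by stage with exact bookkeeping", {
    pet <- toy_case()
    grid <- imageGrid(pet)
    ses <- Session(caseId = "toy", readerId = "r1", interactions = list(
        removeClick(voxelToWorld(grid, c(16, 5, 16)), stage = 1,
                    note = "brain"),
        addSeed(voxelToWorld(grid, c(3, 3, 14)), note = "small lesion")))
    wr <- runWorkflow(pet, ses)
    v <- tmtvByStage(wr)
    expect_equal(unname(v), c(16, 16, 16, 16 + voxelVolume(grid)))
    expect_true(all(interactionLog(wr)$status == "applied"))
    # stage masks are exposed for all stages including raw preselection
    expect_equal(tmtv(stageComponents(wr, 0)), 24)
    expect_equal(tmtv(stageComponents(wr, 3)), 16)
    # replay determinism: identical output on identical input
    wr2 <- runWorkflow(pet, ses)
    expect_identical(tmtvByStage(wr2), tmtvByStage(wr))
    expect_identical(maskLabels(stageComponents(wr2, 4)@mask),
                     maskLabels(stageComponents(wr, 4)@mask))
})

test_that("strict mode aborts on the first failure; lenient mode logs and continues", {
    pet <- toy_case()
    grid <- imageGrid(pet)
    bad_click <- removeClick(voxelToWorld(grid, c(10, 10, 10)), stage = 1)
    good_seed <- addSeed(voxelToWorld(grid, c(3, 3, 14)))
    ses <- Session(interactions = list(bad_click, good_seed))
    expect_error(runWorkflow(pet, ses, strict = TRUE), "no component")
    wr <- runWorkflow(pet, ses, strict = FALSE)
    log <- interactionLog(wr)
    expect_equal(log$status, c("failed", "applied"))
    expect_match(log$message[1], "no component")
    expect_equal(tmtv(wr), tmtv(preselect(pet)) + voxelVolume(grid))
})

test_that("sessions round-trip through JSON, including edit masks on disk", {
    g <- VoxelGrid(c(8L, 8L, 8L), spacing = 4)
    cut <- array(0L, c(8, 8, 8)); cut[4:5, , ] <- 1L
    ses <- Session(caseId = "caseX", readerId = "rdr", interactions = list(
        removeClick(c(12, 12, 12), stage = 1, note = "brain"),
        removeClick(c(20, 20, 20), stage = 2, note = "spleen"),
        editMask(mask = MaskVolume(cut, g), note = "myocardium"),
        addSeed(c(4, 4, 4), note = "small")),
        suvMin = 2.5, minVolume = 1.0, connectivity = 18)
    dir <- withr::local_tempdir()
    path <- file.path(dir, "session.json")
    writeSession(ses, path)
    back <- readSession(path)
    expect_equal(back@caseId, "caseX")
    expect_equal(sessionParams(back),
                 list(suv_min = 2.5, min_volume_cm3 = 1.0,
                      connectivity = 18L))
    ias <- sessionInteractions(back)
    expect_equal(vapply(ias, function(x) x$kind, ""),
                 c("remove_click", "remove_click", "edit_mask", "add_seed"))
    expect_equal(ias[[1]]$point_mm, c(12, 12, 12))
    # the edit mask was externalized and resolves to identical labels
    m <- readVolume(ias[[3]]$mask_path, mask = TRUE)
    expect_identical(maskLabels(m), cut)
    expect_true(validObject(back))
})
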