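test_that("sphere rasterization matches a voxel-center containment oracle", {
    g <- VoxelGrid(c(16L, 16L, 16L), spacing = 2)
    ctr <- c(15, 15, 15); r <- 10
    spec <- phantomSpec(list(
        organSpec("ball", "lesion", "sphere", ctr, r, suv = 8)),
        grid = g, backgroundSuv = 0)
    ras <- rasterizePhantom(spec)
    n_oracle <- sphere_count_oracle(ctr, r, g)
    expect_equal(ras$truth$voxel_count, n_oracle)
    expect_equal(ras$truth$volume_cm3, n_oracle * 0.008)
    # voxelized volume within one surface-voxel layer of the analytic
    # 4/3 pi r^3 = 4.18879 cm3 (layer bound: 4 pi r^2 * spacing / 1000)
    expect_lt(abs(ras$truth$volume_cm3 - 4.18879), 4 * pi * 100 * 2 / 1000)
    # painted voxels carry the organ SUV, others the background
    expect_setequal(unique(as.vector(suvValues(ras$pet))), c(0, 8))
    expect_equal(sum(suvValues(ras$pet) == 8), n_oracle)
})

test_that("zero organs yield a uniform background volume", {
    spec <- phantomSpec(list(), grid = VoxelGrid(c(8L, 8L, 8L), spacing = 4),
                        backgroundSuv = 1.3)
    ras <- rasterizePhantom(spec)
    expect_true(all(suvValues(ras$pet) == 1.3))
    expect_equal(nrow(ras$truth), 0L)
})

test_that("painter's rule: higher paint order wins; equal-order overlap errors", {
    g <- VoxelGrid(c(12L, 12L, 12L), spacing = 2)
    lo <- organSpec("lo", "lesion", "sphere", c(10, 10, 10), 6, suv = 5,
                    paintOrder = 1L)
    hi <- organSpec("hi", "physiologic", "sphere", c(14, 10, 10), 6, suv = 9,
                    paintOrder = 2L)
    ras <- rasterizePhantom(phantomSpec(list(lo, hi), grid = g,
                                        backgroundSuv = 0))
    own <- maskLabels(ras$organMasks)
    # every voxel inside both shapes belongs to 'hi'
    both <- sphere_count_oracle(c(10, 10, 10), 6, g) +
        sphere_count_oracle(c(14, 10, 10), 6, g) -
        sum(own > 0L)
    expect_gt(both, 0)  # the shapes really overlap
    expect_equal(sum(own == 2L), sphere_count_oracle(c(14, 10, 10), 6, g))
    # a voxel inside 'lo' only keeps the low-order SUV
    expect_equal(suvValues(ras$pet)[4, 6, 6], 5)
    clash <- organSpec("clash", "lesion", "sphere", c(12, 10, 10), 6,
                       suv = 7, paintOrder = 2L)
    expect_error(rasterizePhantom(phantomSpec(list(hi, clash), grid = g,
                                              backgroundSuv = 0)),
                 "equal paint order")
})

test_that("tube rasterization stays within the cylinder bounds", {
    g <- VoxelGrid(c(12L, 12L, 30L), spacing = 2)
    spec <- phantomSpec(list(
        organSpec("rod", "lesion", "tube", c(10, 10, 6), 5, suv = 6,
                  paintOrder = 1L, end = c(10, 10, 50))),
        grid = g, backgroundSuv = 0)
    ras <- rasterizePhantom(spec)
    idx <- which(maskLabels(ras$organMasks) == 1L, arr.ind = TRUE)
    w <- t(apply(idx, 1, function(i) voxelToWorld(g, i)))
    expect_true(all(w[, 3] >= 6 & w[, 3] <= 50))
    expect_true(all((w[, 1] - 10)^2 + (w[, 2] - 10)^2 <= 25))
    # analytic volume pi r^2 L = pi*25*44/1000 = 3.456 cm3; voxelized near it
    expect_lt(abs(ras$truth$volume_cm3 - 3.456), 1.5)
})

test_that("organs beyond the grid are clipped with a warning", {
    g <- VoxelGrid(c(8L, 8L, 8L), spacing = 2)
    spec <- phantomSpec(list(
        organSpec("out", "lesion", "sphere", c(14, 7, 7), 6, suv = 5)),
        grid = g, backgroundSuv = 0)
    expect_warning(ras <- rasterizePhantom(spec), "clipped")
    expect_gt(ras$truth$voxel_count, 0)
})

test_that("degradation: identity at zero, seed-reproducible, constant-preserving", {
    set.seed(5)
    g <- VoxelGrid(c(10L, 10L, 10L), spacing = 4)
    pet <- PETVolume(array(runif(1000, 0, 6), c(10, 10, 10)), g)
    expect_identical(suvValues(degradeVolume(pet, 0, 0)), suvValues(pet))
    d1 <- degradeVolume(pet, 5, 0.3, seed = 9)
    d2 <- degradeVolume(pet, 5, 0.3, seed = 9)
    expect_identical(suvValues(d1), suvValues(d2))
    d3 <- degradeVolume(pet, 5, 0.3, seed = 10)
    expect_false(identical(suvValues(d1), suvValues(d3)))
    # blurring a uniform volume changes nothing (reflective boundaries)
    u <- PETVolume(array(2.5, c(10, 10, 10)), g)
    expect_equal(suvValues(degradeVolume(u, 8, 0)), suvValues(u),
                 tolerance = 1e-12)
    expect_true(all(suvValues(degradeVolume(u, 0, 3, seed = 1)) >= 0))
})

test_that("the scenario library covers the benchmark's uptake patterns", {
    nm <- scenarioNames()
    expect_true(all(c("multifocal_nodal", "bulky_disease",
                      "reactive_spleen_marrow", "diffuse_spleen_included",
                      "diffuse_spleen_reactive_marrow", "kidney_fused_node",
                      "myocardium_edit", "small_lesion_addition") %in% nm))
    expect_error(phantomScenario("no_such_case"), "unknown scenario")
})

test_that("diffuse-spleen scenarios encode spleen at 1.6 x liver uptake", {
    sc <- phantomScenario("diffuse_spleen_included")
    expect_equal(sc$spleenLiverRatio, 1.6)
    expect_gt(sc$spleenLiverRatio, 1.5)
    # spleen included: no stage-2 interactions, spleen volume inside TMTV2
    stages <- vapply(sessionInteractions(sc$session), function(x) x$stage, 1L)
    expect_false(any(stages == 2L))
    spleen_vol <- sc$truth$volume_cm3[sc$truth$name == "spleen"]
    expect_equal(sc$expected[["TMTV2"]] -
                 phantomScenario("diffuse_spleen_reactive_marrow")$expected[["TMTV2"]],
                 spleen_vol)
})

test_that("sub-3 cm3 lesions are excluded at preselection and restored at stage 4", {
    sc <- phantomScenario("small_lesion_addition")
    small <- sc$truth[grepl("small_node", sc$truth$name), ]
    expect_true(all(small$volume_cm3 < 3))
    expect_true(all(small$volume_cm3 > 0))
    expect_equal(sc$expected[["TMTV4"]] - sc$expected[["TMTV1"]],
                 sum(small$volume_cm3))
})

test_that("phantom brain appears in preselection until clicked away", {
    sc <- phantomScenario("multifocal_nodal")
    cs <- preselect(sc$pet)
    brain_vol <- sc$truth$volume_cm3[sc$truth$name == "brain"]
    expect_gt(brain_vol, 500)  # a large organ, present pre-interaction
    expect_true(any(abs(componentTable(cs)$volume_cm3 - brain_vol) < 1e-9))
})

test_that("random phantoms are seed-reproducible", {
    s1 <- randomPhantomSpec(123)
    s2 <- randomPhantomSpec(123)
    r1 <- rasterizePhantom(s1); r2 <- rasterizePhantom(s2)
    expect_identical(suvValues(r1$pet), suvValues(r2$pet))
    expect_false(identical(suvValues(rasterizePhantom(randomPhantomSpec(124))$pet),
                           suvValues(r1$pet)))
})
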