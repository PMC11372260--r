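test_that("the reference TMTV is the reader median, even and odd panels", {
    # four readers: mean of the two middle order statistics
    expect_equal(referenceTmtv(c(178, 229, 137, 159)), 168.5)
    # three readers: middle order statistic
    expect_equal(referenceTmtv(c(275, 129, 282)), 275)
    expect_equal(referenceTmtv(c(400, 400, 400)), 400)
    expect_equal(referenceTmtv(c(786, 788, 49, NA)), 786)
    expect_error(referenceTmtv(c(100)), "at least 2")
    # permutation invariance and range containment
    set.seed(31)
    for (i in 1:20) {
        v <- runif(sample(2:6, 1), 5, 2000)
        expect_equal(referenceTmtv(sample(v)), referenceTmtv(v))
        expect_gte(referenceTmtv(v), min(v))
        expect_lte(referenceTmtv(v), max(v))
    }
})

test_that("the 10 cm3 / 10% agreement rule is an OR of strict comparisons", {
    a0 <- agreement(400, 400)
    expect_true(a0$pass)
    expect_equal(a0$abs_diff, 0); expect_equal(a0$rel_diff, 0)
    # low reader vs the four-reader median 412.5: fails both arms
    a1 <- agreement(252, 412.5)
    expect_equal(a1$abs_diff, 160.5)
    expect_equal(a1$rel_diff, 160.5 / 412.5, tolerance = 1e-12)
    expect_gt(a1$rel_diff, 0.38); expect_false(a1$pass)
    # 1650 vs 1665: abs 15 >= 10 but rel ~0.009 passes the 10% arm
    a2 <- agreement(1650, 1665)
    expect_equal(a2$abs_diff, 15)
    expect_lt(a2$rel_diff, 0.01)
    expect_true(a2$pass)
    # strict inequality at both boundaries
    expect_false(agreement(110, 100)$pass)       # abs 10, rel 0.10 exactly
    expect_true(agreement(110 - 1e-9, 100)$pass)
    expect_error(agreement(5, 0), "reference")
    # pass is monotone in both tolerances
    for (tol in list(c(5, 0.05), c(10, 0.10), c(20, 0.20))) {
        narrow <- agreement(252, 412.5, absTol = tol[1], relTol = tol[2])$pass
        wide <- agreement(252, 412.5, absTol = tol[1] * 10,
                          relTol = tol[2] * 10)$pass
        expect_true(!narrow || wide)
    }
})

test_that("ICC(2,1): perfect agreement, degeneracy, and invariances", {
    m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
    expect_equal(iccAgreement(m)$icc, 1)
    expect_warning(res <- iccAgreement(matrix(7, 4, 3)), "zero total")
    expect_equal(res$icc, 1)
    set.seed(8)
    big <- matrix(rnorm(60, 100, 30), 20, 3) + rnorm(20)
    expect_equal(iccAgreement(big)$icc,
                 iccAgreement(big[sample(20), ])$icc)
    # case-wise deletion of incomplete rows
    with_na <- rbind(big, c(NA, 1, 2))
    expect_equal(iccAgreement(with_na)$icc, iccAgreement(big)$icc)
    expect_equal(iccAgreement(with_na)$n_cases, 20)
    expect_error(iccAgreement(matrix(1:4, 4, 1)), ">= 2")
    # systematic reader offsets count against absolute agreement
    shifted <- big; shifted[, 2] <- shifted[, 2] + 50
    expect_lt(iccAgreement(shifted)$icc, iccAgreement(big)$icc)
})

test_that("ICC estimator recovers a known variance decomposition", {
    set.seed(99)
    n <- 2000; k <- 4; rho <- 0.9
    m <- matrix(rnorm(n, 0, sqrt(rho)), n, k) +
        matrix(rnorm(n * k, 0, sqrt(1 - rho)), n, k)
    expect_equal(iccAgreement(m)$icc, rho, tolerance = 0.02)
})

test_that("difference statistics match a two-pass oracle and handle edge cases", {
    d0 <- diffStats(c(5, 10, 20), c(5, 10, 20))
    expect_equal(d0$mean_diff, 0); expect_equal(d0$sd_diff, 0)
    expect_equal(d0$pearson_r, 1)
    d1 <- diffStats(c(5, 10, 20) + 5, c(5, 10, 20))
    expect_equal(d1$mean_diff, 5); expect_equal(d1$sd_diff, 0)
    # constant series: correlation flagged NA rather than NaN noise
    expect_true(is.na(diffStats(c(3, 3, 3), c(1, 2, 3))$pearson_r))
    set.seed(13)
    v <- runif(50, 0, 2000); r <- v + rnorm(50, 0, 40)
    ds <- diffStats(v, r)
    oracle <- two_pass_meansd(v - r)
    expect_equal(ds$mean_diff, oracle$mean, tolerance = 1e-9)
    expect_equal(ds$sd_diff, oracle$sd, tolerance = 1e-9)
    expect_equal(nrow(ds$table), 50)
    expect_error(diffStats(1:3, 1:4), "equal length")
})

test_that("discrepancy flagging reproduces the adjudicated worked examples", {
    # largest spleen-driven discrepancy: max relative deviation ~0.659
    f05 <- flagDiscrepancies(c(1680, 1706, 1650, 567))
    expect_true(f05$flagged)
    expect_equal(f05$reference, 1665)
    expect_equal(f05$max_rel_dev, 1098 / 1665, tolerance = 1e-9)
    h11 <- flagDiscrepancies(c(178, 229, 137, 159))
    expect_true(h11$flagged)
    expect_equal(h11$max_rel_dev, 60.5 / 168.5, tolerance = 1e-9)
    expect_false(flagDiscrepancies(c(500, 500, 500))$flagged)
    # manual-editing cases pass the 25% relative rule but trip the
    # absolute arm at the default 45 cm3
    b05 <- flagDiscrepancies(c(272, 321, 318))
    expect_false(any(b05$deviations$flagged_rel))
    expect_true(any(b05$deviations$flagged_abs))
    expect_true(b05$flagged)
})

test_that("the packaged discrepant-case fixture behaves as published", {
    tab <- discrepantCases()
    expect_equal(length(unique(tab$case_id)), 8L)
    expect_setequal(unique(tab$subtype), c("HL", "FL", "DLBCL"))
    by_case <- split(tab, tab$case_id)
    meds <- vapply(by_case, function(d) referenceTmtv(d$tmtv_cm3), 1)
    expect_equal(meds[["H11"]], 168.5)
    expect_equal(meds[["H15"]], 275)
    expect_equal(meds[["F02"]], 412.5)
    expect_equal(meds[["F05"]], 1665)
    # the >25% relative rule alone flags exactly the five spleen cases
    rel_only <- vapply(by_case, function(d)
        any(flagDiscrepancies(d$tmtv_cm3)$deviations$flagged_rel), TRUE)
    spleen <- vapply(by_case, function(d)
        all(d$adjudicator_note == "Spleen"), TRUE)
    expect_equal(sum(spleen), 5L)
    expect_true(all(rel_only[spleen]))
    # every adjudicated case is flagged under the default joint rule
    flagged <- vapply(by_case, function(d)
        flagDiscrepancies(d$tmtv_cm3)$flagged, TRUE)
    expect_true(all(flagged))
})

test_that("implementation validation reports per-case pass/fail correctly", {
    ref <- data.frame(case_id = sprintf("c%02d", 1:6), stage = 4,
                      reference_tmtv_cm3 = c(8, 50, 120, 400, 900, 2288))
    meas <- data.frame(case_id = ref$case_id, stage = 4,
                       tmtv_cm3 = ref$reference_tmtv_cm3)
    rep0 <- validateImplementation(meas, ref)
    expect_true(rep0$all_pass)
    expect_equal(rep0$pass_fraction, 1)
    meas2 <- meas; meas2$tmtv_cm3[3] <- meas2$tmtv_cm3[3] * 1.5
    rep1 <- validateImplementation(meas2, ref)
    expect_false(rep1$all_pass)
    expect_equal(rep1$failures$case_id, "c03")
    expect_equal(rep1$pass_fraction, 5 / 6)
    expect_error(validateImplementation(
        data.frame(case_id = "x", stage = 1, tmtv_cm3 = 1),
        data.frame(case_id = "y", stage = 1, reference_tmtv_cm3 = 1)),
        "overlapping")
    # CSV paths are accepted
    d <- withr::local_tempdir()
    write.csv(meas, file.path(d, "m.csv"), row.names = FALSE)
    write.csv(ref, file.path(d, "r.csv"), row.names = FALSE)
    expect_true(validateImplementation(file.path(d, "m.csv"),
                                       file.path(d, "r.csv"))$all_pass)
})
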