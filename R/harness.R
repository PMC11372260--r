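#' Reference TMTV from a reader panel
#'
#' The per-case reference value is the median TMTV of the 3 or 4 readers;
#' for an even count, the mean of the two middle order statistics. At least
#' two finite values are required.
#'
#' @param values numeric vector of reader TMTVs (cm3); NAs are dropped.
#' @return the reference TMTV (cm3).
#' @examples
#' referenceTmtv(c(178, 229, 137, 159))  # 168.5
#' @export
referenceTmtv <- function(values) {
    values <- values[is.finite(values)]
    if (length(values) < 2L)
        stop("at least 2 reader values are required for a reference",
             call. = FALSE)
    stats::median(values)
}

#' Tolerance-based agreement with a reference value
#'
#' A measurement agrees with the reference when the absolute difference is
#' less than \code{absTol} cm3 *or* the relative difference (denominator:
#' the reference) is less than \code{relTol}. Comparisons are strict
#' (\code{<}); the defaults are the benchmark's 10 cm3 / 10\% rule.
#'
#' @param value measured TMTV (cm3).
#' @param reference reference TMTV (cm3, > 0).
#' @param absTol absolute tolerance in cm3 (default 10).
#' @param relTol relative tolerance as a fraction (default 0.10).
#' @return data.frame with \code{value}, \code{reference}, \code{abs_diff},
#'   \code{rel_diff} and logical \code{pass}. Vectorized over
#'   \code{value}/\code{reference}.
#' @examples
#' agreement(252, 412.5)   # fails both arms
#' agreement(1650, 1665)   # abs 15 >= 10 but rel ~0.009: passes
#' @export
agreement <- function(value, reference, absTol = 10, relTol = 0.10) {
    if (any(reference <= 0))
        stop("reference must be > 0", call. = FALSE)
    abs_diff <- abs(value - reference)
    rel_diff <- abs_diff / reference
    data.frame(value = value, reference = reference, abs_diff = abs_diff,
               rel_diff = rel_diff,
               pass = abs_diff < absTol | rel_diff < relTol,
               abs_tol = absTol, rel_tol = relTol)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater: both cases and
#' readers are treated as random samples, and systematic reader offsets
#' count against agreement. Computed from the two-way ANOVA mean squares
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with \eqn{MS_R} the between-case, \eqn{MS_C} the between-reader and
#' \eqn{MS_E} the residual mean square, over \eqn{n} cases and \eqn{k}
#' readers. Rows with missing readers are dropped (case-wise deletion). A
#' degenerate panel with zero total variance is defined as ICC 1 with a
#' warning.
#'
#' @param m numeric matrix, cases x readers (>= 2 complete cases, >= 2
#'   readers).
#' @return list with \code{icc}, \code{model} descriptor, \code{n_cases},
#'   \code{n_readers} and the mean squares.
#' @export
iccAgreement <- function(m) {
    m <- as.matrix(m)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    n <- nrow(m); k <- ncol(m)
    if (n < 2L || k < 2L)
        stop("need >= 2 complete cases and >= 2 readers", call. = FALSE)
    grand <- mean(m)
    row_m <- rowMeans(m)
    col_m <- colMeans(m)
    ss_total <- sum((m - grand)^2)
    ss_rows <- k * sum((row_m - grand)^2)
    ss_cols <- n * sum((col_m - grand)^2)
    ss_err <- ss_total - ss_rows - ss_cols
    msr <- ss_rows / (n - 1)
    msc <- ss_cols / (k - 1)
    mse <- ss_err / ((n - 1) * (k - 1))
    if (ss_total <= 0) {
        warning("zero total variance; ICC defined as 1")
        icc <- 1
    } else {
        icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    }
    list(icc = icc,
         model = "two-way random effects, absolute agreement, single rater (ICC(2,1))",
         n_cases = n, n_readers = k, ms_rows = msr, ms_cols = msc,
         ms_error = mse)
}

#' Difference statistics for value-vs-reference comparisons
#'
#' Mean and standard deviation of the paired differences (value minus
#' reference), the Pearson correlation, and the per-case table used by the
#' difference (Bland-Altman style) plots. The correlation is reported as NA
#' when either side is constant.
#'
#' @param values,references paired numeric vectors (equal length >= 2).
#' @return list with \code{mean_diff}, \code{sd_diff}, \code{pearson_r}
#'   and \code{table} (columns value, reference, diff).
#' @export
diffStats <- function(values, references) {
    if (length(values) != length(references))
        stop("values and references must have equal length", call. = FALSE)
    if (length(values) < 2L)
        stop("need at least 2 pairs", call. = FALSE)
    d <- values - references
    r <- if (stats::sd(values) > 0 && stats::sd(references) > 0)
        stats::cor(values, references) else NA_real_
    list(mean_diff = mean(d), sd_diff = stats::sd(d), pearson_r = r,
         table = data.frame(value = values, reference = references,
                            diff = d))
}

#' Flag a case with large inter-reader discrepancies for adjudication
#'
#' A case is flagged when any reader deviates from the case median by more
#' than \code{relThresh} (relative) or more than \code{absThresh} cm3
#' (absolute). With the defaults, the flag captures both the > 25\%
#' relative discrepancies the benchmark attributed to diffuse splenic
#' uptake and the ~50-100 cm3 absolute discrepancies due to manual
#' editing.
#'
#' @param values named numeric vector of one case's reader TMTVs (cm3).
#' @param relThresh relative deviation threshold (default 0.25).
#' @param absThresh absolute deviation threshold in cm3 (default 45).
#' @return list with \code{flagged}, the \code{reference} median, and a
#'   per-reader \code{deviations} table (abs_dev, rel_dev, flagged_rel,
#'   flagged_abs).
#' @examples
#' flagDiscrepancies(c(r1 = 1680, r2 = 1706, r3 = 1650, r4 = 567))
#' @export
flagDiscrepancies <- function(values, relThresh = 0.25, absThresh = 45) {
    ref <- referenceTmtv(values)
    ok <- is.finite(values)
    abs_dev <- abs(values[ok] - ref)
    rel_dev <- abs_dev / ref
    dev <- data.frame(reader = if (is.null(names(values[ok])))
        paste0("reader", seq_along(abs_dev)) else names(values[ok]),
        tmtv_cm3 = unname(values[ok]),
        abs_dev = unname(abs_dev), rel_dev = unname(rel_dev),
        flagged_rel = unname(rel_dev > relThresh),
        flagged_abs = unname(abs_dev > absThresh))
    list(flagged = any(dev$flagged_rel | dev$flagged_abs), reference = ref,
         max_rel_dev = max(dev$rel_dev), max_abs_dev = max(dev$abs_dev),
         deviations = dev)
}

#' Packaged multi-reader fixture: eight adjudicated discrepant cases
#'
#' Loads the packaged table of per-reader final TMTVs for the eight
#' benchmark cases with large inter-reader discrepancies, together with
#' the adjudicator's note on the cause (diffuse splenic uptake in five
#' cases; manual-editing differences in the rest).
#'
#' @return data.frame with columns \code{case_id}, \code{subtype},
#'   \code{stage}, \code{reader_id}, \code{tmtv_cm3},
#'   \code{adjudicator_note}.
#' @export
discrepantCases <- function() {
    utils::read.csv(system.file("extdata", "discrepant_cases_multireader.csv",
                                package = "tmtvbench", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Validate a TMTV implementation against reference tables
#'
#' Compares measured per-case TMTVs with reference values under the
#' benchmark tolerance rule (pass when within \code{absTol} cm3 or
#' \code{relTol} of the reference) for every case/stage present in both
#' tables.
#'
#' @param measured data.frame or CSV path with columns \code{case_id},
#'   \code{stage}, \code{tmtv_cm3} (and optionally \code{subtype},
#'   \code{reader_id}).
#' @param reference data.frame or CSV path with columns \code{case_id},
#'   \code{stage}, \code{reference_tmtv_cm3}.
#' @param absTol,relTol tolerances (defaults 10 cm3 / 0.10).
#' @return list with \code{results} (per-case table with pass flags),
#'   \code{pass_fraction_by_stage}, \code{pass_fraction} overall,
#'   \code{failures} and \code{all_pass}.
#' @export
validateImplementation <- function(measured, reference, absTol = 10,
                                   relTol = 0.10) {
    if (is.character(measured))
        measured <- utils::read.csv(measured, stringsAsFactors = FALSE)
    if (is.character(reference))
        reference <- utils::read.csv(reference, stringsAsFactors = FALSE)
    if (!all(c("case_id", "stage", "tmtv_cm3") %in% names(measured)))
        stop("measured table needs case_id, stage, tmtv_cm3", call. = FALSE)
    if (!all(c("case_id", "stage", "reference_tmtv_cm3") %in%
             names(reference)))
        stop("reference table needs case_id, stage, reference_tmtv_cm3",
             call. = FALSE)
    merged <- merge(measured, reference, by = c("case_id", "stage"))
    if (!nrow(merged))
        stop("no overlapping case_id/stage keys between the tables",
             call. = FALSE)
    agr <- agreement(merged$tmtv_cm3, merged$reference_tmtv_cm3,
                     absTol = absTol, relTol = relTol)
    res <- cbind(merged[, c("case_id", "stage")], agr)
    by_stage <- tapply(res$pass, res$stage, mean)
    list(results = res,
         pass_fraction_by_stage = by_stage,
         pass_fraction = mean(res$pass),
         failures = res[!res$pass, , drop = FALSE],
         all_pass = all(res$pass),
         abs_tol = absTol, rel_tol = relTol)
}
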