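#' Maximum-intensity projection
#'
#' Projects a PET volume (or mask) to 2-D by taking the maximum along the
#' axis orthogonal to the requested plane: coronal collapses y
#' (anterior-posterior), sagittal collapses x, axial collapses z. Pixel
#' spacing of the retained axes is carried over for aspect-correct
#' rendering.
#'
#' @param vol a [PETVolume-class] or [MaskVolume-class] (masks are
#'   projected as max of the labels, so any segmented voxel along the ray
#'   shows).
#' @param plane "coronal", "sagittal" or "axial".
#' @return a [ProjectionImage-class].
#' @export
mip <- function(vol, plane = c("coronal", "sagittal", "axial")) {
    plane <- match.arg(plane)
    arr <- if (is(vol, "MaskVolume")) vol@labels else vol@values
    sp <- imageGrid(vol)@spacing
    axis <- switch(plane, sagittal = 1L, coronal = 2L, axial = 3L)
    keep <- setdiff(1:3, axis)
    m <- apply(arr, keep, max)
    new("ProjectionImage", values = m, plane = plane,
        pixelSpacing = sp[keep])
}

#' Projection accessors
#' @param proj a [ProjectionImage-class].
#' @return the pixel matrix / plane string.
#' @export
projectionValues <- function(proj) proj@values

#' @rdname projectionValues
#' @export
projectionPlane <- function(proj) proj@plane

setMethod("show", "ProjectionImage", function(object) {
    cat(sprintf("ProjectionImage (%s): %d x %d pixels, spacing (%g, %g) mm, max %.3g\n",
                object@plane, nrow(object@values), ncol(object@values),
                object@pixelSpacing[1], object@pixelSpacing[2],
                max(object@values)))
})

# nearest-neighbour scaling to honour anisotropic pixel spacing
.nn_scale <- function(m, spacing) {
    s <- spacing / min(spacing)
    ri <- rep(seq_len(nrow(m)), each = round(s[1]))
    ci <- rep(seq_len(ncol(m)), each = round(s[2]))
    m[ri, ci, drop = FALSE]
}

#' Render a projection to PNG
#'
#' Writes the projection with the de-facto PET MIP convention: inverted
#' grayscale (high uptake dark) windowed to [0, \code{displayMaxSuv}], with
#' the optional segmentation overlay blended in red at fixed opacity.
#' Pixels are replicated to honour the pixel aspect ratio; the superior
#' side of the image is up. Rendering is side-effect-only and never alters
#' the projected data.
#'
#' @param proj a [ProjectionImage-class] of SUV values.
#' @param path output PNG path.
#' @param maskProj optional [ProjectionImage-class] of the projected
#'   segmentation (same plane and size); non-zero pixels are overlaid.
#' @param displayMaxSuv display window upper bound (default 10).
#' @param overlayAlpha overlay opacity in [0, 1].
#' @return \code{path}, invisibly.
#' @export
renderMip <- function(proj, path, maskProj = NULL, displayMaxSuv = 10,
                      overlayAlpha = 0.4) {
    g <- 1 - pmin(pmax(proj@values / displayMaxSuv, 0), 1)
    r <- g; gg <- g; b <- g
    if (!is.null(maskProj)) {
        if (!identical(dim(maskProj@values), dim(g)))
            stop("mask projection size does not match", call. = FALSE)
        ov <- maskProj@values > 0
        r[ov] <- (1 - overlayAlpha) * r[ov] + overlayAlpha * 1
        gg[ov] <- (1 - overlayAlpha) * gg[ov]
        b[ov] <- (1 - overlayAlpha) * b[ov]
    }
    # matrix rows are the first retained axis (e.g. x), columns the second
    # (e.g. z). PNG rows run top to bottom: transpose and flip so the
    # second axis (superior for coronal/sagittal) points up.
    orient <- function(m) {
        m <- .nn_scale(m, proj@pixelSpacing)
        t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    }
    chans <- lapply(list(r, gg, b), orient)
    img <- array(0, c(dim(chans[[1]]), 3))
    for (ch in 1:3) img[, , ch] <- chans[[ch]]
    png::writePNG(img, path)
    invisible(path)
}

#' Correlation and difference plots for reader agreement
#'
#' Writes the two standard agreement figures from a [diffStats()] result:
#' a scatter of measured vs reference TMTV with the identity line, and a
#' difference-vs-reference plot with the mean difference and mean +/- 1.96
#' SD limits of agreement. Band positions come from the [diffStats()]
#' output, never recomputed here.
#'
#' @param stats a [diffStats()] result.
#' @param scatterPath,differencePath output image paths (PNG).
#' @return character(2) of the written paths, invisibly.
#' @export
agreementPlots <- function(stats, scatterPath, differencePath) {
    tab <- stats$table
    if (nrow(tab) < 2L) stop("need at least 2 cases", call. = FALSE)
    p1 <- ggplot2::ggplot(tab, ggplot2::aes(x = reference, y = value)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                             colour = "grey50") +
        ggplot2::geom_point(alpha = 0.7) +
        ggplot2::labs(x = "Reference TMTV (cm3)", y = "Measured TMTV (cm3)",
                      title = "Measured vs reference TMTV") +
        ggplot2::theme_bw()
    ggplot2::ggsave(scatterPath, p1, width = 5, height = 5, dpi = 120)
    lo <- stats$mean_diff - 1.96 * stats$sd_diff
    hi <- stats$mean_diff + 1.96 * stats$sd_diff
    p2 <- ggplot2::ggplot(tab, ggplot2::aes(x = reference, y = diff)) +
        ggplot2::geom_hline(yintercept = stats$mean_diff,
                            colour = "steelblue") +
        ggplot2::geom_hline(yintercept = c(lo, hi), linetype = "dashed",
                            colour = "steelblue") +
        ggplot2::geom_point(alpha = 0.7) +
        ggplot2::labs(x = "Reference TMTV (cm3)",
                      y = "Measured - reference (cm3)",
                      title = "Difference plot") +
        ggplot2::theme_bw()
    ggplot2::ggsave(differencePath, p2, width = 5, height = 5, dpi = 120)
    invisible(c(scatterPath, differencePath))
}
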