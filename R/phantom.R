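#' Construct an organ specification
#'
#' @param name unique organ name.
#' @param role "lesion", "physiologic", "reference_tissue" or "background".
#' @param shape "sphere", "ellipsoid", "box" or "tube".
#' @param center numeric(3) mm; for a tube, the first endpoint.
#' @param radii sphere/tube radius (1 value) or ellipsoid semi-axes / box
#'   half-widths (3 values), in mm.
#' @param suv uniform SUV painted inside the shape.
#' @param paintOrder integer; the higher order wins where shapes overlap.
#' @param end numeric(3) mm, second tube endpoint.
#' @return an [OrganSpec-class].
#' @export
organSpec <- function(name, role, shape, center, radii, suv,
                      paintOrder = 1L, end = c(NA_real_, NA_real_, NA_real_)) {
    new("OrganSpec", name = name, role = role, shape = shape,
        center = as.numeric(center), radii = as.numeric(radii),
        end = as.numeric(end), suv = as.numeric(suv),
        paintOrder = as.integer(paintOrder))
}

#' Default phantom grid
#'
#' 128 x 128 x 160 voxels at 4 mm isotropic spacing (51.2 x 51.2 x 64 cm):
#' whole-body scale at typical PET resolution, small enough for
#' second-scale tests.
#' @return a [VoxelGrid-class].
#' @export
defaultPhantomGrid <- function()
    VoxelGrid(c(128L, 128L, 160L), spacing = 4)

#' Construct a phantom specification
#'
#' @param organs list of [OrganSpec-class].
#' @param grid a [VoxelGrid-class] (default [defaultPhantomGrid()]).
#' @param backgroundSuv uniform SUV outside all organs (default 0.8,
#'   typical soft-tissue background).
#' @param psfFwhm Gaussian PSF FWHM in mm (0 = no blur).
#' @param noiseSd additive Gaussian noise SD in SUV (0 = none).
#' @param seed integer seed for the noise.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(organs, grid = defaultPhantomGrid(),
                        backgroundSuv = 0.8, psfFwhm = 0, noiseSd = 0,
                        seed = 1L) {
    new("PhantomSpec", grid = grid, backgroundSuv = backgroundSuv,
        organs = organs, psfFwhm = psfFwhm, noiseSd = noiseSd,
        seed = as.integer(seed))
}

# Logical containment of voxel centers in an analytic shape.
# cx, cy, cz: voxel-center world coordinate vectors (length nx, ny, nz).
.contain_mask <- function(organ, cx, cy, cz) {
    nx <- length(cx); ny <- length(cy); nz <- length(cz)
    X <- array(cx, c(nx, ny, nz))
    Y <- array(rep(cy, each = nx), c(nx, ny, nz))
    Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
    ctr <- organ@center
    switch(organ@shape,
        sphere = {
            r2 <- organ@radii[1]^2
            (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= r2
        },
        ellipsoid = {
            r <- organ@radii
            ((X - ctr[1]) / r[1])^2 + ((Y - ctr[2]) / r[2])^2 +
                ((Z - ctr[3]) / r[3])^2 <= 1
        },
        box = {
            r <- organ@radii
            abs(X - ctr[1]) <= r[1] & abs(Y - ctr[2]) <= r[2] &
                abs(Z - ctr[3]) <= r[3]
        },
        tube = {
            # finite cylinder between center and end with given radius
            a <- ctr; b <- organ@end
            ab <- b - a
            L2 <- sum(ab^2)
            PX <- X - a[1]; PY <- Y - a[2]; PZ <- Z - a[3]
            t <- (PX * ab[1] + PY * ab[2] + PZ * ab[3]) / L2
            tc <- pmin(pmax(t, 0), 1)
            d2 <- (PX - tc * ab[1])^2 + (PY - tc * ab[2])^2 +
                  (PZ - tc * ab[3])^2
            d2 <= organ@radii[1]^2 & t >= 0 & t <= 1
        },
        stop("unknown shape ", organ@shape))
}

#' Rasterize a phantom to a PET volume with exact ground truth
#'
#' Paints each organ's analytic shape onto the grid by voxel-center
#' containment (no antialiasing, so truth volumes are integer-voxel exact);
#' where organs overlap the higher \code{paintOrder} wins, and two
#' overlapping organs with equal paint order are an error. Ground-truth
#' organ masks and volumes are recorded *before* any PSF blur or noise is
#' applied. Organs extending beyond the grid are clipped with a warning.
#'
#' @param spec a [PhantomSpec-class].
#' @param degrade logical; apply the spec's PSF/noise degradation to the
#'   returned PET volume (truth is always recorded pre-degradation).
#' @return a list with elements
#'   \describe{
#'     \item{pet}{the [PETVolume-class] (degraded if requested);}
#'     \item{truth}{data.frame per organ: name, role, suv, painted voxel
#'       count and volume (cm3);}
#'     \item{organMasks}{a [MaskVolume-class] labeling each voxel with the
#'       index of the organ that painted it (0 = background);}
#'     \item{liverMeanSuv, spleenLiverRatio}{reference-tissue statistics
#'       (NA when liver/spleen absent), supporting the "diffuse splenic
#'       uptake > 1.5 x liver" criterion.}
#'   }
#' @export
rasterizePhantom <- function(spec, degrade = TRUE) {
    grid <- spec@grid
    dims <- grid@shape
    cx <- grid@origin[1] + (seq_len(dims[1]) - 1) * grid@spacing[1]
    cy <- grid@origin[2] + (seq_len(dims[2]) - 1) * grid@spacing[2]
    cz <- grid@origin[3] + (seq_len(dims[3]) - 1) * grid@spacing[3]
    lim_lo <- c(cx[1], cy[1], cz[1])
    lim_hi <- c(cx[dims[1]], cy[dims[2]], cz[dims[3]])

    suv <- array(spec@backgroundSuv, dims)
    owner <- array(0L, dims)
    order_of <- array(-Inf, dims)

    organs <- spec@organs
    if (length(organs)) {
        po <- vapply(organs, function(o) o@paintOrder, 1L)
        for (i in order(po)) {
            o <- organs[[i]]
            ext <- if (o@shape == "tube")
                c(max(o@radii), max(o@radii), max(o@radii)) else
                rep(max(o@radii), 3)
            lo <- pmin(o@center, if (o@shape == "tube") o@end else o@center) - ext
            hi <- pmax(o@center, if (o@shape == "tube") o@end else o@center) + ext
            if (any(lo < lim_lo) || any(hi > lim_hi))
                warning("organ '", o@name, "' extends beyond the grid; clipped")
            inside <- .contain_mask(o, cx, cy, cz)
            clash <- inside & (order_of == o@paintOrder)
            if (any(clash))
                stop("organs '", o@name, "' and '",
                     organs[[owner[which(clash)[1]]]]@name,
                     "' overlap with equal paint order", call. = FALSE)
            suv[inside] <- o@suv
            owner[inside] <- i
            order_of[inside] <- o@paintOrder
        }
    }

    counts <- tabulate(owner[owner > 0L], nbins = length(organs))
    truth <- data.frame(
        name = vapply(organs, function(o) o@name, ""),
        role = vapply(organs, function(o) o@role, ""),
        suv = vapply(organs, function(o) o@suv, 1),
        voxel_count = as.integer(counts),
        volume_cm3 = counts * voxelVolume(grid),
        stringsAsFactors = FALSE)

    liver <- which(truth$role == "reference_tissue" & truth$name == "liver")
    liver_suv <- if (length(liver)) truth$suv[liver[1]] else NA_real_
    spleen <- which(truth$name == "spleen")
    ratio <- if (length(spleen) && length(liver))
        truth$suv[spleen[1]] / liver_suv else NA_real_

    pet <- PETVolume(suv, grid)
    if (degrade && (spec@psfFwhm > 0 || spec@noiseSd > 0))
        pet <- degradeVolume(pet, spec@psfFwhm, spec@noiseSd, spec@seed)

    list(pet = pet, truth = truth,
         organMasks = MaskVolume(owner, grid),
         liverMeanSuv = liver_suv, spleenLiverRatio = ratio)
}

#' Degrade a PET volume with scanner-like blur and noise
#'
#' Applies a separable Gaussian point-spread function (sigma = FWHM /
#' 2.355 per axis, converted to voxels by the grid spacing; reflective
#' boundaries) followed by additive Gaussian noise clamped at 0. Fully
#' determined by \code{seed}.
#'
#' @param pet a [PETVolume-class].
#' @param psfFwhm PSF full width at half maximum in mm (0 = no blur).
#' @param noiseSd noise standard deviation in SUV (0 = none).
#' @param seed integer seed.
#' @return the degraded [PETVolume-class].
#' @export
degradeVolume <- function(pet, psfFwhm = 0, noiseSd = 0, seed = 1L) {
    stopifnot(psfFwhm >= 0, noiseSd >= 0)
    v <- pet@values
    dims <- pet@grid@shape
    if (psfFwhm > 0) {
        sigma_vox <- (psfFwhm / 2.355) / pet@grid@spacing
        v <- array(.gauss_blur_cpp(as.numeric(v), as.integer(dims),
                                   as.numeric(sigma_vox)), dims)
    }
    if (noiseSd > 0) {
        old <- .Random.seed_save()
        on.exit(.Random.seed_restore(old))
        set.seed(seed)
        v <- v + array(stats::rnorm(prod(dims), 0, noiseSd), dims)
        v[v < 0] <- 0
    }
    new("PETVolume", grid = pet@grid, values = v, meta = pet@meta)
}

# save/restore the global RNG state so seeded degradation does not disturb
# the caller's random stream
.Random.seed_save <- function()
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
.Random.seed_restore <- function(old) {
    if (is.null(old)) return(invisible())
    assign(".Random.seed", old, envir = globalenv())
}

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %d organ(s), background SUV %g, PSF %g mm, noise SD %g SUV\n",
                length(object@organs), object@backgroundSuv, object@psfFwhm,
                object@noiseSd))
    show(object@grid)
})
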