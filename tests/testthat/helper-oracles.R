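# Independent oracles, written deliberately without reference to the
# package internals: plain-R loops and queues only.

# Voxel-loop threshold oracle.
threshold_oracle <- function(values, suv_min) {
    d <- dim(values)
    out <- array(0L, d)
    for (k in seq_len(d[3]))
        for (j in seq_len(d[2]))
            for (i in seq_len(d[1]))
                if (values[i, j, k] >= suv_min) out[i, j, k] <- 1L
    out
}

# Breadth-first flood-fill labeling oracle. Returns an integer label array;
# labels are assigned in scan order of the first voxel reached.
flood_fill_oracle <- function(mask, connectivity) {
    d <- dim(mask)
    offs <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        m <- abs(dx) + abs(dy) + abs(dz)
        if (m == 0) next
        if (connectivity == 6 && m > 1) next
        if (connectivity == 18 && m > 2) next
        offs[[length(offs) + 1L]] <- c(dx, dy, dz)
    }
    lab <- array(0L, d)
    nxt <- 0L
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
        if (mask[i, j, k] == 0 || lab[i, j, k] != 0) next
        nxt <- nxt + 1L
        queue <- list(c(i, j, k))
        lab[i, j, k] <- nxt
        while (length(queue)) {
            p <- queue[[1]]; queue <- queue[-1]
            for (o in offs) {
                q <- p + o
                if (any(q < 1) || any(q > d)) next
                if (mask[q[1], q[2], q[3]] != 0 &&
                    lab[q[1], q[2], q[3]] == 0) {
                    lab[q[1], q[2], q[3]] <- nxt
                    queue[[length(queue) + 1L]] <- q
                }
            }
        }
    }
    lab
}

# Canonical form of a labeling: for each label, the sorted set of linear
# indices, ordered by smallest member -- identical iff the partitions agree.
partition_of <- function(lab) {
    idx <- which(lab > 0)
    sets <- split(idx, lab[idx])
    sets <- lapply(sets, sort)
    unname(sets[order(vapply(sets, min, 1))])
}

# Voxel-center-in-sphere containment count oracle.
sphere_count_oracle <- function(center, radius, grid) {
    d <- gridShape(grid); sp <- gridSpacing(grid); o <- gridOrigin(grid)
    n <- 0L
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
        p <- o + (c(i, j, k) - 1) * sp
        if (sum((p - center)^2) <= radius^2) n <- n + 1L
    }
    n
}

# Two-pass mean/sd oracle.
two_pass_meansd <- function(x) {
    m <- sum(x) / length(x)
    list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# Random binary mask as a 3-D array.
random_mask <- function(seed, dims = c(10L, 10L, 10L), p = 0.25) {
    set.seed(seed)
    array(as.integer(runif(prod(dims)) < p), dims)
}

# Small random SUV field paired with a unit-spacing grid.
random_pet <- function(seed, dims = c(8L, 8L, 8L), max_suv = 8) {
    set.seed(seed)
    PETVolume(array(runif(prod(dims), 0, max_suv), dims),
              VoxelGrid(as.integer(dims), spacing = 4))
}

# Random valid session for fuzz tests: clicks at component centroids and at
# random points (which may legitimately fail), a random box edit mask, and
# random seed clicks. Built only from the phantom's PET volume.
random_session <- function(seed, pet) {
    set.seed(seed)
    cs <- preselect(pet)
    tab <- componentTable(cs)
    grid <- imageGrid(pet)
    rand_point <- function() voxelToWorld(grid, sapply(gridShape(grid),
                                                       function(n) sample(n, 1)))
    ias <- list()
    for (stage in 1:2) {
        for (r in seq_len(sample(0:2, 1))) {
            if (nrow(tab) && runif(1) < 0.7) {
                row <- tab[sample(nrow(tab), 1), ]
                pt <- c(row$centroid_x, row$centroid_y, row$centroid_z)
            } else pt <- rand_point()
            ias <- c(ias, list(removeClick(pt, stage = stage)))
        }
    }
    if (runif(1) < 0.6) {
        lo <- sapply(gridShape(grid), function(n) sample(n, 1))
        hi <- pmin(lo + sample(3:12, 3, replace = TRUE), gridShape(grid))
        box <- array(0L, gridShape(grid))
        box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
        ias <- c(ias, list(editMask(mask = MaskVolume(box, grid))))
    }
    for (r in seq_len(sample(0:3, 1)))
        ias <- c(ias, list(addSeed(rand_point())))
    Session(caseId = sprintf("fuzz%d", seed), readerId = "fuzz",
            interactions = ias)
}
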