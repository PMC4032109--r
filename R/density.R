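## Ion occupancy density grids: nearest-voxel binning of one tracked atom
## over an aligned trajectory, occupancy-threshold contouring, and the
## occupancy -> total-residence-time conversion used to label contour levels.

#' Accumulate a fractional-occupancy grid for one atom
#'
#' The grid spans the atom's bounding box padded by 2 voxels on every side.
#' Each frame increments the voxel containing the atom (half-open intervals
#' \code{[low, high)}); values are counts divided by the frame count, so
#' they sum to exactly 1.  Binning is nearest-voxel with no kernel
#' smoothing, keeping the frame-count semantics of occupancy and residence
#' time exact.
#'
#' @param traj an aligned [Trajectory-class].
#' @param selection selection string resolving to exactly one atom,
#'   e.g. \code{"A:201:MG"}.
#' @param spacing voxel edge, Angstroms (default 0.5).
#' @return a [DensityGrid-class].
#' @export
accumulateDensity <- function(traj, selection, spacing = 0.5) {
    idx <- .matchSelection(topology(traj), selection)
    if (length(idx) != 1L)
        stop("selection must resolve to exactly one atom; got ", length(idx))
    pos <- traj@xyz[, (3L * (idx - 1L) + 1L):(3L * idx), drop = FALSE]
    n <- nrow(pos)
    mn <- apply(pos, 2L, min)
    mx <- apply(pos, 2L, max)
    origin <- mn - 2 * spacing
    counts <- as.integer(floor((mx - origin) / spacing) + 1L + 2L)
    iv <- floor(sweep(pos, 2L, origin) / spacing) + 1L
    lin <- iv[, 1] + counts[1] * (iv[, 2] - 1L) +
        counts[1] * counts[2] * (iv[, 3] - 1L)
    tab <- tabulate(lin, nbins = prod(counts))
    vals <- array(tab / n, dim = counts)
    new("DensityGrid", origin = origin, spacing = spacing, counts = counts,
        values = vals, nFrames = as.integer(n))
}

#' Contour a density grid at an occupancy threshold
#'
#' The comparison is \code{value >= threshold}, so a voxel sitting exactly
#' at the threshold is included ("at least" semantics).
#'
#' @param grid a [DensityGrid-class].
#' @param threshold fractional occupancy in (0, 1].
#' @return list with \code{mask} (logical array) and \code{nVoxels}.
#' @export
contourMask <- function(grid, threshold) {
    if (threshold <= 0 || threshold > 1)
        stop("threshold must be in (0, 1]")
    mask <- grid@values >= threshold
    list(mask = mask, nVoxels = sum(mask))
}

#' Convert an occupancy threshold to a minimum total residence time
#'
#' A voxel at fractional occupancy \code{threshold} over a trajectory of
#' \code{trajLengthNs} nanoseconds was occupied for at least
#' \code{threshold * trajLengthNs} ns in total; the result is returned in
#' picoseconds, together with a rounded-up integer convenience value.
#'
#' @param threshold fractional occupancy in (0, 1].
#' @param trajLengthNs trajectory length, ns.
#' @return list with \code{ps} and \code{psCeiling}.
#' @export
#' @examples
#' occupancyToResidence(0.0005, 89)   # 44.5 ps, ceiling 45 ps
occupancyToResidence <- function(threshold, trajLengthNs) {
    if (threshold <= 0 || threshold > 1)
        stop("threshold must be in (0, 1]")
    if (trajLengthNs <= 0) stop("trajectory length must be positive")
    ps <- threshold * trajLengthNs * 1000
    list(ps = ps, psCeiling = as.integer(ceiling(ps)))
}

#' Occupancy-weighted centroid of a density grid
#'
#' @param grid a [DensityGrid-class] with positive total mass.
#' @return length-3 numeric: the occupancy-weighted mean of voxel centers,
#'   Angstroms.
#' @export
densityCentroid <- function(grid) {
    w <- grid@values
    tot <- sum(w)
    if (tot <= 0) stop("grid has no occupancy")
    centers <- lapply(1:3, function(k)
        grid@origin[k] + (seq_len(grid@counts[k]) - 0.5) * grid@spacing)
    idx <- which(w > 0, arr.ind = TRUE)
    ww <- w[idx]
    c(sum(centers[[1]][idx[, 1]] * ww),
      sum(centers[[2]][idx[, 2]] * ww),
      sum(centers[[3]][idx[, 3]] * ww)) / tot
}
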