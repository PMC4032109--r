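## Positional-stability metrics for a tracked ion in the aligned frame:
## RMSD about a reference position, initial-to-final displacement, and
## inter-site distances.

#' Extract an ion position trace from an aligned trajectory
#'
#' @param traj an aligned [Trajectory-class].
#' @param selection selection string resolving to exactly one atom.
#' @param reference reference position (length-3, Angstroms); default the
#'   frame-1 position.  Alternatives such as the time-mean position or a
#'   crystallographic site can be passed explicitly.
#' @return an [IonTrace-class].
#' @export
ionTrace <- function(traj, selection, reference = NULL) {
    idx <- .matchSelection(topology(traj), selection)
    if (length(idx) != 1L)
        stop("selection must resolve to exactly one atom; got ", length(idx))
    pos <- traj@xyz[, (3L * (idx - 1L) + 1L):(3L * idx), drop = FALSE]
    if (is.null(reference)) reference <- pos[1L, ]
    new("IonTrace", positions = unname(pos),
        reference = as.numeric(reference),
        frameSpacing = frameSpacing(traj))
}

#' RMSD of an ion about its reference position
#'
#' \code{sqrt(mean |position - reference|^2)} over all frames.  With the
#' default frame-1 reference this measures drift from the initial position;
#' passing the time-mean position gives the minimal second moment.
#'
#' @param trace an [IonTrace-class].
#' @param reference optional override of the trace's reference position.
#' @return RMSD in Angstroms.
#' @export
ionRmsd <- function(trace, reference = NULL) {
    if (is.null(reference)) reference <- trace@reference
    d <- sweep(trace@positions, 2L, as.numeric(reference))
    sqrt(mean(rowSums(d * d)))
}

#' Initial-to-final displacement of an ion
#'
#' Distance between the mean position over the first \code{headWindow}
#' frames and the mean over the last \code{tailWindow} frames.  The default
#' windows are 1\% of the frames (minimum 1), trading single-frame noise
#' against locality of the endpoints.
#'
#' @param trace an [IonTrace-class].
#' @param headWindow,tailWindow window sizes in frames; the windows must not
#'   overlap.
#' @return displacement in Angstroms.
#' @export
endpointDisplacement <- function(trace,
                                 headWindow = NULL, tailWindow = NULL) {
    n <- nrow(trace@positions)
    if (is.null(headWindow)) headWindow <- max(1L, floor(0.01 * n))
    if (is.null(tailWindow)) tailWindow <- max(1L, floor(0.01 * n))
    headWindow <- as.integer(headWindow); tailWindow <- as.integer(tailWindow)
    if (headWindow < 1L || tailWindow < 1L)
        stop("windows must contain at least one frame")
    if (headWindow + tailWindow > n)
        stop("head and tail windows overlap")
    head <- colMeans(trace@positions[seq_len(headWindow), , drop = FALSE])
    tail <- colMeans(trace@positions[(n - tailWindow + 1L):n, , drop = FALSE])
    sqrt(sum((head - tail)^2))
}

#' Euclidean distance between two binding sites
#'
#' @param siteA,siteB length-3 coordinates, Angstroms.
#' @return distance in Angstroms.
#' @export
#' @examples
#' siteDistance(c(0, 0, 0), c(3, 4, 0))  # 5
siteDistance <- function(siteA, siteB) {
    stopifnot(length(siteA) == 3L, length(siteB) == 3L,
              all(is.finite(c(siteA, siteB))))
    sqrt(sum((as.numeric(siteA) - as.numeric(siteB))^2))
}
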