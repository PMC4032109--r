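## Rigid-body least-squares superposition (Kabsch algorithm).
## Used to remove global tumbling before internal analyses and to
## transplant ion coordinates between structures.

#' Optimal proper rigid superposition of paired point sets
#'
#' Finds the rotation R (det +1) and translation t minimizing the RMSD of
#' \code{mobile} onto \code{reference} over all proper rigid transforms,
#' via singular value decomposition of the cross-covariance matrix.
#' Reflections are excluded by sign-correcting the smallest singular vector,
#' so only physical rigid-body motions are returned.  No mass weighting.
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows
#'   (n >= 3, non-collinear).
#' @param selection optional character vector of atom identifiers recorded in
#'   the result.
#' @return a [SuperpositionResult-class]; the transform maps mobile points x
#'   to \code{R x + t}, and \code{rmsd} is evaluated after the transform.
#' @export
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' fit <- kabschFit(p, p)
#' fit@rmsd   # 0
kabschFit <- function(mobile, reference, selection = character()) {
    mobile <- as.matrix(mobile); reference <- as.matrix(reference)
    if (!all(dim(mobile) == dim(reference)))
        stop("mobile and reference must have the same dimensions")
    if (ncol(mobile) != 3L) stop("coordinate sets must be n x 3")
    n <- nrow(mobile)
    if (n < 3L) stop("degenerate input: need at least 3 points")
    cm <- colMeans(mobile); cr <- colMeans(reference)
    P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
    sv <- svd(crossprod(P, Q))        # H = sum_i p_i q_i^T
    if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
        stop("degenerate input: points are collinear")
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    t <- as.vector(cr - R %*% cm)
    moved <- transformCoords(mobile, R, t)
    rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
    new("SuperpositionResult", rotation = R, translation = t,
        rmsd = rmsd, selection = as.character(selection))
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param rotation 3x3 matrix.
#' @param translation length-3 vector.
#' @return the transformed n x 3 matrix \code{coords \%*\% t(R) + t}.
#' @export
transformCoords <- function(coords, rotation, translation) {
    sweep(as.matrix(coords) %*% t(rotation), 2L, -translation)
}

#' Remove global rotation/translation from every frame
#'
#' Each frame is rigidly transformed by its own [kabschFit()] of the selected
#' atoms onto the corresponding atoms of \code{reference}; all atoms of the
#' frame move together, so internal geometry is untouched.  This is the
#' prerequisite for order-parameter, density and ion-position analyses, all
#' of which presume that overall tumbling has been removed.
#'
#' @param traj a [Trajectory-class].
#' @param reference a [Structure-class]; defaults to the trajectory topology.
#' @param selection selection string(s) (\code{"chain:resno:atomname"},
#'   \code{*} wildcards, comma-separated atom names); default backbone
#'   N, CA, C, O of all residues.
#' @return the aligned [Trajectory-class].
#' @export
alignFrames <- function(traj, reference = topology(traj),
                        selection = backboneSelection()) {
    idxT <- .matchSelection(topology(traj), selection)
    if (length(idxT) == 0L) stop("selection matches no atoms in trajectory")
    pairs <- .pairAtoms(topology(traj), reference)
    pairs <- pairs[pairs[, "ix"] %in% idxT, , drop = FALSE]
    if (nrow(pairs) < 3L)
        stop("selection resolves to fewer than 3 atoms shared with reference")
    refXYZ <- coords(reference)[pairs[, "iref"], , drop = FALSE]
    xyz <- traj@xyz
    out <- xyz
    for (f in seq_len(nrow(xyz))) {
        frame <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
        fit <- kabschFit(frame[pairs[, "ix"], , drop = FALSE], refXYZ)
        out[f, ] <- as.vector(t(transformCoords(frame, fit@rotation,
                                                fit@translation)))
    }
    newTrajectory(topology(traj), out, frameSpacing(traj))
}

#' Transplant an ion between structures by superposition
#'
#' Fits the donor structure onto the acceptor over \code{fitSelection}
#' (default: all shared backbone atoms) and appends the donor's ion, mapped
#' through the fitted transform, to the acceptor.  This is how
#' crystallographic metal positions from an ion-bound structure are modeled
#' into an apo structure.
#'
#' @param donor structure containing the ion.
#' @param acceptor structure to receive the ion.
#' @param ionId selection string identifying exactly one atom in the donor,
#'   e.g. \code{"A:201:MG"}.
#' @param fitSelection selection used for the rigid fit.
#' @return the acceptor [Structure-class] with one appended ion atom.
#' @export
transplantIon <- function(donor, acceptor, ionId,
                          fitSelection = backboneSelection()) {
    iIon <- .matchSelection(donor, ionId)
    if (length(iIon) != 1L)
        stop("ionId must resolve to exactly one atom in the donor; got ",
             length(iIon))
    idxD <- .matchSelection(donor, fitSelection)
    pairs <- .pairAtoms(donor, acceptor)
    pairs <- pairs[pairs[, "ix"] %in% idxD, , drop = FALSE]
    if (nrow(pairs) < 3L)
        stop("fit selection resolves to fewer than 3 shared atoms")
    fit <- kabschFit(coords(donor)[pairs[, "ix"], , drop = FALSE],
                     coords(acceptor)[pairs[, "iref"], , drop = FALSE])
    newPos <- transformCoords(coords(donor)[iIon, , drop = FALSE],
                              fit@rotation, fit@translation)
    aAcc <- atoms(acceptor)
    ion <- atoms(donor)[iIon, ]
    ion$serial <- max(aAcc$serial) + 1L
    ion$x <- newPos[1, 1]; ion$y <- newPos[1, 2]; ion$z <- newPos[1, 3]
    if (any(aAcc$chain == ion$chain & aAcc$resNo == ion$resNo &
            aAcc$atomName == ion$atomName))
        ion$resNo <- max(aAcc$resNo[aAcc$chain == ion$chain]) + 1L
    newStructure(rbind(aAcc, ion))
}
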