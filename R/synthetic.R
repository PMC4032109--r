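## Seeded synthetic-trajectory generators with analytic ground truth.
##
## Scaffolds are chemically minimal ideal-geometry fragments, not physical
## peptides: only the atoms each analysis consumes are guaranteed present.
## Cone and telegraph generators sample frames i.i.d. -- the plateau value
## of the orientational correlation depends only on the orientational
## distribution, not on kinetics -- while the confined-ion generator uses a
## discrete Ornstein-Uhlenbeck process so frames carry realistic serial
## correlation.  All generators are bit-reproducible for a fixed seed.

.tileFrames <- function(structure, n) {
    base <- as.vector(t(coords(structure)))
    matrix(base, nrow = n, ncol = length(base), byrow = TRUE)
}

.xyzCols <- function(i) (3L * (i - 1L) + 1L):(3L * i)

#' Wobble-in-a-cone trajectory with known S2
#'
#' A poly-Asp scaffold whose Cb->Cg unit vector is drawn i.i.d. uniformly
#' over the spherical cap of semi-angle \code{theta0} about the z axis
#' (rigid backbone atoms ride along unchanged).  The analytic order
#' parameter for this distribution is
#' \code{S2 = (cos(theta0) * (1 + cos(theta0)) / 2)^2}: 1 in the rigid
#' limit, 0 at \code{theta0 = 90} degrees and beyond-hemisphere isotropy at
#' 180 degrees.
#'
#' @param theta0 cone semi-angle, degrees, in (0, 180].
#' @param n number of frames (>= 2).
#' @param nResidues number of independent Asp residues (default 1).
#' @param frameSpacing ps between frames (default 10).
#' @param seed RNG seed.
#' @return list with \code{trajectory} ([Trajectory-class]), analytic
#'   \code{s2}, \code{theta0} and \code{seed}.
#' @export
#' @examples
#' g <- genConeTrajectory(60, n = 1000, seed = 1)
#' g$s2                                    # 0.140625
genConeTrajectory <- function(theta0, n, nResidues = 1L, frameSpacing = 10,
                              seed = 1L) {
    if (theta0 <= 0 || theta0 > 180)
        stop("theta0 must be in (0, 180] degrees")
    if (n < 2L) stop("need at least 2 frames")
    c0 <- cos(.deg2rad(theta0))
    frags <- do.call(rbind, lapply(seq_len(nResidues), function(r)
        .aspFragment(resNo = as.integer(r), offset = c(10 * (r - 1), 0, 0))))
    top <- newStructure(frags)
    xyz <- .tileFrames(top, n)
    .withSeed(seed, {
        for (r in seq_len(nResidues)) {
            cb <- 6L * (r - 1L) + 5L          # CB row within fragment r
            cg <- cb + 1L
            cosv <- stats::runif(n, min = c0, max = 1)
            phi <- stats::runif(n, 0, 2 * pi)
            s <- sqrt(pmax(0, 1 - cosv^2))
            mu <- cbind(s * cos(phi), s * sin(phi), cosv)
            xyz[, .xyzCols(cg)] <- xyz[, .xyzCols(cb)] + 1.53 * mu
        }
    })
    list(trajectory = newTrajectory(top, xyz, frameSpacing),
         s2 = (c0 * (1 + c0) / 2)^2, theta0 = theta0, seed = seed)
}

#' Two-site orientational jump trajectory with known S2
#'
#' The Cb->Cg vector of a single Asp fragment switches i.i.d. per frame
#' between two fixed orientations separated by \code{beta} degrees, with
#' stationary populations \code{p} and \code{1 - p}.  The analytic order
#' parameter is \code{S2 = 1 - 3 p (1 - p) sin^2(beta)}.
#'
#' @param beta jump angle, degrees, in [0, 180].
#' @param p population of the first site, in [0, 1].
#' @param n number of frames.
#' @param frameSpacing ps between frames.
#' @param seed RNG seed.
#' @return list with \code{trajectory}, analytic \code{s2}, \code{beta},
#'   \code{p}, \code{seed}.
#' @export
genTwoSiteTrajectory <- function(beta, p = 0.5, n, frameSpacing = 10,
                                 seed = 1L) {
    if (p < 0 || p > 1) stop("p must be in [0, 1]")
    if (beta < 0 || beta > 180) stop("beta must be in [0, 180] degrees")
    if (n < 2L) stop("need at least 2 frames")
    b <- .deg2rad(beta)
    mu1 <- c(0, 0, 1)
    mu2 <- c(sin(b), 0, cos(b))
    top <- newStructure(.aspFragment())
    xyz <- .tileFrames(top, n)
    .withSeed(seed, {
        inSite1 <- stats::runif(n) < p
        mu <- matrix(mu2, nrow = n, ncol = 3, byrow = TRUE)
        mu[inSite1, ] <- matrix(mu1, nrow = sum(inSite1), ncol = 3,
                                byrow = TRUE)
        xyz[, .xyzCols(6L)] <- xyz[, .xyzCols(5L)] + 1.53 * mu
    })
    list(trajectory = newTrajectory(top, xyz, frameSpacing),
         s2 = 1 - 3 * p * (1 - p) * sin(b)^2, beta = beta, p = p,
         seed = seed)
}

#' Telegraph hydrogen-bond trajectory with known occupancy
#'
#' A two-residue fixture (Asn sidechain amide donor, Asp carboxylate
#' acceptor) whose acceptor oxygen sits in a bonded geometry
#' (donor-acceptor distance 2.9 Angstroms, 5 degree deviation) with
#' per-frame probability \code{p}, and an unbonded geometry (4.5 Angstroms)
#' otherwise, i.i.d. per frame.
#'
#' @param p bonded probability per frame, in [0, 1].
#' @param n number of frames.
#' @param frameSpacing ps between frames.
#' @param seed RNG seed.
#' @return list with \code{trajectory}, \code{occupancy} (= p),
#'   \code{donor} and \code{acceptor} residue labels, \code{seed}.
#' @export
genHbondTrajectory <- function(p, n, frameSpacing = 10, seed = 1L) {
    if (p < 0 || p > 1) stop("p must be in [0, 1]")
    if (n < 2L) stop("need at least 2 frames")
    dev5 <- .deg2rad(5)
    top <- newStructure(data.frame(
        atomName = c("CB", "CG", "ND2", "HD21", "CG", "OD1"),
        resName = c(rep("ASN", 4), rep("ASP", 2)),
        chain = "A", resNo = c(1L, 1L, 1L, 1L, 2L, 2L),
        x = c(-2.0, -1.0, 0, sin(dev5), -1.2, 0),
        y = c(0.5, 0.3, 0, 0, 3.5, 0),
        z = c(-1.0, -0.5, 0, cos(dev5), 2.9, 2.9),
        stringsAsFactors = FALSE))
    xyz <- .tileFrames(top, n)
    .withSeed(seed, {
        bonded <- stats::runif(n) < p
        xyz[!bonded, .xyzCols(6L)[3]] <- 4.5    # OD1 z: 2.9 -> 4.5
    })
    list(trajectory = newTrajectory(top, xyz, frameSpacing),
         occupancy = p, donor = "A:1", acceptor = "A:2", seed = seed)
}

#' Harmonically confined ion trajectory with known center and width
#'
#' A rigid 20-residue scaffold plus one Mg ion following an independent
#' discrete Ornstein-Uhlenbeck process per axis: stationary Gaussian with
#' standard deviation \code{sigma} about the well center, with AR(1)
#' autocorrelation \code{phi} between successive frames.  An optional
#' \code{drift} shifts the well center linearly from \code{center} to
#' \code{center + drift} over the trajectory, for endpoint-displacement
#' tests.
#'
#' @param sigma per-axis stationary standard deviation, Angstroms (> 0).
#' @param n number of frames.
#' @param center well center, length-3, Angstroms.
#' @param phi frame-to-frame AR(1) coefficient in [0, 1).
#' @param drift total linear shift of the center, length-3, Angstroms.
#' @param frameSpacing ps between frames.
#' @param seed RNG seed.
#' @return list with \code{trajectory}, \code{center}, \code{sigma},
#'   \code{drift}, \code{ion} (selection string of the Mg atom),
#'   \code{seed}.
#' @export
genConfinedIonTrajectory <- function(sigma, n, center = c(0, 0, 0),
                                     phi = 0.9, drift = c(0, 0, 0),
                                     frameSpacing = 10, seed = 1L) {
    if (sigma <= 0) stop("sigma must be positive")
    if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
    if (n < 2L) stop("need at least 2 frames")
    ang <- 2 * pi * (0:19) / 20
    scaffold <- do.call(rbind, lapply(1:20, function(r) {
        f <- .aspFragment(resNo = as.integer(r),
                          offset = c(12 * cos(ang[r]), 12 * sin(ang[r]),
                                     2 * ((r %% 2) - 0.5)))
        f[f$atomName %in% c("N", "CA", "C", "O"), ]
    }))
    scaffold$resName <- "GLY"
    ion <- data.frame(atomName = "MG", resName = "MG", chain = "A",
                      resNo = 100L, x = center[1], y = center[2],
                      z = center[3], stringsAsFactors = FALSE)
    top <- newStructure(rbind(scaffold, ion))
    a <- atoms(top)
    top@atoms$element[a$atomName == "MG"] <- "MG"
    top@atoms$recordType[a$atomName == "MG"] <- "HETATM"
    iIon <- nAtoms(top)
    xyz <- .tileFrames(top, n)
    ctr <- sapply(1:3, function(k)
        center[k] + (seq_len(n) - 1) / (n - 1) * drift[k])
    .withSeed(seed, {
        for (k in 1:3) {
            innov <- c(sigma * stats::rnorm(1),
                       sigma * sqrt(1 - phi^2) * stats::rnorm(n - 1L))
            dev <- as.numeric(stats::filter(innov, phi,
                                            method = "recursive"))
            xyz[, .xyzCols(iIon)[k]] <- ctr[, k] + dev
        }
    })
    list(trajectory = newTrajectory(top, xyz, frameSpacing),
         center = center, sigma = sigma, drift = drift,
         ion = "A:100:MG", seed = seed)
}

#' Apply global rigid-body tumbling to every frame
#'
#' Each frame is independently rotated (random axis, rotation angle uniform
#' in \code{[0, maxAngle]} degrees) and translated (each component uniform
#' in \code{[-maxTranslation, maxTranslation]} Angstroms).  Zero magnitudes
#' return the input unchanged.  Used to validate that [alignFrames()]
#' removes overall motion.
#'
#' @param traj a [Trajectory-class].
#' @param maxAngle rotation magnitude, degrees (default 180: arbitrary
#'   rotations).
#' @param maxTranslation translation bound, Angstroms (default 5).
#' @param seed RNG seed.
#' @return the tumbled [Trajectory-class].
#' @export
applyGlobalTumbling <- function(traj, maxAngle = 180, maxTranslation = 5,
                                seed = 1L) {
    if (maxAngle == 0 && maxTranslation == 0) return(traj)
    xyz <- traj@xyz
    n <- nrow(xyz)
    .withSeed(seed, {
        for (f in seq_len(n)) {
            ax <- stats::rnorm(3)
            ax <- ax / sqrt(sum(ax^2))
            ang <- .deg2rad(stats::runif(1, 0, maxAngle))
            K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                          -ax[2], ax[1], 0), nrow = 3, byrow = TRUE)
            R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
            tr <- stats::runif(3, -maxTranslation, maxTranslation)
            frame <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
            xyz[f, ] <- as.vector(t(transformCoords(frame, R, tr)))
        }
    })
    newTrajectory(topology(traj), xyz, frameSpacing(traj))
}
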