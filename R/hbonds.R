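## Geometric hydrogen-bond detection and occupancy aggregation.
##
## A residue pair's occupancy is the fraction of frames in which ANY
## donor-hydrogen-acceptor triad of the pair satisfies the criteria
## (distance and angular deviation both strictly below their cutoffs).
## Distances and angles are rigid-motion invariant, so no alignment is
## needed before this analysis.

#' Construct hydrogen-bond criteria
#'
#' Defaults are a donor-acceptor distance below 3.1 Angstroms and an angular
#' deviation from linearity below 25 degrees.  The default convention
#' measures the deviation at the donor, between the D->H and D->A
#' directions; a literal D-H-A included angle below 25 degrees would be
#' geometrically impossible for a bonded pair, so the deviation reading is
#' the near-linear criterion intended.  \code{"dha-supplement"} (180 degrees
#' minus the D-H-A included angle) is available as the alternative
#' convention.
#'
#' @param maxDistance donor-acceptor cutoff, Angstroms.
#' @param maxAngle angular-deviation cutoff, degrees.
#' @param convention "donor-deviation" (default) or "dha-supplement".
#' @return an [HBondCriteria-class].
#' @export
hbondCriteria <- function(maxDistance = 3.1, maxAngle = 25,
                          convention = c("donor-deviation",
                                         "dha-supplement")) {
    new("HBondCriteria", maxDistance = maxDistance, maxAngle = maxAngle,
        convention = match.arg(convention))
}

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

## sidechain acceptor atoms per residue class
.ACCEPTOR_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                        ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"))

.residueRows <- function(a, residue) {
    parts <- strsplit(residue, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
        stop("residue must be 'chain:resno', got: ", residue)
    which(a$chain == parts[1] & a$resNo == as.integer(parts[2]))
}

## hydrogens covalently bound to heavy atom i (distance < 1.25 A)
.boundHydrogens <- function(a, rows, i) {
    hs <- rows[a$element[rows] == "H" | grepl("^[0-9]*H", a$atomName[rows])]
    if (length(hs) == 0L) return(integer())
    d2 <- (a$x[hs] - a$x[i])^2 + (a$y[hs] - a$y[i])^2 + (a$z[hs] - a$z[i])^2
    hs[d2 < 1.25^2]
}

#' Enumerate donor-hydrogen-acceptor triads for a residue pair
#'
#' Donors are the donor residue's sidechain N/O heavy atoms, one triad per
#' covalently bound hydrogen (hydrogens must be explicit in the structure;
#' a donor heavy atom with no bound hydrogen is skipped with a warning).
#' Acceptors are the acceptor residue's sidechain O/N atoms by class:
#' Asp OD1/OD2, Glu OE1/OE2, Asn OD1, Gln OE1, and His ND1/NE2 when
#' unprotonated.  Backbone atoms are excluded by default (inter-sidechain
#' bonds); set \code{includeBackbone = TRUE} to add backbone N-H donors and
#' carbonyl O acceptors.
#'
#' @param structure a [Structure-class] with explicit hydrogens (for a
#'   trajectory, its topology with frame-1 coordinates).
#' @param donorResidue,acceptorResidue residues as \code{"chain:resno"}.
#' @param includeBackbone include backbone donor/acceptor atoms.
#' @return data.frame with atom indices d, h, a and name columns donorAtom,
#'   hydrogenAtom, acceptorAtom; zero rows when the pair has no triads.
#' @export
enumerateTriads <- function(structure, donorResidue, acceptorResidue,
                            includeBackbone = FALSE) {
    at <- atoms(structure)
    dRows <- .residueRows(at, donorResidue)
    aRows <- .residueRows(at, acceptorResidue)
    empty <- data.frame(d = integer(), h = integer(), a = integer(),
                        donorAtom = character(), hydrogenAtom = character(),
                        acceptorAtom = character(), stringsAsFactors = FALSE)
    if (length(dRows) == 0L || length(aRows) == 0L) return(empty)

    heavy <- dRows[at$element[dRows] %in% c("N", "O")]
    if (!includeBackbone)
        heavy <- heavy[!at$atomName[heavy] %in% .BACKBONE_ATOMS]
    accNames <- .ACCEPTOR_ATOMS[[at$resName[aRows[1]]]]
    acc <- aRows[at$atomName[aRows] %in% accNames]
    if (includeBackbone) acc <- union(acc, aRows[at$atomName[aRows] == "O"])
    if (at$resName[aRows[1]] == "HIS" && length(acc) > 0L)
        ## protonated His nitrogens are donors, not acceptors
        acc <- acc[vapply(acc, function(i)
            length(.boundHydrogens(at, aRows, i)) == 0L, logical(1))]

    triads <- empty
    for (i in heavy) {
        hs <- .boundHydrogens(at, dRows, i)
        if (length(hs) == 0L) {
            ## a bare N is a donor missing its hydrogens -- flag it; a bare
            ## O (carbonyl/carboxylate) is simply not a donor
            if (at$element[i] == "N")
                warning(sprintf(
                    "donor atom %s of %s has no bound hydrogen; %s",
                    at$atomName[i], donorResidue, "triads skipped"))
            next
        }
        for (h in hs) for (j in acc)
            triads <- rbind(triads, data.frame(
                d = i, h = h, a = j,
                donorAtom = at$atomName[i], hydrogenAtom = at$atomName[h],
                acceptorAtom = at$atomName[j], stringsAsFactors = FALSE))
    }
    triads
}

#' Test one donor-hydrogen-acceptor triad against the criteria
#'
#' @param d,h,a coordinates: length-3 vectors, or congruent n x 3 matrices
#'   to evaluate n frames at once.
#' @param criteria an [HBondCriteria-class].
#' @return logical (vector of length n): bonded or not.
#' @export
#' @examples
#' hbondInFrame(c(0, 0, 0), c(0, 0, 1), c(0, 0, 3), hbondCriteria())  # TRUE
hbondInFrame <- function(d, h, a, criteria = hbondCriteria()) {
    d <- rbind(d); h <- rbind(h); a <- rbind(a)
    da <- a - d
    dh <- h - d
    nDH <- sqrt(rowSums(dh * dh))
    if (any(nDH < 1e-6)) stop("hydrogen coincides with donor")
    nDA <- sqrt(rowSums(da * da))
    if (criteria@convention == "donor-deviation") {
        cosv <- rowSums(dh * da) / (nDH * pmax(nDA, 1e-12))
    } else {                       # 180 - (D-H-A included angle)
        ha <- a - h
        nHA <- sqrt(rowSums(ha * ha))
        cosv <- rowSums(dh * ha) / (nDH * pmax(nHA, 1e-12))
    }
    dev <- acos(pmin(1, pmax(-1, cosv))) / pi * 180
    nDA < criteria@maxDistance & dev < criteria@maxAngle
}

#' Hydrogen-bond occupancy of a residue pair over a trajectory
#'
#' Occupancy is the fraction of frames in which any triad of the pair is
#' bonded.  A pair with no triads is reported as occupancy 0 with a warning.
#'
#' @param traj a [Trajectory-class] (alignment not required; the criteria
#'   are rigid-motion invariant).
#' @param donorResidue,acceptorResidue residues as \code{"chain:resno"}.
#' @param criteria an [HBondCriteria-class].
#' @param includeBackbone passed to [enumerateTriads()].
#' @return one-row data.frame: donor, acceptor, occupancy, nFrames, nTriads.
#' @export
hbondOccupancy <- function(traj, donorResidue, acceptorResidue,
                           criteria = hbondCriteria(),
                           includeBackbone = FALSE) {
    top <- topology(traj)
    triads <- enumerateTriads(top, donorResidue, acceptorResidue,
                              includeBackbone)
    n <- nFrames(traj)
    row <- data.frame(donor = donorResidue, acceptor = acceptorResidue,
                      occupancy = 0, nFrames = n, nTriads = nrow(triads),
                      stringsAsFactors = FALSE)
    if (nrow(triads) == 0L) {
        warning(sprintf("no donor-acceptor triads for pair %s -> %s",
                        donorResidue, acceptorResidue))
        return(row)
    }
    cols <- function(i) traj@xyz[, (3L * (i - 1L) + 1L):(3L * i),
                                 drop = FALSE]
    bonded <- rep(FALSE, n)
    for (k in seq_len(nrow(triads)))
        bonded <- bonded | hbondInFrame(cols(triads$d[k]), cols(triads$h[k]),
                                        cols(triads$a[k]), criteria)
    row$occupancy <- sum(bonded) / n
    row
}

#' Occupancy table for several residue pairs and trajectories
#'
#' Builds a table in the layout of a hydrogen-bond network summary: one row
#' per donor-acceptor pair, one occupancy column per trajectory.
#'
#' @param trajs named list of [Trajectory-class] objects (names become
#'   occupancy column names).
#' @param pairs two-column matrix or data.frame of
#'   (donor \code{"chain:resno"}, acceptor \code{"chain:resno"}).
#' @param criteria an [HBondCriteria-class].
#' @return data.frame: donor, acceptor, then one occupancy column per
#'   trajectory.
#' @export
hbondNetwork <- function(trajs, pairs, criteria = hbondCriteria()) {
    pairs <- as.matrix(pairs)
    out <- data.frame(donor = pairs[, 1], acceptor = pairs[, 2],
                      stringsAsFactors = FALSE)
    for (nm in names(trajs))
        out[[nm]] <- vapply(seq_len(nrow(pairs)), function(k)
            hbondOccupancy(trajs[[nm]], pairs[k, 1], pairs[k, 2],
                           criteria)$occupancy, numeric(1))
    out
}
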