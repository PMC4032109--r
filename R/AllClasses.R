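#' @import methods
NULL

#' Protein structure: an atom table with coordinates
#'
#' A \code{Structure} holds the atoms of one model of a PDB-style structure:
#' serial number, atom name, residue identity, chain, coordinates in
#' Angstroms, B-factor and element symbol.  The atom table is a
#' \code{data.frame} with columns \code{serial}, \code{atomName},
#' \code{resName}, \code{chain}, \code{resNo}, \code{x}, \code{y}, \code{z},
#' \code{bFactor}, \code{element} and \code{recordType}.
#'
#' @slot atoms data.frame of atom records (one row per atom).
#' @seealso [readPdbStructure()], [Trajectory-class]
#' @export
setClass("Structure", representation(atoms = "data.frame"))

.STRUCTURE_COLS <- c("serial", "atomName", "resName", "chain", "resNo",
                     "x", "y", "z", "bFactor", "element", "recordType")

setValidity("Structure", function(object) {
    a <- object@atoms
    if (!all(.STRUCTURE_COLS %in% names(a)))
        return(paste("atoms must have columns:",
                     paste(.STRUCTURE_COLS, collapse = ", ")))
    if (nrow(a) == 0L)
        return("Structure must contain at least one atom")
    if (!all(is.finite(c(a$x, a$y, a$z))))
        return("coordinates must be finite")
    key <- paste(a$chain, a$resNo, a$atomName, sep = ":")
    if (anyDuplicated(key))
        return("(chain, resNo, atomName) must be unique")
    if (any(diff(a$serial) <= 0))
        return("serial numbers must be strictly increasing")
    TRUE
})

#' Trajectory: ordered frames sharing one topology
#'
#' Coordinates are stored as an \code{nFrames x 3*nAtoms} matrix in
#' x1,y1,z1,x2,... column order (the layout used by bio3d), with the atom
#' order of the topology \code{Structure}.  \code{frameSpacing} is the time
#' between saved frames in picoseconds; the trajectory length in nanoseconds
#' is \code{nFrames * frameSpacing / 1000}.
#'
#' @slot topology a [Structure-class] describing every frame's atoms.
#' @slot xyz numeric matrix, one row per frame.
#' @slot frameSpacing time between frames, ps.
#' @seealso [readTrajectory()], [alignFrames()]
#' @export
setClass("Trajectory",
         representation(topology = "Structure", xyz = "matrix",
                        frameSpacing = "numeric"))

setValidity("Trajectory", function(object) {
    na <- nrow(object@topology@atoms)
    if (ncol(object@xyz) != 3L * na)
        return(sprintf("xyz has %d columns; topology implies %d",
                       ncol(object@xyz), 3L * na))
    if (nrow(object@xyz) < 1L)
        return("trajectory must contain at least one frame")
    if (length(object@frameSpacing) != 1L || !is.finite(object@frameSpacing) ||
        object@frameSpacing <= 0)
        return("frameSpacing must be a single positive number (ps)")
    if (!all(is.finite(object@xyz)))
        return("frame coordinates must be finite")
    TRUE
})

#' Result of a least-squares rigid-body superposition
#'
#' Proper rigid transform \code{y = R x + t} minimizing the RMSD of the
#' mobile set onto the reference set, with the RMSD evaluated after the
#' transform.  The rotation always has determinant +1 (reflections are
#' excluded).
#'
#' @slot rotation 3x3 orthonormal matrix, det +1.
#' @slot translation length-3 numeric, Angstroms.
#' @slot rmsd post-fit RMSD, Angstroms.
#' @slot selection character vector of atom identifiers used for the fit
#'   (may be empty when fitting bare coordinate sets).
#' @seealso [kabschFit()]
#' @export
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", selection = "character"))

setValidity("SuperpositionResult", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det +1)")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
        return("rotation must be orthonormal")
    if (object@rmsd < 0) return("rmsd must be non-negative")
    TRUE
})

#' Per-frame unit vectors of one chemical bond
#'
#' The time series of the unit vector along a specific sidechain bond of one
#' residue, one row per trajectory frame.  These are the inputs to the
#' generalized order parameter S2.
#'
#' @slot chain,resNo,resName residue identity.
#' @slot bond length-2 character: names of the from- and to-atoms.
#' @slot vectors nFrames x 3 matrix of unit vectors.
#' @seealso [extractBondVectors()], [computeS2()]
#' @export
setClass("BondVectorSeries",
         representation(chain = "character", resNo = "integer",
                        resName = "character", bond = "character",
                        vectors = "matrix"))

setValidity("BondVectorSeries", function(object) {
    v <- object@vectors
    if (ncol(v) != 3L) return("vectors must have 3 columns")
    if (nrow(v) < 1L) return("vectors must have at least one frame")
    n2 <- rowSums(v * v)
    if (max(abs(sqrt(n2) - 1)) > 1e-6)
        return("vectors must be unit length within 1e-6")
    if (length(object@bond) != 2L) return("bond must name two atoms")
    TRUE
})

#' Geometric hydrogen-bond criteria
#'
#' A donor--hydrogen--acceptor triad is counted as bonded in a frame when the
#' donor--acceptor distance is strictly below \code{maxDistance} and the
#' angular deviation from linearity is strictly below \code{maxAngle}.  Two
#' angle conventions are available: \code{"donor-deviation"} (default)
#' measures the angle at the donor between the D-H and D-A directions;
#' \code{"dha-supplement"} measures 180 degrees minus the D-H-A included
#' angle.  Both are near zero for an ideally linear hydrogen bond.
#'
#' @slot maxDistance donor-acceptor distance cutoff, Angstroms (default 3.1).
#' @slot maxAngle angular deviation cutoff, degrees (default 25).
#' @slot convention one of "donor-deviation", "dha-supplement".
#' @seealso [hbondCriteria()], [hbondOccupancy()]
#' @export
setClass("HBondCriteria",
         representation(maxDistance = "numeric", maxAngle = "numeric",
                        convention = "character"))

setValidity("HBondCriteria", function(object) {
    if (object@maxDistance <= 0) return("maxDistance must be positive")
    if (object@maxAngle <= 0) return("maxAngle must be positive")
    if (!object@convention %in% c("donor-deviation", "dha-supplement"))
        return("unknown angle convention")
    TRUE
})

#' 3-D fractional-occupancy grid for one tracked atom
#'
#' Cubic voxels of edge \code{spacing} starting at \code{origin}; voxel
#' \code{[i,j,k]} covers the half-open box
#' \code{origin + spacing*([i,j,k]-1)} to \code{origin + spacing*[i,j,k]}.
#' Values are fractions of frames in which the tracked atom fell inside the
#' voxel, so they sum to exactly 1 when one atom is binned per frame.
#'
#' @slot origin length-3 numeric, Angstroms (low corner of voxel [1,1,1]).
#' @slot spacing voxel edge, Angstroms.
#' @slot counts integer vector of voxel counts along x, y, z.
#' @slot values 3-D array of fractional occupancies.
#' @slot nFrames number of frames accumulated.
#' @seealso [accumulateDensity()], [writeDensityDX()]
#' @export
setClass("DensityGrid",
         representation(origin = "numeric", spacing = "numeric",
                        counts = "integer", values = "array",
                        nFrames = "integer"))

setValidity("DensityGrid", function(object) {
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (object@spacing <= 0) return("spacing must be positive")
    if (length(object@counts) != 3L || any(object@counts < 1L))
        return("counts must be 3 positive integers")
    if (!all(dim(object@values) == object@counts))
        return("values array dimensions must equal counts")
    if (any(object@values < 0) || any(object@values > 1))
        return("values must be fractional occupancies in [0, 1]")
    TRUE
})

#' Position time series of a tracked ion
#'
#' Per-frame coordinates of one atom in the aligned frame of reference, plus
#' the reference position about which positional metrics are computed
#' (by default the frame-1 position).
#'
#' @slot positions nFrames x 3 matrix, Angstroms.
#' @slot reference length-3 numeric, Angstroms.
#' @slot frameSpacing ps between frames.
#' @seealso [ionTrace()], [ionRmsd()]
#' @export
setClass("IonTrace",
         representation(positions = "matrix", reference = "numeric",
                        frameSpacing = "numeric"))

setValidity("IonTrace", function(object) {
    if (ncol(object@positions) != 3L) return("positions must be n x 3")
    if (nrow(object@positions) < 2L) return("need at least 2 frames")
    if (!all(is.finite(object@positions))) return("positions must be finite")
    if (length(object@reference) != 3L || !all(is.finite(object@reference)))
        return("reference must be a finite 3-vector")
    TRUE
})
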