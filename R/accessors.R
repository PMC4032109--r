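#' Accessors for Structure objects
#'
#' @param x a [Structure-class].
#' @param ... unused.
#' @return \code{atoms} returns the atom \code{data.frame}; \code{nAtoms} the
#'   atom count; \code{coords} an nAtoms x 3 coordinate matrix (Angstroms).
#' @name Structure-accessors
#' @aliases atoms nAtoms coords
#' @examples
#' s <- exampleStructure()
#' nAtoms(s)
#' head(coords(s))
NULL

#' @rdname Structure-accessors
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @rdname Structure-accessors
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

#' @rdname Structure-accessors
#' @export
setMethod("coords", "Structure", function(x, ...) {
    m <- as.matrix(x@atoms[, c("x", "y", "z")])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
})

#' Accessors for Trajectory objects
#'
#' @param x a [Trajectory-class].
#' @param i frame index (1-based).
#' @return \code{topology} the shared [Structure-class]; \code{nFrames} the
#'   frame count; \code{frameSpacing} the frame interval in ps;
#'   \code{trajLength} the total length in ns; \code{frameCoords} the
#'   nAtoms x 3 coordinates of frame \code{i}.
#' @name Trajectory-accessors
#' @aliases topology nFrames frameSpacing trajLength frameCoords
NULL

#' @rdname Trajectory-accessors
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname Trajectory-accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) nrow(x@xyz))

#' @rdname Trajectory-accessors
#' @export
setMethod("frameSpacing", "Trajectory", function(x) x@frameSpacing)

#' @rdname Trajectory-accessors
#' @export
setMethod("trajLength", "Trajectory",
          function(x) nrow(x@xyz) * x@frameSpacing / 1000)

#' @rdname Trajectory-accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
    stopifnot(length(i) == 1L, i >= 1L, i <= nrow(x@xyz))
    matrix(x@xyz[i, ], ncol = 3L, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
})

#' Accessors for DensityGrid objects
#'
#' @param x a [DensityGrid-class].
#' @return \code{gridValues} the 3-D occupancy array; \code{gridOrigin} the
#'   low corner (Angstroms); \code{gridSpacing} the voxel edge (Angstroms).
#' @name DensityGrid-accessors
#' @aliases gridValues gridOrigin gridSpacing
NULL

#' @rdname DensityGrid-accessors
#' @export
setMethod("gridValues", "DensityGrid", function(x) x@values)

#' @rdname DensityGrid-accessors
#' @export
setMethod("gridOrigin", "DensityGrid", function(x) x@origin)

#' @rdname DensityGrid-accessors
#' @export
setMethod("gridSpacing", "DensityGrid", function(x) x@spacing)

setMethod("show", "Structure", function(object) {
    a <- object@atoms
    cat(sprintf("Structure: %d atoms, %d residues, chains: %s\n",
                nrow(a), length(unique(paste(a$chain, a$resNo))),
                paste(unique(a$chain), collapse = " ")))
})

setMethod("show", "Trajectory", function(object) {
    cat(sprintf(
        "Trajectory: %d frames x %d atoms, dt = %g ps (%.4g ns total)\n",
        nrow(object@xyz), nAtoms(object@topology), object@frameSpacing,
        trajLength(object)))
})

setMethod("show", "SuperpositionResult", function(object) {
    cat(sprintf("SuperpositionResult: rmsd = %.4f A over %d fitted atoms\n",
                object@rmsd, max(1L, length(object@selection))))
})

setMethod("show", "BondVectorSeries", function(object) {
    cat(sprintf("BondVectorSeries: %s %s%d bond %s->%s, %d frames\n",
                object@resName, object@chain, object@resNo,
                object@bond[1], object@bond[2], nrow(object@vectors)))
})

setMethod("show", "DensityGrid", function(object) {
    cat(sprintf(
        "DensityGrid: %d x %d x %d voxels @ %g A, %d frames, mass %.6f\n",
        object@counts[1], object@counts[2], object@counts[3],
        object@spacing, object@nFrames, sum(object@values)))
})

setMethod("show", "HBondCriteria", function(object) {
    cat(sprintf("HBondCriteria: d(D-A) < %g A, deviation < %g deg (%s)\n",
                object@maxDistance, object@maxAngle, object@convention))
})

setMethod("show", "IonTrace", function(object) {
    cat(sprintf("IonTrace: %d frames, dt = %g ps, reference (%.2f %.2f %.2f)\n",
                nrow(object@positions), object@frameSpacing,
                object@reference[1], object@reference[2],
                object@reference[3]))
})
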