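#' Construct a Structure from an atom table
#'
#' Low-level constructor used by the readers and the synthetic generators.
#' Missing \code{serial} is filled with 1..n; missing \code{bFactor} with 0;
#' missing \code{element} is guessed from the first letter of the atom name.
#'
#' @param atoms data.frame with at least atomName, resName, chain, resNo,
#'   x, y, z.
#' @return a [Structure-class].
#' @export
#' @examples
#' s <- newStructure(data.frame(atomName = "CA", resName = "GLY",
#'                              chain = "A", resNo = 1, x = 0, y = 0, z = 0))
newStructure <- function(atoms) {
    atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
    if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
    if (is.null(atoms$bFactor)) atoms$bFactor <- 0
    if (is.null(atoms$recordType)) atoms$recordType <- "ATOM"
    if (is.null(atoms$element))
        atoms$element <- substr(gsub("[0-9]", "", atoms$atomName), 1L, 1L)
    atoms$resNo <- as.integer(atoms$resNo)
    atoms$serial <- as.integer(atoms$serial)
    rownames(atoms) <- NULL
    new("Structure", atoms = atoms[, .STRUCTURE_COLS])
}

#' Construct a Trajectory
#'
#' @param topology a [Structure-class].
#' @param xyz nFrames x 3*nAtoms coordinate matrix (x1,y1,z1,x2,... order),
#'   or a list of nAtoms x 3 frame matrices.
#' @param frameSpacing time between frames, ps.
#' @return a [Trajectory-class].
#' @export
newTrajectory <- function(topology, xyz, frameSpacing) {
    if (is.list(xyz))
        xyz <- do.call(rbind, lapply(xyz, function(m) as.vector(t(m))))
    new("Trajectory", topology = topology, xyz = xyz,
        frameSpacing = as.numeric(frameSpacing))
}

#' A tiny example structure (one aspartate fragment)
#'
#' @return a [Structure-class] with backbone and Cb/Cg atoms of one Asp.
#' @export
exampleStructure <- function() {
    newStructure(.aspFragment(chain = "A", resNo = 1L, offset = c(0, 0, 0)))
}

## minimal Asp residue: rigid backbone-like tetrad + CB, CG
.aspFragment <- function(chain = "A", resNo = 1L, offset = c(0, 0, 0),
                         cg = c(0, 0, 1.53)) {
    base <- rbind(
        N  = c(-1.20,  0.80, 0.00),
        CA = c( 0.00,  0.00, 0.00),
        C  = c( 1.30,  0.75, 0.00),
        O  = c( 1.35,  1.98, 0.10),
        CB = c( 0.00, -0.90, 1.20),
        CG = c( 0.00, -0.90, 1.20) + cg)
    df <- data.frame(atomName = rownames(base), resName = "ASP",
                     chain = chain, resNo = resNo,
                     x = base[, 1] + offset[1], y = base[, 2] + offset[2],
                     z = base[, 3] + offset[3],
                     stringsAsFactors = FALSE)
    df
}

## --- selections ------------------------------------------------------------

## "chain:resno:atomname" with "*" wildcards; atomname may be a comma list;
## a character vector of selections is a union.
.matchSelection <- function(structure, selection) {
    a <- atoms(structure)
    hit <- rep(FALSE, nrow(a))
    for (sel in selection) {
        parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
        if (length(parts) != 3L)
            stop("selection must be 'chain:resno:atomname', got: ", sel)
        ok <- rep(TRUE, nrow(a))
        if (parts[1] != "*") ok <- ok & a$chain == parts[1]
        if (parts[2] != "*") ok <- ok & a$resNo == as.integer(parts[2])
        if (parts[3] != "*") {
            names_ok <- trimws(strsplit(parts[3], ",", fixed = TRUE)[[1]])
            ok <- ok & a$atomName %in% names_ok
        }
        hit <- hit | ok
    }
    which(hit)
}

#' Default backbone fit selection
#'
#' Backbone N, CA, C, O atoms of all residues; the conservative standard
#' selection for rigid-body fitting.
#' @return a selection string.
#' @export
backboneSelection <- function() "*:*:N,CA,C,O"

## match atoms of `x` to atoms of `ref` by (chain, resNo, atomName);
## returns a 2-column index matrix (ix, iref), only atoms present in both
.pairAtoms <- function(x, ref) {
    ax <- atoms(x); ar <- atoms(ref)
    kx <- paste(ax$chain, ax$resNo, ax$atomName, sep = ":")
    kr <- paste(ar$chain, ar$resNo, ar$atomName, sep = ":")
    ir <- match(kx, kr)
    keep <- !is.na(ir)
    cbind(ix = which(keep), iref = ir[keep])
}

## run `expr` with a local RNG seeded at `seed`, restoring global state
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    set.seed(as.integer(seed))
    expr
}

.deg2rad <- function(x) x * pi / 180

## uniform random proper rotation matrices (quaternion method)
.randomRotation <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
}
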