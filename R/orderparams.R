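## Generalized order parameters S2 for sidechain bond vectors.
##
## S2 = (1/2) * (3 * sum_ij <mu_i mu_j>^2 - 1), the long-time plateau of the
## second-rank angular reorientational correlation function of a bond unit
## vector: 1 for a fully rigid bond, 0 for isotropic disorder.  <.> is the
## plain arithmetic average over all frames of an aligned trajectory.

## symmetry-axis bond per residue class
.S2_BONDS <- list(ASP = c("CB", "CG"), ASN = c("CB", "CG"),
                  GLU = c("CG", "CD"), GLN = c("CG", "CD"))
.DENQ_CODE <- c(D = "ASP", E = "GLU", N = "ASN", Q = "GLN")

#' Extract sidechain bond-vector series from an aligned trajectory
#'
#' For each selected Asp/Asn residue the Cb->Cg bond is used; for Glu/Gln,
#' Cg->Cd.  These are the symmetry axes carrying the sidechain carboxyl /
#' carboxamide groups whose dynamics sidechain NMR observables report on.
#' Vectors are normalized per frame.  The trajectory must already be
#' aligned (see [alignFrames()]); global tumbling left in the frames would
#' depress every S2 toward zero.
#'
#' @param traj an aligned [Trajectory-class].
#' @param residues which residue types to use, as one-letter codes from
#'   "DENQ" (default all four).
#' @return a list of [BondVectorSeries-class], one per selected residue.
#' @export
extractBondVectors <- function(traj, residues = "DENQ") {
    wanted <- unname(.DENQ_CODE[strsplit(toupper(residues), "")[[1]]])
    if (any(is.na(wanted))) stop("residues must be letters from DENQ")
    a <- atoms(topology(traj))
    resKey <- paste(a$chain, a$resNo)
    out <- list()
    for (key in unique(resKey[a$resName %in% wanted])) {
        rows <- which(resKey == key)
        rn <- a$resName[rows[1]]
        bond <- .S2_BONDS[[rn]]
        iFrom <- rows[a$atomName[rows] == bond[1]]
        iTo <- rows[a$atomName[rows] == bond[2]]
        if (length(iFrom) != 1L || length(iTo) != 1L)
            stop(sprintf("residue %s %s lacks bond atoms %s-%s",
                         rn, key, bond[1], bond[2]))
        v <- traj@xyz[, (3L * (iTo - 1L) + 1L):(3L * iTo), drop = FALSE] -
            traj@xyz[, (3L * (iFrom - 1L) + 1L):(3L * iFrom), drop = FALSE]
        nrm <- sqrt(rowSums(v * v))
        if (any(nrm == 0))
            stop(sprintf("zero-length bond vector for residue %s at frame %d",
                         key, which(nrm == 0)[1]))
        v <- v / nrm
        out[[length(out) + 1L]] <- new(
            "BondVectorSeries", chain = a$chain[rows[1]],
            resNo = a$resNo[rows[1]], resName = rn, bond = bond,
            vectors = unname(v))
    }
    out
}

.seriesVectors <- function(series) {
    if (is(series, "BondVectorSeries")) series@vectors
    else as.matrix(series)
}

#' Generalized order parameter of a bond-vector series
#'
#' Computes \code{S2 = (3 * sum_ij <mu_i mu_j>^2 - 1) / 2} with the average
#' taken over all frames and i, j running over x, y, z.  Equals 1 for a
#' fixed vector and 0 in the isotropic limit; values as low as -0.5 are
#' algebraically possible for finite noisy samples.
#'
#' @param series a [BondVectorSeries-class] or an n x 3 matrix of unit
#'   vectors (n >= 2).
#' @return the scalar S2 (dimensionless).
#' @export
#' @examples
#' computeS2(matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE))  # 1
computeS2 <- function(series) {
    v <- .seriesVectors(series)
    if (nrow(v) < 2L) stop("need at least 2 frames")
    nrm2 <- rowSums(v * v)
    if (max(abs(sqrt(nrm2) - 1)) > 1e-4)
        stop("input vectors are not unit length")
    M <- crossprod(v) / nrow(v)        # M[i,j] = <mu_i mu_j>
    0.5 * (3 * sum(M * M) - 1)
}

#' S2 with a block-averaged standard error
#'
#' The series is split into \code{nBlocks} contiguous equal blocks (any
#' remainder frames are dropped from the end), S2 is computed on each block,
#' and the SEM is the standard deviation of the per-block values divided by
#' \code{sqrt(nBlocks)}.  The reported \code{s2} itself uses the full series.
#' Block averaging absorbs the serial correlation of trajectory frames that
#' a naive per-frame SEM would ignore.
#'
#' @param series a [BondVectorSeries-class] or n x 3 unit-vector matrix.
#' @param nBlocks number of blocks (>= 2; default 10).
#' @return list with \code{s2}, \code{sem}, \code{nFrames} (frames used),
#'   \code{nBlocks} and the per-block values \code{blockS2}.
#' @export
blockSEM <- function(series, nBlocks = 10L) {
    nBlocks <- as.integer(nBlocks)
    if (nBlocks < 2L) stop("nBlocks must be at least 2")
    v <- .seriesVectors(series)
    n <- nrow(v)
    if (n < 2L * nBlocks)
        stop("need at least 2 frames per block")
    bl <- n %/% nBlocks
    blockS2 <- vapply(seq_len(nBlocks), function(b)
        computeS2(v[((b - 1L) * bl + 1L):(b * bl), , drop = FALSE]),
        numeric(1))
    list(s2 = computeS2(v), sem = stats::sd(blockS2) / sqrt(nBlocks),
         nFrames = n, nBlocks = nBlocks, blockS2 = blockS2)
}

#' Per-residue order-parameter table for a trajectory
#'
#' Convenience wrapper: extracts DENQ bond vectors and computes S2 with
#' block-averaged SEMs for each residue.
#'
#' @param traj an aligned [Trajectory-class].
#' @param residues one-letter codes from "DENQ".
#' @param nBlocks blocks for the SEM (default 10).
#' @return data.frame with columns chain, resNo, resName, bond, s2, sem,
#'   nFrames, nBlocks.
#' @export
orderParameters <- function(traj, residues = "DENQ", nBlocks = 10L) {
    series <- extractBondVectors(traj, residues)
    rows <- lapply(series, function(s) {
        b <- blockSEM(s, nBlocks)
        data.frame(chain = s@chain, resNo = s@resNo, resName = s@resName,
                   bond = paste(s@bond, collapse = "-"),
                   s2 = b$s2, sem = b$sem, nFrames = b$nFrames,
                   nBlocks = b$nBlocks, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Compare per-residue S2 between two conditions
#'
#' For each residue present in both tables, reports the difference
#' \code{deltaS2 = s2_a - s2_b}, the pooled SEM
#' \code{sqrt(sem_a^2 + sem_b^2)}, and a per-residue significance call
#' \code{|deltaS2| > 1.96 * pooledSem} (a plain two-sided 5% normal
#' criterion; no multiple-testing correction).
#'
#' @param a,b data.frames as returned by [orderParameters()] (columns chain,
#'   resNo, s2, sem); must cover the same residues.
#' @return data.frame with chain, resNo, resName, deltaS2, pooledSem,
#'   significant.
#' @export
compareS2 <- function(a, b) {
    ka <- paste(a$chain, a$resNo)
    kb <- paste(b$chain, b$resNo)
    if (length(ka) != length(kb) || !setequal(ka, kb))
        stop("residue sets do not match between conditions")
    ib <- match(ka, kb)
    deltaS2 <- a$s2 - b$s2[ib]
    pooledSem <- sqrt(a$sem^2 + b$sem[ib]^2)
    data.frame(chain = a$chain, resNo = a$resNo,
               resName = if (!is.null(a$resName)) a$resName else NA,
               deltaS2 = deltaS2, pooledSem = pooledSem,
               significant = abs(deltaS2) > 1.96 * pooledSem,
               stringsAsFactors = FALSE)
}
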