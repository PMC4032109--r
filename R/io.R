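## PDB / trajectory / OpenDX / result-table I/O.
## Fixed-column PDB parsing and writing are delegated to bio3d; a light
## pre-scan supplies precise line-number / frame-index diagnostics.

.scanPdbLines <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- grepl("^(ATOM  |HETATM)", lines)
    if (!any(rec))
        stop("empty input: no ATOM/HETATM records in ", path)
    for (i in which(rec)) {
        ln <- lines[i]
        if (nchar(ln) < 54L)
            stop(sprintf("malformed PDB record at line %d: too short", i))
        xyz <- suppressWarnings(as.numeric(c(
            substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
        if (any(is.na(xyz)))
            stop(sprintf(
                "malformed PDB record at line %d: unparseable coordinates", i))
    }
    lines
}

#' Read a protein structure from a PDB file
#'
#' Reads all ATOM and HETATM records of the first model.  Alternate
#' locations other than '' or 'A' are dropped so that the topology is
#' deterministic.  Coordinates are in Angstroms; the B-factor column is
#' preserved.
#'
#' @param path path to a PDB file.
#' @return a [Structure-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writePdbStructure(exampleStructure(), f)
#' readPdbStructure(f)
readPdbStructure <- function(path) {
    .scanPdbLines(path)
    p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                          verbose = FALSE))
    a <- p$atom
    chain <- ifelse(is.na(a$chain), "A", a$chain)
    elesy <- ifelse(is.na(a$elesy) | a$elesy == "",
                    substr(gsub("[0-9]", "", a$elety), 1L, 1L),
                    a$elesy)
    newStructure(data.frame(
        serial = a$eleno, atomName = a$elety, resName = a$resid,
        chain = chain, resNo = a$resno,
        x = a$x, y = a$y, z = a$z,
        bFactor = ifelse(is.na(a$b), 0, a$b),
        element = elesy, recordType = a$type,
        stringsAsFactors = FALSE))
}

#' Write a Structure to a PDB file
#'
#' @param structure a [Structure-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePdbStructure <- function(structure, path) {
    a <- atoms(structure)
    bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(
                         a[, c("x", "y", "z")]))),
                     type = a$recordType, resno = a$resNo, resid = a$resName,
                     eleno = a$serial, elety = a$atomName, chain = a$chain,
                     b = a$bFactor, elesy = a$element)
    invisible(path)
}

#' Read a trajectory from multi-model PDB or DCD
#'
#' Frames are taken in file order; atoms correspond to the topology by
#' position in record order.  The frame-saving interval is not carried by
#' either format and must be supplied.
#'
#' @param path multi-model PDB (MODEL/ENDMDL) or a .dcd file.
#' @param topology the [Structure-class] shared by all frames.
#' @param frameSpacing time between frames, ps.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology, frameSpacing) {
    na <- nAtoms(topology)
    if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
        xyz <- bio3d::read.dcd(path, verbose = FALSE)
        if (ncol(xyz) != 3L * na)
            stop(sprintf("DCD atom count %d does not match topology (%d)",
                         ncol(xyz) / 3L, na))
        return(newTrajectory(topology, unclass(xyz), frameSpacing))
    }
    lines <- .scanPdbLines(path)
    modelStarts <- grep("^MODEL", lines)
    if (length(modelStarts) > 0L) {
        ends <- grep("^ENDMDL", lines)
        if (length(ends) != length(modelStarts))
            stop("unbalanced MODEL/ENDMDL records in ", path)
        for (k in seq_along(modelStarts)) {
            cnt <- sum(grepl("^(ATOM  |HETATM)",
                             lines[modelStarts[k]:ends[k]]))
            if (cnt != na)
                stop(sprintf(
                    "frame %d has %d atoms; topology has %d", k, cnt, na))
        }
    } else if (sum(grepl("^(ATOM  |HETATM)", lines)) != na) {
        stop(sprintf("frame 1 has %d atoms; topology has %d",
                     sum(grepl("^(ATOM  |HETATM)", lines)), na))
    }
    p <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          verbose = FALSE))
    xyz <- unclass(p$xyz)
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    newTrajectory(topology, xyz, frameSpacing)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTrajectory <- function(traj, path) {
    a <- atoms(topology(traj))
    bio3d::write.pdb(file = path, xyz = traj@xyz,
                     type = a$recordType, resno = a$resNo, resid = a$resName,
                     eleno = a$serial, elety = a$atomName, chain = a$chain,
                     b = a$bFactor, elesy = a$element)
    invisible(path)
}

## --- OpenDX scalar fields --------------------------------------------------

#' Write a DensityGrid as an OpenDX scalar field
#'
#' Standard OpenDX regular-grid layout: \code{gridpositions} with origin and
#' three axis-aligned deltas, then the data array with the z index varying
#' fastest (x slowest), three values per line.  Readable by VMD, PyMOL and
#' gridDataFormats.
#'
#' @param grid a [DensityGrid-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeDensityDX <- function(grid, path) {
    ct <- grid@counts
    n <- prod(ct)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "# OpenDX fractional-occupancy map (unsmoothed nearest-voxel binning)",
        sprintf("# frames: %d", grid@nFrames),
        sprintf("object 1 class gridpositions counts %d %d %d",
                ct[1], ct[2], ct[3]),
        sprintf("origin %.6f %.6f %.6f",
                grid@origin[1], grid@origin[2], grid@origin[3]),
        sprintf("delta %.6f 0.000000 0.000000", grid@spacing),
        sprintf("delta 0.000000 %.6f 0.000000", grid@spacing),
        sprintf("delta 0.000000 0.000000 %.6f", grid@spacing),
        sprintf("object 2 class gridconnections counts %d %d %d",
                ct[1], ct[2], ct[3]),
        sprintf("object 3 class array type double rank 0 items %d data follows",
                n)), con)
    v <- as.vector(aperm(grid@values, c(3L, 2L, 1L)))  # z fastest
    pad <- c(v, rep(NA_real_, (3L - length(v) %% 3L) %% 3L))
    m <- matrix(sprintf("%.6e", pad), ncol = 3L, byrow = TRUE)
    rows <- apply(m, 1L, function(r) paste(r[!grepl("NA", r)], collapse = " "))
    writeLines(rows, con)
    writeLines(c('attribute "dep" string "positions"',
                 'object "density" class field',
                 'component "positions" value 1',
                 'component "connections" value 2',
                 'component "data" value 3'), con)
    invisible(path)
}

#' Read an OpenDX scalar field written by [writeDensityDX()]
#'
#' @param path a .dx file.
#' @return a [DensityGrid-class] (nFrames is taken from the header comment
#'   when present, else 0).
#' @export
readDensityDX <- function(path) {
    lines <- readLines(path, warn = FALSE)
    gp <- grep("class gridpositions", lines, value = TRUE)[1]
    ct <- as.integer(utils::tail(strsplit(gp, "\\s+")[[1]], 3L))
    og <- grep("^origin", lines, value = TRUE)[1]
    origin <- as.numeric(strsplit(og, "\\s+")[[1]][2:4])
    dl <- grep("^delta", lines, value = TRUE)
    spacing <- max(as.numeric(strsplit(dl[1], "\\s+")[[1]][2:4]))
    nfLine <- grep("^# frames:", lines, value = TRUE)
    nf <- if (length(nfLine)) as.integer(sub("^# frames:\\s*", "", nfLine[1]))
          else 0L
    dataStart <- grep("data follows", lines)[1]
    dataEnd <- grep("^attribute", lines)[1] - 1L
    v <- as.numeric(unlist(strsplit(trimws(
        lines[(dataStart + 1L):dataEnd]), "\\s+")))
    stopifnot(length(v) == prod(ct))
    vals <- aperm(array(v, dim = rev(ct)), c(3L, 2L, 1L))
    new("DensityGrid", origin = origin, spacing = spacing, counts = ct,
        values = vals, nFrames = nf)
}

## --- result tables ---------------------------------------------------------

#' Write a result table as TSV with provenance comments
#'
#' Metadata key/value pairs (input files, parameters, seed, package version)
#' are written as leading \code{# key: value} comment lines.  Numeric columns
#' are formatted with a fixed \code{\%.6g} so identical runs produce
#' byte-identical files.
#'
#' @param df a data.frame.
#' @param path output file path.
#' @param metadata named list of provenance values.
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(df, path, metadata = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(metadata))
        writeLines(sprintf("# %s: %s", k, as.character(metadata[[k]])), con)
    out <- df
    for (j in seq_along(out))
        if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
            out[[j]] <- sprintf("%.6g", out[[j]])
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a TSV result table written by [writeResultTable()]
#'
#' @param path file path.
#' @return a data.frame; provenance comments are attached as
#'   \code{attr(, "metadata")}.
#' @export
readResultTable <- function(path) {
    lines <- readLines(path, warn = FALSE)
    metaLines <- grep("^# ", lines, value = TRUE)
    meta <- list()
    for (ml in metaLines) {
        kv <- sub("^# ", "", ml)
        k <- sub(":.*$", "", kv)
        meta[[k]] <- trimws(sub("^[^:]*:", "", kv))
    }
    df <- utils::read.table(text = lines[!grepl("^# ", lines)], sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    attr(df, "metadata") <- meta
    df
}
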