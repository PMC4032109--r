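#' @rdname Structure-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Structure-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Structure-accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("frameSpacing", function(x) standardGeneric("frameSpacing"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("trajLength", function(x) standardGeneric("trajLength"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname DensityGrid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
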