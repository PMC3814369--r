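#' @rdname ChainModel-accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @rdname AssemblyModel-accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname ChainModel-accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname ChainModel-accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname AssemblyModel-accessors
#' @export
setGeneric("caTable", function(x) standardGeneric("caTable"))

#' Apply a rigid-body transform
#'
#' Transforms all atom coordinates of a chain or assembly (or the rows of
#' an n x 3 coordinate matrix) by `x' = R x + t`. Pairwise distances are
#' preserved to numerical precision.
#'
#' @param x a `ChainModel`, `AssemblyModel`, or n x 3 coordinate matrix.
#' @param transform a [RigidTransform].
#' @return the transformed object, same class as `x`.
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))

#' @rdname CrossLinkSet-accessors
#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))
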