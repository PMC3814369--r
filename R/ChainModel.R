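#' Construct a single-chain backbone model
#'
#' @param chainId chain identifier.
#' @param atoms data.frame with columns `resno`, `code`, `elety`
#'   (N/CA/C/O), `x`, `y`, `z`. Every residue must carry a CA atom.
#' @param provenance optional data.frame (`resno`, `source`); defaults to
#'   `source = "input"` for every residue.
#' @return a [ChainModel-class].
#' @export
ChainModel <- function(chainId, atoms, provenance = NULL) {
  atoms <- as.data.frame(atoms)
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(provenance)) {
    provenance <- data.frame(resno = unique(atoms$resno),
                             source = "input",
                             stringsAsFactors = FALSE)
  }
  new("ChainModel", chainId = as.character(chainId), atoms = atoms,
      provenance = as.data.frame(provenance))
}

#' Accessors for ChainModel
#'
#' `chainId` returns the chain identifier, `residueNumbers` the ordered
#' residue numbers, `caCoords` the n x 3 matrix of CA coordinates (row
#' names are residue numbers).
#'
#' @param x a [ChainModel-class].
#' @name ChainModel-accessors
NULL

#' @rdname ChainModel-accessors
#' @export
setMethod("chainId", "ChainModel", function(x) x@chainId)

#' @rdname ChainModel-accessors
#' @export
setMethod("residueNumbers", "ChainModel",
          function(x) unique(x@atoms$resno))

#' @rdname ChainModel-accessors
#' @export
setMethod("caCoords", "ChainModel", function(x) {
  ca <- x@atoms[x@atoms$elety == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
})

#' @export
setMethod("length", "ChainModel", function(x) length(unique(x@atoms$resno)))

#' @export
setMethod("show", "ChainModel", function(object) {
  n <- length(object)
  rng <- if (n) range(object@atoms$resno) else c(NA, NA)
  cat(sprintf("ChainModel '%s': %d residues (%s-%s), %d atoms\n",
              object@chainId, n, rng[1], rng[2], nrow(object@atoms)))
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "ChainModel", function(x, transform) {
  xyz <- as.matrix(x@atoms[, c("x", "y", "z")])
  xyz <- transformCoords(xyz, transform)
  a <- x@atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  initialize(x, atoms = a)
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform) {
  transformCoords(x, transform)
})

#' Extract the one-letter sequence of the modeled residues
#'
#' @param x a [ChainModel-class].
#' @return named character vector of one-letter codes (names are residue
#'   numbers).
#' @export
chainSequence <- function(x) {
  stopifnot(is(x, "ChainModel"))
  ca <- x@atoms[x@atoms$elety == "CA", ]
  stats::setNames(ca$code, ca$resno)
}
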