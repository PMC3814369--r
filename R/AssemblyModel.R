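#' Construct a multi-chain assembly model
#'
#' @param chains list of [ChainModel-class] objects with unique chain ids,
#'   or a single `ChainModel`.
#' @param metadata named list of free-form provenance (transforms applied,
#'   mapping choice, interface metrics).
#' @return an [AssemblyModel-class].
#' @export
AssemblyModel <- function(chains = list(), metadata = list()) {
  if (is(chains, "ChainModel")) chains <- list(chains)
  ids <- vapply(chains, chainId, character(1))
  names(chains) <- ids
  new("AssemblyModel", chains = chains, metadata = metadata)
}

#' Accessors for AssemblyModel
#'
#' `chainIds` returns the chain identifiers; `caTable` a data.frame of
#' all CA atoms (`chain`, `resno`, `x`, `y`, `z`); `caCoords` the bare
#' n x 3 coordinate matrix.
#'
#' @param x an [AssemblyModel-class].
#' @name AssemblyModel-accessors
NULL

#' @rdname AssemblyModel-accessors
#' @export
setMethod("chainIds", "AssemblyModel",
          function(x) vapply(x@chains, chainId, character(1), USE.NAMES = FALSE))

#' @rdname AssemblyModel-accessors
#' @export
setMethod("caTable", "AssemblyModel", function(x) {
  out <- lapply(x@chains, function(ch) {
    ca <- ch@atoms[ch@atoms$elety == "CA", , drop = FALSE]
    data.frame(chain = ch@chainId, resno = ca$resno,
               x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
})

#' @rdname AssemblyModel-accessors
#' @export
setMethod("caCoords", "AssemblyModel", function(x) {
  tb <- caTable(x)
  if (is.null(tb)) return(matrix(numeric(0), 0, 3))
  m <- as.matrix(tb[, c("x", "y", "z")])
  rownames(m) <- paste0(tb$chain, ":", tb$resno)
  m
})

#' @export
setMethod("length", "AssemblyModel", function(x) length(x@chains))

#' @export
setMethod("show", "AssemblyModel", function(object) {
  cat(sprintf("AssemblyModel: %d chain(s)\n", length(object@chains)))
  for (ch in object@chains) {
    cat("  "); show(ch)
  }
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "AssemblyModel", function(x, transform) {
  chains <- lapply(x@chains, applyTransform, transform = transform)
  md <- x@metadata
  md$transforms <- c(md$transforms, list(transform))
  initialize(x, chains = chains, metadata = md)
})

#' Get a chain from an assembly
#'
#' @param model an [AssemblyModel-class].
#' @param id chain identifier.
#' @return the [ChainModel-class]; error if absent.
#' @export
getChain <- function(model, id) {
  stopifnot(is(model, "AssemblyModel"))
  if (!id %in% names(model@chains))
    stop(sprintf("chain '%s' not in model (has: %s)", id,
                 paste(names(model@chains), collapse = ", ")))
  model@chains[[id]]
}

#' Combine assemblies or chains into one model
#'
#' @param ... `AssemblyModel` and/or `ChainModel` objects.
#' @param metadata metadata for the combined model.
#' @return an [AssemblyModel-class]; error on chain-id collision.
#' @export
combineModels <- function(..., metadata = list()) {
  parts <- list(...)
  chains <- list()
  for (p in parts) {
    if (is(p, "ChainModel")) chains <- c(chains, list(p))
    else if (is(p, "AssemblyModel")) chains <- c(chains, unname(p@chains))
    else stop("combineModels accepts ChainModel and AssemblyModel objects")
  }
  AssemblyModel(chains, metadata = metadata)
}

#' Rename chains of an assembly
#'
#' @param model an [AssemblyModel-class].
#' @param map named character vector, old id -> new id.
#' @return the renamed model.
#' @export
renameChains <- function(model, map) {
  chains <- lapply(model@chains, function(ch) {
    if (ch@chainId %in% names(map))
      initialize(ch, chainId = unname(map[[ch@chainId]]))
    else ch
  })
  AssemblyModel(chains, metadata = model@metadata)
}
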