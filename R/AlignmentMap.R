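#' Construct a residue-residue alignment map
#'
#' @param query query subunit name.
#' @param templateChain template chain identifier.
#' @param pairs two-column matrix or data.frame of aligned residue
#'   numbers (`query`, `template`), both 1-based and strictly increasing.
#' @return an [AlignmentMap-class].
#' @export
AlignmentMap <- function(query, templateChain, pairs) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("query", "template")
  new("AlignmentMap", query = as.character(query),
      templateChain = as.character(templateChain), pairs = pairs)
}

#' Build an alignment from contiguous-range shorthand
#'
#' Parses strings of the form `"46-127:19-108"` (comma-separated for
#' several segments) into an ungapped [AlignmentMap-class]. When the two
#' ranges of a segment differ in length — as they do when a gapped
#' alignment is summarized by its end points — positions are paired from
#' the range starts and the longer range's tail is left unaligned.
#'
#' @param query query subunit name.
#' @param templateChain template chain identifier.
#' @param ranges shorthand string, e.g. `"46-127:19-108"`.
#' @return an [AlignmentMap-class].
#' @examples
#' alignmentFromRanges("Med4", "A", "46-127:19-108")
#' @export
alignmentFromRanges <- function(query, templateChain, ranges) {
  segs <- strsplit(ranges, ",", fixed = TRUE)[[1]]
  pairs <- lapply(segs, function(s) {
    m <- regmatches(s, regexec("^\\s*(\\d+)-(\\d+):(\\d+)-(\\d+)\\s*$", s))[[1]]
    if (length(m) != 5)
      stop("range shorthand must look like '46-127:19-108', got: ", s)
    v <- as.integer(m[-1])
    q <- v[1]:v[2]; t <- v[3]:v[4]
    n <- min(length(q), length(t))
    cbind(q[seq_len(n)], t[seq_len(n)])
  })
  AlignmentMap(query, templateChain, do.call(rbind, pairs))
}

#' @export
setMethod("length", "AlignmentMap", function(x) nrow(x@pairs))

#' @export
setMethod("show", "AlignmentMap", function(object) {
  p <- object@pairs
  cat(sprintf("AlignmentMap %s -> chain %s: %d pairs (%d-%d : %d-%d)\n",
              object@query, object@templateChain, nrow(p),
              p[1, 1], p[nrow(p), 1], p[1, 2], p[nrow(p), 2]))
})
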