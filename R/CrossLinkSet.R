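#' Construct a cross-link set
#'
#' Builds a [CrossLinkSet-class] from a data.frame of site pairs. Each
#' row's two sites are put into canonical (unordered) form — the
#' lexicographically smaller `(subunit, residue)` site first — and
#' `link_class` is recomputed from subunit equality. No deduplication is
#' performed; see [deduplicateLinks()].
#'
#' @param df data.frame with columns `subunit_a`, `residue_a`,
#'   `subunit_b`, `residue_b` and optionally `spectral_count` (default 1)
#'   and `spectrum_id`.
#' @param sequences optional named character vector or `AAStringSet`; when
#'   given, residue indices are checked against subunit lengths.
#' @return a [CrossLinkSet-class].
#' @export
CrossLinkSet <- function(df, sequences = NULL) {
  df <- as.data.frame(df)
  need <- c("subunit_a", "residue_a", "subunit_b", "residue_b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df$subunit_a <- as.character(df$subunit_a)
  df$subunit_b <- as.character(df$subunit_b)
  df$residue_a <- as.integer(df$residue_a)
  df$residue_b <- as.integer(df$residue_b)
  if (anyNA(df$residue_a) || anyNA(df$residue_b))
    stop("residue indices must be integers")
  if (is.null(df$spectral_count)) df$spectral_count <- rep(1L, nrow(df))
  if (nrow(df)) {
    # canonical unordered site order
    swap <- (df$subunit_b < df$subunit_a) |
      (df$subunit_b == df$subunit_a & df$residue_b < df$residue_a)
    if (any(swap)) {
      tmp_s <- df$subunit_a[swap]; tmp_r <- df$residue_a[swap]
      df$subunit_a[swap] <- df$subunit_b[swap]
      df$residue_a[swap] <- df$residue_b[swap]
      df$subunit_b[swap] <- tmp_s
      df$residue_b[swap] <- tmp_r
    }
  }
  df$link_class <- ifelse(df$subunit_a == df$subunit_b, "intra", "inter")
  if (!is.null(sequences)) {
    lens <- sequenceLengths(sequences)
    for (side in c("a", "b")) {
      su <- df[[paste0("subunit_", side)]]
      rs <- df[[paste0("residue_", side)]]
      known <- su %in% names(lens)
      bad <- known & (rs < 1L | rs > lens[su])
      if (any(bad))
        stop(sprintf("residue index out of range for subunit %s (row %d)",
                     su[which(bad)[1]], which(bad)[1]))
    }
  }
  keep <- intersect(c("subunit_a", "residue_a", "subunit_b", "residue_b",
                      "spectral_count", "link_class", "spectrum_id"),
                    names(df))
  new("CrossLinkSet", links = df[, keep, drop = FALSE])
}

#' Accessors for CrossLinkSet
#'
#' `linkTable` returns the underlying data.frame.
#'
#' @param x a [CrossLinkSet-class].
#' @name CrossLinkSet-accessors
NULL

#' @rdname CrossLinkSet-accessors
#' @export
setMethod("linkTable", "CrossLinkSet", function(x) x@links)

#' @export
setMethod("length", "CrossLinkSet", function(x) nrow(x@links))

#' @export
setMethod("show", "CrossLinkSet", function(object) {
  df <- object@links
  cat(sprintf("CrossLinkSet: %d pair(s) (%d intra, %d inter), %d spectra\n",
              nrow(df), sum(df$link_class == "intra"),
              sum(df$link_class == "inter"), sum(df$spectral_count)))
  if (nrow(df)) print(utils::head(df, 6))
  if (nrow(df) > 6) cat("  ...\n")
})

setMethod("as.data.frame", "CrossLinkSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@links)

# lengths of sequences given as AAStringSet or named character vector
sequenceLengths <- function(sequences) {
  if (is(sequences, "XStringSet")) {
    stats::setNames(Biostrings::width(sequences), names(sequences))
  } else {
    stats::setNames(nchar(sequences), names(sequences))
  }
}

# sequences as a plain named character vector
asSequenceVector <- function(sequences) {
  if (is(sequences, "XStringSet")) {
    stats::setNames(as.character(sequences), names(sequences))
  } else {
    sequences
  }
}
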