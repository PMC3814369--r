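#' Monoisotopic peptide mass
#'
#' Sum of the standard monoisotopic residue masses plus one water
#' (18.010565 Da).
#'
#' @param sequence non-empty string of standard one-letter codes.
#' @return mass in Da.
#' @examples
#' peptideMass("G")   # 75.03203
#' peptideMass("AG")  # 146.06913
#' @export
peptideMass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  aa <- strsplit(sequence, "")[[1]]
  m <- .RESIDUE_MASS[aa]
  if (anyNA(m))
    stop("unknown residue code(s): ",
         paste(unique(aa[is.na(m)]), collapse = ""))
  sum(m) + .MASS_WATER
}

# 1-based positions after which an enzyme cleaves
cleavageSites <- function(sequence, enzyme, glucResidues = "E") {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  sites <- integer(0)
  if (enzyme %in% c("trypsin", "trypsin+gluc")) {
    # C-terminal of K/R, except before proline
    kr <- which(aa %in% c("K", "R"))
    kr <- kr[kr < n & aa[kr + 1L] != "P"]
    sites <- c(sites, kr)
  }
  if (enzyme %in% c("gluc", "trypsin+gluc")) {
    e <- which(aa %in% glucResidues)
    sites <- c(sites, e[e < n])
  }
  sort(unique(sites))
}

#' In-silico protease digestion
#'
#' Trypsin cleaves C-terminal of K/R except before proline; GluC cleaves
#' C-terminal of glutamate (aspartate optionally, via `glucResidues`);
#' the combined enzyme uses the union of sites. Returns all peptides with
#' 0..`maxMissed` internal missed cleavage sites. For `maxMissed = 0` the
#' peptides tile the sequence exactly.
#'
#' @param sequence amino-acid string, or a single named element of an
#'   `AAStringSet` / named character vector (the name is carried through).
#' @param enzyme one of `"trypsin"`, `"gluc"`, `"trypsin+gluc"`.
#' @param maxMissed maximum number of missed cleavages (>= 0).
#' @param subunit subunit name recorded on the peptides.
#' @param glucResidues residues GluC cleaves after (default `"E"`).
#' @return data.frame with columns `subunit`, `start`, `end`, `sequence`,
#'   `missed`, `mass`.
#' @examples
#' digest("AKRPK", "trypsin")           # AK, RPK
#' digest("KKK", "trypsin", maxMissed = 1)
#' @export
digest <- function(sequence, enzyme = c("trypsin", "gluc", "trypsin+gluc"),
                   maxMissed = 0, subunit = NULL, glucResidues = "E") {
  enzyme <- match.arg(enzyme)
  if (is(sequence, "XStringSet") ||
      (!is.null(names(sequence)) && length(sequence) == 1L)) {
    if (is.null(subunit)) subunit <- names(sequence)[1]
    sequence <- asSequenceVector(sequence)[[1]]
  }
  if (!nzchar(sequence)) stop("cannot digest an empty sequence")
  if (is.null(subunit)) subunit <- NA_character_
  stopifnot(maxMissed >= 0)
  n <- nchar(sequence)
  sites <- cleavageSites(sequence, enzyme, glucResidues)
  bounds <- c(0L, sites, n)           # segment k spans bounds[k]+1 .. bounds[k+1]
  nseg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nseg)) {
    for (m in 0:min(maxMissed, nseg - i)) {
      start <- bounds[i] + 1L
      end <- bounds[i + 1L + m]
      rows[[length(rows) + 1L]] <-
        data.frame(subunit = subunit, start = start, end = end,
                   sequence = substr(sequence, start, end),
                   missed = m, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$mass <- vapply(out$sequence, peptideMass, numeric(1), USE.NAMES = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}
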