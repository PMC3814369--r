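#' Read backbone chain models from a PDB file
#'
#' Parses ATOM records (via bio3d) into one [ChainModel-class] per chain.
#' Only backbone atoms (N, CA, C, O) of standard residues are retained;
#' residues lacking a CA are dropped with a warning. Alternate locations
#' are resolved by keeping the first-listed conformer. Files using
#' insertion codes are rejected with an error, as are malformed
#' coordinate fields (reported with their line number).
#'
#' @param file path to a PDB file, or a character vector of PDB lines.
#' @param chainFilter optional character vector of chain ids to keep.
#' @return list of [ChainModel-class], one per chain, in file order.
#' @export
readPDB <- function(file, chainFilter = NULL) {
  if (length(file) > 1L || grepl("\n", file[1], fixed = TRUE)) {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(lines, file)
  } else {
    lines <- readLines(file, warn = FALSE)
  }
  isatom <- grepl("^ATOM  |^HETATM", lines)
  if (!any(grepl("^ATOM  ", lines)))
    stop("no ATOM records found: empty structure")
  # validate fixed-column coordinate fields before handing to the parser
  for (i in which(isatom)) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[i], cols[1], cols[2])))
      if (is.na(v))
        stop(sprintf("malformed coordinate field at line %d", i))
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported")
  codes <- suppressWarnings(bio3d::aa321(at$resid))
  at <- at[codes %in% .AA_CODES, , drop = FALSE]
  at$code <- suppressWarnings(bio3d::aa321(at$resid))
  if (!nrow(at)) stop("no standard-residue ATOM records found")
  # first-listed altloc conformer per (chain, residue, atom)
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  at <- at[!duplicated(key), , drop = FALSE]
  at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  chains <- unique(at$chain)
  if (!is.null(chainFilter)) chains <- chains[chains %in% chainFilter]
  out <- lapply(chains, function(cid) {
    ai <- at[at$chain == cid, , drop = FALSE]
    has_ca <- ai$resno %in% ai$resno[ai$elety == "CA"]
    if (any(!has_ca)) {
      warning(sprintf("chain %s: dropped %d residue(s) without CA",
                      cid, length(unique(ai$resno[!has_ca]))))
      ai <- ai[has_ca, , drop = FALSE]
    }
    ai <- ai[order(ai$resno, match(ai$elety, c("N", "CA", "C", "O"))), ]
    ChainModel(cid, data.frame(
      resno = ai$resno, code = ai$code, elety = ai$elety,
      x = ai$x, y = ai$y, z = ai$z, stringsAsFactors = FALSE))
  })
  names(out) <- chains
  out
}

#' Read a PDB file directly into an assembly
#'
#' @inheritParams readPDB
#' @return an [AssemblyModel-class].
#' @export
readPDBAssembly <- function(file, chainFilter = NULL) {
  AssemblyModel(readPDB(file, chainFilter))
}

# one-letter -> three-letter residue codes for writing
.aa123 <- function(code) {
  tab <- c(G = "GLY", A = "ALA", S = "SER", P = "PRO", V = "VAL",
           T = "THR", C = "CYS", L = "LEU", I = "ILE", N = "ASN",
           D = "ASP", Q = "GLN", K = "LYS", E = "GLU", M = "MET",
           H = "HIS", F = "PHE", R = "ARG", Y = "TYR", W = "TRP")
  out <- tab[code]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Write a model as PDB text
#'
#' Writes ATOM records in fixed-column PDB format (coordinates to three
#' decimals). Round-tripping through [readPDB()] reproduces chain ids,
#' residue numbers and coordinates at PDB precision.
#'
#' @param model an [AssemblyModel-class] or [ChainModel-class].
#' @param file output path; omit (`NULL`) to return the lines invisibly
#'   without writing.
#' @return invisibly, the character vector of PDB lines.
#' @export
writePDB <- function(model, file = NULL) {
  if (is(model, "ChainModel")) model <- AssemblyModel(list(model))
  stopifnot(is(model, "AssemblyModel"))
  if (length(model@chains) == 0L ||
      all(vapply(model@chains, function(ch) nrow(ch@atoms) == 0L, logical(1))))
    stop("cannot write an empty model")
  lines <- character()
  serial <- 0L
  for (ch in model@chains) {
    if (nchar(ch@chainId) != 1L)
      stop(sprintf("chain id '%s' does not fit the single-character PDB chain column",
                   ch@chainId))
    a <- ch@atoms
    if (any(a$resno > 9999L | a$resno < -999L))
      stop("residue number does not fit the PDB resSeq column")
    for (i in seq_len(nrow(a))) {
      xyz <- c(a$x[i], a$y[i], a$z[i])
      fx <- sprintf("%8.3f", xyz)
      if (any(nchar(fx) > 8L))
        stop(sprintf("coordinate overflow at %s:%d: |coord| too large for PDB format",
                     ch@chainId, a$resno[i]))
      serial <- serial + 1L
      name4 <- if (nchar(a$elety[i]) < 4L)
        sprintf(" %-3s", a$elety[i]) else a$elety[i]
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %s%s%s  1.00  0.00          %2s",
        serial %% 100000L, name4, .aa123(a$code[i]), ch@chainId, a$resno[i],
        fx[1], fx[2], fx[3], substr(a$elety[i], 1, 1)))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
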