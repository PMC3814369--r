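#' Read a cross-link site table
#'
#' Reads a TSV with header columns `subunit_a`, `residue_a`, `subunit_b`,
#' `residue_b` and optionally `spectrum_id`, one row per spectrum match.
#' No deduplication is performed here (see [deduplicateLinks()]);
#' `link_class` is assigned from subunit equality.
#'
#' @param file path to the TSV file.
#' @param sequences optional sequences for residue-range validation.
#' @return a [CrossLinkSet-class].
#' @export
readCrossLinkTable <- function(file, sequences = NULL) {
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("subunit_a", "residue_a", "subunit_b", "residue_b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cross-link table is missing column(s): ",
         paste(miss, collapse = ", "))
  for (col in c("residue_a", "residue_b")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    v <- as.integer(num)
    bad <- is.na(v) | v != num
    if (any(bad))
      stop(sprintf("non-integer %s at row %d", col, which(bad)[1]))
    df[[col]] <- v
  }
  CrossLinkSet(df, sequences = sequences)
}

#' Write a cross-link set as TSV
#'
#' @param links a [CrossLinkSet-class] or compatible data.frame.
#' @param file output path.
#' @export
writeCrossLinkTable <- function(links, file) {
  df <- if (is(links, "CrossLinkSet")) linkTable(links) else as.data.frame(links)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a pipeline configuration file
#'
#' YAML with (all optional) blocks: `chain_map` (subunit -> chain id or
#' list of chain ids per copy), `residue_offset` (chain id -> integer
#' offset; full-length residue = model residue + offset), `linker`
#' (fields of [LinkerSpec()]), and `tolerances` (`ms1_ppm`, `ms2_ppm`).
#'
#' @param file path to a YAML configuration file.
#' @return a list with elements `chain_map`, `offsets`, `linker`,
#'   `tolerances`, `seed`.
#' @export
readPipelineConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  out <- list(
    chain_map = cfg$chain_map,
    offsets = if (!is.null(cfg$residue_offset))
      unlist(cfg$residue_offset) else NULL,
    tolerances = utils::modifyList(list(ms1_ppm = 10, ms2_ppm = 20),
                                   if (is.null(cfg$tolerances)) list()
                                   else cfg$tolerances),
    seed = cfg$seed
  )
  if (!is.null(out$offsets) && any(out$offsets != round(out$offsets)))
    stop("residue_offset values must be integers")
  if (!is.null(cfg$chain_map)) {
    flat <- unlist(cfg$chain_map)
    if (anyDuplicated(flat))
      stop("chain_map must not assign one chain id to several subunits")
  }
  if (!is.null(cfg$linker)) {
    lk <- cfg$linker
    out$linker <- LinkerSpec(
      name = if (is.null(lk$name)) "linker" else lk$name,
      spacerLength = lk$spacer_length,
      sidechainAllowance = lk$sidechain_allowance,
      bridgeMassLight = if (is.null(lk$bridge_mass_light)) NA_real_
        else lk$bridge_mass_light,
      heavyLightDelta = if (is.null(lk$heavy_light_delta)) 0
        else lk$heavy_light_delta,
      reactiveTargets = if (is.null(lk$reactive_targets)) "K"
        else lk$reactive_targets,
      ntermReactive = if (is.null(lk$nterm_reactive)) TRUE
        else lk$nterm_reactive)
  }
  out
}

#' Read a peak list
#'
#' TSV with columns `mz`, `charge`, `intensity`.
#'
#' @param file path.
#' @return data.frame with those columns.
#' @export
readPeakList <- function(file) {
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  need <- c("mz", "charge", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak list is missing column(s): ", paste(miss, collapse = ", "))
  df
}
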