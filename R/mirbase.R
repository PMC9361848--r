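# Registry-scale scans. These functions run the same detection core as the
# pipeline over a miRBase-style hairpin/mature pair, filtered by id pattern
# or species. Reproducing the published registry-wide counts (82 of 88
# MIR159 precursors nested across 36 species; 6 nested groups with 18 mature
# miRNAs in Arabidopsis) requires the miRBase release 21 hairpin/mature
# files, which are not redistributed here; point `hairpin`/`mature` at local
# copies (see analysis/06_mirbase_reproduction.R).

#' Scan a hairpin/mature set for nested structures
#'
#' @param hairpin,mature FASTA paths (miRBase dialect).
#' @param dotbracket optional Vienna dot-bracket file of externally computed
#'   structures; precursors without one are folded with [fold_maxpair()].
#' @param pattern optional regular expression on precursor ids (e.g.
#'   `"MIR159"`).
#' @param species optional species-code filter (e.g. `"ath"`).
#' @param ... thresholds forwarded to the detection core
#'   (`min_duplex_pairing`, `max_mismatches`, `min_loop`, `overhang`).
#' @return a list: `inventories`, `summary` (a `nested_summary`), and
#'   `mature_names` (all named spans with lengths, for mature-length checks).
#' @export
nested_scan <- function(hairpin, mature, dotbracket = NULL,
                        pattern = NULL, species = NULL, ...) {
  precursors <- read_fasta_dialect(hairpin, "hairpin")
  matures <- read_fasta_dialect(mature, "mature")
  if (!is.null(pattern)) {
    precursors <- precursors[grepl(pattern, precursors$id), , drop = FALSE]
    matures <- matures[grepl(pattern, matures$id, ignore.case = TRUE), , drop = FALSE]
  }
  if (!is.null(species)) {
    precursors <- precursors[precursors$species_code %in% species, , drop = FALSE]
    matures <- matures[matures$species_code %in% species, , drop = FALSE]
  }
  if (!nrow(precursors)) stop("no precursors left after filtering", call. = FALSE)
  structures <- if (!is.null(dotbracket)) read_dotbracket(dotbracket) else NULL
  det <- .detect_all(precursors, matures, structures, ...)
  mature_names <- do.call(rbind, lapply(det$inventories, function(x) {
    if (is.null(x$names)) return(NULL)
    data.frame(precursor_id = x$precursor_id, name = x$names$name,
               start = x$names$start, end = x$names$end,
               length = x$names$end - x$names$start, kind = x$names$kind,
               stringsAsFactors = FALSE)
  }))
  list(inventories = det$inventories,
       summary = summarize_inventories(det$inventories),
       mature_names = mature_names)
}

#' Reproduce the registry-wide nested-MIR159 counts
#'
#' Filters a miRBase hairpin/mature pair to the MIR159 family and reports the
#' nested/total and species counts. With miRBase release 21 files and
#' externally computed structures this targets the published 82-of-88 /
#' 36-species figures; counts are sensitive to the fold and threshold
#' choices, which are echoed in the result.
#'
#' @inheritParams nested_scan
#' @return a list: `total`, `nested`, `n_species`, `summary`, `scan`.
#' @export
reproduce_mirbase_counts <- function(hairpin, mature, dotbracket = NULL,
                                     pattern = "MIR159", ...) {
  scan <- nested_scan(hairpin, mature, dotbracket, pattern = pattern, ...)
  list(total = scan$summary$total,
       nested = scan$summary$nested_count,
       n_species = scan$summary$n_species,
       summary = scan$summary,
       scan = scan)
}

#' Genome-wide nested scan for one species
#'
#' Scans all precursors of one species (default Arabidopsis, `"ath"`) and
#' reports the nested groups and the mature miRNAs they contain.
#'
#' @inheritParams nested_scan
#' @return a list: `n_groups` (nested precursors), `n_matures` (named small
#'   RNAs on nested precursors), `mature_names`.
#' @export
species_nested_scan <- function(hairpin, mature, dotbracket = NULL,
                                species = "ath", ...) {
  scan <- nested_scan(hairpin, mature, dotbracket, species = species, ...)
  nested_ids <- vapply(Filter(function(x) isTRUE(x$is_nested), scan$inventories),
                       function(x) x$precursor_id, "")
  mn <- scan$mature_names
  mn <- mn[mn$precursor_id %in% nested_ids, , drop = FALSE]
  list(n_groups = length(nested_ids),
       n_matures = if (is.null(mn)) 0L else nrow(mn),
       mature_names = mn)
}
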