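# Reading/writing the standard formats and coordinate bookkeeping.
#
# Conventions used throughout the package:
#   * precursor-local coordinates are 0-based, half-open [start, end);
#   * genomic coordinates are 1-based, inclusive (GFF dialect);
#   * conversion between the two happens only in this file.

.RNA_ALPHABET <- c("A", "C", "G", "U")

.check_rna <- function(sequence, id = "<sequence>") {
  bad <- gsub("[ACGU]", "", sequence)
  if (nzchar(bad)) {
    stop(sprintf("alphabet error in '%s': illegal character(s) '%s' (expected A/C/G/U)",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
         call. = FALSE)
  }
  invisible(sequence)
}

.normalize_rna <- function(sequence) {
  chartr("Tt", "Uu", toupper(sequence))
}

.revcomp_rna <- function(sequence) {
  comp <- chartr("ACGU", "UGCA", sequence)
  vapply(comp, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), "",
         USE.NAMES = FALSE)
}

#' Read miRBase-dialect FASTA
#'
#' Parses hairpin (`"MIR..."`) or mature (`"miR..."`) records in the miRBase
#' header dialect: the first whitespace-delimited token of the header is the
#' record id, whose lowercase prefix before the first hyphen is the
#' three-letter species code; the remainder of the header (accession,
#' free-text description) is kept verbatim. DNA input is normalized to RNA
#' (T to U).
#'
#' @param source path to a FASTA file, or a literal FASTA string (detected by
#'   a leading `">"`).
#' @param record_kind `"hairpin"` or `"mature"`; controls the length check.
#' @param min_hairpin_length minimum hairpin length (default 40).
#' @param mature_length_range allowed mature length range (default 18..26).
#' @return a `data.frame` with columns `id`, `species_code`, `sequence`,
#'   `length` and `description`.
#' @export
read_fasta_dialect <- function(source,
                               record_kind = c("hairpin", "mature"),
                               min_hairpin_length = 40,
                               mature_length_range = c(18, 26)) {
  record_kind <- match.arg(record_kind)
  path <- source
  if (length(source) == 1 && grepl("^>", source)) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path))
    writeLines(source, path)
  }
  if (!file.exists(path)) stop("FASTA source not found: ", path, call. = FALSE)

  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  bad <- hdr[!grepl("^>\\s*\\S", lines[hdr])]
  if (length(bad)) {
    stop(sprintf("parse error: FASTA header with no id token at line %d", bad[1]),
         call. = FALSE)
  }

  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!grepl("-", id))) {
    stop("malformed id (no species prefix before a hyphen): ",
         paste(id[!grepl("-", id)], collapse = ", "), call. = FALSE)
  }
  sequence <- .normalize_rna(as.character(set))
  for (i in seq_along(sequence)) .check_rna(sequence[i], id[i])

  species_code <- tolower(sub("-.*$", "", id))
  len <- nchar(sequence)
  if (record_kind == "hairpin") {
    short <- id[len < min_hairpin_length]
    if (length(short)) {
      stop(sprintf("hairpin record(s) shorter than %d nt: %s",
                   min_hairpin_length, paste(short, collapse = ", ")), call. = FALSE)
    }
  } else {
    off <- id[len < mature_length_range[1] | len > mature_length_range[2]]
    if (length(off)) {
      stop(sprintf("mature record(s) outside [%d, %d] nt: %s",
                   mature_length_range[1], mature_length_range[2],
                   paste(off, collapse = ", ")), call. = FALSE)
    }
  }
  out <- data.frame(id = id, species_code = species_code, sequence = sequence,
                    length = len, description = description,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write sequences as FASTA
#'
#' @param ids,sequences character vectors of equal length.
#' @param path output file.
#' @param descriptions optional header descriptions.
#' @export
write_fasta <- function(ids, sequences, path, descriptions = NULL) {
  stopifnot(length(ids) == length(sequences))
  hdr <- paste0(">", ids)
  if (!is.null(descriptions)) {
    hdr <- ifelse(nzchar(descriptions), paste(hdr, descriptions), hdr)
  }
  writeLines(as.vector(rbind(hdr, sequences)), path)
  invisible(path)
}

#' Genomic locus (1-based inclusive)
#'
#' Reverse-order coordinate pairs (start > end), as printed for minus-strand
#' genes, are normalized by swapping the bounds and setting the strand to
#' `"-"`.
#'
#' @param chromosome chromosome name.
#' @param start,end positive integers, 1-based inclusive. `start > end` is
#'   accepted and normalized.
#' @param strand `"+"`, `"-"` or `NULL` (inferred: `"-"` for reverse-order
#'   input, otherwise `"+"`).
#' @return an object of class `genomic_locus`.
#' @export
genomic_locus <- function(chromosome, start, end, strand = NULL) {
  if (!is.numeric(start) || !is.numeric(end) || start < 1 || end < 1 ||
      start != round(start) || end != round(end)) {
    stop("start and end must be positive integers (1-based inclusive)", call. = FALSE)
  }
  if (start > end) {
    tmp <- start; start <- end; end <- tmp
    strand <- "-"
  }
  if (is.null(strand)) strand <- "+"
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(chromosome = as.character(chromosome),
                 start = as.integer(start), end = as.integer(end),
                 strand = strand),
            class = "genomic_locus")
}

#' @export
print.genomic_locus <- function(x, ...) {
  cat(sprintf("<genomic_locus> %s:%d-%d(%s), %d bp\n",
              x$chromosome, x$start, x$end, x$strand, inclusive_length(x)))
  invisible(x)
}

#' Inclusive length of a genomic locus
#'
#' `end - start + 1`; invariant under strand and under reverse-order input
#' normalization.
#'
#' @param locus a [genomic_locus()].
#' @return a positive integer.
#' @export
inclusive_length <- function(locus) {
  stopifnot(inherits(locus, "genomic_locus"))
  locus$end - locus$start + 1L
}

#' Convert between genomic (1-based inclusive) and local (0-based half-open)
#'
#' Minus-strand loci are read in reverse complement, so local position 0 maps
#' to the genomic `end` on the minus strand.
#'
#' @param locus a [genomic_locus()].
#' @param span local span `c(start, end)`, 0-based half-open.
#' @return `local_to_genomic`: `c(start, end)` 1-based inclusive;
#'   `genomic_to_local`: `c(start, end)` 0-based half-open.
#' @export
local_to_genomic <- function(locus, span) {
  stopifnot(inherits(locus, "genomic_locus"), length(span) == 2, span[1] < span[2])
  if (locus$strand == "+") {
    c(locus$start + span[1], locus$start + span[2] - 1L)
  } else {
    c(locus$end - span[2] + 1L, locus$end - span[1])
  }
}

#' @rdname local_to_genomic
#' @param gstart,gend genomic coordinates, 1-based inclusive.
#' @export
genomic_to_local <- function(locus, gstart, gend) {
  stopifnot(inherits(locus, "genomic_locus"), gstart <= gend)
  if (locus$strand == "+") {
    c(gstart - locus$start, gend - locus$start + 1L)
  } else {
    c(locus$end - gend, locus$end - gstart + 1L)
  }
}

#' Read GFF3-style loci
#'
#' Minimal GFF3 reader for precursor loci: seqid, start, end, strand and the
#' `ID` attribute.
#'
#' @param path a GFF3 file.
#' @return a `data.frame` with columns `id`, `chromosome`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_loci <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(id = character(), chromosome = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) stop("malformed GFF3 line (fewer than 9 fields)", call. = FALSE)
  attr9 <- vapply(f, `[`, "", 9)
  id <- sub(".*ID=([^;]+).*", "\\1", attr9)
  data.frame(id = id,
             chromosome = vapply(f, `[`, "", 1),
             start = as.integer(vapply(f, `[`, "", 4)),
             end = as.integer(vapply(f, `[`, "", 5)),
             strand = vapply(f, `[`, "", 7),
             stringsAsFactors = FALSE)
}

#' Write / read an inventory summary report
#'
#' Writes the summary produced by [summarize_inventories()] as a pair of
#' files: `<prefix>.tsv` (counts, deterministic column order) and
#' `<prefix>.json` (full detail). Counts round-trip through [read_report()].
#'
#' @param summary a `nested_summary` (or a compatible list with `nested_count`
#'   and `total`).
#' @param prefix output path prefix (without extension).
#' @return invisibly, the two file paths.
#' @export
write_report <- function(summary, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  counts <- data.frame(nested = summary$nested_count %||% summary$nested,
                       total = summary$total,
                       n_species = summary$n_species %||% NA_integer_)
  ok <- tryCatch({
    write.table(counts, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write report to ", tsv, call. = FALSE)
  jsonlite::write_json(unclass(summary), json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_report
#' @export
read_report <- function(prefix) {
  jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
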