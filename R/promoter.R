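# Promoter truncation/deletion bookkeeping and cis-element scanning.
#
# Positions are TSS-relative: -1 is the base immediately upstream of the
# transcription start site and -L the 5' end of an L-bp promoter. Deletions
# are specified in the coordinates of the ORIGINAL promoter (as construct
# names like "delta858-862" are), so two deletions can be applied in either
# order; every retained base remembers its original position. Hit positions
# are reported in the coordinates of the current construct: bases downstream
# of a deletion keep their position, upstream bases are renumbered.

#' Promoter sequence with TSS-relative coordinates
#'
#' @param id identifier.
#' @param sequence DNA string over `A,C,G,T` (the last base is position -1).
#' @return a `promoter_construct` of length L covering positions -L .. -1.
#' @export
promoter_sequence <- function(id, sequence) {
  sequence <- toupper(sequence)
  bad <- gsub("[ACGT]", "", sequence)
  if (nzchar(bad)) {
    stop(sprintf("alphabet error in promoter '%s': illegal character(s) '%s'",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
         call. = FALSE)
  }
  L <- nchar(sequence)
  if (L < 1) stop("promoter must have length >= 1", call. = FALSE)
  structure(list(id = id, name = id, sequence = sequence,
                 orig_positions = seq.int(-L, -1L),
                 operations = list()),
            class = "promoter_construct")
}

#' @export
print.promoter_construct <- function(x, ...) {
  ops <- if (length(x$operations)) {
    paste(vapply(x$operations, function(o) o$label, ""), collapse = ", ")
  } else "none"
  cat(sprintf("<promoter_construct> %s: %d bp (positions %d..-1); operations: %s\n",
              x$name, nchar(x$sequence), -nchar(x$sequence), ops))
  invisible(x)
}

#' Current TSS-relative positions of a construct
#' @param p a `promoter_construct`.
#' @return integer vector, `-L .. -1` for the current length L.
#' @export
construct_positions <- function(p) {
  L <- nchar(p$sequence)
  seq.int(-L, -1L)
}

#' Truncate a promoter to the L bases nearest the TSS
#'
#' @param p a `promoter_construct`.
#' @param length_bp bases to keep (the construct then covers
#'   `-length_bp .. -1`).
#' @param name construct name (default e.g. `"1.0kb"`).
#' @return a `promoter_construct`.
#' @export
truncate_promoter <- function(p, length_bp,
                              name = sprintf("%.1fkb", length_bp / 1000)) {
  stopifnot(inherits(p, "promoter_construct"))
  L <- nchar(p$sequence)
  if (length_bp > L) {
    stop(sprintf("cannot truncate to %d bp: only %d bp available", length_bp, L),
         call. = FALSE)
  }
  if (length_bp < 1) stop("truncation length must be positive", call. = FALSE)
  keep <- (L - length_bp + 1):L
  p$sequence <- substr(p$sequence, keep[1], L)
  p$orig_positions <- p$orig_positions[keep]
  p$operations <- c(p$operations,
                    list(list(op = "truncate", length = as.integer(length_bp),
                              label = sprintf("truncate %d", length_bp))))
  p$name <- name
  p
}

#' Delete an internal span (original coordinates)
#'
#' `delete_span(p, 858, 862)` removes the bases at original positions
#' -858 .. -862 inclusive (5 bp, the length of a GGATA box). Downstream
#' positions are unchanged, upstream positions are renumbered.
#'
#' @param p a `promoter_construct`.
#' @param a,b positive integers; the span `-max(a,b) .. -min(a,b)` is removed.
#' @param name construct name (default e.g. `"delta858-862"`).
#' @return a `promoter_construct` shorter by `|a - b| + 1`.
#' @export
delete_span <- function(p, a, b,
                        name = sprintf("delta%d-%d", min(a, b), max(a, b))) {
  stopifnot(inherits(p, "promoter_construct"))
  if (a < 1 || b < 1) stop("deletion bounds must be positive", call. = FALSE)
  lo <- min(a, b); hi <- max(a, b)
  target <- seq.int(-hi, -lo)
  if (!all(target %in% p$orig_positions)) {
    stop(sprintf("deletion span -%d..-%d lies (partly) outside the construct", hi, lo),
         call. = FALSE)
  }
  drop <- p$orig_positions %in% target
  chars <- strsplit(p$sequence, "")[[1]]
  p$sequence <- paste(chars[!drop], collapse = "")
  p$orig_positions <- p$orig_positions[!drop]
  p$operations <- c(p$operations,
                    list(list(op = "delete", from = as.integer(lo), to = as.integer(hi),
                              label = sprintf("delete [-%d,-%d]", hi, lo))))
  p$name <- name
  p
}

#' Built-in cis-element table
#'
#' A small PLACE-style table: the MybSt1 core (GGATA), the TATA box and the
#' CAAT box. User tables with the same columns (IUPAC consensus allowed) can
#' be passed to [scan_motifs()].
#' @return data.frame with `name` and `consensus`.
#' @export
builtin_motifs <- function() {
  data.frame(name = c("MybSt1", "TATA-box", "CAAT-box"),
             consensus = c("GGATA", "TATAAA", "CCAAT"),
             stringsAsFactors = FALSE)
}

#' Scan a construct for cis-elements
#'
#' Exact IUPAC-consensus matching. A hit's position is the TSS-relative
#' coordinate of its most-upstream base in the CURRENT construct. With
#' `strands = "both"` the reverse complement of each consensus is also
#' scanned and tagged strand `"-"`. Hits are ordered by position, then name.
#'
#' @param p a `promoter_construct`.
#' @param motifs data.frame with `name` and `consensus` (length >= 3).
#' @param strands `"+"` or `"both"`.
#' @return data.frame `motif_name`, `consensus`, `position`, `strand`,
#'   `match`.
#' @export
scan_motifs <- function(p, motifs = builtin_motifs(), strands = c("+", "both")) {
  stopifnot(inherits(p, "promoter_construct"))
  strands <- match.arg(strands)
  empty <- data.frame(motif_name = character(), consensus = character(),
                      position = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE)
  if (!nrow(motifs)) return(empty)
  if (any(nchar(motifs$consensus) < 3)) {
    stop("motifs must be at least 3 nt long", call. = FALSE)
  }
  subject <- Biostrings::DNAString(p$sequence)
  L <- nchar(p$sequence)
  rows <- list()
  for (k in seq_len(nrow(motifs))) {
    pats <- list(`+` = Biostrings::DNAString(motifs$consensus[k]))
    if (strands == "both") {
      pats[["-"]] <- Biostrings::reverseComplement(pats[["+"]])
    }
    for (s in names(pats)) {
      m <- Biostrings::matchPattern(pats[[s]], subject, fixed = FALSE)
      if (!length(m)) next
      st <- Biostrings::start(m)
      rows <- c(rows, list(data.frame(
        motif_name = motifs$name[k],
        consensus = motifs$consensus[k],
        position = st - L - 1L,
        strand = s,
        match = as.character(m),
        stringsAsFactors = FALSE)))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$motif_name, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Write constructs as FASTA with operation provenance in the headers
#' @param constructs list of `promoter_construct`.
#' @param path output FASTA.
#' @export
write_constructs <- function(constructs, path) {
  ids <- vapply(constructs, function(p) p$name, "")
  desc <- vapply(constructs, function(p) {
    if (!length(p$operations)) return("unmodified")
    paste(vapply(p$operations, function(o) o$label, ""), collapse = "; ")
  }, "")
  write_fasta(ids, vapply(constructs, function(p) p$sequence, ""), path,
              descriptions = desc)
}
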