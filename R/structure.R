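# Stem-loop secondary structure: prediction, validation and decomposition.
#
# The built-in folder maximizes the number of legal base pairs (Watson-Crick
# plus GU wobble) under a minimum hairpin-loop constraint, with a fully
# deterministic traceback. Externally computed (e.g. thermodynamic) structures
# enter through ingest_dotbracket(), which validates the same invariants.

.LEGAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

.new_secondary_structure <- function(sequence, pair_table) {
  n <- nchar(sequence)
  db <- rep(".", n)
  paired <- which(!is.na(pair_table))
  db[paired[pair_table[paired] > paired]] <- "("
  db[paired[pair_table[paired] < paired]] <- ")"
  structure(list(sequence = sequence,
                 dotbracket = paste(db, collapse = ""),
                 pair_table = pair_table,
                 n = n),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs\n%s\n%s\n",
              x$n, n_pairs(x), x$sequence, x$dotbracket))
  invisible(x)
}

#' Number of base pairs in a structure
#' @param ss a `secondary_structure`.
#' @export
n_pairs <- function(ss) {
  sum(!is.na(ss$pair_table)) / 2L
}

#' Fold by base-pair maximization
#'
#' Predicts a pseudoknot-free secondary structure maximizing the number of
#' legal pairs (AU/UA/GC/CG/GU/UG) subject to a minimum hairpin loop of
#' `min_loop` unpaired bases between any pair. The traceback is
#' deterministic: at ties a position is paired rather than left unpaired, and
#' the smallest admissible partner wins.
#'
#' @param sequence RNA string (T is not accepted; see [read_fasta_dialect()]
#'   for normalization on input).
#' @param min_loop minimum number of unpaired bases enclosed by a pair
#'   (default 3).
#' @return a `secondary_structure` (sequence, dot-bracket, pair table).
#' @export
fold_maxpair <- function(sequence, min_loop = 3) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  .check_rna(sequence)
  pt <- .nussinov_pairs(sequence, as.integer(min_loop))
  pt[pt == 0L] <- NA_integer_
  .new_secondary_structure(sequence, pt)
}

#' Ingest a dot-bracket structure
#'
#' Validates an externally computed structure (e.g. RNAfold output) against
#' the package invariants: balanced non-crossing brackets, minimum loop size,
#' and legal base pairs.
#'
#' @param sequence RNA string.
#' @param dotbracket dot-bracket string of equal length over `(`, `)`, `.`.
#' @param min_loop minimum hairpin loop size to enforce (default 3).
#' @return a `secondary_structure`.
#' @export
ingest_dotbracket <- function(sequence, dotbracket, min_loop = 3) {
  sequence <- toupper(sequence)
  .check_rna(sequence)
  n <- nchar(sequence)
  if (nchar(dotbracket) != n) {
    stop("structure error: sequence and dot-bracket lengths differ", call. = FALSE)
  }
  ch <- strsplit(dotbracket, "")[[1]]
  if (any(!ch %in% c("(", ")", "."))) {
    stop("structure error: dot-bracket may contain only '(', ')' and '.'", call. = FALSE)
  }
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  sq <- strsplit(sequence, "")[[1]]
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) {
        stop(sprintf("structure error: unbalanced ')' at position %d", i), call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j - 1 < min_loop) {
        stop(sprintf("structure error: pair (%d,%d) violates min_loop = %d",
                     j, i, min_loop), call. = FALSE)
      }
      if (!(paste0(sq[j], sq[i]) %in% .LEGAL_PAIRS)) {
        stop(sprintf("pairing error: illegal pair %s-%s at positions (%d,%d)",
                     sq[j], sq[i], j, i), call. = FALSE)
      }
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(stack)) {
    stop(sprintf("structure error: unbalanced '(' at position %d", stack[1]),
         call. = FALSE)
  }
  .new_secondary_structure(sequence, pt)
}

#' Read / write Vienna dot-bracket files
#'
#' Blocks of `>id`, sequence line, structure line.
#'
#' @param path file path.
#' @return `read_dotbracket`: a named list of `secondary_structure`s.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr) || any(diff(c(hdr, length(lines) + 1)) != 3)) {
    stop("malformed dot-bracket file: expected blocks of header/sequence/structure",
         call. = FALSE)
  }
  out <- lapply(hdr, function(h) {
    ingest_dotbracket(.normalize_rna(lines[h + 1]),
                      sub("\\s.*$", "", lines[h + 2]))
  })
  names(out) <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  out
}

#' @rdname read_dotbracket
#' @param structures named list of `secondary_structure`s.
#' @export
write_dotbracket <- function(structures, path) {
  stopifnot(length(names(structures)) == length(structures))
  writeLines(unlist(lapply(names(structures), function(id) {
    c(paste0(">", id), structures[[id]]$sequence, structures[[id]]$dotbracket)
  })), path)
  invisible(path)
}

# Follow the 5'-most helix path from the outermost pair down to the pair that
# closes the terminal loop. Returns that closing pair c(a, b), 1-based.
.terminal_pair <- function(pt) {
  i <- min(which(!is.na(pt)))
  j <- pt[i]
  repeat {
    inner <- which(!is.na(pt))
    inner <- inner[inner > i & inner < j & pt[inner] > inner]
    if (!length(inner)) return(c(i, j))
    i <- min(inner)
    j <- pt[i]
  }
}

#' Decompose a fold-back into arms, loop and flanks
#'
#' Every position is assigned exactly one label: `5arm` (from the first paired
#' position down to the terminal-loop closing pair, bulges included), `loop`
#' (the terminal hairpin loop, reached by following the 5'-most helix path),
#' `3arm` (from the loop's closing partner to the last paired position), or
#' `flank` (unpaired ends). Spans are 0-based half-open.
#'
#' @param ss a `secondary_structure` with at least one pair.
#' @return a list with `five_arm`, `three_arm`, `loop`, `flank5`, `flank3`
#'   spans, the per-position `labels` vector, and a `helices` data.frame of
#'   maximal stacked runs.
#' @export
decompose <- function(ss) {
  pt <- ss$pair_table
  if (all(is.na(pt))) stop("no hairpin: structure has no base pairs", call. = FALSE)
  n <- ss$n
  p5 <- min(which(!is.na(pt)))
  p3 <- max(which(!is.na(pt)))
  tp <- .terminal_pair(pt)
  a <- tp[1]; b <- tp[2]

  labels <- rep("flank", n)
  labels[p5:a] <- "5arm"
  if (b - a > 1) labels[(a + 1):(b - 1)] <- "loop"
  labels[b:p3] <- "3arm"

  paired <- which(!is.na(pt) & pt > seq_len(n))
  helix_id <- cumsum(c(TRUE, diff(paired) != 1 | diff(pt[paired]) != -1))
  helices <- do.call(rbind, lapply(split(paired, helix_id), function(idx) {
    data.frame(start5 = min(idx) - 1L, end5 = max(idx),
               start3 = min(pt[idx]) - 1L, end3 = max(pt[idx]),
               length = length(idx))
  }))
  rownames(helices) <- NULL

  list(five_arm = c(p5 - 1L, a), three_arm = c(b - 1L, p3),
       loop = c(a, b - 1L),
       flank5 = c(0L, p5 - 1L), flank3 = c(p3, n),
       labels = labels, helices = helices)
}

#' Classify hairpin topology
#'
#' A fold-back is an `elongated_stem` when it contains no multiloop (internal
#' loops and bulges are allowed), and `branched` when at least one internal
#' node spawns two or more child helices, as in the branched loop-proximal
#' region of dicot MIR159a stem-loops versus the single elongated monocot
#' stem.
#'
#' @param ss a `secondary_structure`.
#' @return a list with `label` (`"elongated_stem"` or `"branched"`),
#'   `branch_count` (helices emanating from multiloops) and
#'   `longest_stem_run` (longest stacked helix).
#' @export
classify_topology <- function(ss) {
  pt <- ss$pair_table
  dec <- decompose(ss)
  n <- ss$n
  # children[i] = number of pairs immediately enclosed by the pair opening at i
  children <- integer(n)
  stack <- integer(0)
  db <- strsplit(ss$dotbracket, "")[[1]]
  for (i in seq_len(n)) {
    if (db[i] == "(") {
      stack <- c(stack, i)
    } else if (db[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (length(stack)) {
        children[stack[length(stack)]] <- children[stack[length(stack)]] + 1L
      }
    }
  }
  opens <- which(db == "(")
  multi <- opens[children[opens] >= 2L]
  branch_count <- sum(children[multi])
  list(label = if (length(multi)) "branched" else "elongated_stem",
       branch_count = as.integer(branch_count),
       longest_stem_run = max(dec$helices$length))
}
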