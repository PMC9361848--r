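# Duplex detection, nestedness decision, sibling naming, and inventories.
#
# A nested miRNA structure is a fold-back precursor that fully contains
# another miRNA precursor: two (or more) miRNA/miRNA* duplexes on the same
# stem where the inner duplex lies strictly inside the region enclosed by the
# outer one, and all mature small RNAs are pairwise non-overlapping.
# Sibling naming follows duplex index k counted from the basal (outermost)
# duplex: x.k-5 on the 5' arm, x.k-3 on the 3' arm, and a loop-distal single
# RNA gets the next index with no arm suffix.

.span_overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]
.span_inside <- function(inner, outer) outer[1] < inner[1] && inner[2] < outer[2]

#' Map a mature miRNA onto its precursor
#'
#' Exact substring search (sequences are compared after T-to-U
#' normalization). The leftmost match is returned; additional matches trigger
#' a warning listing all positions.
#'
#' @param precursor_seq precursor RNA string (or a row from
#'   [read_fasta_dialect()]).
#' @param mature_seq mature RNA string.
#' @return a span `c(start, end)`, 0-based half-open, with attribute
#'   `"matches"` giving all 0-based match starts.
#' @export
map_mature <- function(precursor_seq, mature_seq) {
  if (is.list(precursor_seq)) precursor_seq <- precursor_seq$sequence
  if (is.list(mature_seq)) mature_seq <- mature_seq$sequence
  precursor_seq <- .normalize_rna(precursor_seq)
  mature_seq <- .normalize_rna(mature_seq)
  hits <- gregexpr(mature_seq, precursor_seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    stop("mapping error: mature sequence does not occur in the precursor",
         call. = FALSE)
  }
  starts <- as.integer(hits) - 1L
  if (length(starts) > 1) {
    warning(sprintf("ambiguous mapping: mature occurs %d times (0-based starts: %s); using leftmost",
                    length(starts), paste(starts, collapse = ", ")), call. = FALSE)
  }
  span <- c(starts[1], starts[1] + nchar(mature_seq))
  attr(span, "matches") <- starts
  span
}

#' Infer the miRNA* (star) strand of a duplex
#'
#' The raw star span is the partner interval of the mature's paired
#' positions, then shifted downstream by `overhang` nucleotides so each
#' strand carries the Dicer-standard 2-nt 3' overhang (set `overhang = 0` for
#' exact-partner mode), and clipped to the precursor.
#'
#' @param ss a `secondary_structure` of the precursor.
#' @param mature_span mature span, 0-based half-open.
#' @param min_pairing minimum fraction of mature positions that must be
#'   paired (default 0.6); below it the mature is "not on a stem".
#' @param overhang 3' overhang in nt (default 2).
#' @param precursor_id optional id carried into the duplex.
#' @return a `mir_duplex`: precursor id, mature/star spans, arms,
#'   `paired_fraction`, `mismatches` (unpaired mature positions).
#' @export
infer_star <- function(ss, mature_span, min_pairing = 0.6, overhang = 2,
                       precursor_id = NULL) {
  stopifnot(inherits(ss, "secondary_structure"))
  idx <- (mature_span[1] + 1L):mature_span[2]          # 1-based positions
  if (mature_span[1] < 0 || mature_span[2] > ss$n) {
    stop("mature span outside the precursor", call. = FALSE)
  }
  partners <- ss$pair_table[idx]
  paired_fraction <- mean(!is.na(partners))
  if (paired_fraction < min_pairing) {
    stop(sprintf("not on a stem: only %.0f%% of mature positions are paired (minimum %.0f%%)",
                 100 * paired_fraction, 100 * min_pairing), call. = FALSE)
  }
  dec <- decompose(ss)
  arm_votes <- table(dec$labels[idx])
  mature_arm <- names(which.max(arm_votes))
  if (!mature_arm %in% c("5arm", "3arm")) {
    stop("not on a stem: mature lies mostly in the loop or flank", call. = FALSE)
  }
  raw <- range(partners, na.rm = TRUE)                  # 1-based inclusive
  star1 <- max(1L, raw[1] + as.integer(overhang))
  star2 <- min(ss$n, raw[2] + as.integer(overhang))
  star_span <- c(star1 - 1L, star2)                     # 0-based half-open
  if (.span_overlaps(mature_span, star_span)) {
    stop("not on a stem: inferred star overlaps the mature (loop-spanning duplex)",
         call. = FALSE)
  }
  structure(list(precursor_id = precursor_id %||% NA_character_,
                 mature_span = c(mature_span[1], mature_span[2]),
                 star_span = star_span,
                 mature_arm = mature_arm,
                 star_arm = if (mature_arm == "5arm") "3arm" else "5arm",
                 paired_fraction = paired_fraction,
                 mismatches = sum(is.na(partners))),
            class = "mir_duplex")
}

#' @export
print.mir_duplex <- function(x, ...) {
  cat(sprintf("<mir_duplex> %s mature [%d,%d) on %s, star [%d,%d); paired %.2f, %d mismatches\n",
              x$precursor_id, x$mature_span[1], x$mature_span[2], x$mature_arm,
              x$star_span[1], x$star_span[2], x$paired_fraction, x$mismatches))
  invisible(x)
}

# region enclosed by a duplex: from its 5'-most base to its 3'-most base
.enclosed_region <- function(d) {
  c(min(d$mature_span[1], d$star_span[1]), max(d$mature_span[2], d$star_span[2]))
}

#' Decide nestedness of a set of duplexes on one precursor
#'
#' Accepted duplexes (pairing fraction and mismatch thresholds) are ordered
#' by 5'-arm start. The inventory is nested when at least two accepted
#' duplexes stand in strict containment: the inner duplex's mature and star
#' spans both lie strictly inside the region enclosed by the outer duplex
#' (outer mature start to outer star end), with all mature/star spans
#' pairwise non-overlapping. Overlapping duplex pairs are rejected from the
#' nested relation and reported, not fatal. Loop-distal candidate spans
#' (mature records that map between the innermost duplex and the loop) are
#' kept when they fall strictly inside the innermost enclosed region without
#' touching any duplex span.
#'
#' @param precursor_id precursor id.
#' @param ss the precursor `secondary_structure`.
#' @param duplexes list of `mir_duplex` from [infer_star()].
#' @param loop_distal optional list of candidate spans (0-based half-open).
#' @param min_duplex_pairing,max_mismatches duplex acceptance thresholds
#'   (defaults 0.6 and 7; echoed in the result).
#' @return a `nested_inventory`.
#' @export
detect_nested <- function(precursor_id, ss, duplexes, loop_distal = list(),
                          min_duplex_pairing = 0.6, max_mismatches = 7) {
  stopifnot(inherits(ss, "secondary_structure"))
  accepted <- Filter(function(d) {
    d$paired_fraction >= min_duplex_pairing && d$mismatches <= max_mismatches
  }, duplexes)

  # collapse mirrored detections of one duplex (mature given for both arms)
  if (length(accepted) > 1) {
    keys <- vapply(accepted, function(d) {
      spans <- rbind(d$mature_span, d$star_span)
      spans <- spans[order(spans[, 1]), , drop = FALSE]
      paste(t(spans), collapse = ",")
    }, "")
    keep <- !duplicated(keys)
    # prefer the representative whose mature sits on the 5' arm
    for (k in unique(keys[duplicated(keys)])) {
      grp <- which(keys == k)
      pref <- grp[vapply(accepted[grp], function(d) d$mature_arm == "5arm", NA)]
      keep[grp] <- FALSE
      keep[if (length(pref)) pref[1] else grp[1]] <- TRUE
    }
    accepted <- accepted[keep]
  }

  ord <- order(vapply(accepted, function(d) .enclosed_region(d)[1], 0))
  accepted <- accepted[ord]

  # reject overlapping duplex pairs from the nested relation
  rejections <- data.frame(duplex_i = integer(), duplex_j = integer(),
                           reason = character(), stringsAsFactors = FALSE)
  n_d <- length(accepted)
  in_relation <- rep(TRUE, n_d)
  if (n_d >= 2) {
    for (i in seq_len(n_d - 1)) {
      for (j in (i + 1):n_d) {
        spans_i <- list(accepted[[i]]$mature_span, accepted[[i]]$star_span)
        spans_j <- list(accepted[[j]]$mature_span, accepted[[j]]$star_span)
        overl <- any(vapply(spans_i, function(a) {
          any(vapply(spans_j, function(b) .span_overlaps(a, b), NA))
        }, NA))
        if (overl) {
          in_relation[c(i, j)] <- FALSE
          rejections <- rbind(rejections, data.frame(
            duplex_i = i, duplex_j = j,
            reason = "overlapping mature/star spans", stringsAsFactors = FALSE))
        }
      }
    }
  }

  rel <- which(in_relation)
  is_nested <- FALSE
  if (length(rel) >= 2) {
    for (i in rel) {
      for (j in rel) {
        if (i == j) next
        outer <- .enclosed_region(accepted[[i]])
        dj <- accepted[[j]]
        if (.span_inside(dj$mature_span, outer) && .span_inside(dj$star_span, outer)) {
          is_nested <- TRUE
        }
      }
    }
  }

  # loop-distal small RNAs: strictly inside the innermost duplex's enclosed
  # region, overlapping no duplex span
  ld <- list()
  if (length(accepted) && length(loop_distal)) {
    inner <- .enclosed_region(accepted[[length(accepted)]])
    all_spans <- unlist(lapply(accepted, function(d) list(d$mature_span, d$star_span)),
                        recursive = FALSE)
    for (s in loop_distal) {
      sp <- c(s[[1]], s[[2]])
      clash <- any(vapply(all_spans, function(a) .span_overlaps(a, sp), NA))
      if (.span_inside(sp, inner) && !clash) ld <- c(ld, list(sp))
    }
    ld <- ld[order(vapply(ld, `[`, 0, 1))]
  }

  structure(list(precursor_id = precursor_id,
                 duplexes = accepted,
                 loop_distal_rnas = ld,
                 is_nested = is_nested,
                 rejections = rejections,
                 params = list(min_duplex_pairing = min_duplex_pairing,
                               max_mismatches = max_mismatches)),
            class = "nested_inventory")
}

#' @export
print.nested_inventory <- function(x, ...) {
  cat(sprintf("<nested_inventory> %s: %d duplex(es), %d loop-distal RNA(s), nested = %s\n",
              x$precursor_id, length(x$duplexes), length(x$loop_distal_rnas),
              x$is_nested))
  invisible(x)
}

#' Assign sibling names on a nested inventory
#'
#' Duplexes are numbered `.1, .2, ...` from the basal (outermost) duplex; the
#' 5'-arm sibling is suffixed `-5` and the 3'-arm sibling `-3`; a loop-distal
#' single RNA takes the next index with no arm suffix. For an
#' `ath-MIR159a`-like precursor with two duplexes and one loop-distal RNA the
#' names read, in 5'-to-3' precursor order: `.1-5, .2-5, .3, .2-3, .1-3`.
#'
#' @param inv a `nested_inventory`.
#' @param base name stem; default derives the mature-style stem from the
#'   precursor id (`MIR` to `miR`).
#' @return the inventory with a `names` data.frame (`name`, `start`, `end`,
#'   `kind`), ordered by span start.
#' @export
name_siblings <- function(inv, base = NULL) {
  stopifnot(inherits(inv, "nested_inventory"))
  if (is.null(base)) base <- sub("MIR", "miR", inv$precursor_id, fixed = TRUE)
  rows <- list()
  k <- 0L
  for (d in inv$duplexes) {
    k <- k + 1L
    five <- if (d$mature_arm == "5arm") d$mature_span else d$star_span
    three <- if (d$mature_arm == "5arm") d$star_span else d$mature_span
    rows <- c(rows,
              list(data.frame(name = sprintf("%s.%d-5", base, k),
                              start = five[1], end = five[2], kind = "sibling_5arm",
                              stringsAsFactors = FALSE),
                   data.frame(name = sprintf("%s.%d-3", base, k),
                              start = three[1], end = three[2], kind = "sibling_3arm",
                              stringsAsFactors = FALSE)))
  }
  for (s in inv$loop_distal_rnas) {
    k <- k + 1L
    rows <- c(rows, list(data.frame(name = sprintf("%s.%d", base, k),
                                    start = s[1], end = s[2], kind = "loop_distal",
                                    stringsAsFactors = FALSE)))
  }
  nm <- do.call(rbind, rows)
  if (!is.null(nm)) {
    nm <- nm[order(nm$start), ]
    rownames(nm) <- NULL
  }
  inv$names <- nm
  inv
}

#' Summarize nested inventories across precursors
#'
#' @param inventories list of `nested_inventory` (named or carrying
#'   `precursor_id`s).
#' @return a `nested_summary`: `total`, `nested_count`, `n_species`,
#'   `per_species` table, `mature_lengths` histogram and a per-precursor
#'   table.
#' @export
summarize_inventories <- function(inventories) {
  if (!length(inventories)) stop("need at least one inventory", call. = FALSE)
  ids <- vapply(inventories, function(x) x$precursor_id, "")
  species <- tolower(sub("-.*$", "", ids))
  nested <- vapply(inventories, function(x) isTRUE(x$is_nested), NA)
  per_precursor <- data.frame(precursor_id = ids, species_code = species,
                              n_duplexes = vapply(inventories, function(x) length(x$duplexes), 0L),
                              n_loop_distal = vapply(inventories, function(x) length(x$loop_distal_rnas), 0L),
                              is_nested = nested, stringsAsFactors = FALSE)
  per_precursor <- per_precursor[order(per_precursor$precursor_id), ]
  rownames(per_precursor) <- NULL
  per_species <- data.frame(species_code = sort(unique(species)),
                            total = as.vector(table(species)[sort(unique(species))]),
                            nested = vapply(sort(unique(species)), function(s) {
                              sum(nested[species == s])
                            }, 0L), stringsAsFactors = FALSE)
  rownames(per_species) <- NULL
  lens <- unlist(lapply(inventories, function(x) {
    if (is.null(x$names)) {
      unlist(lapply(x$duplexes, function(d) d$mature_span[2] - d$mature_span[1]))
    } else {
      x$names$end - x$names$start
    }
  }))
  mature_lengths <- as.data.frame(table(length = lens), stringsAsFactors = FALSE)
  mature_lengths$length <- as.integer(mature_lengths$length)
  names(mature_lengths)[2] <- "count"
  structure(list(total = length(inventories),
                 nested_count = sum(nested),
                 n_species = length(unique(species)),
                 per_species = per_species,
                 mature_lengths = mature_lengths,
                 per_precursor = per_precursor),
            class = "nested_summary")
}

#' @export
print.nested_summary <- function(x, ...) {
  cat(sprintf("<nested_summary> %d of %d precursors nested across %d species\n",
              x$nested_count, x$total, x$n_species))
  invisible(x)
}
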