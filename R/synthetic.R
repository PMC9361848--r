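# Seeded generators for every input class the pipeline consumes, each with
# serialized ground truth: fold-back precursors with planted non-overlapping
# duplexes (the nested-architecture of MIR159a: two duplexes plus a
# loop-distal RNA), species panels evolved from an ancestor under
# region-specific substitution rates, promoters with motifs planted at stated
# upstream offsets, and Ct replicate tables with Gaussian noise.

.NONPAIRING <- c(A = "C", U = "C", G = "A", C = "A")

.sample_rna <- function(n) paste(sample(.RNA_ALPHABET, n, replace = TRUE), collapse = "")

#' Specification of a synthetic fold-back precursor
#'
#' Planted duplexes live on the 5' arm (offsets are 0-based arm positions);
#' the 3' arm is the reverse complement of the 5' arm except where mismatches
#' are planted, so any two non-overlapping planted duplexes are strictly
#' nested by construction. An optional loop-distal span marks a single small
#' RNA between the innermost duplex and the loop; its partner region is
#' de-paired below the duplex-acceptance threshold so it is recovered as a
#' loop-distal RNA, not a third duplex.
#'
#' @param arm_length 5' arm length (default 80 nt).
#' @param loop_length terminal loop length (default 12 nt, must be >= 3).
#' @param duplexes list of `list(offset, length, mismatches)` (defaults: two
#'   21-nt duplexes at arm offsets 5 and 35, mirroring the MIR159a
#'   architecture).
#' @param loop_distal optional `list(offset, length)` (default a 20-nt RNA at
#'   offset 60).
#' @param seed integer seed.
#' @param id precursor id in miRBase dialect (default `"saa-MIR159a"`).
#' @return a `hairpin_spec`.
#' @export
hairpin_spec <- function(arm_length = 80, loop_length = 12,
                         duplexes = list(list(offset = 5, length = 21, mismatches = 0),
                                         list(offset = 35, length = 21, mismatches = 0)),
                         loop_distal = list(offset = 60, length = 20),
                         seed = 1, id = "saa-MIR159a") {
  if (loop_length < 3) stop("loop_length must be >= 3", call. = FALSE)
  spans <- lapply(duplexes, function(d) c(d$offset, d$offset + d$length))
  if (length(loop_distal)) spans <- c(spans, list(c(loop_distal$offset,
                                                    loop_distal$offset + loop_distal$length)))
  for (s in spans) {
    if (s[1] < 0 || s[2] > arm_length) stop("planted span outside the arm", call. = FALSE)
  }
  if (length(spans) > 1) {
    ord <- order(vapply(spans, `[`, 0, 1))
    spans <- spans[ord]
    for (i in seq_len(length(spans) - 1)) {
      if (spans[[i]][2] > spans[[i + 1]][1]) {
        stop("planted spans overlap", call. = FALSE)
      }
    }
  }
  for (d in duplexes) {
    if (d$mismatches >= d$length) stop("more mismatches than duplex positions", call. = FALSE)
  }
  structure(list(arm_length = as.integer(arm_length),
                 loop_length = as.integer(loop_length),
                 duplexes = duplexes, loop_distal = loop_distal,
                 seed = as.integer(seed), id = id),
            class = "hairpin_spec")
}

#' Generate a fold-back precursor with planted duplexes and ground truth
#'
#' Deterministic given the spec (which carries the seed). The arm sequence is
#' re-sampled (bounded retries) until (a) every emitted mature sequence
#' occurs exactly once in the precursor and (b) the base-pair-maximizing fold
#' pairs every planted mismatch-free duplex position, so detection is
#' well-posed on the generated instance.
#'
#' @param spec a [hairpin_spec()].
#' @param overhang star-strand 3' overhang used for the ground-truth star
#'   spans (default 2, matching [infer_star()]).
#' @param max_tries resampling bound (default 50).
#' @return a list: `precursor` (id, species_code, sequence), `structure` (the
#'   ground-truth `secondary_structure`), and `truth` (duplex spans, star
#'   spans, loop-distal span, sibling names, mature records).
#' @export
make_hairpin <- function(spec, overhang = 2, max_tries = 50) {
  stopifnot(inherits(spec, "hairpin_spec"))
  A <- spec$arm_length; L <- spec$loop_length
  n <- 2L * A + L
  with_seed(spec$seed, {
    for (try in seq_len(max_tries)) {
      arm5 <- strsplit(.sample_rna(A), "")[[1]]
      loop <- strsplit(.sample_rna(L), "")[[1]]
      arm3 <- rev(chartr("ACGU", "UGCA", paste(arm5, collapse = "")) |>
                    strsplit("") |> unlist())

      broken <- integer(0)  # 1-based 5'-arm positions whose pair is destroyed
      for (d in spec$duplexes) {
        if (d$mismatches > 0) {
          mm <- sort(sample(seq.int(d$offset + 1L, d$offset + d$length), d$mismatches))
          broken <- c(broken, mm)
        }
      }
      if (length(spec$loop_distal)) {
        ld <- spec$loop_distal
        # de-pair alternate positions: paired fraction <= 0.5 < default 0.6
        broken <- c(broken, seq.int(ld$offset + 1L, ld$offset + ld$length, by = 2L))
      }
      for (i in broken) arm3[A - i + 1L] <- .NONPAIRING[[arm5[i]]]

      sequence <- paste(c(arm5, loop, arm3), collapse = "")
      db <- rep(".", n)
      paired5 <- setdiff(seq_len(A), broken)
      db[paired5] <- "("
      db[n + 1L - paired5] <- ")"
      ss <- ingest_dotbracket(sequence, paste(db, collapse = ""))

      # ground truth
      base <- sub("MIR", "miR", spec$id, fixed = TRUE)
      truth_rows <- list()
      mature_records <- list()
      k <- 0L
      ok <- TRUE
      for (d in spec$duplexes) {
        k <- k + 1L
        mspan <- c(d$offset, d$offset + d$length)
        pos <- seq.int(mspan[1] + 1L, mspan[2])
        paired <- setdiff(pos, broken)
        raw <- c(n + 1L - max(paired), n + 1L - min(paired))   # 1-based inclusive
        sspan <- c(max(1L, raw[1] + overhang) - 1L, min(n, raw[2] + overhang))
        truth_rows <- c(truth_rows, list(
          data.frame(name = sprintf("%s.%d-5", base, k), start = mspan[1], end = mspan[2],
                     kind = "sibling_5arm", stringsAsFactors = FALSE),
          data.frame(name = sprintf("%s.%d-3", base, k), start = sspan[1], end = sspan[2],
                     kind = "sibling_3arm", stringsAsFactors = FALSE)))
        mat_seq <- substr(sequence, mspan[1] + 1L, mspan[2])
        mature_records <- c(mature_records, list(
          data.frame(id = sprintf("%s.%d-5", base, k), sequence = mat_seq,
                     precursor_id = spec$id, stringsAsFactors = FALSE)))
        if (d$mismatches == 0) {
          ok <- ok && all(!is.na(ss$pair_table[pos]))
        }
      }
      if (length(spec$loop_distal)) {
        k <- k + 1L
        ld <- spec$loop_distal
        ldspan <- c(ld$offset, ld$offset + ld$length)
        truth_rows <- c(truth_rows, list(
          data.frame(name = sprintf("%s.%d", base, k), start = ldspan[1], end = ldspan[2],
                     kind = "loop_distal", stringsAsFactors = FALSE)))
        mature_records <- c(mature_records, list(
          data.frame(id = sprintf("%s.%d", base, k),
                     sequence = substr(sequence, ldspan[1] + 1L, ldspan[2]),
                     precursor_id = spec$id, stringsAsFactors = FALSE)))
      }
      names_df <- do.call(rbind, truth_rows)
      if (!is.null(names_df)) {
        names_df <- names_df[order(names_df$start), ]
        rownames(names_df) <- NULL
      }
      matures <- do.call(rbind, mature_records)

      # uniqueness of every emitted mature within the precursor
      for (sq in matures$sequence) {
        hits <- gregexpr(sq, sequence, fixed = TRUE)[[1]]
        if (length(hits) != 1 || hits[1] == -1L) ok <- FALSE
      }
      # fold check: maximum-pairing fold must pair all mismatch-free duplex sites
      if (ok) {
        folded <- fold_maxpair(sequence)
        for (d in spec$duplexes) {
          if (d$mismatches == 0) {
            pos <- seq.int(d$offset + 1L, d$offset + d$length)
            if (any(is.na(folded$pair_table[pos]))) ok <- FALSE
          }
        }
      }
      if (ok) {
        return(list(precursor = list(id = spec$id,
                                     species_code = tolower(sub("-.*$", "", spec$id)),
                                     sequence = sequence),
                    structure = ss,
                    truth = list(names = names_df, matures = matures,
                                 n_duplexes = length(spec$duplexes),
                                 is_nested = length(spec$duplexes) >= 2,
                                 loop_span = c(A, A + L)),
                    spec = spec))
      }
    }
    stop("could not generate a well-posed hairpin in ", max_tries, " tries", call. = FALSE)
  })
}

#' Write a hairpin fixture as pipeline input files
#'
#' Emits `hairpin.fa`, `mature.fa` (precursor hint in the description),
#' `structures.db` (dot-bracket) and `truth.json` under `dir`.
#'
#' @param hairpins list of [make_hairpin()] results.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_hairpin_fixture <- function(hairpins, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hp_fa <- file.path(dir, "hairpin.fa")
  mat_fa <- file.path(dir, "mature.fa")
  db <- file.path(dir, "structures.db")
  truth <- file.path(dir, "truth.json")
  write_fasta(vapply(hairpins, function(h) h$precursor$id, ""),
              vapply(hairpins, function(h) h$precursor$sequence, ""), hp_fa)
  matures <- do.call(rbind, lapply(hairpins, function(h) h$truth$matures))
  write_fasta(matures$id, matures$sequence, mat_fa,
              descriptions = paste0("precursor=", matures$precursor_id))
  sslist <- lapply(hairpins, function(h) h$structure)
  names(sslist) <- vapply(hairpins, function(h) h$precursor$id, "")
  write_dotbracket(sslist, db)
  jsonlite::write_json(lapply(hairpins, function(h) h$truth), truth,
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(hairpin = hp_fa, mature = mat_fa, dotbracket = db, truth = truth))
}

#' Specification of a synthetic species panel
#'
#' Region-specific per-site substitution rates emulate the observed
#' constraint pattern: duplex regions evolve slower than loops, which evolve
#' slower than (or equal to) flanks.
#'
#' @param n_species panel size (default 10; ignored when `tree` is given).
#' @param duplex_rate,loop_rate,flank_rate per-site substitution rates in
#'   `[0, 1)` (defaults 0.02 / 0.10 / 0.20).
#' @param tree optional generating `phylo` with branch lengths; without it a
#'   star tree is used and rates are per-tip substitution probabilities.
#' @param seed integer seed.
#' @export
panel_spec <- function(n_species = 10, duplex_rate = 0.02, loop_rate = 0.10,
                       flank_rate = 0.20, tree = NULL, seed = 1) {
  rates <- c(duplex_rate, loop_rate, flank_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)", call. = FALSE)
  if (duplex_rate > loop_rate) {
    warning("duplex_rate > loop_rate: inverted constraint relative to the default model",
            call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species), duplex_rate = duplex_rate,
                 loop_rate = loop_rate, flank_rate = flank_rate,
                 tree = tree, seed = as.integer(seed)),
            class = "panel_spec")
}

.mutate_sites <- function(chars, p_site) {
  hit <- which(runif(length(chars)) < p_site)
  for (i in hit) {
    chars[i] <- sample(setdiff(.RNA_ALPHABET, chars[i]), 1)
  }
  chars
}

#' Evolve a species panel from an ancestor
#'
#' Indel-free by design, so the true alignment is the panel itself. With a
#' generating tree, each edge substitutes per site with the Jukes-Cantor
#' probability `(3/4)(1 - exp(-(4/3) rate t))` for branch length `t`; without
#' one, each species derives independently from the ancestor with the
#' region rate as the per-site substitution probability.
#'
#' @param ancestor a [make_hairpin()] result, or `list(sequence = ...)` with
#'   an optional `regions` character vector (`"duplex"`, `"loop"`, `"flank"`)
#'   of the same length.
#' @param spec a [panel_spec()].
#' @return a list: `precursors` data.frame (id, species_code, sequence),
#'   `alignment` (an `aligned_set`), `regions`, `spec`.
#' @export
make_panel <- function(ancestor, spec) {
  stopifnot(inherits(spec, "panel_spec"))
  if (!is.null(ancestor$precursor)) {
    sequence <- ancestor$precursor$sequence
    n <- nchar(sequence)
    regions <- rep("flank", n)
    nm <- ancestor$truth$names
    dup <- nm[nm$kind %in% c("sibling_5arm", "sibling_3arm"), , drop = FALSE]
    for (i in seq_len(nrow(dup))) regions[(dup$start[i] + 1L):dup$end[i]] <- "duplex"
    ls <- ancestor$truth$loop_span
    regions[(ls[1] + 1L):ls[2]] <- "loop"
  } else {
    sequence <- .normalize_rna(ancestor$sequence)
    n <- nchar(sequence)
    regions <- ancestor$regions %||% rep("flank", n)
    if (length(regions) != n) stop("regions length mismatch", call. = FALSE)
  }
  rate <- c(duplex = spec$duplex_rate, loop = spec$loop_rate,
            flank = spec$flank_rate)[regions]
  anc_chars <- strsplit(sequence, "")[[1]]

  with_seed(spec$seed, {
    if (is.null(spec$tree)) {
      n_sp <- spec$n_species
      codes <- paste0("s", letters[(seq_len(n_sp) - 1L) %/% 26L + 1L],
                      letters[(seq_len(n_sp) - 1L) %% 26L + 1L])
      seqs <- vapply(seq_len(n_sp), function(i) {
        paste(.mutate_sites(anc_chars, rate), collapse = "")
      }, "")
      ids <- paste0(codes, "-MIR159")
    } else {
      tree <- ape::reorder.phylo(spec$tree, "cladewise")
      ntip <- length(tree$tip.label)
      root <- ntip + 1L
      node_seq <- vector("list", ntip + tree$Nnode)
      node_seq[[root]] <- anc_chars
      for (e in seq_len(nrow(tree$edge))) {
        parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
        t_len <- tree$edge.length[e]
        p_site <- 0.75 * (1 - exp(-(4 / 3) * rate * t_len))
        node_seq[[child]] <- .mutate_sites(node_seq[[parent]], p_site)
      }
      seqs <- vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""), "")
      ids <- tree$tip.label
      codes <- tolower(substr(ids, 1, 3))
    }
    names(seqs) <- ids
    list(precursors = data.frame(id = ids, species_code = codes,
                                 sequence = unname(seqs), stringsAsFactors = FALSE),
         alignment = aligned_set(seqs),
         regions = regions, spec = spec)
  })
}

#' Generate a promoter with planted motifs and no accidental occurrences
#'
#' A uniform-composition background is sampled, the motifs are planted at
#' their stated TSS-relative positions (the position is the most-upstream
#' base of the motif), and accidental occurrences of any planted motif (both
#' strands) are destroyed by point repair, re-scanning until the scan
#' recovers exactly the planted set.
#'
#' @param length promoter length in bp (default 3000).
#' @param planted list of `list(motif, position)` with negative positions;
#'   default: the two-GGATA MybSt1 layout at -862 and -950.
#' @param seed integer seed.
#' @param id promoter id.
#' @param max_tries repair-iteration bound (default 100).
#' @return a list: `promoter` (a `promoter_construct`), `truth` data.frame,
#'   `motif_table`.
#' @export
make_promoter <- function(length = 3000,
                          planted = list(list(motif = "GGATA", position = -862),
                                         list(motif = "GGATA", position = -950)),
                          seed = 1, id = "synthetic-promoter", max_tries = 100) {
  truth <- do.call(rbind, lapply(planted, function(p) {
    data.frame(motif = toupper(p$motif), position = as.integer(p$position),
               stringsAsFactors = FALSE)
  }))
  spans <- list()
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth))) {
      idx <- truth$position[i] + length + 1L
      len_m <- nchar(truth$motif[i])
      if (idx < 1L || idx + len_m - 1L > length) {
        stop("planted motif does not fit in the promoter", call. = FALSE)
      }
      spans[[i]] <- c(idx, idx + len_m - 1L)
    }
    if (nrow(truth) > 1) {
      ord <- order(vapply(spans, `[`, 0, 1))
      for (i in seq_len(nrow(truth) - 1)) {
        if (spans[[ord[i]]][2] >= spans[[ord[i + 1]]][1]) {
          stop("planted motifs overlap", call. = FALSE)
        }
      }
    }
  }
  motif_table <- if (is.null(truth)) {
    data.frame(name = character(), consensus = character(), stringsAsFactors = FALSE)
  } else {
    u <- unique(truth$motif)
    data.frame(name = u, consensus = u, stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    planted_idx <- integer(0)
    if (!is.null(truth)) {
      for (i in seq_len(nrow(truth))) {
        idx <- spans[[i]]
        m <- strsplit(truth$motif[i], "")[[1]]
        chars[idx[1]:idx[2]] <- m
        planted_idx <- c(planted_idx, idx[1]:idx[2])
      }
    }
    if (!nrow(motif_table)) {
      return(list(promoter = promoter_sequence(id, paste(chars, collapse = "")),
                  truth = truth, motif_table = motif_table))
    }
    for (try in seq_len(max_tries)) {
      p <- promoter_sequence(id, paste(chars, collapse = ""))
      hits <- scan_motifs(p, motif_table, strands = "both")
      wanted <- paste(truth$motif, truth$position, "+")
      got <- paste(hits$consensus, hits$position, hits$strand)
      extra <- which(!(got %in% wanted))
      if (!length(extra) && all(wanted %in% got)) {
        return(list(promoter = p, truth = truth, motif_table = motif_table,
                    tries = try))
      }
      if (!all(wanted %in% got)) {
        stop("planted motif lost during repair (should not happen)", call. = FALSE)
      }
      for (e in extra) {
        idx0 <- hits$position[e] + length + 1L
        cells <- setdiff(idx0:(idx0 + nchar(hits$consensus[e]) - 1L), planted_idx)
        if (!length(cells)) {
          stop("impossible avoidance: accidental hit lies entirely inside planted motifs",
               call. = FALSE)
        }
        cell <- cells[(length(cells) + 1L) %/% 2L]
        chars[cell] <- sample(setdiff(c("A", "C", "G", "T"), chars[cell]), 1)
      }
    }
    stop("could not generate a clean promoter background in ", max_tries,
         " repair iterations", call. = FALSE)
  })
}

#' Generate a Ct replicate table with known fold changes
#'
#' Reference Cts are fixed; target Cts are
#' `ct_reference - log2(fold) + N(0, sigma)`, so with `sigma = 0` the
#' estimated fold equals the planted fold exactly.
#'
#' @param groups named numeric vector of true folds (e.g.
#'   `c("Col-0" = 1, "OE" = 6)`); names are sample groups.
#' @param n_replicates technical replicates per record (default 3).
#' @param sigma Gaussian Ct noise (default 0.1).
#' @param seed integer seed.
#' @param target,reference target and reference names (defaults
#'   `"miR159a.1-5"`, `"U6"`).
#' @param ct_reference fixed reference Ct (default 20).
#' @return a `ct_table` with attribute `"truth"` (the fold vector).
#' @export
make_ct <- function(groups, n_replicates = 3, sigma = 0.1, seed = 1,
                    target = "miR159a.1-5", reference = "U6", ct_reference = 20) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector of folds", call. = FALSE)
  }
  if (any(groups <= 0)) stop("folds must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (g in names(groups)) {
      ct_t <- ct_reference - log2(groups[[g]]) + rnorm(n_replicates, 0, sigma)
      rows <- c(rows, list(
        data.frame(sample_group = g, target = target, reference = reference,
                   t(setNames(ct_t, paste0("ct_", seq_len(n_replicates)))),
                   stringsAsFactors = FALSE),
        data.frame(sample_group = g, target = reference, reference = reference,
                   t(setNames(rep(ct_reference, n_replicates),
                              paste0("ct_", seq_len(n_replicates)))),
                   stringsAsFactors = FALSE)))
    }
    tab <- as_ct_table(do.call(rbind, rows))
    attr(tab, "truth") <- groups
    tab
  })
}
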