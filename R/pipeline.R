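# Orchestration: ingest -> fold -> detect -> summarize -> evolve -> report,
# driven by a single config whose thresholds are echoed verbatim into the run
# metadata (most thresholds of this analysis are conventions, so every run
# must self-document its choices).

#' Build a pipeline configuration
#'
#' @param hairpin hairpin FASTA path (required).
#' @param mature mature FASTA path (required for duplex detection; mature
#'   headers may carry a `precursor=<id>` hint, otherwise matures are mapped
#'   by substring search).
#' @param dotbracket optional Vienna dot-bracket file with externally
#'   computed structures (ids must match the hairpin ids); precursors without
#'   one are folded with [fold_maxpair()].
#' @param gff optional GFF3 loci file.
#' @param alignment optional aligned FASTA for the conservation/phylogeny
#'   stage.
#' @param labels optional 2-column TSV (leaf, group) for the two-group split
#'   check.
#' @param out_dir output directory.
#' @param min_duplex_pairing,max_mismatches duplex acceptance thresholds.
#' @param conserved_threshold,specific_threshold region-conservation calls.
#' @param min_loop minimum hairpin loop for folding/validation.
#' @param overhang star-strand 3' overhang (nt).
#' @param seed integer seed (recorded; the analysis itself is deterministic).
#' @return a `run_config`.
#' @export
pipeline_config <- function(hairpin, mature = NULL, dotbracket = NULL,
                            gff = NULL, alignment = NULL, labels = NULL,
                            out_dir = tempfile("nestedmir_run_"),
                            min_duplex_pairing = 0.6, max_mismatches = 7,
                            conserved_threshold = 0.75, specific_threshold = 0.5,
                            min_loop = 3, overhang = 2, seed = 1) {
  structure(list(hairpin = hairpin, mature = mature, dotbracket = dotbracket,
                 gff = gff, alignment = alignment, labels = labels,
                 out_dir = out_dir,
                 min_duplex_pairing = min_duplex_pairing,
                 max_mismatches = max_mismatches,
                 conserved_threshold = conserved_threshold,
                 specific_threshold = specific_threshold,
                 min_loop = min_loop, overhang = overhang,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Returns diagnostics (a character vector), not exceptions; an empty vector
#' means the config is runnable.
#'
#' @param config a `run_config`.
#' @return character vector of diagnostics.
#' @export
validate_config <- function(config) {
  d <- character(0)
  if (is.null(config$hairpin)) {
    d <- c(d, "missing required input: hairpin FASTA")
  } else if (!file.exists(config$hairpin)) {
    d <- c(d, paste0("hairpin FASTA not found: ", config$hairpin))
  }
  for (f in c("mature", "dotbracket", "gff", "alignment", "labels")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      d <- c(d, sprintf("%s file not found: %s", f, config[[f]]))
    }
  }
  if (is.null(config$mature)) {
    d <- c(d, "dependency: duplex detection requires a mature FASTA")
  }
  for (thr in c("min_duplex_pairing", "conserved_threshold", "specific_threshold")) {
    v <- config[[thr]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      d <- c(d, sprintf("%s = %s outside [0, 1]", thr, format(v)))
    }
  }
  if (!is.numeric(config$min_loop) || config$min_loop < 0 ||
      config$min_loop != round(config$min_loop)) {
    d <- c(d, "min_loop must be a non-negative integer")
  }
  if (!is.numeric(config$max_mismatches) || config$max_mismatches < 0) {
    d <- c(d, "max_mismatches must be non-negative")
  }
  if (!is.numeric(config$overhang) || config$overhang < 0) {
    d <- c(d, "overhang must be non-negative")
  }
  d
}

.mature_hint <- function(description) {
  ifelse(grepl("precursor=", description),
         sub(".*precursor=(\\S+).*", "\\1", description), NA_character_)
}

# Core detection over a set of precursors: structure, mapped matures, star
# inference, nestedness, naming. Matures whose star inference fails with a
# "not on a stem" condition become loop-distal candidates.
.detect_all <- function(precursors, matures, structures = NULL,
                        min_duplex_pairing = 0.6, max_mismatches = 7,
                        min_loop = 3, overhang = 2) {
  hint <- .mature_hint(matures$description %||% rep("", nrow(matures)))
  inventories <- vector("list", nrow(precursors))
  ss_out <- vector("list", nrow(precursors))
  for (i in seq_len(nrow(precursors))) {
    id <- precursors$id[i]
    seq <- precursors$sequence[i]
    ss <- if (!is.null(structures) && id %in% names(structures)) {
      structures[[id]]
    } else {
      fold_maxpair(seq, min_loop = min_loop)
    }
    ss_out[[i]] <- ss
    cand <- which((!is.na(hint) & hint == id) |
                    (is.na(hint) & vapply(matures$sequence, function(m) {
                      grepl(m, seq, fixed = TRUE)
                    }, NA, USE.NAMES = FALSE)))
    duplexes <- list()
    loop_distal <- list()
    for (j in cand) {
      span <- tryCatch(suppressWarnings(map_mature(seq, matures$sequence[j])),
                       error = function(e) NULL)
      if (is.null(span)) next
      dup <- tryCatch(
        infer_star(ss, span, min_pairing = min_duplex_pairing,
                   overhang = overhang, precursor_id = id),
        error = function(e) {
          if (grepl("not on a stem", conditionMessage(e))) NULL else stop(e)
        })
      if (is.null(dup)) {
        loop_distal <- c(loop_distal, list(span))
      } else {
        duplexes <- c(duplexes, list(dup))
      }
    }
    inv <- detect_nested(id, ss, duplexes, loop_distal = loop_distal,
                         min_duplex_pairing = min_duplex_pairing,
                         max_mismatches = max_mismatches)
    inventories[[i]] <- name_siblings(inv)
  }
  names(ss_out) <- precursors$id
  list(inventories = inventories, structures = ss_out)
}

#' Run the full pipeline
#'
#' Stages: ingest, fold (or ingest external structures), detect, summarize,
#' and optionally evolve (conservation profile, JC69 distances, NJ tree).
#' Outputs are deterministic given config and inputs: run metadata (all
#' thresholds echoed), per-precursor structures, inventories (JSON and a
#' BED-like TSV, 0-based half-open), the nested summary, a plain-text report,
#' and a stage manifest; partial results are preserved when a stage fails.
#'
#' @param config a `run_config` from [pipeline_config()].
#' @return invisibly, a list with `inventories`, `summary`, optional
#'   `evolution`, `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  diags <- validate_config(config)
  if (length(diags)) {
    stop("config error:\n  - ", paste(diags, collapse = "\n  - "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  manifest <- list()
  note <- function(stage, status, detail = "") {
    manifest[[stage]] <<- list(status = status, detail = detail)
    log_lines <<- c(log_lines, sprintf("[%s] %s %s", stage, status, detail))
  }
  res <- list(out_dir = config$out_dir)

  meta <- unclass(config)
  meta$tree <- NULL
  jsonlite::write_json(meta, file.path(config$out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  stage <- function(name, expr) {
    tryCatch({
      v <- force(expr)
      v
    }, error = function(e) {
      note(name, "failed", conditionMessage(e))
      NULL
    })
  }

  # ingest
  precursors <- stage("ingest", {
    p <- read_fasta_dialect(config$hairpin, "hairpin")
    note("ingest", "ok", sprintf("%d precursors", nrow(p)))
    p
  })
  matures <- NULL
  if (!is.null(precursors)) {
    matures <- stage("ingest_mature", {
      m <- read_fasta_dialect(config$mature, "mature")
      note("ingest_mature", "ok", sprintf("%d matures", nrow(m)))
      m
    })
  }
  structures <- NULL
  if (!is.null(config$dotbracket) && !is.null(precursors)) {
    structures <- stage("ingest_structures", {
      s <- read_dotbracket(config$dotbracket)
      note("ingest_structures", "ok", sprintf("%d structures", length(s)))
      s
    })
  }

  # detect + summarize
  if (!is.null(precursors) && !is.null(matures)) {
    det <- stage("detect", {
      d <- .detect_all(precursors, matures, structures,
                       min_duplex_pairing = config$min_duplex_pairing,
                       max_mismatches = config$max_mismatches,
                       min_loop = config$min_loop, overhang = config$overhang)
      note("detect", "ok", sprintf("%d inventories", length(d$inventories)))
      d
    })
    if (!is.null(det)) {
      res$inventories <- det$inventories
      write_dotbracket(det$structures, file.path(config$out_dir, "structures.db"))
      inv_json <- lapply(det$inventories, function(x) {
        list(precursor_id = x$precursor_id, is_nested = x$is_nested,
             n_duplexes = length(x$duplexes), names = x$names,
             params = x$params)
      })
      jsonlite::write_json(inv_json, file.path(config$out_dir, "inventories.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      bed <- do.call(rbind, lapply(det$inventories, function(x) {
        if (is.null(x$names)) return(NULL)
        data.frame(precursor = x$precursor_id, start = x$names$start,
                   end = x$names$end, name = x$names$name, kind = x$names$kind,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(bed)) {
        write.table(bed, file.path(config$out_dir, "inventory.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      summ <- stage("summarize", {
        s <- summarize_inventories(det$inventories)
        note("summarize", "ok", sprintf("%d of %d nested", s$nested_count, s$total))
        s
      })
      if (!is.null(summ)) {
        res$summary <- summ
        write_report(summ, file.path(config$out_dir, "nested_summary"))
        report <- c(sprintf("%d of %d precursors nested", summ$nested_count, summ$total),
                    sprintf("%d species", summ$n_species),
                    sprintf("thresholds: min_duplex_pairing=%g max_mismatches=%g min_loop=%g overhang=%g",
                            config$min_duplex_pairing, config$max_mismatches,
                            config$min_loop, config$overhang))
        writeLines(report, file.path(config$out_dir, "report.txt"))
      }
    }
  }

  # evolve (optional)
  if (!is.null(config$alignment)) {
    evo <- stage("evolve", {
      a <- read_alignment(config$alignment)
      prof <- conservation_profile(a)
      d <- pdistance(a, "JC69")
      tree <- neighbor_joining(d)
      split_ok <- NA
      if (!is.null(config$labels)) {
        lab <- read.delim(config$labels, header = FALSE,
                          col.names = c("leaf", "group"),
                          stringsAsFactors = FALSE)
        split_ok <- two_group_split(tree, setNames(lab$group, lab$leaf))
      }
      note("evolve", "ok", sprintf("%d rows x %d cols", length(a$ids), a$n_cols))
      list(profile = prof, distances = d, tree = tree, two_group_split = split_ok)
    })
    if (!is.null(evo)) {
      res$evolution <- evo
      write.table(evo$profile, file.path(config$out_dir, "conservation_profile.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_phylip(evo$distances, file.path(config$out_dir, "distances.phy"))
      ape::write.tree(evo$tree, file.path(config$out_dir, "tree.nwk"))
    }
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  res$manifest <- manifest
  res$ok <- !any(vapply(manifest, function(m) m$status == "failed", NA))
  invisible(res)
}
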