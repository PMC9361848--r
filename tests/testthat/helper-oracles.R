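# Independent oracles and small fixture builders used across the suite.

LEGAL <- c("AU", "UA", "GC", "CG", "GU", "UG")

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                              collapse = "")

# Brute-force maximum pair count by recursive enumeration of all non-crossing
# structures (independent of the package's dynamic-programming folder).
max_pairs_enum <- function(sequence, min_loop = 3) {
  chars <- strsplit(sequence, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (paste0(chars[i], chars[k]) %in% LEGAL) {
        cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (cand > best) best <- cand
      }
    }
    best
  }
  if (length(chars) < 2) 0L else rec(1L, length(chars))
}

# Recover a nested inventory from a generated hairpin through the public API,
# using the generator's ground-truth structure (the external-structure
# fidelity route).
recover_inventory <- function(hp, min_pairing = 0.6, overhang = 2,
                              use_fold = FALSE) {
  ss <- if (use_fold) fold_maxpair(hp$precursor$sequence) else hp$structure
  duplexes <- list()
  loop_distal <- list()
  for (i in seq_len(nrow(hp$truth$matures))) {
    span <- map_mature(hp$precursor$sequence, hp$truth$matures$sequence[i])
    dup <- tryCatch(
      infer_star(ss, span, min_pairing = min_pairing, overhang = overhang,
                 precursor_id = hp$precursor$id),
      error = function(e) NULL)
    if (is.null(dup)) loop_distal <- c(loop_distal, list(span))
    else duplexes <- c(duplexes, list(dup))
  }
  name_siblings(detect_nested(hp$precursor$id, ss, duplexes,
                              loop_distal = loop_distal,
                              min_duplex_pairing = min_pairing))
}

# A perfect hairpin: arms exactly complementary around an A-only loop.
perfect_hairpin <- function(arm, loop_len = 6, seed = 1) {
  set.seed(seed)
  arm5 <- rand_rna(arm)
  arm3 <- paste(rev(strsplit(chartr("ACGU", "UGCA", arm5), "")[[1]]), collapse = "")
  seq <- paste0(arm5, strrep("A", loop_len), arm3)
  db <- paste0(strrep("(", arm), strrep(".", loop_len), strrep(")", arm))
  list(sequence = seq, dotbracket = db)
}

# The six-precursor synthetic study set: five nested (two duplexes plus a
# loop-distal RNA, the MIR159a architecture) and one single-duplex hairpin.
study_hairpins <- function() {
  lapply(1:6, function(i) {
    id <- sprintf("s%s%s-MIR159a", letters[i], letters[i])
    sp <- if (i < 6) {
      hairpin_spec(seed = i, id = id)
    } else {
      hairpin_spec(duplexes = list(list(offset = 5, length = 21, mismatches = 0)),
                   loop_distal = NULL, seed = i, id = id)
    }
    make_hairpin(sp)
  })
}

# Robinson-Foulds distance between unrooted topologies, as a bare number.
rf_dist <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
}

# Random binary tree with positive branch lengths (additive metric source).
rand_tree <- function(ntaxa, min_bl = 0.05, max_bl = 0.3) {
  tr <- ape::rtree(ntaxa, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}
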