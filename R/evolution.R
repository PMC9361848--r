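# Conservation profiling of aligned stem-loops and distance-based phylogeny.
#
# Alignments are ingested (computing them is out of scope); distances are
# p-distances with optional Jukes-Cantor correction; trees come from a
# hand-rolled Saitou-Nei neighbor joining with a lexicographic tie-break so
# runs are bit-reproducible. ape handles newick serialization and is the
# independent cross-check in the test suite.

#' Construct an aligned set
#'
#' @param sequences named character vector of gapped sequences over
#'   `A,C,G,U,-` (T normalized to U).
#' @return an `aligned_set`: ids, sequences, `n_cols`, and a character matrix.
#' @export
aligned_set <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("aligned sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sequences))) stop("duplicate row ids", call. = FALSE)
  if (length(sequences) < 2) stop("an alignment needs at least 2 rows", call. = FALSE)
  sequences <- .normalize_rna(sequences)
  n_cols <- unique(nchar(sequences))
  if (length(n_cols) != 1) stop("alignment rows differ in length", call. = FALSE)
  bad <- gsub("[ACGU-]", "", paste(sequences, collapse = ""))
  if (nzchar(bad)) {
    stop("alphabet error in alignment: illegal character(s) ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(sequences, ""))
  rownames(mat) <- names(sequences)
  structure(list(ids = names(sequences), sequences = sequences,
                 n_cols = n_cols, mat = mat),
            class = "aligned_set")
}

#' Read an aligned FASTA file
#' @param path aligned-FASTA file (all records equal length).
#' @return an `aligned_set`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  sequences <- as.character(set)
  names(sequences) <- sub("\\s.*$", "", names(set))
  aligned_set(sequences)
}

#' Per-column conservation profile
#'
#' Column identity is the frequency of the modal residue among non-gap
#' characters; the gap fraction is reported separately. An all-gap column has
#' identity 0 by convention and gap fraction 1.
#'
#' @param a an `aligned_set`.
#' @return a data.frame with `column`, `identity`, `gap_fraction`.
#' @export
conservation_profile <- function(a) {
  stopifnot(inherits(a, "aligned_set"))
  identity <- numeric(a$n_cols)
  gapfrac <- numeric(a$n_cols)
  for (j in seq_len(a$n_cols)) {
    col <- a$mat[, j]
    gapfrac[j] <- mean(col == "-")
    res <- col[col != "-"]
    identity[j] <- if (length(res)) max(table(res)) / length(res) else 0
  }
  data.frame(column = seq_len(a$n_cols), identity = identity,
             gap_fraction = gapfrac)
}

#' Region conservation summary
#'
#' Computes the region consensus (modal non-gap residue per column,
#' alphabetical tie-break) and each member's identity to it, then calls
#' members conserved (identity at or above `conserved_threshold`) or specific
#' (below `specific_threshold`). Thresholds are echoed in the result, since
#' the conserved/specific percentages only mean something relative to them.
#'
#' @param a an `aligned_set`.
#' @param region alignment-column interval `c(from, to)`, 1-based inclusive.
#' @param conserved_threshold default 0.75.
#' @param specific_threshold default 0.50.
#' @return a list: `mean_identity`, `consensus`, per-`member` table,
#'   `fraction_conserved`, `fraction_specific`, `thresholds`.
#' @export
region_conservation <- function(a, region, conserved_threshold = 0.75,
                                specific_threshold = 0.50) {
  stopifnot(inherits(a, "aligned_set"))
  if (length(region) != 2 || region[1] > region[2] ||
      region[1] < 1 || region[2] > a$n_cols) {
    stop("empty or out-of-range region", call. = FALSE)
  }
  cols <- region[1]:region[2]
  consensus <- vapply(cols, function(j) {
    res <- a$mat[, j]
    res <- res[res != "-"]
    if (!length(res)) return(NA_character_)
    tab <- table(res)
    names(tab)[which.max(tab)]            # table() is alphabetical: ties resolved
  }, "")
  defined <- !is.na(consensus)
  ident <- vapply(seq_along(a$ids), function(i) {
    if (!any(defined)) return(NA_real_)
    mean(a$mat[i, cols[defined]] == consensus[defined])
  }, 0)
  members <- data.frame(id = a$ids, identity = ident,
                        conserved = ident >= conserved_threshold,
                        specific = ident < specific_threshold,
                        stringsAsFactors = FALSE)
  list(mean_identity = mean(ident),
       consensus = paste(ifelse(is.na(consensus), "-", consensus), collapse = ""),
       members = members,
       fraction_conserved = mean(members$conserved),
       fraction_specific = mean(members$specific),
       thresholds = list(conserved = conserved_threshold,
                         specific = specific_threshold))
}

#' Pairwise distances from an alignment
#'
#' p-distance over columns where both rows are non-gap, optionally corrected
#' with the Jukes-Cantor 1969 model, `d = -(3/4) log(1 - 4p/3)`. Saturated
#' pairs (`p >= 0.75`, outside the JC69 domain) are set to `ceiling` with a
#' warning.
#'
#' @param a an `aligned_set`.
#' @param correction `"none"` or `"JC69"`.
#' @param ceiling distance assigned to saturated pairs (default 5).
#' @return a symmetric numeric matrix with zero diagonal, row/column names
#'   the alignment ids, and attribute `"correction"`.
#' @export
pdistance <- function(a, correction = c("none", "JC69"), ceiling = 5) {
  stopifnot(inherits(a, "aligned_set"))
  correction <- match.arg(correction)
  n <- length(a$ids)
  d <- matrix(0, n, n, dimnames = list(a$ids, a$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- a$mat[i, ] != "-" & a$mat[j, ] != "-"
      if (!any(ok)) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     a$ids[i], a$ids[j]), call. = FALSE)
      }
      p <- mean(a$mat[i, ok] != a$mat[j, ok])
      v <- p
      if (correction == "JC69") {
        if (p >= 0.75) {
          warning(sprintf("saturated pair '%s'/'%s' (p = %.3f >= 0.75): distance set to ceiling %g",
                          a$ids[i], a$ids[j], p, ceiling), call. = FALSE)
          v <- ceiling
        } else {
          v <- -0.75 * log(1 - 4 * p / 3)
        }
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  attr(d, "correction") <- correction
  d
}

#' Jukes-Cantor correction of a p-distance
#' @param p proportion of differing sites, in `[0, 0.75)`.
#' @return corrected distance `-(3/4) log(1 - 4p/3)`.
#' @export
jc69 <- function(p) {
  if (any(p < 0 | p >= 0.75)) stop("JC69 is defined for p in [0, 0.75)", call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, branch lengths are
#' `d(i,j)/2 +- (r_i - r_j)/(2(n-2))`, and the matrix is reduced. Ties on Q
#' are broken by the lexicographically smallest pair of subtree labels (the
#' smallest original id in each subtree), so the result is deterministic.
#' Negative branch-length estimates are clamped to zero and the raw values
#' recorded in the `"clamped"` attribute. NJ is exact on additive matrices:
#' it returns the generating topology and path lengths.
#'
#' @param d symmetric distance matrix with zero diagonal and row/column
#'   names; 2 taxa give a single split edge.
#' @return an [ape::read.tree()] `phylo` (unrooted for >= 3 taxa).
#' @export
neighbor_joining <- function(d) {
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    stop("distance matrix must have row and column names", call. = FALSE)
  }
  if (!isSymmetric(unname(d), tol = 1e-12)) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  ids <- rownames(d)
  n <- length(ids)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  clamped <- data.frame(node = character(), raw = numeric(), stringsAsFactors = FALSE)
  clamp <- function(x, label) {
    if (x < 0) {
      clamped <<- rbind(clamped, data.frame(node = label, raw = x,
                                            stringsAsFactors = FALSE))
      return(0)
    }
    x
  }
  fmt <- function(x) sprintf("%.15g", x)

  if (n == 2) {
    nwk <- sprintf("(%s:%s,%s:%s);", ids[1], fmt(d[1, 2] / 2), ids[2], fmt(d[1, 2] / 2))
    tree <- ape::read.tree(text = nwk)
    attr(tree, "clamped") <- clamped
    return(tree)
  }

  # active nodes: newick fragment + tie-break label (smallest original id)
  frag <- as.list(ids)
  names(frag) <- ids
  lab <- ids
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(lab[ij[1]], lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)), lab[i])
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))), lab[j])
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[[i]], fmt(li), frag[[j]], fmt(lj))
    newlab <- min(lab[i], lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], list(newfrag))
    lab <- c(lab[keep], newlab)
    dimnames(D2) <- list(lab, lab)
    D <- D2
  }
  # final three-way join (closed form)
  a <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2, lab[1])
  b <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2, lab[2])
  c3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2, lab[3])
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[[1]], fmt(a), frag[[2]], fmt(b), frag[[3]], fmt(c3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Does one edge split the tree into the two label groups?
#'
#' True when some edge bipartition of the leaves equals the bipartition
#' induced by the two group labels (e.g. monocot vs dicot).
#'
#' @param tree a `phylo`.
#' @param group_labels named vector mapping every leaf to one of two groups.
#' @return logical.
#' @export
two_group_split <- function(tree, group_labels) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(group_labels))
  if (length(missing)) {
    stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- unique(group_labels[tips])
  if (length(groups) != 2) return(FALSE)
  target <- sort(tips[group_labels[tips] == groups[1]])
  ntip <- length(tips)
  below <- function(node) {
    if (node <= ntip) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(below(tree$edge[e, 2]))
    other <- sort(setdiff(tips, side))
    if (identical(side, target) || identical(other, target)) return(TRUE)
  }
  FALSE
}

#' Write a distance matrix in PHYLIP square format
#' @param d symmetric matrix with dimnames.
#' @param path output file.
#' @export
write_phylip <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
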