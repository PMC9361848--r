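# Relative quantification for qPCR: 2^-deltaCt, replicate summaries and
# group tests. miRNA targets are normalized to U-6, mRNA targets to
# CYCLOPHILIN (any reference works: a row whose target equals the reference
# name supplies the reference Cts for its sample group); the baseline group's
# mean is set to 1.

#' 2^-deltaCt relative quantity
#'
#' @param ct_target,ct_reference finite Ct values (vectorized).
#' @return `2^-(ct_target - ct_reference)`.
#' @export
relative_quantity <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  2^-(ct_target - ct_reference)
}

#' Read a Ct table
#'
#' CSV with columns `sample_group`, `target`, `reference` and replicate
#' columns `ct_1 .. ct_N` (any column starting with `ct`). Rows whose
#' `target` equals a reference gene name carry that reference's Cts for the
#' sample group.
#'
#' @param path CSV file.
#' @return a validated `ct_table` data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_ct_table(df)
}

#' @rdname read_ct_table
#' @param df a data.frame in the same layout.
#' @export
as_ct_table <- function(df) {
  need <- c("sample_group", "target", "reference")
  if (!all(need %in% names(df))) {
    stop("ct table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ctcols <- grep("^ct", names(df), value = TRUE)
  if (!length(ctcols)) stop("ct table has no replicate columns (ct_1 ...)", call. = FALSE)
  cts <- as.matrix(df[, ctcols, drop = FALSE])
  if (any(rowSums(!is.na(cts)) < 1)) {
    stop("every record needs at least one replicate Ct", call. = FALSE)
  }
  if (any(cts[!is.na(cts)] <= 0 | cts[!is.na(cts)] > 45)) {
    stop("Ct values must lie in (0, 45]", call. = FALSE)
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

.ct_matrix <- function(table, row) {
  ctcols <- grep("^ct", names(table), value = TRUE)
  v <- as.numeric(table[row, ctcols])
  v[!is.na(v)]
}

#' Per-replicate relative quantities
#'
#' Pairs each target replicate Ct with the same-index reference replicate Ct
#' in the same sample group and applies [relative_quantity()].
#'
#' @param table a `ct_table`.
#' @return long data.frame: `sample_group`, `target`, `reference`,
#'   `replicate`, `rq`.
#' @export
replicate_rq <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  refs <- unique(table$reference)
  is_ref <- table$target %in% refs
  out <- list()
  for (i in which(!is_ref)) {
    g <- table$sample_group[i]
    ref <- table$reference[i]
    j <- which(table$sample_group == g & table$target == ref)
    if (!length(j)) {
      stop(sprintf("no reference ('%s') record for target '%s' in group '%s'",
                   ref, table$target[i], g), call. = FALSE)
    }
    ct_t <- .ct_matrix(table, i)
    ct_r <- .ct_matrix(table, j[1])
    if (length(ct_r) == 1) ct_r <- rep(ct_r, length(ct_t))
    if (length(ct_r) != length(ct_t)) {
      stop(sprintf("replicate count mismatch between '%s' and reference '%s' in group '%s'",
                   table$target[i], ref, g), call. = FALSE)
    }
    out <- c(out, list(data.frame(sample_group = g, target = table$target[i],
                                  reference = ref,
                                  replicate = seq_along(ct_t),
                                  rq = relative_quantity(ct_t, ct_r),
                                  stringsAsFactors = FALSE)))
  }
  do.call(rbind, out)
}

#' Summarize replicate relative expression against a baseline group
#'
#' Per-replicate RQs are averaged per (group, target); the SEM is taken over
#' the replicate RQs; fold change is the ratio of the group mean to the
#' baseline group's mean, so the baseline's fold is exactly 1 (the
#' wild-type-set-to-1 convention of qPCR figures).
#'
#' @param table a `ct_table`.
#' @param baseline_group group whose mean RQ is set to 1 (e.g. `"Col-0"`).
#' @return data.frame: `sample_group`, `target`, `reference`, `n_replicates`,
#'   `mean_rq`, `sem`, `fold`.
#' @export
summarize_replicates <- function(table, baseline_group) {
  rq <- replicate_rq(table)
  key <- interaction(rq$sample_group, rq$target, drop = TRUE)
  agg <- do.call(rbind, lapply(split(rq, key), function(g) {
    data.frame(sample_group = g$sample_group[1], target = g$target[1],
               reference = g$reference[1], n_replicates = nrow(g),
               mean_rq = mean(g$rq),
               sem = if (nrow(g) > 1) sd(g$rq) / sqrt(nrow(g)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$fold <- NA_real_
  for (tg in unique(agg$target)) {
    base <- agg$mean_rq[agg$target == tg & agg$sample_group == baseline_group]
    if (!length(base)) {
      stop(sprintf("baseline group '%s' missing for target '%s'",
                   baseline_group, tg), call. = FALSE)
    }
    agg$fold[agg$target == tg] <- agg$mean_rq[agg$target == tg] / base
  }
  agg[order(agg$target, agg$sample_group), , drop = FALSE]
}

.stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Two-group t test or k-group one-way ANOVA on expression values
#'
#' Two groups give a two-sided Student's t test (equal variances); more give
#' a one-way ANOVA. Significance stars follow the usual figure-caption
#' thresholds 0.05 / 0.01 / 0.001. Groups whose values are all identical are
#' handled explicitly (t = 0, p = 1 when the means agree).
#'
#' @param values numeric vector (e.g. replicate RQs).
#' @param groups group factor of the same length (>= 2 observations each).
#' @return list: `method`, `statistic`, `p_value`, `stars`.
#' @export
group_tests <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "),
         call. = FALSE)
  }
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (k == 2) {
    split_v <- split(values, groups)
    if (sd(values) == 0 || (sd(split_v[[1]]) == 0 && sd(split_v[[2]]) == 0)) {
      if (mean(split_v[[1]]) == mean(split_v[[2]])) {
        return(list(method = "t", statistic = 0, p_value = 1, stars = "ns"))
      }
      return(list(method = "t", statistic = Inf, p_value = 0, stars = "***"))
    }
    tt <- t.test(split_v[[1]], split_v[[2]], var.equal = TRUE)
    return(list(method = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value, stars = .stars(tt$p.value)))
  }
  fit <- anova(aov(values ~ groups))
  list(method = "anova", statistic = fit[["F value"]][1],
       p_value = fit[["Pr(>F)"]][1], stars = .stars(fit[["Pr(>F)"]][1]))
}
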