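# Generators: determinism, spec validation, ground-truth consistency.

test_that("generators are deterministic given (spec, seed)", {
  h1 <- make_hairpin(hairpin_spec(seed = 5))
  h2 <- make_hairpin(hairpin_spec(seed = 5))
  expect_identical(h1$precursor$sequence, h2$precursor$sequence)
  expect_identical(h1$truth$names, h2$truth$names)
  expect_false(identical(h1$precursor$sequence,
                         make_hairpin(hairpin_spec(seed = 6))$precursor$sequence))

  p1 <- make_promoter(seed = 3)
  p2 <- make_promoter(seed = 3)
  expect_identical(p1$promoter$sequence, p2$promoter$sequence)

  c1 <- make_ct(c(a = 1, b = 2), sigma = 0.3, seed = 4)
  c2 <- make_ct(c(a = 1, b = 2), sigma = 0.3, seed = 4)
  expect_identical(c1, c2)

  hp <- make_hairpin(hairpin_spec(seed = 2))
  pa1 <- make_panel(hp, panel_spec(n_species = 4, seed = 8))
  pa2 <- make_panel(hp, panel_spec(n_species = 4, seed = 8))
  expect_identical(pa1$precursors, pa2$precursors)
})

test_that("hairpin specs are validated", {
  expect_error(hairpin_spec(duplexes = list(list(offset = 5, length = 30, mismatches = 0),
                                            list(offset = 20, length = 21, mismatches = 0))),
               "overlap")
  expect_error(hairpin_spec(duplexes = list(list(offset = 70, length = 21, mismatches = 0))),
               "outside the arm")
  expect_error(hairpin_spec(loop_length = 2), "loop_length")
  expect_error(hairpin_spec(duplexes = list(list(offset = 5, length = 5, mismatches = 6))),
               "mismatches")
})

test_that("generated hairpins honor their ground truth", {
  hp <- make_hairpin(hairpin_spec(seed = 13))
  n <- nchar(hp$precursor$sequence)
  expect_equal(n, 2 * 80 + 12)
  # truth structure ingests cleanly and the fold covers planted duplex sites
  folded <- fold_maxpair(hp$precursor$sequence)
  for (d in hp$spec$duplexes) {
    pos <- (d$offset + 1):(d$offset + d$length)
    expect_true(all(!is.na(folded$pair_table[pos])))
  }
  # every emitted mature occurs exactly once
  for (sq in hp$truth$matures$sequence) {
    expect_length(attr(map_mature(hp$precursor$sequence, sq), "matches"), 1)
  }
  # no planted duplexes -> plain hairpin, not nested downstream
  plain <- make_hairpin(hairpin_spec(duplexes = list(), loop_distal = NULL, seed = 14))
  expect_null(plain$truth$names)
})

test_that("panels: zero rates copy the ancestor; constrained regions stay conserved", {
  hp <- make_hairpin(hairpin_spec(seed = 2))
  pan0 <- make_panel(hp, panel_spec(n_species = 5, duplex_rate = 0, loop_rate = 0,
                                    flank_rate = 0, seed = 1))
  expect_true(all(pan0$precursors$sequence == hp$precursor$sequence))
  expect_true(all(conservation_profile(pan0$alignment)$identity == 1))

  pan <- make_panel(hp, panel_spec(n_species = 10, duplex_rate = 0,
                                   loop_rate = 0.1, flank_rate = 0.3, seed = 5))
  prof <- conservation_profile(pan$alignment)
  expect_equal(mean(prof$identity[pan$regions == "duplex"]), 1)
  expect_gt(mean(prof$identity[pan$regions == "duplex"]),
            mean(prof$identity[pan$regions == "flank"]))
  expect_error(panel_spec(flank_rate = 1), "\\[0, 1\\)")
  expect_warning(panel_spec(duplex_rate = 0.5, loop_rate = 0.1), "inverted")
})

test_that("promoter generator plants motifs exactly and only there", {
  pr <- make_promoter(length = 3000, seed = 17)
  hits <- scan_motifs(pr$promoter, pr$motif_table, strands = "both")
  expect_equal(nrow(hits), 2)
  expect_equal(sort(hits$position), c(-950L, -862L))
  expect_true(all(hits$strand == "+"))
  # no planted motifs -> no hits for any probe motif
  pr0 <- make_promoter(length = 500, planted = list(), seed = 18)
  expect_equal(nchar(pr0$promoter$sequence), 500)
  expect_error(make_promoter(length = 100,
                             planted = list(list(motif = "GGATA", position = -200)),
                             seed = 1), "does not fit")
  expect_error(make_promoter(length = 3000,
                             planted = list(list(motif = "GGATA", position = -862),
                                            list(motif = "GGATA", position = -860)),
                             seed = 1), "overlap")
})

test_that("Ct generator: noiseless folds are exact; reference Cts fixed", {
  ct <- make_ct(c(WT = 1, EV = 6, OE = 2), sigma = 0, seed = 1)
  out <- summarize_replicates(ct, "WT")
  expect_equal(setNames(out$fold, out$sample_group)[c("WT", "EV", "OE")],
               c(WT = 1, EV = 6, OE = 2))
  refs <- ct[ct$target == "U6", grep("^ct", names(ct))]
  expect_true(all(refs == 20))
  expect_error(make_ct(c(a = -1)), "positive")
  expect_error(make_ct(c(a = 1), sigma = -0.1), "sigma")
})
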