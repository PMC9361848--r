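# Folding, dot-bracket validation, decomposition and topology.

test_that("fold_maxpair handles the canonical small cases", {
  expect_equal(n_pairs(fold_maxpair("GGGAAAACCC")), 3)
  ss <- fold_maxpair("AAAA")
  expect_equal(n_pairs(ss), 0)
  expect_equal(ss$dotbracket, "....")
  expect_equal(n_pairs(fold_maxpair("GCGC")), 0)   # min_loop = 3 forbids any pair
  expect_error(fold_maxpair("ACGT"), "alphabet")
  expect_error(fold_maxpair(""), "non-empty")
})

test_that("a perfectly complementary hairpin pairs exactly (n - L)/2 bases", {
  for (arm in c(10, 25, 40)) {
    hp <- perfect_hairpin(arm, loop_len = 6, seed = arm)
    ss <- fold_maxpair(hp$sequence)
    expect_equal(n_pairs(ss), arm)
  }
})

test_that("ingest_dotbracket validates structures and rejects bad input", {
  ss <- ingest_dotbracket("GGGAAAACCC", "(((....)))")
  expect_equal(n_pairs(ss), 3)
  expect_equal(ss$pair_table[1], 10L)
  expect_equal(ss$pair_table[ss$pair_table[1]], 1L)     # involution
  expect_error(ingest_dotbracket("GGGAAAACCC", "(((....))"), "length")
  expect_error(ingest_dotbracket("GGGAAAACC", "(((....))"), "unbalanced")
  expect_error(ingest_dotbracket("GGGACCC", "(((.)))"), "min_loop")
  expect_error(ingest_dotbracket("GGGAAAAACC", "(((....)))"), "illegal pair G-A")
})

test_that("dot-bracket files round-trip", {
  hp <- perfect_hairpin(12, seed = 3)
  ss <- ingest_dotbracket(hp$sequence, hp$dotbracket)
  path <- tempfile(fileext = ".db")
  write_dotbracket(list(x = ss), path)
  back <- read_dotbracket(path)
  expect_equal(back$x$dotbracket, ss$dotbracket)
  expect_equal(back$x$sequence, ss$sequence)
})

test_that("decompose labels partition the precursor into arms, loop and flanks", {
  hp <- perfect_hairpin(12, loop_len = 6, seed = 5)
  ss <- ingest_dotbracket(hp$sequence, hp$dotbracket)
  dec <- decompose(ss)
  expect_equal(dec$five_arm, c(0L, 12L))
  expect_equal(dec$loop, c(12L, 18L))
  expect_equal(dec$three_arm, c(18L, 30L))
  expect_equal(table(dec$labels)[["5arm"]], 12)
  expect_true(all(dec$labels %in% c("5arm", "3arm", "loop", "flank")))

  # bulge on the 5' arm stays labeled 5arm; unpaired ends are flank
  db <- "..(((.(((....))).))).."
  ss2 <- ingest_dotbracket("AAGGGAGGGAAAACCCACCCAA", db)
  dec2 <- decompose(ss2)
  expect_equal(dec2$labels[6], "5arm")     # bulged base inside the 5' helix
  expect_equal(dec2$labels[c(1, 2, 21, 22)], rep("flank", 4))
  expect_setequal(which(dec2$labels == "loop"), 10:13)

  expect_error(decompose(fold_maxpair("AAAA")), "no hairpin")
})

test_that("decompose labels partition [0, n) on random folded sequences", {
  set.seed(19)
  for (i in 1:25) {
    ss <- fold_maxpair(rand_rna(sample(40:90, 1)))
    if (n_pairs(ss) == 0) next
    dec <- decompose(ss)
    expect_equal(length(dec$labels), ss$n)
    expect_false(any(is.na(dec$labels)))
    # 5' arm positions pair only into the 3' arm
    five <- which(dec$labels == "5arm")
    partners <- ss$pair_table[five]
    expect_true(all(dec$labels[partners[!is.na(partners)]] == "3arm"))
  }
})

test_that("topology: elongated stems vs branched multiloops", {
  hp <- perfect_hairpin(15, seed = 2)
  topo <- classify_topology(ingest_dotbracket(hp$sequence, hp$dotbracket))
  expect_equal(topo$label, "elongated_stem")
  expect_equal(topo$branch_count, 0L)
  expect_equal(topo$longest_stem_run, 15)

  # three-way junction: two helices emanate from a multiloop
  db <- "((..((....))..((....))..))"
  topo2 <- classify_topology(ingest_dotbracket("GGAAGGAAAACCAAGGAAAACCAACC", db))
  expect_equal(topo2$label, "branched")
  expect_gte(topo2$branch_count, 2L)

  # internal loops only (no multiloop) stay elongated
  ss3 <- ingest_dotbracket("GGGAAGGGAAAACCCAACCC", "(((..(((....)))..)))")
  expect_equal(classify_topology(ss3)$label, "elongated_stem")
})
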