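# TSS-relative promoter bookkeeping and cis-element scanning.

test_that("truncation keeps exactly the bases nearest the TSS", {
  set.seed(6)
  p <- promoter_sequence("prom", paste(sample(c("A", "C", "G", "T"), 3000,
                                              replace = TRUE), collapse = ""))
  t1 <- truncate_promoter(p, 1000)
  expect_equal(nchar(t1$sequence), 1000)
  expect_equal(construct_positions(t1), seq(-1000L, -1L))
  expect_equal(t1$sequence, substr(p$sequence, 2001, 3000))
  expect_equal(truncate_promoter(p, 3000)$sequence, p$sequence)   # identity
  expect_error(truncate_promoter(p, 3001), "only 3000 bp available")
})

test_that("deletions remove the stated span and renumber upstream bases only", {
  set.seed(7)
  p <- promoter_sequence("prom", paste(sample(c("A", "C", "G", "T"), 1500,
                                              replace = TRUE), collapse = ""))
  d1 <- delete_span(p, 858, 862)
  expect_equal(nchar(d1$sequence), 1495)            # 862 - 858 + 1 = 5 removed
  d2 <- delete_span(d1, 946, 950)                   # original coordinates
  expect_equal(nchar(d2$sequence), 1490)
  # downstream sequence identical, upstream shifted
  expect_equal(substr(d1$sequence, 1495 - 857 + 1, 1495),
               substr(p$sequence, 1500 - 857 + 1, 1500))
  d3 <- delete_span(p, 5, 5)
  expect_equal(nchar(d3$sequence), 1499)
  expect_error(delete_span(p, 1501, 1505), "outside the construct")
  # reversed bounds behave the same
  expect_equal(delete_span(p, 862, 858)$sequence, d1$sequence)
})

test_that("the two-GGATA MybSt1 layout yields 2, then 1, then 0 hits", {
  pr <- make_promoter(seed = 11)
  myb <- builtin_motifs()[builtin_motifs()$name == "MybSt1", ]
  hits <- scan_motifs(pr$promoter, myb)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$position, c(-950L, -862L))
  expect_equal(hits$match, c("GGATA", "GGATA"))
  # interval arithmetic: the printed coordinates span exactly the motif length
  expect_equal(abs(-858 - (-862)) + 1, nchar("GGATA"))

  d1 <- delete_span(pr$promoter, 858, 862)
  h1 <- scan_motifs(d1, myb)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$position, -945L)   # renumbered by the 5-bp deletion downstream
  d2 <- delete_span(d1, 946, 950)
  expect_equal(nrow(scan_motifs(d2, myb)), 0)
})

test_that("minus-strand scanning reports reverse-complement matches", {
  p <- promoter_sequence("p", paste0("AAAA", "GGATA", "AAAA", "TATCC", "AAAA"))
  myb <- data.frame(name = "MybSt1", consensus = "GGATA")
  plus <- scan_motifs(p, myb, strands = "+")
  expect_equal(nrow(plus), 1)
  both <- scan_motifs(p, myb, strands = "both")
  expect_equal(nrow(both), 2)
  expect_setequal(both$strand, c("+", "-"))
  expect_equal(both$position[both$strand == "-"], -9L)   # TATCC = revcomp(GGATA)
  # deterministic order: position then name
  expect_false(is.unsorted(both$position))
})

test_that("IUPAC ambiguity codes in the consensus are honored", {
  p <- promoter_sequence("p", paste0(strrep("C", 20), "TATAAA", strrep("C", 20),
                                     "TATAAT", strrep("C", 10)))
  hits <- scan_motifs(p, data.frame(name = "TATA", consensus = "TATAAW"))
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$match, c("TATAAA", "TATAAT"))
  expect_error(scan_motifs(p, data.frame(name = "x", consensus = "GG")), "at least 3")
  expect_equal(nrow(scan_motifs(p, builtin_motifs()[0, ])), 0)   # empty table
})

test_that("truncation preserves hit positions; deletions remove only intersecting hits", {
  pr <- make_promoter(length = 3000,
                      planted = list(list(motif = "GGATA", position = -862),
                                     list(motif = "GGATA", position = -950),
                                     list(motif = "GGATA", position = -2500)),
                      seed = 23)
  myb <- data.frame(name = "MybSt1", consensus = "GGATA")
  full <- scan_motifs(pr$promoter, myb)
  expect_equal(full$position, c(-2500L, -950L, -862L))
  t1 <- truncate_promoter(pr$promoter, 1000)
  expect_equal(scan_motifs(t1, myb)$position,
               full$position[full$position >= -1000])
  # deletion upstream of both proximal hits shifts neither
  dup <- delete_span(pr$promoter, 2000, 2004)
  expect_equal(scan_motifs(dup, myb)$position[2:3], c(-950L, -862L))
  # a deletion clipping a hit's span removes it
  dhit <- delete_span(pr$promoter, 860, 861)
  expect_equal(nrow(scan_motifs(dhit, myb)), 2)
})
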