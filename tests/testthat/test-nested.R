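# Mature mapping, star inference, nestedness and the sibling naming scheme.

test_that("map_mature finds the leftmost exact match and reports multiplicity", {
  set.seed(8)
  mature <- "UUUGGAUUGAAGGGAGCUCUA"
  pre <- paste0(rand_rna(17), mature, rand_rna(30))
  expect_equal(unclass(map_mature(pre, mature))[1:2], c(17L, 38L))
  expect_error(map_mature(rand_rna(50), mature), "does not occur")
  dup <- paste0(rand_rna(10), mature, rand_rna(5), mature, rand_rna(5))
  expect_warning(span <- map_mature(dup, mature), "2 times")
  expect_equal(span[1], 10L)
  expect_equal(attr(span, "matches"), c(10L, 36L))
  # DNA-style input is normalized before matching
  expect_equal(map_mature(chartr("U", "T", pre), chartr("U", "T", mature))[1], 17L)
})

test_that("infer_star places the star on the opposite arm with the 3' overhang shift", {
  # perfect 52-nt hairpin: 21-nt arms fully paired, 10-nt loop
  hp <- perfect_hairpin(21, loop_len = 10, seed = 4)
  ss <- ingest_dotbracket(hp$sequence, hp$dotbracket)

  d0 <- infer_star(ss, c(0L, 21L), overhang = 0)
  expect_equal(d0$star_span, c(31L, 52L))          # exact partner span
  expect_equal(d0$mature_arm, "5arm")
  expect_equal(d0$paired_fraction, 1)
  expect_equal(d0$mismatches, 0L)

  d2 <- infer_star(ss, c(0L, 21L), overhang = 2)
  expect_equal(d2$star_span, c(33L, 52L))          # shifted, clipped at the 3' end

  # mature on the 3' arm: arms swap and the star shifts toward the loop
  d3 <- infer_star(ss, c(31L, 52L), overhang = 0)
  expect_equal(d3$mature_arm, "3arm")
  expect_equal(d3$star_arm, "5arm")
  expect_equal(d3$star_span, c(0L, 21L))

  # mature centered on the terminal loop is rejected
  expect_error(infer_star(ss, c(16L, 37L), overhang = 0), "not on a stem")
})

test_that("detect_nested: containment, single duplex, and overlap rejection", {
  hp <- make_hairpin(hairpin_spec(seed = 21))
  inv <- recover_inventory(hp)
  expect_true(inv$is_nested)
  expect_length(inv$duplexes, 2)
  expect_length(inv$loop_distal_rnas, 1)

  single <- make_hairpin(hairpin_spec(duplexes = list(list(offset = 5, length = 21, mismatches = 0)),
                                      loop_distal = NULL, seed = 22))
  inv1 <- recover_inventory(single)
  expect_false(inv1$is_nested)
  expect_length(inv1$duplexes, 1)

  # overlapping mature spans: the pair is rejected, recorded, not fatal
  ss <- hp$structure
  d1 <- infer_star(ss, c(5L, 26L), precursor_id = hp$precursor$id)
  d2 <- infer_star(ss, c(8L, 29L), precursor_id = hp$precursor$id)  # overlaps d1
  inv2 <- detect_nested(hp$precursor$id, ss, list(d1, d2))
  expect_false(inv2$is_nested)
  expect_gt(nrow(inv2$rejections), 0)
})

test_that("mirrored duplex detections (mature given for both arms) collapse to one", {
  hp <- make_hairpin(hairpin_spec(seed = 30))
  ss <- hp$structure
  d_fwd <- infer_star(ss, c(5L, 26L), precursor_id = hp$precursor$id)
  d_rev <- infer_star(ss, d_fwd$star_span, precursor_id = hp$precursor$id)
  inv <- detect_nested(hp$precursor$id, ss, list(d_fwd, d_rev))
  expect_length(inv$duplexes, 1)
  expect_equal(inv$duplexes[[1]]$mature_arm, "5arm")
})

test_that("sibling naming follows the basal-to-distal scheme", {
  # two duplexes + loop-distal RNA: names in 5'->3' order .1-5, .2-5, .3, .2-3, .1-3
  hp <- make_hairpin(hairpin_spec(seed = 1, id = "ath-MIR159a"))
  inv <- recover_inventory(hp)
  expect_equal(inv$names$name,
               paste0("ath-miR159a.", c("1-5", "2-5", "3", "2-3", "1-3")))
  expect_equal(inv$names$name, hp$truth$names$name)
  expect_equal(inv$names$start, hp$truth$names$start)
  expect_equal(inv$names$end, hp$truth$names$end)

  # degenerate case: single duplex
  single <- make_hairpin(hairpin_spec(duplexes = list(list(offset = 5, length = 21, mismatches = 0)),
                                      loop_distal = NULL, seed = 2, id = "osa-MIR159a"))
  inv1 <- recover_inventory(single)
  expect_equal(inv1$names$name, paste0("osa-miR159a.", c("1-5", "1-3")))

  # triple nest: .1-5, .2-5, .3-5, .3-3, .2-3, .1-3
  triple <- make_hairpin(hairpin_spec(
    arm_length = 90, loop_length = 12,
    duplexes = list(list(offset = 2, length = 21, mismatches = 0),
                    list(offset = 27, length = 21, mismatches = 0),
                    list(offset = 52, length = 21, mismatches = 0)),
    loop_distal = NULL, seed = 3, id = "gma-MIR159a"))
  inv3 <- recover_inventory(triple)
  expect_true(inv3$is_nested)
  expect_equal(inv3$names$name,
               paste0("gma-miR159a.", c("1-5", "2-5", "3-5", "3-3", "2-3", "1-3")))
})

test_that("naming is a bijection ordered 5'-arm ascending then 3'-arm descending", {
  for (seed in c(11, 12, 13)) {
    inv <- recover_inventory(make_hairpin(hairpin_spec(seed = seed)))
    nm <- inv$names
    expect_false(any(duplicated(nm$name)))
    expect_false(any(duplicated(paste(nm$start, nm$end))))
    idx <- as.integer(sub(".*\\.(\\d+).*", "\\1", nm$name))
    five <- grepl("-5$", nm$name)
    three <- grepl("-3$", nm$name)
    expect_false(is.unsorted(idx[five], strictly = TRUE))
    expect_false(is.unsorted(rev(idx[three]), strictly = TRUE))
    expect_true(all(which(five) < which(three)[1]))
  }
})

test_that("summarize_inventories counts are permutation-invariant", {
  hps <- study_hairpins()
  invs <- lapply(hps, recover_inventory)
  s <- summarize_inventories(invs)
  expect_equal(s$nested_count, 5L)
  expect_equal(s$total, 6L)
  expect_equal(s$n_species, 6L)
  set.seed(2)
  s2 <- summarize_inventories(invs[sample(6)])
  expect_equal(s2$per_precursor, s$per_precursor)
  expect_equal(s2$mature_lengths, s$mature_lengths)
  # all-singleton set
  singles <- lapply(1:3, function(i) {
    recover_inventory(make_hairpin(hairpin_spec(
      duplexes = list(list(offset = 5, length = 21, mismatches = 0)),
      loop_distal = NULL, seed = 40 + i, id = sprintf("s%s%s-MIR160", letters[i], letters[i]))))
  })
  expect_equal(summarize_inventories(singles)$nested_count, 0L)
})
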