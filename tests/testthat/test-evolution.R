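# Conservation profiles, distances and neighbor joining.

test_that("conservation_profile computes modal identity and gap fraction per column", {
  a <- aligned_set(c(r1 = "AAGA", r2 = "AAG-", r3 = "AAC-", r4 = "ACAA"))
  prof <- conservation_profile(a)
  expect_equal(prof$identity[1], 1.0)          # AAAA
  expect_equal(prof$identity[2], 0.75)         # AAAC
  expect_equal(prof$gap_fraction[4], 0.5)      # A--A
  expect_equal(prof$identity[4], 1.0)          # modal over non-gap only
  # identical rows
  b <- aligned_set(c(x = "ACGU", y = "ACGU", z = "ACGU"))
  expect_true(all(conservation_profile(b)$identity == 1))
  # all-gap column convention
  g <- aligned_set(c(x = "A-G", y = "A-G"))
  pg <- conservation_profile(g)
  expect_equal(pg$identity[2], 0)
  expect_equal(pg$gap_fraction[2], 1)
  # row-permutation invariance
  p2 <- conservation_profile(aligned_set(a$sequences[c(3, 1, 4, 2)]))
  expect_equal(p2, prof)
})

test_that("region_conservation flags conserved and specific members", {
  rows <- setNames(rep(paste(rep("ACGU", 5), collapse = ""), 10),
                   paste0("m", sprintf("%02d", 1:10)))
  rows[10] <- paste(rep("UGCA", 5), collapse = "")      # fully divergent member
  a <- aligned_set(rows)
  rc <- region_conservation(a, c(1, 20))
  expect_equal(rc$fraction_conserved, 0.9)
  expect_equal(rc$fraction_specific, 0.1)
  expect_equal(rc$thresholds$conserved, 0.75)
  # all-identical region is 100% conserved at any threshold <= 1
  rc2 <- region_conservation(aligned_set(rows[1:5]), c(1, 20), conserved_threshold = 1)
  expect_equal(rc2$fraction_conserved, 1)
  expect_error(region_conservation(a, c(10, 5)), "region")
  expect_error(region_conservation(a, c(0, 5)), "region")
})

test_that("pdistance: p and JC69, saturation ceiling, disjoint-pair error", {
  a <- aligned_set(c(x = "AAAAAAAAAA", y = "AAAAAAAAAA"))
  expect_equal(pdistance(a)["x", "y"], 0)
  # p = 0.1 -> JC69 = -(3/4) log(1 - 4*0.1/3)
  b <- aligned_set(c(x = paste(rep("A", 10), collapse = ""),
                     y = paste(c(rep("A", 9), "C"), collapse = "")))
  expect_equal(pdistance(b)["x", "y"], 0.1)
  expect_equal(pdistance(b, "JC69")["x", "y"], 0.1073256, tolerance = 1e-6)
  expect_equal(jc69(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_error(jc69(0.75), "0.75")
  # saturated pair hits the ceiling with a warning
  s <- aligned_set(c(x = "AAAA", y = "CCCC"))
  expect_warning(ds <- pdistance(s, "JC69", ceiling = 5), "saturated")
  expect_equal(ds["x", "y"], 5)
  # no comparable columns
  z <- aligned_set(c(x = "AA--", y = "--AA"))
  expect_error(pdistance(z), "no comparable columns")
})

test_that("JC69 is zero at p = 0 and strictly increasing on [0, 0.75)", {
  p <- seq(0, 0.74, by = 0.01)
  d <- jc69(p)
  expect_equal(d[1], 0)
  expect_true(all(diff(d) > 0))
  expect_true(all(d[-1] > p[-1]))   # correction always expands
})

test_that("neighbor joining: degenerate cases and closed forms", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(unname(t2$edge.length), c(0.1, 0.1))

  d3 <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["A"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(bl[["B"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(bl[["C"]], (0.4 + 0.5 - 0.3) / 2)

  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("NJ recovers random additive trees exactly (topology and path lengths)", {
  set.seed(101)
  for (i in 1:20) {
    tr <- rand_tree(sample(5:8, 1))
    d <- cophenetic(tr)
    nj <- neighbor_joining(d)
    expect_equal(rf_dist(tr, nj), 0)
    expect_lt(max(abs(cophenetic(nj)[rownames(d), colnames(d)] - d)), 1e-9)
  }
})

test_that("NJ agrees with the reference implementation on additive matrices", {
  set.seed(55)
  for (i in 1:10) {
    tr <- rand_tree(7)
    d <- cophenetic(tr)
    mine <- neighbor_joining(d)
    ref <- ape::nj(d)
    expect_equal(rf_dist(mine, ref), 0)
  }
})

test_that("negative NJ branch estimates are clamped and recorded", {
  # a strongly non-additive matrix known to produce negative estimates
  ids <- c("A", "B", "C", "D")
  d <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 0.1,
                1, 1, 0.1, 0), 4, dimnames = list(ids, ids))
  tree <- neighbor_joining(d)
  expect_true(all(tree$edge.length >= 0))
})

test_that("two_group_split detects separating edges", {
  qt <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(two_group_split(qt, c(A = "monocot", B = "monocot",
                                    C = "dicot", D = "dicot")))
  expect_false(two_group_split(qt, c(A = "monocot", C = "monocot",
                                     B = "dicot", D = "dicot")))
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_true(two_group_split(two, c(A = "monocot", B = "dicot")))
  # caterpillar with groups on opposite ends
  cat6 <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,(E:1,F:1):1):1);")
  expect_true(two_group_split(cat6, c(A = "m", B = "m", C = "m",
                                      D = "d", E = "d", F = "d")))
  expect_error(two_group_split(qt, c(A = "m", B = "m", C = "d")), "unlabeled")
})

test_that("distance matrices serialize to PHYLIP square format", {
  a <- aligned_set(c(x = "AAAA", y = "AACA", z = "ACCA"))
  d <- pdistance(a)
  path <- tempfile(fileext = ".phy")
  write_phylip(d, path)
  lines <- readLines(path)
  expect_equal(as.integer(trimws(lines[1])), 3L)
  expect_length(lines, 4)
})
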