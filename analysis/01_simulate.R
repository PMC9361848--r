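#!/usr/bin/env Rscript
# Build the synthetic study inputs with known ground truth:
#   - six fold-back precursors (five nested with the two-duplex + loop-distal
#     architecture, one single-duplex control), as hairpin/mature FASTA plus
#     dot-bracket structures;
#   - a 12-species panel evolved from nested precursor #1 under region-specific
#     constraint (duplexes most conserved, flanks least);
#   - a 3-kb promoter with two MybSt1 (GGATA) boxes planted at -862 and -950;
#   - Ct tables emulating the wild-type / empty-vector / overexpression
#     comparison (planted folds 1, 6 and 2).
suppressMessages(library(nestedmir))

out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

hairpins <- lapply(1:6, function(i) {
  id <- sprintf("s%s%s-MIR159a", letters[i], letters[i])
  sp <- if (i < 6) {
    hairpin_spec(seed = i, id = id)
  } else {
    hairpin_spec(duplexes = list(list(offset = 5, length = 21, mismatches = 0)),
                 loop_distal = NULL, seed = i, id = id)
  }
  make_hairpin(sp)
})
files <- write_hairpin_fixture(hairpins, out)
cat("wrote", length(hairpins), "precursors:", files[["hairpin"]], "\n")

panel <- make_panel(hairpins[[1]],
                    panel_spec(n_species = 12, duplex_rate = 0.02,
                               loop_rate = 0.10, flank_rate = 0.20, seed = 10))
write_fasta(panel$precursors$id, panel$precursors$sequence,
            file.path(out, "panel_alignment.fa"))
writeLines(panel$regions, file.path(out, "panel_regions.txt"))
cat("wrote 12-species panel (duplex/loop/flank rates 0.02/0.10/0.20)\n")

prom <- make_promoter(length = 3000, seed = 11)
writeLines(c(">pMIR159a synthetic 3.0 kb promoter, MybSt1 GGATA at -862 and -950",
             prom$promoter$sequence), file.path(out, "promoter.fa"))
cat("wrote promoter with", nrow(prom$truth), "planted MybSt1 boxes\n")

ct <- make_ct(c("Col-0" = 1, "empty-vector" = 6, "OE-miR159a" = 2),
              n_replicates = 3, sigma = 0.15, seed = 12,
              target = "miR159a.2-5", reference = "U6")
write.csv(ct, file.path(out, "ct_table.csv"), row.names = FALSE)
cat("wrote Ct table (planted folds: Col-0 1, empty-vector 6, OE-miR159a 2)\n")
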