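#!/usr/bin/env Rscript
# Detect nested structures on the simulated precursors and do the genomic
# bookkeeping of the real ath-MIR159a locus. Requires analysis/01_simulate.R.
suppressMessages(library(nestedmir))

inp <- "results/inputs"
out <- "results/nested"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

res <- run_pipeline(pipeline_config(
  hairpin = file.path(inp, "hairpin.fa"),
  mature = file.path(inp, "mature.fa"),
  dotbracket = file.path(inp, "structures.db"),
  out_dir = out))

s <- res$summary
cat(sprintf("nested census: %d of %d precursors nested across %d species\n",
            s$nested_count, s$total, s$n_species))
nm <- res$inventories[[1]]$names
cat("sibling names on", res$inventories[[1]]$precursor_id, ":",
    paste(nm$name, collapse = ", "), "\n")

# the published ath-MIR159a locus, printed in reverse order (minus strand)
loc <- genomic_locus("chr1", 27713700, 27712893)
nested_loc <- genomic_locus("chr1", 27713416, 27713234)
loci <- data.frame(
  feature = c("pre-MIR159a locus", "nested structure"),
  chromosome = "chr1",
  start = c(loc$start, nested_loc$start),
  end = c(loc$end, nested_loc$end),
  strand = c(loc$strand, nested_loc$strand),
  length_bp = c(inclusive_length(loc), inclusive_length(nested_loc)))
write.table(loci, file.path(out, "mir159a_loci.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("ath-MIR159a locus: %d bp (%s strand); nested structure: %d bp\n",
            loci$length_bp[1], loci$strand[1], loci$length_bp[2]))
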