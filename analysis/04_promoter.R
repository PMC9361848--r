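#!/usr/bin/env Rscript
# Promoter dissection: the truncation series, the MybSt1 deletion constructs,
# and cis-element scans with TSS-relative bookkeeping.
# Requires analysis/01_simulate.R.
suppressMessages(library(nestedmir))

inp <- "results/inputs"
out <- "results/promoter"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seq <- read.delim(file.path(inp, "promoter.fa"), header = FALSE)$V1[2]
p <- promoter_sequence("pMIR159a", seq)

# truncation series covering both printed variants (0.6/0.7 kb) plus the
# 173-bp minimal fragment
series <- c(3000, 2500, 2100, 1500, 1000, 700, 600, 200, 173)
constructs <- lapply(series, function(L) {
  truncate_promoter(p, L, name = if (L >= 1000) sprintf("%.1fkb", L / 1000)
                          else sprintf("%dbp", L))
})
names(constructs) <- vapply(constructs, function(x) x$name, "")

# MybSt1 deletion constructs on the 1.5-kb fragment (the motif is 5 bp, so
# each deletion removes exactly one GGATA box)
p15 <- truncate_promoter(p, 1500, name = "1.5kb")
del <- list(delete_span(p15, 858, 862),
            delete_span(p15, 946, 950),
            delete_span(delete_span(p15, 858, 862), 946, 950,
                        name = "delta858/delta946"))
constructs <- c(constructs, setNames(del, vapply(del, function(x) x$name, "")))
write_constructs(constructs, file.path(out, "constructs.fa"))

myb <- builtin_motifs()
tab <- do.call(rbind, lapply(constructs, function(x) {
  h <- scan_motifs(x, myb)
  data.frame(construct = x$name, length_bp = nchar(x$sequence),
             mybst1_hits = sum(h$motif_name == "MybSt1"),
             positions = paste(h$position[h$motif_name == "MybSt1"],
                               collapse = ","))
}))
rownames(tab) <- NULL
write.table(tab, file.path(out, "mybst1_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab)
cat("MybSt1 boxes: 2 on fragments >= 1.0 kb, removed one-by-one by the deletions\n")
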