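#!/usr/bin/env Rscript
# Relative expression from the simulated Ct table: 2^-deltaCt per replicate,
# fold changes against the wild type (set to 1), SEM, and group tests.
# Requires analysis/01_simulate.R.
suppressMessages(library(nestedmir))

inp <- "results/inputs"
out <- "results/qpcr"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ct <- read_ct_table(file.path(inp, "ct_table.csv"))
summary <- summarize_replicates(ct, "Col-0")
write.csv(summary, file.path(out, "relative_expression.csv"), row.names = FALSE)
print(summary)

rq <- replicate_rq(ct)
# pairwise t tests vs the wild type, ANOVA across all groups
groups <- setdiff(unique(rq$sample_group), "Col-0")
tests <- do.call(rbind, lapply(groups, function(g) {
  sub <- rq[rq$sample_group %in% c("Col-0", g), ]
  t <- group_tests(sub$rq, sub$sample_group)
  data.frame(comparison = paste("Col-0 vs", g), method = t$method,
             statistic = t$statistic, p_value = t$p_value, stars = t$stars)
}))
aov_all <- group_tests(rq$rq, rq$sample_group)
tests <- rbind(tests, data.frame(comparison = "all groups", method = aov_all$method,
                                 statistic = aov_all$statistic,
                                 p_value = aov_all$p_value, stars = aov_all$stars))
write.csv(tests, file.path(out, "group_tests.csv"), row.names = FALSE)
print(tests)
cat("planted folds were 1 (Col-0), 6 (empty-vector), 2 (OE-miR159a)\n")
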