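#!/usr/bin/env Rscript
# Stage 4: methylation-dependent interaction screen.
#
# Simulates a two-condition unique-peptide-count table (wild-type vs
# demethylated cells) with one planted methylation-dependent interactor
# over 300 correlated background proteins, then ranks proteins by the
# pseudocounted ratio R = (n_WT + 1)/(n_KO + 1) and applies the display
# (>= 3 peptides) and hit (> 6 peptides and > 2-fold depletion) filters.
# Expectation from the planted truth: the planted interactor ranks first
# with a clear (>= 2-fold) separation from the runner-up.

suppressMessages(library(repeatscreen))
seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 1L
outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

pep <- simulate_peptide_table(seed = seed)
res <- screen(pep$table, "WT", "Dnmt1KO")
write.table(as.data.frame(res), file.path(outdir, "screen_result.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
export_scatter(res, file.path(outdir, "screen_scatter.tsv"))

message("top of the ranking:")
print(head(as.data.frame(res), 5), row.names = FALSE)
td <- top_dependent(res)
message(sprintf("top protein: %s (planted: %s); separation from runner-up: %.2f; clear top: %s",
                td$top, pep$ground_truth, td$separation, td$clear_top))
message("hits passing the >6 peptide / >2-fold filter: ",
        paste(res$protein[res$hit], collapse = ", "))
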