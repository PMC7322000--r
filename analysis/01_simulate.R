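#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# A 500 kb toy genome carrying an IAP-like LTR-structured ERVK subfamily,
# a second LTR family (MERVL-like), a LINE, a SINE, two DNA-transposon
# subfamilies (the transcriptionally dead background) and four imprinting
# control regions. The planted effects -- ChIP enrichment of LTR families
# and ICRs with a 3x 5'-LTR promoter boost, RNA reactivation (+3 log2) of
# the IAP-like subfamily under targeted deGlcNAcylation, and one
# methylation-dependent proteomic interactor -- are serialized as ground
# truth so stages 2-4 can be read as parameter-recovery experiments.

suppressMessages(library(repeatscreen))
seed <- if (length(commandArgs(TRUE)) >= 1) as.integer(commandArgs(TRUE)[1]) else 1L
outdir <- "results/analysis"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
sim <- simulate_genome(cfg)
print(sim)
lens <- unit_lengths(sim$annotation)
message("unit lengths (bp): ",
        paste(names(lens), lens, sep = "=", collapse = ", "))

write_repeat_bed(sim$annotation, file.path(outdir, "repeats.bed"))
write_icr_bed(sim$icrs, file.path(outdir, "icrs.bed"))
write_ground_truth(sim, file.path(outdir, "ground_truth.json"))
write_genome_fasta(sim, file.path(outdir, "genome.fa"))

# one demo input sample in BED form, so downstream formats are exercised
inp <- simulate_chip_sample(sim, NULL, depth = 10000, seed = seed)
write_fragments_bed(inp, file.path(outdir, "input_demo.bed"))

message("wrote genome annotation, ICRs, ground truth and a demo fragment ",
        "set under ", outdir)
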