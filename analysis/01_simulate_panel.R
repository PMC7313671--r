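#!/usr/bin/env Rscript
# Step 01 - build the simulated isofemale-line panel and record its truth.
#
# Generates the element library and the eight line genomes, writes the
# ground-truth insertion table (results/panel_truth.csv) and, as example
# artifacts of the standard formats, one line's truth alignments as SAM
# and a FASTQ sample (under scratch/, not part of the deliverable).

source("analysis/panel.R")

lib <- panel_library()
lines <- panel_lines(lib)

truth <- do.call(rbind, lapply(lines, `[[`, "truth"))
write.csv(truth, "results/panel_truth.csv", row.names = FALSE)

cat("Element:", lib$annotation$name, "-", lib$annotation$length, "bp,",
    length(lib$annotation$exons), "exons, TIR",
    lib$annotation$tir_length, "bp\n")
cat("Panel of", length(lines), "lines;",
    nrow(truth), "insertions in total,",
    sum(truth$structure != "complete"), "internally deleted\n")

# example artifacts for one element-rich line
ex <- lines[[6]]
sim <- simulate_short_reads(ex, coverage = 5, seed = PANEL_SEED)
write_alignments(sim$truth, "scratch/line06_truth.sam", "sam",
                 targets = c(chr1 = 1e5 + 0,
                             PE = lib$annotation$length))
write_fastq(sim$reads, "scratch/line06_reads.fastq", paired = TRUE)
cat("Wrote results/panel_truth.csv and example SAM/FASTQ under scratch/\n")
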