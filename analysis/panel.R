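# Shared simulated line panel used by analysis steps 01-04: a P-element
# library (canonical 2907-bp element, 31-bp TIRs, four exons) and eight
# isofemale-line genomes of 100 kb spanning the observed range of element
# load: an M line, P lines of 2-20 homozygous copies, lines rich in
# internally deleted {0,3} copies, and one line segregating at zygosity 0.5.
# Sourced, not run, by the numbered scripts.

library(dysgene)

PANEL_SEED <- 20200427L

panel_library <- function() make_te_library(seed = PANEL_SEED)

PANEL_DESIGN <- data.frame(
  line_id = sprintf("line%02d", 1:8),
  n_full = c(0, 2, 5, 8, 12, 3, 6, 20),
  n_truncated = c(0, 0, 0, 4, 0, 9, 0, 0),
  zygosity = c(1, 1, 1, 1, 1, 1, 0.5, 1),
  stringsAsFactors = FALSE)

panel_lines <- function(lib = panel_library()) {
  lapply(seq_len(nrow(PANEL_DESIGN)), function(i) {
    d <- PANEL_DESIGN[i, ]
    base <- random_genome(1e5, seed = PANEL_SEED + i)
    make_line_genome(base, lib, n_full = d$n_full,
                     n_truncated = d$n_truncated, zygosity = d$zygosity,
                     line_id = d$line_id, min_gap = 3000,
                     seed = PANEL_SEED + 100 + i)
  })
}

panel_short_reads <- function(lines, coverage = 30)
  lapply(seq_along(lines), function(i)
    simulate_short_reads(lines[[i]], coverage = coverage,
                         sequences = FALSE,
                         seed = PANEL_SEED + 200 + i))

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
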