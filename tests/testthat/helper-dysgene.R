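# Shared fixtures, built in code: a small element library and a one-row
# alignment-record constructor with sensible defaults.

small_lib <- function(seed = 101)
  make_te_library(te_length = 600, tir_length = 31, seed = seed)

full_lib <- function(seed = 101) make_te_library(seed = seed)

# One alignment record; clip fields derived from read coordinates.
rec <- function(read_id = "r1", mate = 1L, target_id = "chr1",
                target_start = 0L, target_end = 100L, read_start = 0L,
                read_end = read_start + (target_end - target_start),
                read_length = 150L, strand = "+", mapq = 60L,
                secondary = FALSE, supplementary = FALSE) {
  data.frame(read_id = read_id, mate = as.integer(mate),
             target_id = target_id,
             target_start = as.integer(target_start),
             target_end = as.integer(target_end),
             read_start = as.integer(read_start),
             read_end = as.integer(read_end),
             read_length = as.integer(read_length),
             strand = strand, mapq = as.integer(mapq),
             clip_head = as.integer(read_start),
             clip_tail = as.integer(read_length - read_end),
             secondary = secondary, supplementary = supplementary,
             stringsAsFactors = FALSE)
}

# A split read supporting an element insertion: genome block ending at
# `breakpoint` with its tail clipped into a terminal element block.
junction_read <- function(read_id, breakpoint, te_len = 600L,
                          rl = 150L, g_span = 100L) {
  rbind(
    rec(read_id, 1L, "chr1", breakpoint - g_span, breakpoint,
        read_start = 0L, read_length = rl),
    rec(read_id, 1L, "PE", 0L, rl - g_span,
        read_start = g_span, read_length = rl))
}
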