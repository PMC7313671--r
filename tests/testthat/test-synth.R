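test_that("element library has inverted terminal repeats and exact variant arithmetic", {
  lib <- make_te_library(te_length = 662, tir_length = 31, seed = 5)
  cons <- lib$consensus
  expect_equal(nchar(cons), 662)
  tir <- substr(cons, 1, 31)
  tail31 <- substr(cons, 632, 662)
  oracle <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tir)))
  expect_equal(tail31, oracle)
  # 4 equal exons tile the 600-bp internal region; variant {0,3} keeps half
  v <- lib$variants[["trunc_0_3"]]
  expect_equal(nchar(v$seq), 2 * 31 + 600 / 2)
  lib2 <- make_te_library(te_length = 662, tir_length = 31, seed = 5)
  expect_identical(lib2$consensus, cons)
  expect_error(make_te_library(te_length = 50, tir_length = 31), "tir")
  expect_error(make_te_library(exons = list(c(40, 35))), "sorted")
})

test_that("line genomes record insertions with exact length bookkeeping", {
  lib <- small_lib()
  base <- random_genome(20000, seed = 6)
  ln0 <- make_line_genome(base, lib, n_full = 0, seed = 7)
  expect_identical(ln0$haplotypes[[1]]$seq, base)
  expect_equal(nrow(ln0$truth), 0)
  ln2 <- make_line_genome(base, lib, n_full = 2, seed = 7)
  expect_equal(nchar(ln2$haplotypes[[1]]$seq), 20000 + 2 * (600 + 8))
  expect_equal(nrow(ln2$truth), 2)
  expect_true(all(ln2$truth$structure == "complete"))
  expect_error(make_line_genome(base, lib, n_full = 30), "load")
})

test_that("read counts, determinism and error-free substrings hold", {
  lib <- small_lib()
  base <- random_genome(20000, seed = 8)
  ln <- make_line_genome(base, lib, n_full = 0, seed = 9)
  sim <- simulate_short_reads(ln, coverage = 10, read_length = 100,
                              insert_mean = 300, error_rate = 0,
                              seed = 10)
  expect_equal(length(unique(sim$reads$read_id)),
               round(10 * 20000 / (2 * 100)))
  expect_error(simulate_short_reads(ln, coverage = 0), "coverage")
  expect_error(simulate_short_reads(ln, read_length = 400,
                                    insert_mean = 300), "insert_mean")
  # error-free reads are exact (possibly reverse-complemented) substrings
  tr <- sim$truth
  full <- tr[tr$read_start == 0 & tr$read_end == tr$read_length, ]
  pick <- full[sample(nrow(full), 20), ]
  for (i in seq_len(nrow(pick))) {
    r <- pick[i, ]
    sub <- substring(base, r$target_start + 1, r$target_end)
    if (r$strand == "-")
      sub <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    got <- sim$reads$seq[sim$reads$read_id == r$read_id &
                           sim$reads$mate == r$mate]
    expect_identical(got, sub)
  }
  sim2 <- simulate_short_reads(ln, coverage = 10, read_length = 100,
                               insert_mean = 300, error_rate = 0,
                               seed = 10)
  expect_identical(sim2$reads, sim$reads)
  expect_identical(sim2$truth, sim$truth)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads[1:50, ], f1)
  write_fastq(sim2$reads[1:50, ], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)), 200)
})

test_that("junction reads split exactly as a mapper would", {
  lib <- small_lib()
  base <- random_genome(20000, seed = 11)
  ln <- make_line_genome(base, lib, n_full = 1, seed = 12)
  p <- ln$truth$position  # TSD midpoint
  sim <- simulate_short_reads(ln, coverage = 30, read_length = 100,
                              insert_mean = 300, sequences = FALSE,
                              seed = 13)
  tr <- sim$truth
  key <- paste(tr$read_id, tr$mate)
  split_keys <- unique(key[duplicated(key)])
  expect_gt(length(split_keys), 5)
  for (k in split_keys[1:5]) {
    blocks <- tr[key == k, ]
    expect_setequal(blocks$target_id, c("chr1", "PE"))
    # read intervals of the blocks are disjoint and within the read
    ord <- order(blocks$read_start)
    expect_true(all(diff(blocks$read_start[ord]) > 0))
    expect_true(all(blocks$read_end <= blocks$read_length))
    # clip fields mirror read coordinates
    expect_equal(blocks$clip_head, blocks$read_start)
    expect_equal(blocks$clip_tail, blocks$read_length - blocks$read_end)
  }
  # genome-side junction breakpoints flank the recorded midpoint by tsd/2
  g <- tr[tr$target_id == "chr1" & (tr$clip_head >= 20 | tr$clip_tail >= 20), ]
  g <- g[paste(g$read_id, g$mate) %in% split_keys, ]
  clip_right <- (g$clip_tail >= g$clip_head) == (g$strand == "+")
  bp <- ifelse(clip_right, g$target_end, g$target_start)
  expect_true(all(abs(bp - p) == 4))
})

test_that("truth-alignment depth matches requested coverage", {
  lib <- small_lib()
  base <- random_genome(50000, seed = 14)
  ln <- make_line_genome(base, lib, n_full = 0, seed = 15)
  sim <- simulate_short_reads(ln, coverage = 20, sequences = FALSE,
                              seed = 16)
  d <- mean_depth(sim$truth, 50000, target_id = "chr1")
  expect_lt(abs(d - 20) / 20, 0.05)
})

test_that("long reads over truncated copies expose the retained exons", {
  lib <- full_lib()
  base <- random_genome(60000, seed = 17)
  ln <- make_line_genome(base, lib, n_full = 1, n_truncated = 1, seed = 18)
  sim <- simulate_long_reads(ln, coverage = 10, length_mean = 12000,
                             sequences = FALSE, seed = 19)
  tr <- sim$truth
  te <- tr[tr$target_id == "PE", ]
  # element blocks of any one read stay within the consensus and, for the
  # truncated copy, only inside TIR/exon-0/exon-3 intervals
  expect_true(all(te$target_end <= 2907))
  keep <- lib$variants[[1]]$pieces
  trunc_pos <- ln$truth$position[ln$truth$structure != "complete"]
  for (rid in unique(te$read_id)[1:10]) {
    blocks <- te[te$read_id == rid, ]
    in_pieces <- vapply(seq_len(nrow(blocks)), function(i)
      any(blocks$target_start[i] >= keep$cons_start - 1 &
            blocks$target_end[i] <= keep$cons_end + 1), TRUE)
    full_cover <- any(blocks$target_end - blocks$target_start > 2000)
    expect_true(all(in_pieces) || full_cover)
  }
})

test_that("phenotype simulation honours its generative model", {
  design <- data.frame(mother_genotype = "M", father_line = "f1",
                       father_pe_cn = 10, father_hobo_cn = 5,
                       temperature = 29, n_females = 3000)
  flat <- list(ovary0 = c("(Intercept)" = 0),
               ovary1 = c("(Intercept)" = 0),
               ovarioles = c("(Intercept)" = log(20)))
  ph <- simulate_phenotypes(design, flat, seed = 20)
  tab <- table(ph$ovary_count) / nrow(ph)
  expect_true(all(abs(tab - 1 / 3) < 0.04))
  expect_lt(abs(mean(ph$mean_ovarioles, na.rm = TRUE) - 20), 0.5)
  # structural invariants
  n_filled <- (!is.na(ph$ovarioles_left)) + (!is.na(ph$ovarioles_right))
  expect_equal(n_filled, ph$ovary_count)
  expect_identical(is.na(ph$mean_ovarioles), ph$ovary_count == 0L)
  bad <- flat
  bad$ovary0 <- c("(Intercept)" = 0, "motherM:banana" = 1)
  expect_error(simulate_phenotypes(design, bad, seed = 1), "unknown term")
  ph2 <- simulate_phenotypes(design, flat, seed = 20)
  expect_identical(ph2, ph)
})

test_that("dysgenesis probability rises with copy number only for M mothers at 29 degrees", {
  design <- expand.grid(mother_genotype = c("M", "P"),
                        father_pe_cn = c(5, 10, 20),
                        temperature = c(23, 29), stringsAsFactors = FALSE)
  design$father_line <- paste0("f", design$father_pe_cn)
  design$father_hobo_cn <- 10
  design$n_females <- 400
  ph <- simulate_phenotypes(design, seed = 21)
  dys <- with(ph, tapply(ovary_count <= 1,
                         list(mother_genotype, father_pe_cn, temperature),
                         mean))
  m29 <- dys["M", , "29"]
  expect_true(all(diff(m29) > 0))          # monotone in copy number
  expect_true(all(dys["P", , ] < 0.05))    # P mothers unaffected
  expect_true(all(dys[, , "23"] < 0.05))   # no dysgenesis at 23 degrees
})
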