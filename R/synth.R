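# Synthetic-data module: element libraries, line genomes with known
# insertions, short/long reads with truth alignments (standing in for a
# mapper), and diallel-cross phenotype tables.

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Random genome sequence
#'
#' @param length Genome length in bp.
#' @param gc GC content.
#' @param seed Optional RNG seed.
#' @return A character scalar of A/C/G/T.
#' @export
random_genome <- function(length, gc = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Build a transposable-element library
#'
#' Generates a random element consensus whose last `tir_length` bases are
#' the reverse complement of the first (terminal inverted repeats), an
#' annotation with ordered exon intervals, and internally deleted variants
#' that concatenate a subset of exons flanked by both TIRs.
#'
#' @param te_length Element length in bp (default 2907, the canonical
#'   P-element length).
#' @param tir_length Terminal-inverted-repeat length in bp (default 31).
#' @param exons Optional list of 0-based half-open exon intervals
#'   (`c(start, end)`). By default four equal exons tile the internal
#'   region between the TIRs.
#' @param truncated_structures List of integer vectors of retained exon
#'   indices (0-based) for which deletion variants are built.
#' @param name Element name.
#' @param seed Optional RNG seed.
#' @return A list with `annotation` (name, length, exons, tir_length),
#'   `consensus` (character), and `variants`: per structure a list with the
#'   variant `seq` and `pieces`, a data.frame mapping each retained piece to
#'   its consensus interval.
#' @export
make_te_library <- function(te_length = 2907, tir_length = 31, exons = NULL,
                            truncated_structures = list(c(0L, 3L)),
                            name = "PE", seed = NULL) {
  if (2 * tir_length > te_length)
    stop("tir_length * 2 exceeds te_length")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(exons)) {
    inner <- te_length - 2 * tir_length
    cuts <- tir_length + round(inner * 0:4 / 4)
    exons <- lapply(1:4, function(i) c(cuts[i], cuts[i + 1]))
  }
  starts <- vapply(exons, `[`, 0, 1)
  ends <- vapply(exons, `[`, 0, 2)
  if (any(starts >= ends) || any(starts < 0) || any(ends > te_length) ||
      is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1] < ends[-length(ends)]))
    stop("exons must be sorted, disjoint and within [0, te_length)")
  body <- random_genome(te_length - tir_length, gc = 0.5)
  tir <- substr(body, 1, tir_length)
  consensus <- paste0(body, revcomp(tir))
  annotation <- list(name = name, length = te_length,
                     exons = exons, tir_length = tir_length)
  variants <- lapply(truncated_structures, function(keep) {
    keep <- sort(as.integer(keep))
    if (any(keep < 0 | keep >= length(exons)))
      stop("retained exon index out of range")
    ivs <- rbind(c(0L, tir_length),
                 do.call(rbind, exons[keep + 1]),
                 c(te_length - tir_length, te_length))
    pieces <- data.frame(cons_start = as.integer(ivs[, 1]),
                         cons_end = as.integer(ivs[, 2]))
    seq <- paste(substring(consensus, pieces$cons_start + 1,
                           pieces$cons_end), collapse = "")
    list(structure = keep, pieces = pieces, seq = seq)
  })
  names(variants) <- vapply(truncated_structures, function(k)
    paste0("trunc_", paste(sort(k), collapse = "_")), "")
  list(annotation = annotation, consensus = consensus, variants = variants)
}

# Segment map of a haplotype: one row per contiguous block, with the block's
# half-open interval in haplotype coordinates and the target (reference
# contig or element consensus) interval it corresponds to.
new_segments <- function() {
  data.frame(start = integer(), end = integer(), target = character(),
             target_start = integer(), stringsAsFactors = FALSE)
}

#' Insert element copies into a base genome
#'
#' Places `n_full` complete and `n_truncated` internally deleted element
#' copies at uniformly random, non-overlapping positions, each flanked by a
#' target-site duplication of `tsd_length` bp. Returns the carrier
#' haplotype (and the insertion-free base haplotype when `zygosity < 1`)
#' together with a segment map used to emit truth alignments, and a
#' `SimTruth` table recording every insertion. Truth positions are reported
#' at the midpoint of the target-site duplication, so both junction
#' breakpoints lie within `tsd_length / 2` bp of the recorded position.
#'
#' @param base Base genome sequence (character scalar).
#' @param te_library Library from [make_te_library()].
#' @param n_full,n_truncated Numbers of complete / truncated copies.
#' @param truncated_structure Name or index of the library variant used for
#'   truncated copies (default: first variant).
#' @param zygosity Fraction of pool haplotypes carrying the insertions, in
#'   (0, 1]. Reads are drawn from the carrier haplotype with this
#'   probability weight.
#' @param tsd_length Target-site-duplication length (default 8 bp).
#' @param contig Contig name of the base genome.
#' @param line_id Line identifier recorded in the truth table.
#' @param min_gap Minimum spacing between insertion positions and from the
#'   contig ends; a placement error is raised when the genome cannot hold
#'   the requested copies at this spacing.
#' @param seed Optional RNG seed.
#' @return A list with `haplotypes` (each a list of `seq` and `segments`),
#'   `weights`, `truth` (line_id, contig, position, structure, zygosity),
#'   `line_id`, `contig`, `base_length`.
#' @export
make_line_genome <- function(base, te_library, n_full = 0, n_truncated = 0,
                             truncated_structure = NULL, zygosity = 1,
                             tsd_length = 8, contig = "chr1",
                             line_id = "line1", min_gap = 1000L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(zygosity > 0, zygosity <= 1, n_full >= 0, n_truncated >= 0)
  L <- nchar(base)
  n <- n_full + n_truncated
  te_len <- te_library$annotation$length
  if (n * (te_len + tsd_length) > L)
    stop("insertion load too high for base genome length")
  variant <- NULL
  if (n_truncated > 0) {
    if (is.null(truncated_structure)) truncated_structure <- 1L
    variant <- te_library$variants[[truncated_structure]]
    if (is.null(variant)) stop("unknown truncated_structure")
  }
  positions <- integer(0)
  if (n > 0) {
    # uniform placement with guaranteed pairwise gaps: sample in the
    # interval shrunk by the total gap budget, then re-insert the gaps
    slack <- L - 2L * min_gap - (n - 1L) * min_gap
    if (slack < n)
      stop("insertion load too high: cannot place ", n,
           " insertions at spacing ", min_gap)
    cand <- sort(sample.int(slack, n))
    positions <- cand + min_gap + (seq_len(n) - 1L) * min_gap
  }
  is_full <- rep(c(TRUE, FALSE), c(n_full, n_truncated))
  if (n > 0) is_full <- sample(is_full)

  te_name <- te_library$annotation$name
  full_pieces <- data.frame(cons_start = 0L, cons_end = te_len)
  seqs <- character(0)
  segs <- new_segments()
  prev <- 0L  # next base of `base` not yet emitted
  add <- function(seq, target, target_start) {
    seqs[[length(seqs) + 1L]] <<- seq
    segs[nrow(segs) + 1L, ] <<- list(NA_integer_, NA_integer_, target,
                                     as.integer(target_start))
  }
  for (i in seq_len(n)) {
    p <- positions[i]
    # genome up to and including the target site duplication [p, p+tsd)
    add(substring(base, prev + 1, p + tsd_length), contig, prev)
    pieces <- if (is_full[i]) full_pieces else variant$pieces
    for (j in seq_len(nrow(pieces)))
      add(substring(te_library$consensus, pieces$cons_start[j] + 1,
                    pieces$cons_end[j]), te_name, pieces$cons_start[j])
    prev <- p  # duplicated site is emitted again with the downstream block
  }
  add(substring(base, prev + 1, L), contig, prev)
  widths <- nchar(seqs)
  segs$start <- as.integer(cumsum(c(0L, widths[-length(widths)])))
  segs$end <- as.integer(segs$start + widths)
  carrier <- list(seq = paste(seqs, collapse = ""), segments = segs)

  haplotypes <- list(carrier = carrier)
  weights <- 1
  if (zygosity < 1) {
    base_segs <- new_segments()
    base_segs[1L, ] <- list(0L, L, contig, 0L)
    haplotypes$base <- list(seq = base, segments = base_segs)
    weights <- c(zygosity, 1 - zygosity)
  }
  truth <- data.frame(
    line_id = rep(line_id, n), contig = rep(contig, n),
    position = positions + tsd_length %/% 2L,
    structure = ifelse(is_full, "complete",
                       if (n_truncated > 0)
                         paste(variant$structure, collapse = ",") else ""),
    zygosity = rep(zygosity, n), stringsAsFactors = FALSE)
  list(haplotypes = haplotypes, weights = weights, truth = truth,
       line_id = line_id, contig = contig, base_length = L)
}

# Map read intervals on a haplotype to truth alignment records via the
# segment map. `s`,`e` are half-open haplotype intervals; minus-strand reads
# are reported with read coordinates on the original read. Aligned blocks
# shorter than min_block are dropped (a mapper would not report them).
map_reads_to_targets <- function(segments, s, e, read_id, mate, strand,
                                 min_block = 12L, mapq = 60L) {
  rl <- e - s
  mate <- rep_len(mate, length(s))
  strand <- rep_len(strand, length(s))
  i1 <- findInterval(s, segments$start)
  i2 <- findInterval(e - 1L, segments$start)
  rows <- vector("list", 8L)
  nr <- 0L
  emit <- function(idx, part_s, part_e, r_id, r_mate, r_strand, r_len, r_s) {
    w <- part_e - part_s
    keep <- w >= min_block
    if (!any(keep)) return()
    fwd_rs <- part_s - r_s
    fwd_re <- part_e - r_s
    read_start <- ifelse(r_strand == "+", fwd_rs, r_len - fwd_re)
    read_end <- ifelse(r_strand == "+", fwd_re, r_len - fwd_rs)
    df <- data.frame(
      read_id = r_id, mate = r_mate,
      target_id = segments$target[idx],
      target_start = as.integer(segments$target_start[idx] +
                                  (part_s - segments$start[idx])),
      target_end = as.integer(segments$target_start[idx] +
                                (part_e - segments$start[idx])),
      read_start = as.integer(read_start),
      read_end = as.integer(read_end),
      read_length = as.integer(r_len),
      strand = r_strand, mapq = mapq,
      clip_head = as.integer(read_start),
      clip_tail = as.integer(r_len - read_end),
      secondary = FALSE, supplementary = FALSE,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    nr <<- nr + 1L
    rows[[nr]] <<- df
  }
  single <- i1 == i2
  if (any(single)) {
    idx <- i1[single]
    emit(idx, s[single], e[single], read_id[single], mate[single],
         strand[single], rl[single], s[single])
  }
  for (k in which(!single)) {
    js <- seq.int(i1[k], i2[k])
    part_s <- pmax(segments$start[js], s[k])
    part_e <- pmin(segments$end[js], e[k])
    emit(js, part_s, part_e, rep(read_id[k], length(js)),
         rep(mate[k], length(js)), rep(strand[k], length(js)),
         rep(rl[k], length(js)), rep(s[k], length(js)))
  }
  if (nr == 0L) return(empty_alignments())
  do.call(rbind, rows[seq_len(nr)])
}

# Uniform substitution errors applied in place to read sequences.
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  seqs
}

#' Simulate paired-end short reads with truth alignments
#'
#' Draws `round(coverage * genome_length / (2 * read_length))` fragment
#' pairs uniformly from the line's haplotypes (weighted by zygosity) and
#' emits, for every read, the alignment records a mapper would produce:
#' reads crossing an element/genome junction are split into one block per
#' underlying segment with clip fields set accordingly. All blocks are
#' primary so that depth computed with default filters is unbiased.
#'
#' @param line A line from [make_line_genome()].
#' @param coverage Target mean coverage (x).
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment-size distribution (bp).
#' @param error_rate Per-base substitution error rate.
#' @param sequences If `FALSE`, skip sequence generation (truth alignments
#'   only; much faster for depth/insertion benchmarks).
#' @param min_block Minimum aligned block length a mapper would report.
#' @param seed Optional RNG seed.
#' @return A list with `reads` (read_id, mate, seq — `NULL` when
#'   `sequences = FALSE`) and `truth` (alignment data.frame).
#' @export
simulate_short_reads <- function(line, coverage = 30, read_length = 150,
                                 insert_mean = 400, insert_sd = 50,
                                 error_rate = 0.001, sequences = TRUE,
                                 min_block = 12L, seed = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  if (read_length >= insert_mean) stop("read_length must be < insert_mean")
  if (!is.null(seed)) set.seed(seed)
  reads_list <- list(); truth_list <- list()
  for (h in seq_along(line$haplotypes)) {
    hap <- line$haplotypes[[h]]
    Lh <- nchar(hap$seq)
    n_pairs <- round(coverage * line$weights[h] * Lh / (2 * read_length))
    if (n_pairs == 0) next
    frag <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                      read_length), Lh)
    fs <- floor(runif(n_pairs, 0, Lh - frag + 1))
    id <- sprintf("%s_h%d_p%06d", line$line_id, h, seq_len(n_pairs))
    s1 <- fs; e1 <- fs + read_length
    s2 <- fs + frag - read_length; e2 <- fs + frag
    truth_list[[length(truth_list) + 1L]] <- rbind(
      map_reads_to_targets(hap$segments, s1, e1, id, 1L,
                           rep("+", n_pairs), min_block),
      map_reads_to_targets(hap$segments, s2, e2, id, 2L,
                           rep("-", n_pairs), min_block))
    if (sequences) {
      seq1 <- substring(hap$seq, s1 + 1, e1)
      seq2 <- vapply(substring(hap$seq, s2 + 1, e2), revcomp, "",
                     USE.NAMES = FALSE)
      reads_list[[length(reads_list) + 1L]] <- data.frame(
        read_id = rep(id, 2), mate = rep(c(1L, 2L), each = n_pairs),
        seq = apply_errors(c(seq1, seq2), error_rate),
        stringsAsFactors = FALSE)
    }
  }
  list(reads = if (sequences) do.call(rbind, reads_list) else NULL,
       truth = do.call(rbind, truth_list))
}

#' Simulate long reads with truth alignments
#'
#' Single-molecule-style reads long enough to span whole element insertions
#' together with genomic anchor sequence on either side. Truth alignments
#' report, for reads covering an insertion, the element-internal segments
#' actually present, so internal deletions are visible downstream.
#'
#' @inheritParams simulate_short_reads
#' @param length_mean,length_sd Read-length distribution (bp).
#' @return A list with `reads` and `truth` as in [simulate_short_reads()].
#' @export
simulate_long_reads <- function(line, coverage = 5, length_mean = 15000,
                                length_sd = 3000, error_rate = 0.02,
                                sequences = TRUE, min_block = 50L,
                                seed = NULL) {
  if (coverage <= 0) stop("coverage must be positive")
  if (!is.null(seed)) set.seed(seed)
  reads_list <- list(); truth_list <- list()
  for (h in seq_along(line$haplotypes)) {
    hap <- line$haplotypes[[h]]
    Lh <- nchar(hap$seq)
    n_reads <- round(coverage * line$weights[h] * Lh / length_mean)
    if (n_reads == 0) next
    len <- pmin(pmax(round(rnorm(n_reads, length_mean, length_sd)), 500L), Lh)
    s <- floor(runif(n_reads, 0, Lh - len + 1))
    e <- s + len
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    id <- sprintf("%s_h%d_L%06d", line$line_id, h, seq_len(n_reads))
    truth_list[[length(truth_list) + 1L]] <-
      map_reads_to_targets(hap$segments, s, e, id, 0L, strand, min_block)
    if (sequences) {
      sq <- substring(hap$seq, s + 1, e)
      rev <- strand == "-"
      sq[rev] <- vapply(sq[rev], revcomp, "", USE.NAMES = FALSE)
      reads_list[[length(reads_list) + 1L]] <- data.frame(
        read_id = id, mate = 0L, seq = apply_errors(sq, error_rate),
        stringsAsFactors = FALSE)
    }
  }
  list(reads = if (sequences) do.call(rbind, reads_list) else NULL,
       truth = do.call(rbind, truth_list))
}

#' Write reads as FASTQ
#'
#' Phred-33 FASTQ with a constant quality character (the simulator models
#' uniform substitution error, not quality).
#'
#' @param reads `reads` data.frame from a simulator.
#' @param path Output path. For paired reads, mate 1 and 2 go to
#'   `sub("\\.fastq$", "_1.fastq", path)` and `_2` respectively when
#'   `paired = TRUE`.
#' @param paired Write mate-split files.
#' @param qual_char Quality character (default "I" = Q40).
#' @return Character vector of written paths, invisibly.
#' @export
write_fastq <- function(reads, path, paired = FALSE, qual_char = "I") {
  fq <- function(df, p) {
    qual <- strrep(qual_char, nchar(df$seq))
    suffix <- ifelse(df$mate > 0L, paste0("/", df$mate), "")
    writeLines(paste0("@", df$read_id, suffix, "\n", df$seq, "\n+\n", qual), p)
    p
  }
  if (paired) {
    p1 <- sub("\\.fastq$", "_1.fastq", path)
    p2 <- sub("\\.fastq$", "_2.fastq", path)
    fq(reads[reads$mate == 1L, ], p1)
    fq(reads[reads$mate == 2L, ], p2)
    invisible(c(p1, p2))
  } else {
    invisible(fq(reads, path))
  }
}

# ---- phenotype simulation ---------------------------------------------

PHENO_BASE_TERMS <- c("(Intercept)", "motherM", "pe_cn", "hobo_cn",
                      "temperature", "age")

# Build a design matrix from coefficient names: base columns and ":"
# products of base columns.
build_term_matrix <- function(df, term_names) {
  base <- cbind("(Intercept)" = rep(1, nrow(df)),
                motherM = as.numeric(df$mother_genotype == "M"),
                pe_cn = df$father_pe_cn,
                hobo_cn = df$father_hobo_cn,
                temperature = df$temperature,
                age = df$age)
  cols <- lapply(term_names, function(tn) {
    parts <- strsplit(tn, ":", fixed = TRUE)[[1]]
    unknown <- setdiff(parts, colnames(base))
    if (length(unknown))
      stop("unknown term in coefficients: ", tn)
    Reduce(`*`, lapply(parts, function(p) base[, p]))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- term_names
  m
}

#' Default phenotype-model coefficient preset
#'
#' Synthetic generative coefficients for [simulate_phenotypes()] chosen to
#' reproduce the qualitative hybrid-dysgenesis pattern: atrophied ovaries
#' and reduced ovariole counts appear only in crosses of M mothers to
#' element-carrying fathers at high temperature, increase monotonically
#' with paternal element copy number, and dysgenic females senesce slightly
#' faster (an extra ovariole-loss rate on the order of 6e-3 per day at
#' 29 degrees for a 10-copy father). The magnitudes are simulation
#' defaults, not estimates from data.
#'
#' @return A list with named coefficient vectors `ovary0`, `ovary1`
#'   (multinomial logits of 0- and 1-ovary counts against the reference of
#'   2 ovaries) and `ovarioles` (log-linear Poisson mean per ovary).
#' @export
hd_preset_coefficients <- function() {
  list(
    ovary0 = c("(Intercept)" = -7,
               "motherM:pe_cn" = -2.3,
               "motherM:pe_cn:temperature" = 0.1),
    ovary1 = c("(Intercept)" = -5.5,
               "motherM:pe_cn" = -1.84,
               "motherM:pe_cn:temperature" = 0.08),
    ovarioles = c("(Intercept)" = log(20),
                  "age" = -0.004,
                  "motherM:pe_cn" = 0.0575,
                  "motherM:pe_cn:temperature" = -0.0025,
                  "motherM:pe_cn:age" = 0.0023,
                  "motherM:pe_cn:age:temperature" = -1e-4))
}

#' Simulate diallel-cross phenotype records
#'
#' Draws per-female ovary counts from a 3-category multinomial logit
#' (reference category: 2 ovaries) and per-ovary ovariole counts from a
#' log-linear Poisson model, under coefficient vectors over the terms
#' intercept, maternal cytotype (`motherM`), paternal element copy numbers
#' (`pe_cn`, `hobo_cn`), `temperature`, `age` and `:`-interactions thereof.
#'
#' @param design A data.frame with one row per cross condition: columns
#'   `mother_genotype` ("M"/"P"), `father_line`, `father_pe_cn`,
#'   `father_hobo_cn`, `temperature`, `n_females`, and optionally `age`
#'   (default 4 days).
#' @param coefficients Coefficient list as in [hd_preset_coefficients()].
#' @param seed Optional RNG seed.
#' @return A phenotype data.frame with one row per female: `female_id`,
#'   the design columns, `ovary_count`, `ovarioles_left`,
#'   `ovarioles_right` (NA for atrophied ovaries) and `mean_ovarioles`
#'   (NA when both ovaries are atrophied).
#' @export
simulate_phenotypes <- function(design, coefficients = hd_preset_coefficients(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("mother_genotype", "father_line", "father_pe_cn",
                  "temperature", "n_females") %in% names(design)))
  if (is.null(design$father_hobo_cn)) design$father_hobo_cn <- 0
  if (is.null(design$age)) design$age <- 4
  stopifnot(all(c("ovary0", "ovary1", "ovarioles") %in% names(coefficients)))
  df <- design[rep(seq_len(nrow(design)), design$n_females), , drop = FALSE]
  df$n_females <- NULL
  rownames(df) <- NULL
  n <- nrow(df)
  df$female_id <- sprintf("F%05d", seq_len(n))
  l0 <- drop(build_term_matrix(df, names(coefficients$ovary0)) %*%
               coefficients$ovary0)
  l1 <- drop(build_term_matrix(df, names(coefficients$ovary1)) %*%
               coefficients$ovary1)
  # category probabilities (0, 1, 2 ovaries), reference = 2
  denom <- exp(l0) + exp(l1) + 1
  p <- cbind(exp(l0), exp(l1), 1) / denom
  u <- runif(n)
  ovary <- ifelse(u < p[, 1], 0L, ifelse(u < p[, 1] + p[, 2], 1L, 2L))
  log_mu <- drop(build_term_matrix(df, names(coefficients$ovarioles)) %*%
                   coefficients$ovarioles)
  mu <- exp(log_mu)
  left <- ifelse(ovary >= 1L, rpois(n, mu), NA_integer_)
  right <- ifelse(ovary == 2L, rpois(n, mu), NA_integer_)
  # a 1-ovary female's functional ovary is drawn once; assign side at random
  swap <- ovary == 1L & runif(n) < 0.5
  tmp <- left[swap]; left[swap] <- right[swap]; right[swap] <- tmp
  df$ovary_count <- ovary
  df$ovarioles_left <- left
  df$ovarioles_right <- right
  df$mean_ovarioles <- rowMeans(cbind(left, right), na.rm = TRUE)
  df$mean_ovarioles[ovary == 0L] <- NA_real_
  df[, c("female_id", setdiff(names(df), "female_id"))]
}
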