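# Depth-ratio copy number, P/M classification and coverage profiling along
# the element consensus.

filter_alignments <- function(aln, min_mapq = 20L, include_secondary = FALSE,
                              target_id = NULL) {
  keep <- aln$mapq >= min_mapq
  if (!include_secondary) keep <- keep & !aln$secondary & !aln$supplementary
  if (!is.null(target_id)) keep <- keep & aln$target_id %in% target_id
  aln[keep, , drop = FALSE]
}

#' Mean read depth over a target
#'
#' Sum over positions of per-base depth divided by the full target length;
#' positions with zero depth count in the denominator. Records below the
#' mapping-quality threshold, and secondary/supplementary records by
#' default, are excluded (split-read evidence is consumed at a lower
#' threshold by the insertion caller, not here).
#'
#' @param aln Alignment data.frame.
#' @param target_length Target length in bp.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param include_secondary Count secondary/supplementary records.
#' @param target_id Optional target name(s) to restrict to.
#' @return Mean depth in reads.
#' @export
mean_depth <- function(aln, target_length, min_mapq = 20L,
                       include_secondary = FALSE, target_id = NULL) {
  if (target_length <= 0) stop("target_length must be positive")
  a <- filter_alignments(aln, min_mapq, include_secondary, target_id)
  if (nrow(a) == 0) return(0)
  s <- pmax(a$target_start, 0L)
  e <- pmin(a$target_end, target_length)
  sum(pmax(e - s, 0L)) / target_length
}

#' Depth-ratio copy number estimate
#'
#' Element copies per genome: mean read coverage of the element consensus
#' divided by mean read coverage of the host genome.
#'
#' @param te_depth Mean depth over the element consensus.
#' @param genome_depth Mean depth over the host genome.
#' @return Estimated copy number (copies).
#' @export
estimate_copy_number <- function(te_depth, genome_depth) {
  if (any(genome_depth <= 0))
    stop("genome mean depth is zero; copy number is undefined")
  te_depth / genome_depth
}

#' Classify a line as P (element-carrying) or M
#'
#' Lines with fewer than `threshold` estimated copies (default 0.5, i.e.
#' less than a single heterozygous copy) are element-negative (M); the
#' boundary value itself classifies as P because the rule is strict
#' "fewer than".
#'
#' @param copy_number Estimated copy number(s), non-negative.
#' @param threshold Classification threshold in copies.
#' @return Character vector of "P"/"M".
#' @export
classify_infection <- function(copy_number, threshold = 0.5) {
  if (any(copy_number < 0)) stop("copy_number must be non-negative")
  ifelse(copy_number < threshold, "M", "P")
}

#' Per-line copy-number table
#'
#' Convenience wrapper: computes element and genome mean depths from one
#' alignment set and returns a one-row summary with the depth-ratio copy
#' number (reported to 2 decimals) and P/M status.
#'
#' @param aln Alignment data.frame containing both element- and
#'   genome-targeted records.
#' @param annotation Element annotation (from [make_te_library()]).
#' @param genome_length Host genome length in bp.
#' @param line_id Line identifier.
#' @param threshold P/M threshold in copies.
#' @param ... Passed to [mean_depth()] (filters).
#' @return A one-row data.frame: line_id, te_name, te_depth, genome_depth,
#'   copy_number, status.
#' @export
copy_number_estimate <- function(aln, annotation, genome_length,
                                 line_id = "line1", threshold = 0.5, ...) {
  te <- annotation$name
  td <- mean_depth(aln, annotation$length, target_id = te, ...)
  genome_targets <- setdiff(unique(aln$target_id), te)
  gd <- mean_depth(aln, genome_length, target_id = genome_targets, ...)
  cn <- estimate_copy_number(td, gd)
  data.frame(line_id = line_id, te_name = te,
             te_depth = td, genome_depth = gd,
             copy_number = round(cn, 2),
             status = classify_infection(cn, threshold),
             stringsAsFactors = FALSE)
}

#' Per-base coverage profile along the element consensus
#'
#' Counts, for every consensus position, the reads supporting it.
#' Alignments extending past the consensus bounds are clipped to bounds
#' with a warning.
#'
#' @param aln Alignment data.frame (element-targeted records are selected
#'   by `annotation$name`).
#' @param annotation Element annotation.
#' @param min_mapq,include_secondary Depth filters as in [mean_depth()].
#' @return An object of class `coverage_profile`: list with `target_id`,
#'   `depth` (integer vector of length `annotation$length`) and
#'   `mean_depth`.
#' @export
coverage_profile <- function(aln, annotation, min_mapq = 20L,
                             include_secondary = FALSE) {
  len <- annotation$length
  a <- filter_alignments(aln, min_mapq, include_secondary,
                         target_id = annotation$name)
  if (nrow(a) && (any(a$target_start < 0) || any(a$target_end > len))) {
    warning("alignments exceed consensus bounds; clipped")
    a$target_start <- pmax(a$target_start, 0L)
    a$target_end <- pmin(a$target_end, len)
    a <- a[a$target_start < a$target_end, , drop = FALSE]
  }
  depth <- if (nrow(a) == 0) integer(len) else
    as.integer(IRanges::coverage(
      IRanges::IRanges(start = a$target_start + 1L, end = a$target_end),
      width = len))
  structure(list(target_id = annotation$name, depth = depth,
                 mean_depth = mean(depth)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage profile of", x$target_id, "(", length(x$depth), "bp )\n")
  cat("  mean depth:", round(x$mean_depth, 2), "\n")
  invisible(x)
}

#' Per-exon depth summary and terminal/internal fold ratio
#'
#' Mean depth per exon plus the fold ratio of terminal exons (first and
#' last) over internal exons. With the four-exon P-element annotation this
#' is mean depth over exons 0 and 3 divided by mean depth over exons 1 and
#' 2; abundant internally deleted copies retaining only the terminal exons
#' inflate this ratio (three truncated copies per complete copy give an
#' expected fold of 4).
#'
#' @param profile A [coverage_profile()].
#' @param annotation Element annotation.
#' @return A list with `exons` (data.frame exon, start, end, mean_depth),
#'   `fold` (terminal/internal mean-depth ratio) and `internal_zero`
#'   (flag: fold is non-finite because internal depth is 0).
#' @export
exon_summary <- function(profile, annotation) {
  exons <- annotation$exons
  n <- length(exons)
  stopifnot(n >= 2)
  md <- vapply(exons, function(iv)
    mean(profile$depth[(iv[1] + 1):iv[2]]), 0)
  tab <- data.frame(exon = seq_len(n) - 1L,
                    start = vapply(exons, `[`, 0, 1),
                    end = vapply(exons, `[`, 0, 2),
                    mean_depth = md)
  terminal <- c(1L, n)
  internal <- setdiff(seq_len(n), terminal)
  term_mean <- mean(unlist(lapply(exons[terminal], function(iv)
    profile$depth[(iv[1] + 1):iv[2]])))
  int_mean <- mean(unlist(lapply(exons[internal], function(iv)
    profile$depth[(iv[1] + 1):iv[2]])))
  list(exons = tab,
       fold = if (int_mean > 0) term_mean / int_mean else Inf,
       internal_zero = int_mean == 0)
}

#' Classify the exon structure of one element copy from a spanning read
#'
#' Given the element-consensus alignments of a single long read that fully
#' spans an insertion, an exon is retained when at least
#' `retain_frac` of its bases are covered by the read's element-aligned
#' segments; the copy is complete iff all exons are retained.
#'
#' @param te_aln Element-targeted alignment records of one read.
#' @param annotation Element annotation.
#' @param retain_frac Retention threshold (default 0.8).
#' @return A list with `complete` (logical) and `retained` (0-based integer
#'   indices of retained exons).
#' @export
classify_copy_structure <- function(te_aln, annotation, retain_frac = 0.8) {
  exons <- annotation$exons
  if (nrow(te_aln) == 0)
    return(list(complete = FALSE, retained = integer(0)))
  segs <- IRanges::reduce(IRanges::IRanges(
    start = te_aln$target_start + 1L, end = te_aln$target_end))
  frac <- vapply(exons, function(iv) {
    ex <- IRanges::IRanges(start = iv[1] + 1L, end = iv[2])
    ov <- IRanges::intersect(segs, ex)
    sum(IRanges::width(ov)) / (iv[2] - iv[1])
  }, 0)
  retained <- which(frac >= retain_frac) - 1L
  list(complete = length(retained) == length(exons), retained = retained)
}
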