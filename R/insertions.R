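# Insertion-site calling from split short reads and spanning long reads,
# cross-line clustering, and the per-copy site-frequency statistic.

# Single-linkage 1-D clustering: returns integer cluster ids for sorted or
# unsorted positions, with a new cluster wherever the sorted gap exceeds
# `window`.
chain_cluster <- function(pos, window) {
  ord <- order(pos)
  sorted <- pos[ord]
  brk <- c(0L, cumsum(diff(sorted) > window))
  ids <- integer(length(pos))
  ids[ord] <- brk + 1L
  ids
}

#' Call insertion sites from split short reads
#'
#' A genome-targeted record whose clipped side (soft/hard clip of at least
#' `min_clip` bp) belongs to a read that also aligns to a terminal window
#' of the element consensus contributes one breakpoint: at `target_end`
#' when the tail is clipped (element downstream) or `target_start` when
#' the head is clipped. Breakpoints are grouped per contig by
#' single-linkage within `group_window` bp; groups supported by at least
#' `min_support` reads emit a site. A site is `exact` when the modal
#' breakpoint carries more than half of the support (position = modal
#' breakpoint) and `approximate` otherwise (position = support-weighted
#' median breakpoint). Element orientation is inferred from the relative
#' strands of the genome- and element-side alignments of the supporting
#' reads, `unknown` when they disagree.
#'
#' @param aln Alignment records for one line, containing both element- and
#'   genome-targeted records keyed by read id.
#' @param te_name Element target name.
#' @param min_clip Minimum clip length (bp) for split-read evidence.
#' @param min_support Minimum supporting reads per site.
#' @param terminal_window Width (bp) of the element-terminal windows a
#'   split read must touch (TIR-proximal sequence).
#' @param group_window Single-linkage grouping window for raw breakpoints.
#' @param min_mapq Mapping-quality threshold for split evidence (clipped
#'   reads legitimately map poorly, so the default is 1, lower than the
#'   depth filter).
#' @param te_length Element consensus length; inferred from the element
#'   records when `NULL`.
#' @param line_id Line identifier attached to the output.
#' @return A data.frame of insertion sites: line_id, contig, position
#'   (0-based breakpoint), precision ("exact"/"approximate"), support,
#'   te_orientation. Empty, with a warning, when the line has no
#'   element-targeted alignments at all (likely an M line).
#' @export
call_insertions_short <- function(aln, te_name, min_clip = 20L,
                                  min_support = 3L, terminal_window = 200L,
                                  group_window = 15L, min_mapq = 1L,
                                  te_length = NULL, line_id = "line1") {
  empty <- data.frame(line_id = character(), contig = character(),
                      position = integer(), precision = character(),
                      support = integer(), te_orientation = character(),
                      stringsAsFactors = FALSE)
  te <- aln[aln$target_id == te_name & aln$mapq >= min_mapq, , drop = FALSE]
  if (nrow(te) == 0) {
    warning("no element-targeted alignments; likely an M line")
    return(empty)
  }
  if (is.null(te_length)) te_length <- max(te$target_end)
  terminal <- te$target_start < terminal_window |
    te$target_end > te_length - terminal_window
  te <- te[terminal, , drop = FALSE]
  te_key <- paste(te$read_id, te$mate)
  g <- aln[aln$target_id != te_name & aln$mapq >= min_mapq, , drop = FALSE]
  g <- g[paste(g$read_id, g$mate) %in% te_key, , drop = FALSE]
  clip_side <- ifelse(g$clip_tail >= pmax(g$clip_head, min_clip), "tail",
                      ifelse(g$clip_head >= min_clip, "head", "none"))
  g <- g[clip_side != "none", , drop = FALSE]
  clip_side <- clip_side[clip_side != "none"]
  if (nrow(g) == 0) return(empty)
  # the clipped side in *target* orientation: a head clip on a minus-strand
  # record sits at the high-coordinate end of the aligned block
  clip_right <- (clip_side == "tail") == (g$strand == "+")
  bp <- ifelse(clip_right, g$target_end, g$target_start)
  te_strand <- te$strand[match(paste(g$read_id, g$mate), te_key)]
  orient <- ifelse(te_strand == g$strand, "+", "-")

  out <- list()
  for (ctg in unique(g$target_id)) {
    sel <- g$target_id == ctg
    ids <- chain_cluster(bp[sel], group_window)
    for (cl in unique(ids)) {
      b <- bp[sel][ids == cl]
      o <- orient[sel][ids == cl]
      support <- length(b)
      if (support < min_support) next
      tab <- table(b)
      modal_n <- max(tab)
      if (modal_n > support / 2) {
        precision <- "exact"
        position <- as.integer(names(tab)[which.max(tab)])
      } else {
        precision <- "approximate"
        position <- as.integer(round(median(b)))
      }
      out[[length(out) + 1L]] <- data.frame(
        line_id = line_id, contig = ctg, position = position,
        precision = precision, support = support,
        te_orientation = if (length(unique(o)) == 1) o[1] else "unknown",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$contig, res$position), , drop = FALSE]
}

#' Call insertion sites (with copy structure) from spanning long reads
#'
#' A site is called only when a single read carries genomic anchors of at
#' least `anchor_min` bp on both sides of its element-aligned segments;
#' the reported position is the midpoint between the flanking genomic
#' blocks (the centre of the target-site duplication), and the copy
#' structure comes from [classify_copy_structure()]. Reads touching the
#' element with only one (or no) adequate anchor are excluded and counted
#' in the `excluded` attribute.
#'
#' @param aln Long-read alignment records for one line.
#' @param annotation Element annotation.
#' @param anchor_min Minimum genomic anchor length (bp) on each side.
#' @param retain_frac Exon-retention threshold passed on.
#' @param line_id Line identifier.
#' @return A data.frame: line_id, contig, position, precision ("exact"),
#'   support (1 per read before deduplication), te_orientation, structure
#'   ("complete" or comma-separated retained exon indices), read_id; with
#'   attribute `excluded` = number of element-overlapping reads lacking
#'   both anchors.
#' @export
call_insertions_long <- function(aln, annotation, anchor_min = 200L,
                                 retain_frac = 0.8, line_id = "line1") {
  te_name <- annotation$name
  out <- list()
  excluded <- 0L
  for (rid in unique(aln$read_id[aln$target_id == te_name])) {
    r <- aln[aln$read_id == rid, , drop = FALSE]
    r <- r[order(r$read_start), , drop = FALSE]
    is_te <- r$target_id == te_name
    # maximal runs of element blocks along the read; one candidate site each
    run_id <- cumsum(c(TRUE, diff(is_te) != 0))
    called <- FALSE
    for (run in unique(run_id[is_te])) {
      rows <- which(run_id == run)
      left <- if (min(rows) > 1) r[min(rows) - 1L, ] else NULL
      right <- if (max(rows) < nrow(r)) r[max(rows) + 1L, ] else NULL
      ok <- !is.null(left) && !is.null(right) &&
        left$target_id != te_name && right$target_id != te_name &&
        left$target_id == right$target_id &&
        (left$read_end - left$read_start) >= anchor_min &&
        (right$read_end - right$read_start) >= anchor_min
      if (!ok) next
      te <- r[rows, , drop = FALSE]
      strand <- te$strand[1]
      position <- if (strand == "+")
        floor((left$target_end + right$target_start) / 2) else
        floor((right$target_end + left$target_start) / 2)
      cs <- classify_copy_structure(te, annotation, retain_frac)
      out[[length(out) + 1L]] <- data.frame(
        line_id = line_id, contig = left$target_id,
        position = as.integer(position),
        precision = "exact", support = 1L,
        te_orientation = if (all(te$strand == left$strand)) "+" else "-",
        structure = if (cs$complete) "complete" else
          paste(cs$retained, collapse = ","),
        read_id = rid, stringsAsFactors = FALSE)
      called <- TRUE
    }
    if (!called) excluded <- excluded + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(line_id = character(), contig = character(),
               position = integer(), precision = character(),
               support = integer(), te_orientation = character(),
               structure = character(), read_id = character(),
               stringsAsFactors = FALSE)
  attr(res, "excluded") <- excluded
  res
}

#' Cluster insertion sites across lines
#'
#' Single-linkage clustering of per-line sites on the same contig within
#' `window` bp. A cluster may contain at most one site per line: when a
#' line contributes several, the one nearest the cluster median is kept
#' and the others are split into singleton clusters. The returned table
#' gives, per cluster, the consensus position and the number of lines
#' sharing it, plus a histogram of cluster sizes.
#'
#' @param sites Data.frame of sites from one or more lines (needs columns
#'   line_id, contig, position).
#' @param window Clustering window in bp (default 50).
#' @return An object of class `shared_site_table`: list with `clusters`
#'   (cluster_id, contig, position, n_lines), `members` (input rows plus
#'   cluster_id), and `histogram` (data.frame n_lines, n_clusters).
#' @export
cluster_sites_across_lines <- function(sites, window = 50L) {
  stopifnot(nrow(sites) >= 1,
            all(c("line_id", "contig", "position") %in% names(sites)))
  s <- sites
  s$cluster_id <- NA_integer_
  next_id <- 1L
  for (ctg in unique(s$contig)) {
    sel <- which(s$contig == ctg)
    ids <- chain_cluster(s$position[sel], window)
    for (cl in unique(ids)) {
      rows <- sel[ids == cl]
      med <- median(s$position[rows])
      keep_of_line <- tapply(rows, s$line_id[rows], function(rr)
        rr[which.min(abs(s$position[rr] - med))])
      main <- unlist(keep_of_line)
      s$cluster_id[main] <- next_id
      next_id <- next_id + 1L
      for (r in setdiff(rows, main)) {
        s$cluster_id[r] <- next_id
        next_id <- next_id + 1L
      }
    }
  }
  agg <- aggregate(position ~ cluster_id + contig, data = s, FUN = median)
  nl <- as.data.frame(table(s$cluster_id), stringsAsFactors = FALSE)
  names(nl) <- c("cluster_id", "n_lines")
  nl$cluster_id <- as.integer(nl$cluster_id)
  clusters <- merge(agg, nl, by = "cluster_id")
  clusters <- clusters[order(clusters$contig, clusters$position), ]
  rownames(clusters) <- NULL
  hist <- as.data.frame(table(clusters$n_lines), stringsAsFactors = FALSE)
  names(hist) <- c("n_lines", "n_clusters")
  hist$n_lines <- as.integer(hist$n_lines)
  structure(list(clusters = clusters, members = s, histogram = hist),
            class = "shared_site_table")
}

#' @export
print.shared_site_table <- function(x, ...) {
  cat("shared-site table:", nrow(x$clusters), "clusters from",
      nrow(x$members), "sites\n")
  print(x$histogram, row.names = FALSE)
  invisible(x)
}

#' Haplotype-sites per element copy
#'
#' Average number of distinct insertion sites per sequenced element copy:
#' `n_sites / (n_lines * haplotypes_per_line * mean_copy_number)`. A value
#' near 1 indicates that most insertion sites are private to a single
#' haplotype within the sequenced pools. Reported to 3 decimals at the
#' printed reporting precision (truncated).
#'
#' @param n_sites Total number of insertion sites.
#' @param n_lines Number of lines pooled.
#' @param haplotypes_per_line Haplotypes sequenced per line (e.g. 40 for a
#'   pool of 20 diploid flies).
#' @param mean_copy_number Mean element copies per genome.
#' @return Sites per haplotype copy (3 decimals).
#' @export
haplotype_sites_per_copy <- function(n_sites, n_lines, haplotypes_per_line,
                                     mean_copy_number) {
  if (any(c(n_sites, n_lines, haplotypes_per_line, mean_copy_number) <= 0))
    stop("all inputs must be positive")
  x <- n_sites / (n_lines * haplotypes_per_line * mean_copy_number)
  floor(x * 1000 + 1e-9) / 1000
}
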