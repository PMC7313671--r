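# Readers/writers for the standard files the pipeline touches. Every other
# module operates on the internal alignment representation produced here:
# a data.frame with one row per aligned block, 0-based half-open target
# coordinates, and read coordinates always on the *original* read (so
# clip_head == read_start and clip_tail == read_length - read_end for every
# record, whatever the strand or dialect).

ALN_COLS <- c("read_id", "mate", "target_id", "target_start", "target_end",
              "read_start", "read_end", "read_length", "strand", "mapq",
              "clip_head", "clip_tail", "secondary", "supplementary")

#' Construct an empty alignment frame
#'
#' @return A zero-row data.frame with the internal alignment columns.
#' @export
empty_alignments <- function() {
  data.frame(read_id = character(), mate = integer(),
             target_id = character(), target_start = integer(),
             target_end = integer(), read_start = integer(),
             read_end = integer(), read_length = integer(),
             strand = character(), mapq = integer(),
             clip_head = integer(), clip_tail = integer(),
             secondary = logical(), supplementary = logical(),
             stringsAsFactors = FALSE)
}

validate_alignments <- function(aln) {
  stopifnot(is.data.frame(aln), all(ALN_COLS %in% names(aln)))
  if (nrow(aln) == 0) return(invisible(aln))
  bad <- aln$target_start >= aln$target_end | aln$read_start >= aln$read_end |
    aln$clip_head < 0 | aln$clip_tail < 0 | aln$mapq < 0
  if (any(bad)) stop("invalid alignment records at rows: ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  invisible(aln)
}

# Parse CIGAR strings into clip / span lengths. Leading and trailing S/H
# operations count as clips; M/D/N/=/X consume the target, M/I/=/X the read.
cigar_stats <- function(cigar) {
  n <- length(cigar)
  out <- matrix(0L, n, 4,
                dimnames = list(NULL, c("clip_head", "clip_tail",
                                        "tspan", "rspan")))
  ops_list <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  for (i in seq_len(n)) {
    ops <- ops_list[[i]]
    if (length(ops) == 0) stop("unparsable CIGAR: ", cigar[i])
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    k <- length(op)
    ch <- 0L; ct <- 0L
    j <- 1L
    while (j <= k && op[j] %in% c("S", "H")) { ch <- ch + len[j]; j <- j + 1L }
    m <- k
    while (m >= j && op[m] %in% c("S", "H")) { ct <- ct + len[m]; m <- m - 1L }
    body_op <- op[seq.int(j, length.out = max(0L, m - j + 1L))]
    body_len <- len[seq.int(j, length.out = max(0L, m - j + 1L))]
    out[i, ] <- c(ch, ct,
                  sum(body_len[body_op %in% c("M", "D", "N", "=", "X")]),
                  sum(body_len[body_op %in% c("M", "I", "=", "X")]))
  }
  out
}

#' Parse an alignment file into the internal representation
#'
#' Reads plain-text SAM or PAF and returns one row per aligned block with
#' 0-based half-open target coordinates. Soft (`S`) and hard (`H`) CIGAR
#' clips populate `clip_head`/`clip_tail`; for minus-strand SAM records the
#' clips are swapped so that read coordinates always refer to the original
#' (unreversed) read. Unmapped records and records with missing mandatory
#' fields are skipped; their count is reported with a message and attached
#' as attribute `"skipped"`.
#'
#' @param path Path to the alignment file.
#' @param dialect `"sam"` or `"paf"`.
#' @return A data.frame of alignment records (see [empty_alignments()] for
#'   the columns), with attributes `skipped` (count) and, for SAM,
#'   `targets` (named vector of reference lengths from `@SQ` lines).
#' @export
parse_alignments <- function(path, dialect = c("sam", "paf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (dialect == "sam") parse_sam(lines) else parse_paf(lines)
}

parse_sam <- function(lines) {
  is_header <- startsWith(lines, "@")
  header <- lines[is_header]
  if (length(header) &&
      !all(grepl("^@(HD|SQ|RG|PG|CO)(\t|$)", header)))
    stop("malformed SAM header")
  targets <- integer(0)
  sq <- header[startsWith(header, "@SQ")]
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    targets <- stats::setNames(ln, sn)
  }
  body <- lines[!is_header & nzchar(lines)]
  skipped <- 0L
  if (length(body) == 0) {
    out <- empty_alignments()
    attr(out, "skipped") <- skipped
    attr(out, "targets") <- targets
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  keep <- nf >= 11L
  skipped <- skipped + sum(!keep)
  fields <- fields[keep]
  get <- function(i) vapply(fields, `[[`, "", i)
  qname <- get(1)
  flag <- suppressWarnings(as.integer(get(2)))
  rname <- get(3)
  pos <- suppressWarnings(as.integer(get(4)))
  mapq <- suppressWarnings(as.integer(get(5)))
  cigar <- get(6)
  ok <- !is.na(flag) & !is.na(pos) & !is.na(mapq) & rname != "*" &
    cigar != "*" & bitwAnd(flag, 4L) == 0L
  skipped <- skipped + sum(!ok)
  if (skipped > 0) message("parse_alignments: skipped ", skipped, " record(s)")
  qname <- qname[ok]; flag <- flag[ok]; rname <- rname[ok]
  pos <- pos[ok]; mapq <- mapq[ok]; cigar <- cigar[ok]
  cs <- cigar_stats(cigar)
  minus <- bitwAnd(flag, 16L) > 0L
  # SAM clips are in as-aligned orientation; flip for minus strand so clips
  # refer to the original read.
  clip_head <- ifelse(minus, cs[, "clip_tail"], cs[, "clip_head"])
  clip_tail <- ifelse(minus, cs[, "clip_head"], cs[, "clip_tail"])
  read_length <- cs[, "clip_head"] + cs[, "rspan"] + cs[, "clip_tail"]
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L))
  out <- data.frame(
    read_id = qname, mate = as.integer(mate), target_id = rname,
    target_start = pos - 1L, target_end = pos - 1L + cs[, "tspan"],
    read_start = as.integer(clip_head),
    read_end = as.integer(clip_head + cs[, "rspan"]),
    read_length = as.integer(read_length),
    strand = ifelse(minus, "-", "+"), mapq = mapq,
    clip_head = as.integer(clip_head), clip_tail = as.integer(clip_tail),
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    stringsAsFactors = FALSE)
  validate_alignments(out)
  attr(out, "skipped") <- skipped
  attr(out, "targets") <- targets
  out
}

parse_paf <- function(lines) {
  body <- lines[nzchar(lines)]
  skipped <- 0L
  if (length(body) == 0) {
    out <- empty_alignments()
    attr(out, "skipped") <- 0L
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  keep <- lengths(fields) >= 12L
  skipped <- sum(!keep)
  if (skipped > 0) message("parse_alignments: skipped ", skipped, " record(s)")
  fields <- fields[keep]
  get <- function(i) vapply(fields, `[[`, "", i)
  geti <- function(i) suppressWarnings(as.integer(get(i)))
  qname <- get(1)
  mate <- rep(0L, length(qname))
  mate[grepl("/1$", qname)] <- 1L
  mate[grepl("/2$", qname)] <- 2L
  qname <- sub("/[12]$", "", qname)
  tags <- vapply(fields, function(f)
    paste(f[-seq_len(12)], collapse = "\t"), "")
  out <- data.frame(
    read_id = qname, mate = mate, target_id = get(6),
    target_start = geti(8), target_end = geti(9),
    read_start = geti(3), read_end = geti(4),
    read_length = geti(2),
    strand = get(5), mapq = geti(12),
    clip_head = geti(3), clip_tail = geti(2) - geti(4),
    secondary = grepl("tp:A:S", tags, fixed = TRUE),
    supplementary = grepl("su:i:1", tags, fixed = TRUE),
    stringsAsFactors = FALSE)
  validate_alignments(out)
  attr(out, "skipped") <- skipped
  out
}

#' Write alignment records to SAM or PAF
#'
#' Inverse of [parse_alignments()]: `parse(write(parse(x)))` is the identity
#' on the internal representation. SAM output encodes mate, strand,
#' secondary and supplementary status in the FLAG and reconstructs a
#' `S...M...S` CIGAR from the clip fields; PAF output appends `/1`/`/2`
#' mate suffixes to the read name, a `tp:A:P`/`tp:A:S` tag for primary vs
#' secondary, and a private `su:i:1` tag for supplementary records.
#'
#' @param aln Alignment data.frame.
#' @param path Output path.
#' @param dialect `"sam"` or `"paf"`.
#' @param targets Named integer vector of reference lengths. Required for
#'   SAM `@SQ` headers and PAF target-length column; if `NULL`, lengths are
#'   inferred as the per-target maximum `target_end`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, dialect = c("sam", "paf"),
                             targets = NULL) {
  dialect <- match.arg(dialect)
  validate_alignments(aln)
  if (is.null(targets)) {
    targets <- if (nrow(aln)) {
      tapply(aln$target_end, aln$target_id, max)
    } else integer(0)
    targets <- stats::setNames(as.integer(targets), names(targets))
  }
  if (dialect == "sam") {
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(targets),
                        as.integer(targets)))
    if (nrow(aln) == 0) { writeLines(header, path); return(invisible(path)) }
    minus <- aln$strand == "-"
    flag <- ifelse(minus, 16L, 0L) +
      ifelse(aln$mate > 0L, 1L, 0L) +
      ifelse(aln$mate == 1L, 64L, ifelse(aln$mate == 2L, 128L, 0L)) +
      ifelse(aln$secondary, 256L, 0L) +
      ifelse(aln$supplementary, 2048L, 0L)
    span <- aln$read_end - aln$read_start
    ch <- ifelse(minus, aln$clip_tail, aln$clip_head)
    ct <- ifelse(minus, aln$clip_head, aln$clip_tail)
    cigar <- paste0(ifelse(ch > 0, paste0(ch, "S"), ""),
                    span, "M",
                    ifelse(ct > 0, paste0(ct, "S"), ""))
    rows <- paste(aln$read_id, flag, aln$target_id, aln$target_start + 1L,
                  aln$mapq, cigar, "*", 0L, 0L, "*", "*", sep = "\t")
    writeLines(c(header, rows), path)
  } else {
    if (nrow(aln) == 0) { writeLines(character(0), path); return(invisible(path)) }
    qname <- paste0(aln$read_id,
                    ifelse(aln$mate == 1L, "/1",
                           ifelse(aln$mate == 2L, "/2", "")))
    tlen <- as.integer(targets[aln$target_id])
    tlen[is.na(tlen)] <- aln$target_end[is.na(tlen)]
    span <- aln$target_end - aln$target_start
    tags <- paste0("tp:A:", ifelse(aln$secondary, "S", "P"),
                   ifelse(aln$supplementary, "\tsu:i:1", ""))
    rows <- paste(qname, aln$read_length, aln$read_start, aln$read_end,
                  aln$strand, aln$target_id, tlen, aln$target_start,
                  aln$target_end, span, span, aln$mapq, tags, sep = "\t")
    writeLines(rows, path)
  }
  invisible(path)
}

#' Write insertion sites as BED
#'
#' BED3+ output (0-based half-open): contig, position, position + 1,
#' line id, support, precision; rows sorted by contig then position.
#'
#' @param sites Insertion-site data.frame as returned by
#'   [call_insertions_short()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path) {
  if (nrow(sites) == 0) { writeLines(character(0), path); return(invisible(path)) }
  stopifnot(all(c("contig", "position", "line_id", "support",
                  "precision") %in% names(sites)),
            all(sites$position >= 0))
  ord <- order(sites$contig, sites$position)
  s <- sites[ord, ]
  write.table(
    data.frame(s$contig, s$position, s$position + 1L, s$line_id,
               s$support, s$precision),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads a CSV of per-female phenotype records from a diallel cross and
#' validates it: `ovary_count` must be 0, 1 or 2, and the number of
#' non-missing ovariole fields must equal the number of functional ovaries
#' (each atrophied ovary has an empty ovariole field). `mean_ovarioles` is
#' the mean over functional ovaries and is missing for fully atrophied
#' females, which are excluded from ovariole models but retained for
#' ovary-count models.
#'
#' @param path CSV path with columns `female_id`, `mother_genotype`,
#'   `father_line`, `temperature`, `age`, `ovary_count`, `ovarioles_left`,
#'   `ovarioles_right` (extra columns such as `father_pe_cn` are passed
#'   through).
#' @return A data.frame with a `mean_ovarioles` column appended.
#' @export
read_phenotypes <- function(path) {
  req <- c("female_id", "mother_genotype", "father_line", "temperature",
           "age", "ovary_count", "ovarioles_left", "ovarioles_right")
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("phenotype table lacks required column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(!df$ovary_count %in% c(0L, 1L, 2L))
  if (length(bad))
    stop("ovary_count outside {0,1,2} at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  n_present <- (!is.na(df$ovarioles_left)) + (!is.na(df$ovarioles_right))
  bad <- which(n_present != df$ovary_count)
  if (length(bad))
    stop("ovariole fields must be empty iff the ovary is atrophied; ",
         "mismatch at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  df$mean_ovarioles <- rowMeans(df[, c("ovarioles_left", "ovarioles_right")],
                                na.rm = TRUE)
  df$mean_ovarioles[df$ovary_count == 0L] <- NA_real_
  df
}
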