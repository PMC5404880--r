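## Core interval model and BED-family text I/O.
##
## Peak sets are plain GRanges.  At every package boundary coordinates follow
## the BED convention (0-based, half-open); conversion to the 1-based closed
## GRanges representation happens only here.  Condition / replicate labels
## travel in metadata(x).

#' Construct a peak set from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param name optional interval labels.
#' @param score optional numeric scores.
#' @param strand strand characters (`"+"`, `"-"` or `"*"`); peaks are
#'   normally unstranded.
#' @param condition,replicate_id optional labels attached as metadata.
#' @return A [GenomicRanges::GRanges] with `name`/`score` metadata columns.
#' @examples
#' ps <- peak_set("chr1", c(100, 500), c(200, 650))
#' interval_center(ps)
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL,
                     strand = "*", condition = NULL, replicate_id = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) stop("interval start must be < end")
  if (length(start) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start + 1, end = end),
                                 strand = strand)
  }
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  if (!is.null(condition)) S4Vectors::metadata(gr)$condition <- condition
  if (!is.null(replicate_id)) S4Vectors::metadata(gr)$replicate_id <- replicate_id
  gr
}

#' Extract 0-based half-open coordinates from a peak set
#'
#' @param x a `GRanges`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) plus `name`/`score`/`strand` when present.
#' @export
as_bed_df <- function(x) {
  stopifnot(methods::is(x, "GRanges"))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1,
                   end = GenomicRanges::end(x),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(x)
  if (!is.null(mc$name)) df$name <- mc$name
  if (!is.null(mc$score)) df$score <- mc$score
  st <- as.character(GenomicRanges::strand(x))
  if (any(st != "*")) df$strand <- st
  df
}

## shared line-level BED field parser; `path` only for error messages
.parse_bed_lines <- function(lines, path, min_fields = 3) {
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields))
    stop(sprintf("%s: line %d has %d field(s); at least %d required",
                 path, lineno[which(nf < min_fields)[1]],
                 nf[which(nf < min_fields)[1]], min_fields))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("%s: line %d: non-integer coordinates", path, lineno[bad[1]]))
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: invalid interval [%s, %s)", path,
                 lineno[bad[1]], start[bad[1]], end[bad[1]]))
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (any(nf >= 4)) out$name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  if (any(nf >= 5)) out$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")))
  if (any(nf >= 6)) out$strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else "*", "")
  out
}

#' Read a BED3/BED6 file as a peak set
#'
#' Track/browser/comment lines are skipped.  Coordinates are validated
#' (integer, `0 <= start < end`); a malformed line raises an error naming
#' the line number.
#'
#' @param path path to a tab-separated BED file.
#' @param condition,replicate_id optional labels recorded in metadata.
#' @return a `GRanges` (see [peak_set()]); empty file gives an empty set.
#' @export
read_bed <- function(path, condition = NULL, replicate_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .parse_bed_lines(readLines(path), path)
  if (nrow(df) == 0L)
    return(peak_set(character(), numeric(), numeric(),
                    condition = condition, replicate_id = replicate_id))
  strand <- if (!is.null(df$strand)) ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*"
  peak_set(df$chrom, df$start, df$end, name = df$name, score = df$score,
           strand = strand, condition = condition, replicate_id = replicate_id)
}

#' Write a peak set to a BED file
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as_bed_df(x)
  ## BED columns are positional: name is required before score etc.
  cols <- c("chrom", "start", "end")
  if (!is.null(df$score) || !is.null(df$strand)) {
    df$name <- if (is.null(df$name)) "." else ifelse(is.na(df$name), ".", df$name)
  }
  if (!is.null(df$name)) cols <- c(cols, "name")
  if (!is.null(df$strand) && is.null(df$score)) df$score <- 0
  if (!is.null(df$score)) cols <- c(cols, "score")
  if (!is.null(df$strand)) cols <- c(cols, "strand")
  write.table(format(df[cols], scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Input is BED6-like; the TSS is taken as the strand-aware 5' end of each
#' interval (`start` for `+`, `end - 1` for `-`).  Gene names (column 4) need
#' not be unique: a gene may have several TSSs.
#'
#' @param path path to a tab-separated BED6 file.
#' @return data.frame with columns `gene`, `chrom`, `pos` (0-based bp),
#'   `strand`.
#' @export
read_tss <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- .parse_bed_lines(readLines(path), path, min_fields = 4)
  if (nrow(df) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      pos = numeric(), strand = character()))
  strand <- if (!is.null(df$strand)) df$strand else "+"
  pos <- ifelse(strand == "-", df$end - 1, df$start)
  data.frame(gene = df$name, chrom = df$chrom, pos = pos, strand = strand,
             stringsAsFactors = FALSE)
}

#' Merge overlapping intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases.  Under the half-open convention, abutting intervals (`end == start`)
#' share no base and are \emph{not} merged.
#'
#' @param x a `GRanges`.
#' @return a sorted `GRanges` with no overlapping intervals.
#' @export
merge_overlapping <- function(x) {
  stopifnot(methods::is(x, "GRanges"))
  ## min.gapwidth = 0: merge on >=1 shared base only, keep abutting runs apart
  GenomicRanges::reduce(sort(x), min.gapwidth = 0L, ignore.strand = TRUE)
}

#' Element-wise interval overlap test
#'
#' True iff same chromosome and the 0-based half-open intervals share at
#' least one base.  `a` and `b` are recycled to a common length.
#'
#' @param a,b `GRanges` objects.
#' @return logical vector.
#' @export
intervals_overlap <- function(a, b) {
  n <- max(length(a), length(b))
  ia <- rep_len(seq_along(a), n); ib <- rep_len(seq_along(b), n)
  as.character(GenomicRanges::seqnames(a))[ia] ==
    as.character(GenomicRanges::seqnames(b))[ib] &
    GenomicRanges::start(a)[ia] <= GenomicRanges::end(b)[ib] &
    GenomicRanges::start(b)[ib] <= GenomicRanges::end(a)[ia]
}

#' Which query intervals overlap any subject interval?
#'
#' @param query,subject `GRanges` objects.
#' @return logical vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  ## differing seqlevel sets between query and subject are routine here
  suppressWarnings(IRanges::overlapsAny(query, subject, ignore.strand = TRUE))
}

#' Interval centers (0-based)
#'
#' The center of the half-open interval `[start, end)` is
#' `floor((start + end) / 2)`; ties (even total) round down.
#'
#' @param x a `GRanges`.
#' @return numeric vector of 0-based positions.
#' @export
interval_center <- function(x) {
  floor((GenomicRanges::start(x) - 1 + GenomicRanges::end(x)) / 2)
}

#' Total bases covered by a peak set
#'
#' @param x a `GRanges`.
#' @return number of distinct covered bases.
#' @export
covered_bases <- function(x) {
  sum(GenomicRanges::width(GenomicRanges::reduce(x, ignore.strand = TRUE)))
}
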