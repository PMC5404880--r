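## Coverage tracks, reference-point signal matrices and metagene profiles.
##
## A signal_track is binned per-chromosome coverage in mean-per-base units:
## the value stored for a bin is the average per-base coverage inside it, so
## normalization and matrix extraction are bin-size free.

#' Construct a read-record table
#'
#' A read is represented by its 5' end (0-based bp) and strand; that is all
#' the downstream operations (Tn5 offset correction, fragment extension)
#' need.
#'
#' @param chrom chromosome names.
#' @param five_prime 0-based position of each read's 5' end.
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns `chrom`, `five_prime`, `strand`.
#' @export
read_records <- function(chrom, five_prime, strand) {
  five_prime <- as.numeric(five_prime)
  if (any(five_prime < 0)) stop("read 5' positions must be >= 0")
  if (!all(strand %in% c("+", "-"))) stop("read strand must be '+' or '-'")
  data.frame(chrom = as.character(chrom), five_prime = five_prime,
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Tn5 insertion-offset correction for ATAC-seq reads
#'
#' Shifts each read 5' end onto the transposase insertion point: plus-strand
#' reads by +4 bp, minus-strand reads by -5 bp.  Positions are clipped at 0
#' rather than dropped, so the read count is preserved.
#'
#' @param reads a read-record table (see [read_records()]).
#' @return the corrected read-record table.
#' @export
tn5_correct <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  shift <- ifelse(reads$strand == "+", 4, -5)
  reads$five_prime <- pmax(reads$five_prime + shift, 0)
  reads
}

#' Drop reads on excluded chromosomes
#'
#' Mitochondrial reads are conventionally removed before accessibility
#' analysis; the default excludes `"chrM"`.
#'
#' @param reads a read-record table.
#' @param exclude character vector of chromosome names to drop.
#' @return the filtered read-record table.
#' @export
filter_chromosomes <- function(reads, exclude = "chrM") {
  reads[!(reads$chrom %in% exclude), , drop = FALSE]
}

.new_signal_track <- function(bins, bin_size, total_reads, chrom_lengths,
                              normalized = FALSE, fragment_length = NULL,
                              clipped_mass = 0) {
  structure(list(bins = bins, bin_size = as.integer(bin_size),
                 total_reads = total_reads, chrom_lengths = chrom_lengths,
                 normalized = normalized, fragment_length = fragment_length,
                 clipped_mass = clipped_mass),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin size %d bp, %s reads%s\n",
              length(x$bins), x$bin_size, format(x$total_reads, big.mark = ","),
              if (x$normalized) " (per-million normalized)" else ""))
  invisible(x)
}

## per-base mean coverage -> bin means for one chromosome
.bin_means <- function(v, bin_size) {
  pad <- (-length(v)) %% bin_size
  if (pad > 0) v <- c(v, numeric(pad))
  colMeans(matrix(v, nrow = bin_size))
}

#' Extend reads to fragments and pile up binned coverage
#'
#' Each read contributes one unit of coverage over a fragment-length window
#' extending from its 5' end in the 3' direction: `[p, p + L)` for a
#' plus-strand read and `[p - L + 1, p + 1)` for a minus-strand read (both
#' 0-based half-open, so every fragment covers exactly `L` bases).  Coverage
#' is clipped to `[0, chromosome length)`; the clipped mass is recorded in
#' the track so the conservation law `covered mass = reads x L` can be
#' audited.
#'
#' @param reads a read-record table.
#' @param fragment_length fragment length in bp (>= 1).
#' @param bin_size bin width in bp.
#' @param chrom_lengths named numeric vector of chromosome lengths; reads on
#'   chromosomes absent from it are an error.
#' @return a `signal_track` (un-normalized, mean-per-base units).
#' @export
extend_and_pileup <- function(reads, fragment_length, bin_size = 50L,
                              chrom_lengths) {
  fragment_length <- as.integer(fragment_length)
  if (is.na(fragment_length) || fragment_length < 1L)
    stop("fragment_length must be >= 1")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  missing_chr <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(missing_chr))
    stop("reads on chromosome(s) absent from chrom_lengths: ",
         paste(missing_chr, collapse = ", "))
  bins <- vector("list", length(chrom_lengths))
  names(bins) <- names(chrom_lengths)
  clipped <- 0
  for (chr in names(chrom_lengths)) {
    len <- chrom_lengths[[chr]]
    r <- reads[reads$chrom == chr, , drop = FALSE]
    if (nrow(r) == 0L) {
      bins[[chr]] <- numeric(ceiling(len / bin_size))
      next
    }
    s0 <- ifelse(r$strand == "+", r$five_prime, r$five_prime - fragment_length + 1)
    e0 <- s0 + fragment_length                   # 0-based half-open
    s0c <- pmax(s0, 0); e0c <- pmin(e0, len)
    clipped <- clipped + sum((s0c - s0) + (e0 - e0c))
    keep <- e0c > s0c
    cov <- IRanges::coverage(IRanges::IRanges(start = s0c[keep] + 1,
                                              end = e0c[keep]), width = len)
    bins[[chr]] <- .bin_means(as.numeric(cov), bin_size)
  }
  .new_signal_track(bins, bin_size, total_reads = nrow(reads),
                    chrom_lengths = chrom_lengths,
                    fragment_length = fragment_length, clipped_mass = clipped)
}

#' Normalize a track to reads-per-million units
#'
#' @param track a `signal_track` with `total_reads > 0`, not yet normalized.
#' @return the normalized track (`normalized` flag set).
#' @export
normalize_per_million <- function(track) {
  stopifnot(methods::is(track, "signal_track"))
  if (isTRUE(track$normalized)) stop("track is already per-million normalized")
  if (is.null(track$total_reads) || track$total_reads <= 0)
    stop("cannot normalize a track with total_reads = 0")
  f <- 1e6 / track$total_reads
  track$bins <- lapply(track$bins, function(v) v * f)
  track$normalized <- TRUE
  track
}

## per-base track value at 0-based positions (0 outside the chromosome)
.track_values_at <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  for (chr in unique(chrom)) {
    if (!chr %in% names(track$bins))
      stop("chromosome absent from track: ", chr)
    i <- which(chrom == chr)
    v <- track$bins[[chr]]
    len <- track$chrom_lengths[[chr]]
    p <- pos[i]
    ok <- p >= 0 & p < len
    idx <- p[ok] %/% track$bin_size + 1
    vals <- numeric(length(p))
    vals[ok] <- v[idx]
    out[i] <- vals
  }
  out
}

#' Reference-point signal matrix around site centers
#'
#' Row `i` holds the mean track value (mean-per-base units) in each
#' `bin_size` bin of the window `[center_i - window, center_i + window)`.
#' Bins extending past chromosome ends contribute 0.
#'
#' @param track a `signal_track`.
#' @param sites a `GRanges` of sites; sites on chromosomes absent from the
#'   track are an error naming the site.
#' @param window half-window in bp on each side of the center (default 1500).
#' @param bin_size matrix bin width in bp; must divide `window`.
#' @param assay optional assay label stored as an attribute.
#' @return a numeric matrix of class `site_matrix` (sites x bins) with
#'   attributes `window`, `bin_size`, `assay` and `bin_offsets` (bin start
#'   offsets relative to the center).
#' @export
signal_matrix <- function(track, sites, window = 1500L, bin_size = 50L,
                          assay = NULL) {
  stopifnot(methods::is(track, "signal_track"), methods::is(sites, "GRanges"))
  window <- as.integer(window); bin_size <- as.integer(bin_size)
  if (window %% bin_size != 0L) stop("window must be divisible by bin_size")
  chrom <- as.character(GenomicRanges::seqnames(sites))
  bad <- setdiff(unique(chrom), names(track$bins))
  if (length(bad))
    stop("site(s) on chromosome(s) absent from track: ",
         paste(bad, collapse = ", "))
  n <- length(sites)
  ncol <- 2L * window %/% bin_size
  centers <- interval_center(sites)
  offs <- seq.int(-window, window - 1L)
  m <- matrix(0, nrow = n, ncol = ncol)
  if (n > 0L) {
    pos <- rep(centers, each = length(offs)) + rep(offs, times = n)
    vals <- .track_values_at(track, rep(chrom, each = length(offs)), pos)
    ## average per-base values within each matrix bin
    perbase <- matrix(vals, nrow = length(offs))      # (2*window) x n sites
    grp <- rep(seq_len(ncol), each = bin_size)
    m <- t(rowsum(perbase, grp) / bin_size)
  }
  ids <- S4Vectors::mcols(sites)$name
  rownames(m) <- if (!is.null(ids)) ids else sprintf("site_%d", seq_len(n))
  structure(m, window = window, bin_size = bin_size, assay = assay,
            bin_offsets = seq.int(-window, window - 1L, by = bin_size),
            class = c("site_matrix", "matrix", "array"))
}

#' Metagene profile of a site signal matrix
#'
#' @param m a `site_matrix` with at least one site (row).
#' @return numeric vector of per-bin column means; keeps the matrix's
#'   `window`, `bin_size` and `bin_offsets` attributes.
#' @export
metagene_profile <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L)
    stop("metagene_profile needs a matrix with >= 1 site")
  structure(colMeans(m), window = attr(m, "window"),
            bin_size = attr(m, "bin_size"), bin_offsets = attr(m, "bin_offsets"))
}

#' Flank-to-center bimodality index of a metagene profile
#'
#' Ratio of the mean signal in the flank windows `[-1000, -200)` and
#' `[200, 1000)` bp to the mean signal in the center window `[-200, 200)` bp
#' (plus a small epsilon).  Values above 1 indicate flanking enrichment --
#' the "bimodal" nucleosomal configuration typical of active enhancers --
#' and values below 1 indicate a center-enriched profile.
#'
#' @param profile per-bin vector of length `2 * window / bin_size`.
#' @param window,bin_size the window geometry the profile was computed with;
#'   `window` must be at least 1000 bp for the flank windows to exist.
#' @param eps stabilizer added to the center mean (default 1e-9).
#' @return a single numeric ratio.
#' @export
bimodality_index <- function(profile, window = attr(profile, "window"),
                             bin_size = attr(profile, "bin_size"),
                             eps = 1e-9) {
  if (is.null(window) || is.null(bin_size))
    stop("window and bin_size must be supplied (or carried as attributes)")
  window <- as.integer(window); bin_size <- as.integer(bin_size)
  if (window < 1000L) stop("window must be >= 1000 bp for flank windows")
  if (length(profile) != 2L * window %/% bin_size)
    stop("profile length does not match 2 * window / bin_size")
  mid <- seq.int(-window, window - 1L, by = bin_size) + bin_size / 2
  flank <- (mid >= -1000 & mid < -200) | (mid >= 200 & mid < 1000)
  center <- mid >= -200 & mid < 200
  mean(profile[flank]) / (eps + mean(profile[center]))
}

#' Per-site accessibility scalar
#'
#' Mean per-base track signal over the center +/- `halfwidth` window of each
#' site; the scalar every classification step works with.
#'
#' @param track a `signal_track`.
#' @param sites a `GRanges`.
#' @param halfwidth half-window in bp (default 250).
#' @return numeric vector along `sites`.
#' @export
site_accessibility <- function(track, sites, halfwidth = 250L) {
  if (length(sites) == 0L) return(numeric())
  m <- signal_matrix(track, sites, window = as.integer(halfwidth),
                     bin_size = as.integer(halfwidth))
  rowMeans(m)
}

#' Background-calibrated accessibility threshold
#'
#' Samples `n` uniform random positions from the track's chromosomes,
#' computes the accessibility scalar at each, and returns the `q`-th
#' quantile.  Sites above this threshold are called "accessible".
#'
#' @param track a `signal_track`.
#' @param n number of background positions (default 1000).
#' @param halfwidth scalar window half-width in bp (default 250).
#' @param q quantile of the background distribution (default 0.75).
#' @param seed RNG seed for the background draw.
#' @return the threshold (single numeric).
#' @export
accessibility_threshold <- function(track, n = 1000L, halfwidth = 250L,
                                    q = 0.75, seed = 1L) {
  lens <- track$chrom_lengths
  set.seed(seed)
  chr <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(runif(n, halfwidth, lens[chr] - halfwidth))
  bg <- peak_set(chr, pos, pos + 1)
  stats::quantile(site_accessibility(track, bg, halfwidth), q, names = FALSE)
}

#' Write a signal track as bedGraph text
#'
#' One line per bin (`chrom  start  end  value`), 0-based half-open.
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @param keep_zero write zero-valued bins too (default FALSE).
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path, keep_zero = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$bins)) {
    v <- track$bins[[chr]]
    s <- seq.int(0L, by = track$bin_size, length.out = length(v))
    e <- pmin(s + track$bin_size, track$chrom_lengths[[chr]])
    keep <- if (keep_zero) rep(TRUE, length(v)) else v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", chr, s[keep], e[keep], v[keep]), con)
  }
  invisible(path)
}

#' Read a binned bedGraph file back into a signal track
#'
#' Expects the uniform-bin layout produced by [write_track_bedgraph()];
#' bins absent from the file are zero.
#'
#' @param path bedGraph path.
#' @param bin_size bin width in bp used when the track was written.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param total_reads,normalized,fragment_length track metadata to restore.
#' @return a `signal_track`.
#' @export
read_track_bedgraph <- function(path, bin_size, chrom_lengths,
                                total_reads = NA, normalized = TRUE,
                                fragment_length = NULL) {
  df <- .parse_bed_lines(readLines(path), path, min_fields = 4)
  bins <- lapply(chrom_lengths, function(len) numeric(ceiling(len / bin_size)))
  if (nrow(df) > 0L) {
    df$value <- suppressWarnings(as.numeric(df$name))
    if (anyNA(df$value)) stop(path, ": non-numeric bedGraph value")
    for (chr in unique(df$chrom)) {
      if (!chr %in% names(bins)) stop(path, ": unknown chromosome ", chr)
      i <- df$chrom == chr
      bins[[chr]][df$start[i] %/% bin_size + 1] <- df$value[i]
    }
  }
  .new_signal_track(bins, bin_size, total_reads = total_reads,
                    chrom_lengths = chrom_lengths, normalized = normalized,
                    fragment_length = fragment_length)
}
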