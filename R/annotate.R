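## Positional annotation: nearest-TSS distance classes, peak-to-peak
## proximity, and the expression-signature filter.

#' Nearest TSS per site, with promoter / intermediate / distal categories
#'
#' The distance is measured from the site center to the TSS position and is
#' signed (positive when the TSS lies at a larger coordinate than the
#' center).  The nearest TSS minimizes the absolute distance; exact ties are
#' broken toward the smaller TSS coordinate, then the lexicographically
#' smaller gene name.  Categories follow the absolute distance: `promoter`
#' (<= `promoter_bp`), `distal` (> `distal_bp`), and `intermediate` for the
#' band in between (reported so the three categories always partition the
#' sites).
#'
#' @param sites a `GRanges`.
#' @param tss a TSS table from [read_tss()] (columns `gene`, `chrom`, `pos`).
#' @param promoter_bp promoter radius in bp (default 1000).
#' @param distal_bp distal threshold in bp (default 5000).
#' @return list with `records` (data.frame: site, gene, distance, category)
#'   and `summary` (counts per category, median and mean absolute distance).
#' @export
nearest_tss <- function(sites, tss, promoter_bp = 1000, distal_bp = 5000) {
  if (is.null(tss) || nrow(tss) == 0L) stop("TSS annotation is empty")
  n <- length(sites)
  centers <- interval_center(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  ids <- S4Vectors::mcols(sites)$name
  if (is.null(ids)) ids <- sprintf("site_%d", seq_len(n))
  gene <- character(n); dist <- numeric(n)
  for (chr in unique(chrom)) {
    t2 <- tss[tss$chrom == chr, , drop = FALSE]
    if (nrow(t2) == 0L)
      stop("no TSS annotated on chromosome ", chr)
    t2 <- t2[order(t2$pos, t2$gene), , drop = FALSE]
    si <- which(chrom == chr)
    for (i in si) {
      d <- t2$pos - centers[i]
      j <- which(abs(d) == min(abs(d)))[1]   # rows sorted by (pos, gene)
      gene[i] <- t2$gene[j]
      dist[i] <- d[j]
    }
  }
  category <- ifelse(abs(dist) <= promoter_bp, "promoter",
                     ifelse(abs(dist) > distal_bp, "distal", "intermediate"))
  category <- factor(category, levels = c("promoter", "intermediate", "distal"))
  records <- data.frame(site = ids, gene = gene, distance = dist,
                        category = category, stringsAsFactors = FALSE)
  list(records = records,
       summary = list(counts = table(category),
                      median_abs_distance = stats::median(abs(dist)),
                      mean_abs_distance = mean(abs(dist))))
}

#' Nearest center-to-center distances between two peak sets
#'
#' For every peak in `setA` with a `setB` peak center within `max_distance`
#' on the same chromosome, the minimum absolute center-to-center distance;
#' peaks with no such neighbour are counted as unmatched.
#'
#' @param setA,setB non-empty `GRanges` objects.
#' @param max_distance search radius in bp (default 2000).
#' @return list with `distances` (per matched A peak), `median` (NA when no
#'   peak matches), `n_matched`, `n_unmatched`.
#' @export
center_distance_stats <- function(setA, setB, max_distance = 2000) {
  if (length(setA) == 0L || length(setB) == 0L)
    stop("both peak sets must be non-empty")
  ca <- interval_center(setA); cb <- interval_center(setB)
  cha <- as.character(GenomicRanges::seqnames(setA))
  chb <- as.character(GenomicRanges::seqnames(setB))
  nearest <- rep(NA_real_, length(setA))
  for (chr in unique(cha)) {
    bi <- which(chb == chr)
    if (length(bi) == 0L) next
    ai <- which(cha == chr)
    for (i in ai) nearest[i] <- min(abs(ca[i] - cb[bi]))
  }
  matched <- !is.na(nearest) & nearest <= max_distance
  d <- nearest[matched]
  list(distances = d,
       median = if (length(d)) stats::median(d) else NA_real_,
       n_matched = sum(matched),
       n_unmatched = length(setA) - sum(matched))
}

#' Expression-signature filter over a three-condition table
#'
#' Keeps genes transcribed in the reference stem-cell population
#' (`satellite > sc_expressed_min`) and splits them by fold change between
#' the induced and withdrawn conditions, with a pseudocount on both sides of
#' every ratio: `down_regulated` genes are at least `fold_threshold`-fold
#' higher with the inducer than after withdrawal, `up_regulated` genes the
#' reverse.
#'
#' @param expr data.frame with columns `gene`, `satellite`, `treatment`,
#'   `withdrawal` (normalized read counts).
#' @param fold_threshold minimum fold change (default 2).
#' @param sc_expressed_min minimum satellite expression (default 1).
#' @param pseudocount added to numerator and denominator (default 1).
#' @return list with character vectors `down_regulated` and `up_regulated`.
#' @export
expression_signature <- function(expr, fold_threshold = 2,
                                 sc_expressed_min = 1, pseudocount = 1) {
  need <- c("gene", "satellite", "treatment", "withdrawal")
  missing <- setdiff(need, names(expr))
  if (length(missing))
    stop("expression table lacks column(s): ", paste(missing, collapse = ", "))
  expressed <- expr$satellite > sc_expressed_min
  ratio_down <- (expr$treatment + pseudocount) / (expr$withdrawal + pseudocount)
  ratio_up <- (expr$withdrawal + pseudocount) / (expr$treatment + pseudocount)
  list(down_regulated = expr$gene[expressed & ratio_down >= fold_threshold],
       up_regulated = expr$gene[expressed & ratio_up >= fold_threshold])
}
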