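# Independent brute-force oracles the implementation is checked against.
# Everything here works on plain data.frames of 0-based half-open intervals
# (chrom/start/end) and never calls the package's interval machinery.

# set of covered bases, as "chrom:pos" strings
brute_covered_bases <- function(df) {
  if (nrow(df) == 0) return(character())
  unique(unlist(lapply(seq_len(nrow(df)), function(i)
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1)))))
}

brute_pair_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && s1 < e2 && s2 < e1
}

# does interval i of df overlap any interval of ref?
brute_any_overlap <- function(df, ref) {
  vapply(seq_len(nrow(df)), function(i) {
    any(vapply(seq_len(nrow(ref)), function(j)
      brute_pair_overlap(df$chrom[i], df$start[i], df$end[i],
                         ref$chrom[j], ref$start[j], ref$end[j]),
      logical(1)))
  }, logical(1))
}

# two-rule consensus evaluated per candidate by exhaustive enumeration
brute_consensus_keep <- function(candidates, treatment, control, min_support) {
  vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, , drop = FALSE]
    support <- sum(vapply(treatment, function(rep)
      nrow(rep) > 0 && any(brute_any_overlap(cand, rep)), logical(1)))
    hit_control <- any(vapply(control, function(rep)
      nrow(rep) > 0 && any(brute_any_overlap(cand, rep)), logical(1)))
    support >= min_support && !hit_control
  }, logical(1))
}

# closed form Sum (O - E)^2 / E for a 2x2 table
chisq_closed_form <- function(t) {
  E <- outer(rowSums(t), colSums(t)) / sum(t)
  sum((t - E)^2 / E)
}

# per-base averaging of a binned track over a window around a 0-based center
brute_matrix_row <- function(track, chrom, center, window, bin_size) {
  base_val <- function(p) {
    len <- track$chrom_lengths[[chrom]]
    if (p < 0 || p >= len) return(0)
    track$bins[[chrom]][p %/% track$bin_size + 1]
  }
  pos <- seq(center - window, center + window - 1)
  v <- vapply(pos, base_val, numeric(1))
  colMeans(matrix(v, nrow = bin_size))
}

# exhaustive nearest-TSS search with the declared tie-breaks
brute_nearest_tss <- function(chrom, center, tss) {
  t2 <- tss[tss$chrom == chrom, , drop = FALSE]
  d <- t2$pos - center
  best <- which(abs(d) == min(abs(d)))
  best <- best[order(t2$pos[best], t2$gene[best])][1]
  list(gene = t2$gene[best], distance = d[best])
}

# random interval table with no coincident endpoints (keeps the half-open
# abutment case out of randomized comparisons; it is tested explicitly)
random_intervals <- function(n, chroms = "chr1", span = 10000,
                             width_range = c(20, 400)) {
  repeat {
    start <- floor(runif(n, 0, span))
    width <- floor(runif(n, width_range[1], width_range[2]))
    df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                     start = start, end = start + width,
                     stringsAsFactors = FALSE)
    if (!any(df$end %in% df$start)) return(df)
  }
}

df_to_gr <- function(df) {
  peak_set(df$chrom, df$start, df$end,
           name = if (is.null(df$name)) NULL else df$name)
}
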