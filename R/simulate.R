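## Ground-truthed synthetic data with the statistical structure the analysis
## assumes: non-overlapping bound sites of two persistence classes, replicate
## peak calls with per-replicate sensitivity and false-positive noise,
## Poisson coverage tracks (center-peaked accessibility, bimodal flanking
## enhancer marks, promoter-restricted H3K4me3, repressed blocks disjoint
## from bound sites), a co-factor peak set near persistent sites, and an
## expression table with a planted fold-change signature.
##
## Every operation derives its RNG stream from cfg$seed plus a fixed
## per-operation offset (truth +0, peaks +1, tracks +2, expression +3,
## marks +4, panel +5), so stages are individually reproducible.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under: 500
#' non-overlapping bound sites on a 3 x 2 Mb genome, 60% Type 1 (post-
#' withdrawal accessibility at 10% of baseline by the first timepoint)
#' versus 40% Type 2 (90% of baseline), three treatment and two control
#' peak-call replicates at per-replicate sensitivity 0.9, and Poisson
#' coverage of about 300 expected reads per site at baseline.
#'
#' @param seed integer seed; every generator stream derives from it.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_sites number of bound sites.
#' @param type1_fraction fraction of sites whose accessibility collapses on
#'   withdrawal.
#' @param site_width_range min/max bound-site width (bp).
#' @param min_site_spacing minimum center-to-center spacing (bp), keeping
#'   signal windows of neighbouring sites apart.
#' @param timepoints labels of the time course; first is the induced
#'   baseline.
#' @param type1_decay,type2_decay per-timepoint accessibility decay factors
#'   (same length as `timepoints`, first element 1).
#' @param n_treatment_reps,n_control_reps replicate counts for peak calls.
#' @param sensitivity probability a true site is called in one treatment
#'   replicate.
#' @param false_peak_rate_per_mb Poisson rate of spurious peaks per Mb per
#'   replicate.
#' @param reads_per_site expected baseline reads per site per track.
#' @param background_per_bp background coverage rate (reads per bp).
#' @param bin_size track bin width (bp).
#' @param mark_probs probabilities a bound site carries (both, H3K4me1 only,
#'   H3K27ac only, neither) enhancer marks.
#' @param mark_retention per-class probability that a marked site keeps its
#'   mark peaks after withdrawal.
#' @param cofactor_offset_median median absolute center offset (bp) of the
#'   co-factor peak planted near each Type 2 site.
#' @param n_tss number of planted TSSs.
#' @param n_k27me3_blocks,k27me3_block_width repressed-block count and
#'   width range (bp).
#' @param n_genes expression-table size.
#' @param fold_grid planted induced/withdrawn fold changes and their
#'   sampling weights.
#' @param expression_noise_sd log-normal noise sd on measured counts.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 7L,
                       chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                       n_sites = 500L,
                       type1_fraction = 0.6,
                       site_width_range = c(200L, 400L),
                       min_site_spacing = 4000L,
                       timepoints = c("plus_dox", "wd_12h", "wd_24h", "wd_3d"),
                       type1_decay = c(1, 0.10, 0.05, 0.02),
                       type2_decay = c(1, 0.90, 0.88, 0.85),
                       n_treatment_reps = 3L,
                       n_control_reps = 2L,
                       sensitivity = 0.9,
                       false_peak_rate_per_mb = 2,
                       reads_per_site = 300,
                       background_per_bp = 0.01,
                       bin_size = 50L,
                       mark_probs = c(both = 0.8, k4me1_only = 0.1,
                                      k27ac_only = 0.05, neither = 0.05),
                       mark_retention = c(Type1 = 0.2, Type2 = 0.9),
                       cofactor_offset_median = 240,
                       n_tss = 200L,
                       n_k27me3_blocks = 30L,
                       k27me3_block_width = c(5000L, 20000L),
                       n_genes = 120L,
                       fold_grid = list(folds = c(4, 2.5, 1, 1 / 2.5, 1 / 4),
                                        weights = c(2, 2, 4, 2, 2)),
                       expression_noise_sd = 0.1) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$chrom_lengths)) || any(!nzchar(names(cfg$chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (cfg$type1_fraction < 0 || cfg$type1_fraction > 1)
    stop("type1_fraction must be in [0, 1]")
  if (cfg$sensitivity < 0 || cfg$sensitivity > 1)
    stop("sensitivity must be in [0, 1]")
  if (length(cfg$type1_decay) != length(cfg$timepoints) ||
      length(cfg$type2_decay) != length(cfg$timepoints))
    stop("decay vectors must match the number of timepoints")
  if (abs(sum(cfg$mark_probs) - 1) > 1e-8) stop("mark_probs must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

.sim_seed <- function(cfg, offset) as.integer((cfg$seed + offset) %% .Machine$integer.max)

## m positions in [margin, L - margin] with pairwise spacing >= gap
.spaced_positions <- function(m, L, gap, margin) {
  if (m == 0L) return(numeric())
  free <- L - 2 * margin - (m - 1) * gap
  if (free <= 0) stop("requested sites do not fit disjointly on the genome")
  sort(runif(m, 0, free)) + gap * (seq_len(m) - 1) + margin
}

#' Simulate the ground truth
#'
#' Places non-overlapping bound sites, draws their persistence class, mark
#' flags, baseline read depths, co-factor offsets (Type 2 only), planted
#' TSSs, repressed H3K27me3 blocks disjoint from all sites, and the planted
#' expression fold changes.  Deterministic for a fixed config.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `synthetic_truth` with elements `sites`
#'   (`GRanges` with `name`, `type` metadata), `type`, `baseline`, `decay`
#'   (sites x timepoints matrix), `marks` (data.frame of flags),
#'   `cofactor_offset`, `cofactor_peaks` (`GRanges`), `tss` (data.frame),
#'   `k27me3_blocks` (`GRanges`), `genes` (data.frame with planted folds),
#'   and `config`.
#' @export
simulate_truth <- function(cfg = sim_config()) {
  stopifnot(methods::is(cfg, "sim_config"))
  set.seed(.sim_seed(cfg, 0L))
  lens <- cfg$chrom_lengths
  ## apportion sites to chromosomes by length, largest remainder
  raw <- cfg$n_sites * lens / sum(lens)
  m <- floor(raw)
  extra <- order(raw - m, decreasing = TRUE)[seq_len(cfg$n_sites - sum(m))]
  m[extra] <- m[extra] + 1
  chrom <- rep(names(lens), m)
  margin <- 5000
  centers <- unlist(lapply(names(lens), function(chr)
    .spaced_positions(m[[chr]], lens[[chr]], cfg$min_site_spacing, margin)),
    use.names = FALSE)
  centers <- floor(centers)
  width <- floor(runif(cfg$n_sites, cfg$site_width_range[1],
                       cfg$site_width_range[2] + 1))
  start <- centers - floor(width / 2)
  n1 <- round(cfg$n_sites * cfg$type1_fraction)
  type <- sample(c(rep("Type1", n1), rep("Type2", cfg$n_sites - n1)))
  sites <- peak_set(chrom, start, start + width,
                    name = sprintf("site_%04d", seq_len(cfg$n_sites)))
  S4Vectors::mcols(sites)$type <- type
  baseline <- cfg$reads_per_site * rlnorm(cfg$n_sites, 0, 0.25)
  decay <- t(vapply(type, function(ty)
    if (ty == "Type1") cfg$type1_decay else cfg$type2_decay,
    numeric(length(cfg$timepoints))))
  colnames(decay) <- cfg$timepoints
  rownames(decay) <- S4Vectors::mcols(sites)$name
  ## enhancer-mark flags
  mk <- sample(names(cfg$mark_probs), cfg$n_sites, replace = TRUE,
               prob = cfg$mark_probs)
  marks <- data.frame(site = S4Vectors::mcols(sites)$name,
                      H3K4me1 = mk %in% c("both", "k4me1_only"),
                      H3K27ac = mk %in% c("both", "k27ac_only"),
                      stringsAsFactors = FALSE)
  ## co-factor peaks near Type 2 sites: folded-normal center offsets
  sigma <- cfg$cofactor_offset_median / stats::qnorm(0.75)
  offset <- rep(NA_real_, cfg$n_sites)
  i2 <- which(type == "Type2")
  offset[i2] <- round(abs(rnorm(length(i2), 0, sigma))) *
    sample(c(-1, 1), length(i2), replace = TRUE)
  cof_center <- centers[i2] + offset[i2]
  cofactor_peaks <- peak_set(chrom[i2], pmax(cof_center - 100, 0),
                             cof_center + 100,
                             name = S4Vectors::mcols(sites)$name[i2])
  ## planted TSSs (uniform, off the chromosome edges)
  tss_chr <- sample(names(lens), cfg$n_tss, replace = TRUE,
                    prob = lens / sum(lens))
  tss <- data.frame(gene = sprintf("gene_%04d", seq_len(cfg$n_tss)),
                    chrom = tss_chr,
                    pos = floor(runif(cfg$n_tss, margin, lens[tss_chr] - margin)),
                    strand = sample(c("+", "-"), cfg$n_tss, replace = TRUE),
                    stringsAsFactors = FALSE)
  ## H3K27me3 blocks, rejected against site windows
  blocks <- NULL
  guard <- 2000
  site_win <- peak_set(chrom, pmax(centers - guard, 0), centers + guard)
  tries <- 0L
  while (is.null(blocks) || length(blocks) < cfg$n_k27me3_blocks) {
    w <- floor(runif(1, cfg$k27me3_block_width[1], cfg$k27me3_block_width[2]))
    chr <- sample(names(lens), 1, prob = lens / sum(lens))
    s <- floor(runif(1, 0, lens[[chr]] - w))
    cand <- peak_set(chr, s, s + w)
    if (!overlaps_any(cand, site_win) &&
        (is.null(blocks) || !overlaps_any(cand, blocks))) {
      blocks <- if (is.null(blocks)) cand else suppressWarnings(c(blocks, cand))
    }
    tries <- tries + 1L
    if (tries > 100L * cfg$n_k27me3_blocks)
      stop("could not place repressed blocks disjoint from sites")
  }
  ## planted expression folds
  folds <- sample(cfg$fold_grid$folds, cfg$n_genes, replace = TRUE,
                  prob = cfg$fold_grid$weights)
  expressed <- runif(cfg$n_genes) > 0.2
  genes <- data.frame(gene = sprintf("expr_gene_%04d", seq_len(cfg$n_genes)),
                      expressed_in_sc = expressed,
                      planted_fold = folds,
                      base = rlnorm(cfg$n_genes, log(50), 0.5),
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, type = type, center = centers,
                 baseline = baseline, decay = decay, marks = marks,
                 cofactor_offset = offset, cofactor_peaks = cofactor_peaks,
                 tss = tss, k27me3_blocks = sort(blocks), genes = genes,
                 config = cfg),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d sites (%d Type1 / %d Type2) on %d chromosome(s), seed %d\n",
              length(x$sites), sum(x$type == "Type1"), sum(x$type == "Type2"),
              length(x$config$chrom_lengths), x$config$seed))
  invisible(x)
}

#' Simulate replicate peak calls
#'
#' Each treatment replicate contains every true site independently with
#' probability `sensitivity`, plus Poisson-distributed false peaks placed
#' away from true sites; control replicates contain only false peaks.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg its [sim_config()] (defaults to the one in `truth`).
#' @return list with `treatment` and `control`, each a list of `GRanges`.
#' @export
simulate_peak_replicates <- function(truth, cfg = truth$config) {
  set.seed(.sim_seed(cfg, 1L))
  lens <- cfg$chrom_lengths
  genome_mb <- sum(lens) / 1e6
  guard <- 2000
  site_win <- peak_set(as.character(GenomicRanges::seqnames(truth$sites)),
                       pmax(truth$center - guard, 0), truth$center + guard)
  draw_false <- function() {
    n <- rpois(1, cfg$false_peak_rate_per_mb * genome_mb)
    out <- peak_set(character(), numeric(), numeric())
    while (length(out) < n) {
      w <- floor(runif(1, cfg$site_width_range[1], cfg$site_width_range[2]))
      chr <- sample(names(lens), 1, prob = lens / sum(lens))
      s <- floor(runif(1, 0, lens[[chr]] - w))
      cand <- peak_set(chr, s, s + w)
      if (!overlaps_any(cand, site_win)) out <- suppressWarnings(c(out, cand))
    }
    out
  }
  treatment <- lapply(seq_len(cfg$n_treatment_reps), function(r) {
    keep <- runif(length(truth$sites)) < cfg$sensitivity
    gr <- suppressWarnings(c(GenomicRanges::granges(truth$sites[keep]),
                             GenomicRanges::granges(draw_false())))
    S4Vectors::metadata(gr)$condition <- "treatment"
    S4Vectors::metadata(gr)$replicate_id <- paste0("treat_rep", r)
    sort(gr)
  })
  control <- lapply(seq_len(cfg$n_control_reps), function(r) {
    gr <- GenomicRanges::granges(draw_false())
    S4Vectors::metadata(gr)$condition <- "control"
    S4Vectors::metadata(gr)$replicate_id <- paste0("ctl_rep", r)
    sort(gr)
  })
  list(treatment = treatment, control = control)
}

## add Gaussian-shaped expected reads to per-bin rate vectors
.add_gaussian <- function(rates, bin_size, chrom, center, total, sd, lens) {
  for (k in seq_along(center)) {
    chr <- chrom[k]
    nb <- length(rates[[chr]])
    lo <- max(floor((center[k] - 4 * sd) / bin_size), 0)
    hi <- min(ceiling((center[k] + 4 * sd) / bin_size), nb - 1)
    if (hi < lo) next
    bins <- lo:hi
    edges <- c(bins, hi + 1) * bin_size
    cdf <- stats::pnorm(edges, mean = center[k], sd = sd)
    rates[[chr]][bins + 1] <- rates[[chr]][bins + 1] + total[k] * diff(cdf)
  }
  rates
}

.rates_to_track <- function(rates, bin_size, lens) {
  counts <- lapply(rates, function(r) rpois(length(r), r))
  .new_signal_track(lapply(counts, function(v) v / bin_size), bin_size,
                    total_reads = sum(unlist(counts, use.names = FALSE)),
                    chrom_lengths = lens)
}

#' Simulate coverage tracks per assay and timepoint
#'
#' Poisson per-bin counts over Gaussian-shaped expected rates: accessibility
#' (ATAC-like) as a center Gaussian (sd 100 bp) scaled by each site's
#' per-timepoint decay; H3K4me1/H3K27ac as symmetric flank Gaussians at
#' +/-500 bp (sd 150 bp) at marked sites, likewise decaying after
#' withdrawal; H3K4me3 as a center Gaussian at planted TSSs only; H3K27me3
#' as uniform elevation inside its disjoint blocks.  Tracks are in raw count
#' units (mean per base per bin); normalize with [normalize_per_million()].
#'
#' @param truth a `synthetic_truth`.
#' @param cfg its [sim_config()].
#' @param assays subset of `c("atac", "H3K4me1", "H3K27ac", "H3K4me3",
#'   "H3K27me3")` to generate.
#' @return nested list: `$atac`, `$H3K4me1`, `$H3K27ac` are lists of
#'   `signal_track`s named by timepoint; `$H3K4me3` and `$H3K27me3` are
#'   single tracks.
#' @export
simulate_tracks <- function(truth, cfg = truth$config,
                            assays = c("atac", "H3K4me1", "H3K27ac",
                                       "H3K4me3", "H3K27me3")) {
  set.seed(.sim_seed(cfg, 2L))
  lens <- cfg$chrom_lengths
  bs <- cfg$bin_size
  empty_rates <- lapply(lens, function(L)
    rep(cfg$background_per_bp * bs, ceiling(L / bs)))
  chrom <- as.character(GenomicRanges::seqnames(truth$sites))
  out <- list()
  if ("atac" %in% assays) {
    out$atac <- lapply(stats::setNames(seq_along(cfg$timepoints), cfg$timepoints),
                       function(ti) {
      rates <- .add_gaussian(empty_rates, bs, chrom, truth$center,
                             truth$baseline * truth$decay[, ti], 100, lens)
      .rates_to_track(rates, bs, lens)
    })
  }
  for (mark in intersect(c("H3K4me1", "H3K27ac"), assays)) {
    marked <- truth$marks[[mark]]
    out[[mark]] <- lapply(stats::setNames(seq_along(cfg$timepoints), cfg$timepoints),
                          function(ti) {
      amp <- truth$baseline * truth$decay[, ti] * marked / 2
      rates <- .add_gaussian(empty_rates, bs, chrom, truth$center - 500,
                             amp, 150, lens)
      rates <- .add_gaussian(rates, bs, chrom, truth$center + 500,
                             amp, 150, lens)
      .rates_to_track(rates, bs, lens)
    })
  }
  if ("H3K4me3" %in% assays) {
    rates <- .add_gaussian(empty_rates, bs, truth$tss$chrom, truth$tss$pos,
                           rep(cfg$reads_per_site, nrow(truth$tss)), 150, lens)
    out$H3K4me3 <- .rates_to_track(rates, bs, lens)
  }
  if ("H3K27me3" %in% assays) {
    rates <- empty_rates
    bl <- as_bed_df(truth$k27me3_blocks)
    for (k in seq_len(nrow(bl))) {
      b0 <- bl$start[k] %/% bs; b1 <- (bl$end[k] - 1) %/% bs
      rates[[bl$chrom[k]]][(b0:b1) + 1] <-
        rates[[bl$chrom[k]]][(b0:b1) + 1] + 0.2 * bs
    }
    out$H3K27me3 <- .rates_to_track(rates, bs, lens)
  }
  out
}

#' Simulate enhancer-mark peak sets before and after withdrawal
#'
#' Marked sites carry mark peaks over their flanking regions in the induced
#' condition; after withdrawal each site keeps its peaks with the per-class
#' retention probability (`mark_retention`), so Type 1 enhancers are mostly
#' lost and Type 2 enhancers mostly persist.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg its [sim_config()].
#' @return list `induced` / `withdrawn`, each with `GRanges` elements
#'   `H3K4me1` and `H3K27ac`, plus `retained` (logical per site).
#' @export
simulate_mark_peaks <- function(truth, cfg = truth$config) {
  set.seed(.sim_seed(cfg, 4L))
  chrom <- as.character(GenomicRanges::seqnames(truth$sites))
  flank <- function(which_sites)
    peak_set(chrom[which_sites], pmax(truth$center[which_sites] - 800, 0),
             truth$center[which_sites] + 800)
  retained <- runif(length(truth$sites)) <
    cfg$mark_retention[truth$type]
  list(induced = list(H3K4me1 = flank(which(truth$marks$H3K4me1)),
                      H3K27ac = flank(which(truth$marks$H3K27ac))),
       withdrawn = list(
         H3K4me1 = flank(which(truth$marks$H3K4me1 & retained)),
         H3K27ac = flank(which(truth$marks$H3K27ac & retained))),
       retained = retained)
}

#' Simulate the three-condition expression table
#'
#' Measured counts are the planted base expression times the planted
#' induced/withdrawn fold, with multiplicative log-normal noise; genes not
#' expressed in the satellite-like reference get a zero satellite count.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg its [sim_config()].
#' @return list with `table` (data.frame gene/satellite/treatment/
#'   withdrawal) and `truth_down` / `truth_up` (planted signature lists at
#'   the config's fold grid, threshold 2).
#' @export
simulate_expression <- function(truth, cfg = truth$config) {
  set.seed(.sim_seed(cfg, 3L))
  g <- truth$genes
  noise <- function(n) rlnorm(n, 0, cfg$expression_noise_sd)
  n <- nrow(g)
  satellite <- ifelse(g$expressed_in_sc, g$base * noise(n), 0)
  treatment <- g$base * sqrt(g$planted_fold) * noise(n)
  withdrawal <- g$base / sqrt(g$planted_fold) * noise(n)
  list(table = data.frame(gene = g$gene, satellite = satellite,
                          treatment = treatment, withdrawal = withdrawal,
                          stringsAsFactors = FALSE),
       truth_down = g$gene[g$expressed_in_sc & g$planted_fold >= 2],
       truth_up = g$gene[g$expressed_in_sc & g$planted_fold <= 0.5])
}

#' Simulate a multi-sample accessibility panel for PCA
#'
#' Samples from three cell-of-origin batches, some expressing the factor
#' and some not.  Every site carries a batch-specific signal; bound sites
#' additionally carry a factor-dependent signal in factor-expressing
#' samples only.  With many background sites, unrestricted PCA is dominated
#' by batch, while PCA restricted to bound sites separates samples by
#' factor status.
#'
#' @param truth a `synthetic_truth`.
#' @param cfg its [sim_config()].
#' @param n_background number of unbound background sites (default
#'   20000; accessible background sites genome-wide vastly outnumber one
#'   factor's bound sites).
#' @param origin_sd sd of the per-batch site signal (default 2).
#' @param factor_effect added accessibility at bound sites in
#'   factor-expressing samples (default 8).
#' @param noise_sd per-observation noise sd (default 0.5).
#' @param seed RNG seed (default derived from `cfg$seed`).
#' @return list with `matrix` (samples x sites), `sites` (`GRanges` for all
#'   feature columns), `bound` (logical per column), `sample_info`
#'   (data.frame sample/origin/factor_on).
#' @export
simulate_accessibility_panel <- function(truth, cfg = truth$config,
                                         n_background = 20000L, origin_sd = 2,
                                         factor_effect = 8, noise_sd = 0.5,
                                         seed = .sim_seed(cfg, 5L)) {
  set.seed(seed)
  lens <- cfg$chrom_lengths
  bg_chr <- sample(names(lens), n_background, replace = TRUE,
                   prob = lens / sum(lens))
  bg_pos <- floor(runif(n_background, 1000, lens[bg_chr] - 1000))
  bg <- peak_set(bg_chr, bg_pos, bg_pos + 200)
  sites <- suppressWarnings(c(GenomicRanges::granges(truth$sites), bg))
  bound <- c(rep(TRUE, length(truth$sites)), rep(FALSE, n_background))
  sample_info <- data.frame(
    sample = c("iPax_plus_1", "iPax_plus_2", "iPax_minus12h_1",
               "iPax_minus12h_2", "iPax_minus3d_1", "iPax_minus3d_2",
               "MB_ctrl_1", "MB_ctrl_2", "MB_factor_1", "MB_factor_2",
               "MT_1", "MT_2", "satellite_1", "satellite_2"),
    origin = c(rep("iPax_line", 6), rep("C2C12_line", 6), rep("muscle", 2)),
    factor_on = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  nfeat <- length(sites)
  origin_profile <- vapply(unique(sample_info$origin),
                           function(o) rnorm(nfeat, 0, origin_sd),
                           numeric(nfeat))
  x <- t(vapply(seq_len(nrow(sample_info)), function(i) {
    mu <- origin_profile[, sample_info$origin[i]] +
      ifelse(bound & sample_info$factor_on[i], factor_effect, 0)
    mu + rnorm(nfeat, 0, noise_sd)
  }, numeric(nfeat)))
  rownames(x) <- sample_info$sample
  list(matrix = x, sites = sites, bound = bound, sample_info = sample_info)
}

#' Between-group separation of a score vector
#'
#' Fraction of the variance of `scores` explained by `groups` (between-group
#' sum of squares over total).  1 means complete separation of group means
#' with no within-group spread.
#'
#' @param scores numeric vector (e.g. a principal-component coordinate).
#' @param groups grouping vector of the same length.
#' @return numeric in `[0, 1]`.
#' @export
component_separation <- function(scores, groups) {
  if (length(scores) != length(groups)) stop("length mismatch")
  gm <- tapply(scores, groups, mean)
  tot <- sum((scores - mean(scores))^2)
  if (tot == 0) return(0)
  sum(tapply(scores, groups, length) * (gm - mean(scores))^2) / tot
}
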