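# small, fast configuration used by most generator tests
small_cfg <- function(...) {
  defaults <- list(seed = 7, chrom_lengths = c(chr1 = 4e5, chr2 = 4e5),
                   n_sites = 60, n_tss = 40, n_k27me3_blocks = 5,
                   k27me3_block_width = c(2000L, 5000L), n_genes = 40)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("truth generation is deterministic and honours the configured fractions", {
  cfg <- small_cfg()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(as_bed_df(t1$sites), as_bed_df(t2$sites))
  expect_identical(t1$type, t2$type)
  expect_identical(t1$genes, t2$genes)
  expect_equal(sum(t1$type == "Type1"), round(0.6 * 60))
  # type fraction 0 -> all Type2
  t0 <- simulate_truth(small_cfg(type1_fraction = 0))
  expect_true(all(t0$type == "Type2"))
  # sites are pairwise disjoint
  df <- as_bed_df(t1$sites)
  expect_false(any(duplicated(brute_covered_bases(df))))
  # co-factor offsets exist for Type2 sites only
  expect_true(all(is.na(t1$cofactor_offset[t1$type == "Type1"])))
  expect_true(all(!is.na(t1$cofactor_offset[t1$type == "Type2"])))
  # an impossible request errors
  expect_error(simulate_truth(small_cfg(n_sites = 5000)), "fit disjointly")
})

test_that("repressed blocks never overlap bound sites", {
  for (seed in c(7, 8, 9)) {
    tr <- simulate_truth(small_cfg(seed = seed))
    expect_false(any(overlaps_any(tr$k27me3_blocks, tr$sites)))
  }
})

test_that("replicate peak calls follow sensitivity and keep controls site-free", {
  tr <- simulate_truth(small_cfg())
  # sensitivity 1, no false peaks: replicates equal the truth set
  reps <- simulate_peak_replicates(tr, small_cfg(sensitivity = 1,
                                                 false_peak_rate_per_mb = 0))
  for (r in reps$treatment)
    expect_equal(as_bed_df(r)[, c("chrom", "start", "end")],
                 as_bed_df(sort(tr$sites))[, c("chrom", "start", "end")],
                 ignore_attr = TRUE)
  # sensitivity 0: only false peaks remain
  reps0 <- simulate_peak_replicates(tr, small_cfg(sensitivity = 0))
  for (r in reps0$treatment)
    expect_false(any(overlaps_any(r, tr$sites)))
  for (r in reps$control) expect_false(any(overlaps_any(r, tr$sites)))
})

test_that("consensus recovery matches the binomial prediction at sensitivity 0.9", {
  cfg <- sim_config(seed = 11)     # 500 sites, 3 reps, sensitivity 0.9
  tr <- simulate_truth(cfg)
  reps <- simulate_peak_replicates(tr, cfg)
  sites <- consensus_sites(reps$treatment, reps$control, consensus_config(2))
  recovery <- overlap_fraction(tr$sites, sites)
  p <- pbinom(1, 3, 0.9, lower.tail = FALSE)      # P(Bin(3, .9) >= 2) = 0.972
  se <- sqrt(p * (1 - p) / length(tr$sites))
  expect_lt(abs(recovery - p), 3 * se)
})

test_that("simulated tracks carry the planted spatial structure", {
  cfg <- small_cfg(n_sites = 20)
  tr <- simulate_truth(cfg)
  tracks <- simulate_tracks(tr, cfg)
  # ATAC signal mass concentrates near site centers at baseline
  atac <- tracks$atac[[1]]
  m <- signal_matrix(atac, tr$sites, window = 1500, bin_size = 50)
  prof <- metagene_profile(m)
  expect_lt(bimodality_index(prof), 1)            # center-enriched
  # Type1 accessibility ratio at first withdrawal ~ its decay factor
  prof_t <- accessibility_profiles(tracks$atac, tr$sites)
  ratio <- prof_t[tr$type == "Type1", 2] / prof_t[tr$type == "Type1", 1]
  expect_equal(mean(ratio), 0.1, tolerance = 0.25)
  # enhancer-mark metagene is bimodal at marked sites
  marked <- tr$marks$H3K27ac
  mk <- metagene_profile(signal_matrix(tracks$H3K27ac[[1]], tr$sites[marked]))
  expect_gt(bimodality_index(mk), 1)
  # H3K27me3 is elevated inside its blocks and flat at sites
  k27me3 <- tracks$H3K27me3
  blocks <- tr$k27me3_blocks
  in_block <- site_accessibility(k27me3, blocks, halfwidth = 500)
  at_sites <- site_accessibility(k27me3, tr$sites, halfwidth = 500)
  expect_gt(min(in_block), max(at_sites))
})

test_that("mark peak retention follows the per-class probabilities", {
  cfg <- sim_config(seed = 19)
  tr <- simulate_truth(cfg)
  mp <- simulate_mark_peaks(tr, cfg)
  ec_before <- enhancer_categories(tr$sites, mp$induced$H3K4me1,
                                   mp$induced$H3K27ac)
  ec_after <- enhancer_categories(tr$sites, mp$withdrawn$H3K4me1,
                                  mp$withdrawn$H3K27ac)
  ret <- enhancer_retention(ec_before$categories, ec_after$categories, tr$type)
  n1 <- sum(ec_before$categories == "both" & tr$type == "Type1")
  n2 <- sum(ec_before$categories == "both" & tr$type == "Type2")
  expect_lt(abs(ret[["Type1"]] - 0.2), 3 * sqrt(0.2 * 0.8 / n1))
  expect_lt(abs(ret[["Type2"]] - 0.9), 3 * sqrt(0.9 * 0.1 / n2))
})

test_that("expression generator plants a recoverable fold-change signature", {
  cfg <- small_cfg(seed = 3, expression_noise_sd = 0)
  tr <- simulate_truth(cfg)
  ex <- simulate_expression(tr, cfg)
  sig <- expression_signature(ex$table)
  # noise-free: every planted fold >= 2.5 gene is recovered...
  clear_down <- tr$genes$gene[tr$genes$expressed_in_sc & tr$genes$planted_fold >= 2.5]
  clear_up <- tr$genes$gene[tr$genes$expressed_in_sc & tr$genes$planted_fold <= 1 / 2.5]
  expect_true(all(clear_down %in% sig$down_regulated))
  expect_true(all(clear_up %in% sig$up_regulated))
  # ...and no null-fold gene leaks in
  null_genes <- tr$genes$gene[tr$genes$planted_fold == 1]
  expect_length(intersect(null_genes,
                          c(sig$down_regulated, sig$up_regulated)), 0)
  # all folds 1 -> both lists empty
  cfg1 <- small_cfg(fold_grid = list(folds = 1, weights = 1),
                    expression_noise_sd = 0)
  ex1 <- simulate_expression(simulate_truth(cfg1), cfg1)
  s1 <- expression_signature(ex1$table)
  expect_length(s1$down_regulated, 0)
  expect_length(s1$up_regulated, 0)
})

test_that("accessibility panel separates factor status only at bound sites", {
  cfg <- small_cfg(n_sites = 80)
  tr <- simulate_truth(cfg)
  panel <- simulate_accessibility_panel(tr, cfg, n_background = 1500)
  unrestricted <- pca_samples(panel$matrix)
  restricted <- pca_samples(panel$matrix, sites = panel$sites,
                            restrict_to = tr$sites)
  sep <- function(pc, groups) component_separation(pc$coordinates[, 1], groups)
  expect_gt(sep(restricted, panel$sample_info$factor_on), 0.8)
  expect_lt(sep(unrestricted, panel$sample_info$factor_on), 0.5)
  expect_gt(max(sep(unrestricted, panel$sample_info$origin),
                component_separation(unrestricted$coordinates[, 2],
                                     panel$sample_info$origin)), 0.8)
})
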