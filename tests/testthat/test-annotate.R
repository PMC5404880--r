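make_tss <- function(gene, chrom, pos)
  data.frame(gene = gene, chrom = chrom, pos = pos, strand = "+",
             stringsAsFactors = FALSE)

test_that("nearest TSS distances, categories and tie-breaks are correct", {
  sites <- peak_set("chr1", c(10000, 20000, 50000), c(11000, 21000, 51000),
                    name = c("s1", "s2", "s3"))
  # centers: 10500, 20500, 50500
  tss <- make_tss(c("gA", "gB"), "chr1", c(10000, 24000))
  res <- nearest_tss(sites, tss)
  expect_equal(res$records$gene, c("gA", "gB", "gB"))
  expect_equal(res$records$distance, c(-500, 3500, -26500))
  expect_equal(as.character(res$records$category),
               c("promoter", "intermediate", "distal"))
  expect_equal(as.numeric(res$summary$counts), c(1, 1, 1))
  expect_equal(res$summary$median_abs_distance, 3500)
  # equidistant TSSs: lower coordinate wins; same position: name order
  s <- peak_set("chr1", 9000, 11000)     # center 10000
  tie <- make_tss(c("right", "left"), "chr1", c(12000, 8000))
  expect_equal(nearest_tss(s, tie)$records$gene, "left")
  same <- make_tss(c("zeta", "alpha"), "chr1", c(10100, 10100))
  expect_equal(nearest_tss(s, same)$records$gene, "alpha")
  expect_error(nearest_tss(sites, tss[0, ]), "empty")
})

test_that("nearest TSS equals exhaustive search and categories partition the sites", {
  set.seed(31)
  for (rep in 1:10) {
    sdf <- random_intervals(50, chroms = c("chr1", "chr2"), span = 300000)
    tss <- make_tss(sprintf("g%02d", 1:20),
                    sample(c("chr1", "chr2"), 20, TRUE),
                    floor(runif(20, 0, 300000)))
    if (!all(c("chr1", "chr2") %in% tss$chrom)) next
    sites <- df_to_gr(sdf)
    res <- nearest_tss(sites, tss)
    centers <- interval_center(sites)
    for (i in seq_along(sites)) {
      o <- brute_nearest_tss(sdf$chrom[i], centers[i], tss)
      expect_equal(res$records$gene[i], o$gene)
      expect_equal(res$records$distance[i], o$distance)
    }
    expect_equal(sum(res$summary$counts), length(sites))
  }
})

test_that("nearest TSS summary is invariant under coordinate translation", {
  set.seed(33)
  sdf <- random_intervals(20, span = 100000)
  tss <- make_tss(sprintf("g%02d", 1:10), "chr1", floor(runif(10, 0, 100000)))
  r1 <- nearest_tss(df_to_gr(sdf), tss)
  shift <- 5000
  sdf2 <- transform(sdf, start = start + shift, end = end + shift)
  tss2 <- transform(tss, pos = pos + shift)
  r2 <- nearest_tss(df_to_gr(sdf2), tss2)
  expect_equal(r2$records$distance, r1$records$distance)
  expect_equal(r2$summary$median_abs_distance, r1$summary$median_abs_distance)
})

test_that("center-to-center proximity matches the all-pairs oracle", {
  a <- peak_set("chr1", 900, 1100)             # center 1000
  b <- peak_set("chr1", c(1200, 4900), c(1400, 5100))  # centers 1300, 5000
  res <- center_distance_stats(a, b)
  expect_equal(res$distances, 300)
  expect_equal(res$median, 300)
  # identity
  res_id <- center_distance_stats(b, b)
  expect_equal(res_id$distances, c(0, 0))
  expect_equal(res_id$median, 0)
  set.seed(37)
  adf <- random_intervals(30, chroms = c("chr1", "chr2"), span = 40000)
  bdf <- random_intervals(30, chroms = c("chr1", "chr2"), span = 40000)
  r <- center_distance_stats(df_to_gr(adf), df_to_gr(bdf), max_distance = 5000)
  ca <- interval_center(df_to_gr(adf)); cb <- interval_center(df_to_gr(bdf))
  brute <- vapply(seq_len(30), function(i) {
    d <- abs(ca[i] - cb[bdf$chrom == adf$chrom[i]])
    if (length(d) == 0) NA_real_ else min(d)
  }, numeric(1))
  brute_matched <- brute[!is.na(brute) & brute <= 5000]
  expect_equal(sort(r$distances), sort(brute_matched))
  expect_equal(r$n_matched + r$n_unmatched, 30)
  # invariance to within-set shuffling
  perm <- sample(30)
  r2 <- center_distance_stats(df_to_gr(adf[perm, ]), df_to_gr(bdf[sample(30), ]),
                              max_distance = 5000)
  expect_equal(r2$median, r$median)
  # empty result allowed
  far <- center_distance_stats(peak_set("chr1", 0, 10),
                               peak_set("chr1", 90000, 90010),
                               max_distance = 100)
  expect_true(is.na(far$median))
  expect_equal(far$n_unmatched, 1)
})

test_that("expression signature applies the satellite filter and fold rule", {
  expr <- data.frame(gene = c("down1", "up1", "flat", "silent"),
                     satellite = c(50, 30, 40, 0),
                     treatment = c(40, 10, 20, 100),
                     withdrawal = c(10, 40, 21, 5))
  sig <- expression_signature(expr)
  expect_equal(sig$down_regulated, "down1")   # (40+1)/(10+1) = 3.7
  expect_equal(sig$up_regulated, "up1")
  # satellite-silent genes never qualify
  expect_false("silent" %in% c(sig$down_regulated, sig$up_regulated))
  expect_error(expression_signature(expr[, 1:3]), "withdrawal")
  # disjoint lists whenever fold_threshold >= 1
  set.seed(41)
  big <- data.frame(gene = sprintf("g%03d", 1:200),
                    satellite = runif(200, 0, 100),
                    treatment = rlnorm(200, 3, 1),
                    withdrawal = rlnorm(200, 3, 1))
  s2 <- expression_signature(big)
  expect_length(intersect(s2$down_regulated, s2$up_regulated), 0)
})
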