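test_that("k-means separates well-separated archetypes and survives degenerate input", {
  x <- rbind(matrix(0, 10, 4), matrix(10, 8, 4))
  km <- kmeans_sites(x, k = 2, seed = 1)
  expect_length(unique(km$cluster[1:10]), 1)
  expect_length(unique(km$cluster[11:18]), 1)
  expect_false(km$cluster[1] == km$cluster[11])
  # identical rows: no crash, single cluster with a warning
  expect_warning(km0 <- kmeans_sites(matrix(1, 5, 3), k = 2), "distinct")
  expect_equal(km0$cluster, rep(1L, 5))
  expect_error(kmeans_sites(x, k = 30), "exceeds")
  expect_error(kmeans_sites(x, k = 1), ">= 2")
  # two Gaussian archetypes at 5 sigma: perfect recovery
  set.seed(13)
  truth <- rep(1:2, each = 100)
  y <- matrix(rnorm(200 * 6, mean = ifelse(truth == 2, 5, 0)), 200, 6)
  km2 <- kmeans_sites(y, k = 2, seed = 13)
  agree <- max(mean((km2$cluster == 1) == (truth == 1)),
               mean((km2$cluster == 2) == (truth == 1)))
  expect_equal(agree, 1)
  # determinism for a fixed seed
  expect_identical(km2$cluster, kmeans_sites(y, k = 2, seed = 13)$cluster)
})

test_that("type labels follow cluster-level persistence around the threshold", {
  prof <- rbind(site_a = c(10, 1, 1, 1),
                site_b = c(10, 9, 9, 8),
                site_c = c(12, 1.4, 1, 1),
                site_d = c(8, 7.4, 7, 6))
  ty <- classify_types(prof, k = 2, seed = 1, persistence_threshold = 0.5)
  lab <- setNames(ty$table$type, ty$table$site)
  expect_equal(unname(lab[c("site_a", "site_c")]), c("Type1", "Type1"))
  expect_equal(unname(lab[c("site_b", "site_d")]), c("Type2", "Type2"))
  expect_equal(ty$table$persistence, unname(prof[, 2] / prof[, 1]))
  # zero baseline -> unassigned, others unaffected
  prof2 <- rbind(prof, site_e = c(0, 0, 0, 0))
  ty2 <- classify_types(prof2, k = 2, seed = 1)
  expect_equal(ty2$table$type[5], "unassigned")
  expect_equal(ty2$n_unassigned, 1)
  expect_equal(ty2$table$type[1:4], ty$table$type)
})

test_that("typing is invariant to row order and to positive rescaling", {
  set.seed(4)
  n <- 60
  base <- runif(n, 5, 15)
  drop <- ifelse(runif(n) < 0.5, 0.1, 0.9)
  prof <- cbind(base, base * drop * exp(rnorm(n, 0, 0.05)),
                base * drop, base * drop)
  rownames(prof) <- sprintf("s%02d", 1:n)
  ty <- classify_types(prof, seed = 2)
  # positive rescaling
  ty_scaled <- classify_types(prof * 37.5, seed = 2)
  expect_equal(ty_scaled$table$type, ty$table$type)
  # row permutation (compare per-site labels)
  perm <- sample(n)
  ty_perm <- classify_types(prof[perm, ], seed = 2)
  expect_equal(setNames(ty_perm$table$type, ty_perm$table$site)[rownames(prof)],
               setNames(ty$table$type, ty$table$site)[rownames(prof)])
})

test_that("chi-square matches the closed form and rejects degenerate margins", {
  expect_equal(chi_square_accessibility(matrix(c(50, 50, 50, 50), 2)),
               list(statistic = 0, p_value = 1, df = 1))
  t1 <- matrix(c(80, 20, 40, 60), 2, byrow = TRUE)
  res <- chi_square_accessibility(t1)
  expect_equal(res$statistic, chisq_closed_form(t1), tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
  expect_error(chi_square_accessibility(matrix(c(0, 10, 0, 10), 2, byrow = TRUE)),
               "zero row or column")
  expect_error(chi_square_accessibility(matrix(c(1, 2, 3), 3)), "2x2")
  set.seed(6)
  for (i in 1:50) {
    t2 <- matrix(rpois(4, 40) + 1, 2)
    expect_equal(chi_square_accessibility(t2)$statistic, chisq_closed_form(t2),
                 tolerance = 1e-12)
  }
})

test_that("enhancer categories are exhaustive, exclusive, and match the overlap oracle", {
  sites <- peak_set("chr1", c(0, 100, 200, 300), c(50, 150, 250, 350))
  k4 <- peak_set("chr1", c(10, 110), c(20, 120))
  k27 <- peak_set("chr1", c(10, 210), c(20, 220))
  ec <- enhancer_categories(sites, k4, k27)
  expect_equal(as.character(ec$categories),
               c("both", "H3K4me1_only", "H3K27ac_only", "neither"))
  expect_equal(sum(ec$fractions), 1)
  set.seed(17)
  s <- random_intervals(100, span = 50000)
  m1 <- random_intervals(40, span = 50000)
  m2 <- random_intervals(40, span = 50000)
  ec2 <- enhancer_categories(df_to_gr(s), df_to_gr(m1), df_to_gr(m2))
  in1 <- brute_any_overlap(s, m1); in2 <- brute_any_overlap(s, m2)
  expect_equal(as.numeric(ec2$counts),
               c(sum(in1 & !in2), sum(!in1 & in2), sum(in1 & in2),
                 sum(!in1 & !in2)))
  expect_equal(sum(ec2$fractions), 1)
})

test_that("enhancer retention counts 'both' sites that stay 'both', per class", {
  before <- factor(c("both", "both", "both", "neither", "both"),
                   levels = c("H3K4me1_only", "H3K27ac_only", "both", "neither"))
  after_same <- before
  types <- c("Type1", "Type1", "Type2", "Type2", "Type2")
  expect_equal(enhancer_retention(before, after_same, types),
               c(Type1 = 1, Type2 = 1))
  after_none <- factor(rep("neither", 5), levels = levels(before))
  expect_equal(enhancer_retention(before, after_none, types),
               c(Type1 = 0, Type2 = 0))
  after_mixed <- factor(c("neither", "both", "both", "both", "neither"),
                        levels = levels(before))
  expect_equal(enhancer_retention(before, after_mixed, types),
               c(Type1 = 0.5, Type2 = 0.5))
  expect_error(enhancer_retention(before[1:3], after_none, types),
               "same site universe")
})

test_that("PCA coordinates behave: identical samples coincide, variance fractions decay", {
  set.seed(19)
  x <- matrix(rnorm(5 * 40), 5, 40)
  x[2, ] <- x[1, ]
  pc <- pca_samples(x)
  expect_equal(pc$coordinates[1, ], pc$coordinates[2, ])
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # reproducible under the sign convention
  pc2 <- pca_samples(x)
  expect_identical(pc$coordinates, pc2$coordinates)
  expect_error(pca_samples(x[1, , drop = FALSE]), ">= 2 samples")
  sites <- peak_set("chr1", seq(0, 3900, by = 100), seq(50, 3950, by = 100))
  expect_error(pca_samples(x, sites = sites,
                           restrict_to = peak_set("chr9", 1, 2)),
               "fewer than 2 features")
  # restriction keeps only overlapping feature columns
  pc3 <- pca_samples(x, sites = sites, restrict_to = peak_set("chr1", 0, 1000))
  expect_equal(pc3$n_features, 10)
})

test_that("accessibility calls combine background floor and dynamic range", {
  prof <- cbind(base = c(10, 10, 10, 0.1), t1 = c(9, 2, 0.3, 0.1))
  acc <- call_accessible(prof, bg_thresholds = 0.5, dynamic_fraction = 0.25)
  expect_equal(unname(acc[, "base"]), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(acc[, "t1"]), c(TRUE, FALSE, FALSE, FALSE))
})
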