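## Site typing over the factor-withdrawal time course, enhancer signature
## categories, accessibility-change testing and sample PCA.

#' Build per-site accessibility profiles from per-timepoint tracks
#'
#' @param tracks named list of `signal_track`s, one per timepoint, in time
#'   order; the first element is the induced (+inducer) baseline.
#' @param sites a `GRanges`.
#' @param halfwidth accessibility window half-width in bp (default 250).
#' @return matrix (sites x timepoints) of accessibility scalars, with
#'   timepoint labels as column names.
#' @export
accessibility_profiles <- function(tracks, sites, halfwidth = 250L) {
  stopifnot(is.list(tracks), length(tracks) >= 2L, !is.null(names(tracks)))
  prof <- vapply(tracks, site_accessibility, numeric(length(sites)),
                 sites = sites, halfwidth = halfwidth)
  if (length(sites) == 1L) prof <- matrix(prof, nrow = 1,
                                          dimnames = list(NULL, names(tracks)))
  ids <- S4Vectors::mcols(sites)$name
  rownames(prof) <- if (!is.null(ids)) ids else sprintf("site_%d", seq_along(sites))
  prof
}

#' k-means clustering of site feature rows
#'
#' Lloyd's algorithm with several random starts under a fixed seed, so the
#' assignment is deterministic for a given seed.  A degenerate input with
#' fewer distinct rows than clusters is accepted (all rows in cluster 1)
#' with a warning rather than an error.
#'
#' @param x numeric matrix, sites x features.
#' @param k number of clusters (>= 2, <= number of rows).
#' @param seed RNG seed.
#' @param nstart random restarts (default 10).
#' @return list with `cluster` (integer vector along rows), `centers`,
#'   `withinss` and `tot.withinss`.
#' @export
kmeans_sites <- function(x, k, seed = 1L, nstart = 10L) {
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the number of sites")
  if (nrow(unique(x)) < k) {
    warning("fewer distinct rows than clusters; returning a single cluster")
    return(list(cluster = rep(1L, nrow(x)),
                centers = matrix(colMeans(x), nrow = 1),
                withinss = sum(scale(x, scale = FALSE)^2), tot.withinss = NA))
  }
  km <- NULL
  for (attempt in 0:4) {     # Lloyd can hit an empty cluster; re-seed and retry
    set.seed(as.integer((seed + attempt * 1000003) %% .Machine$integer.max))
    km <- tryCatch(suppressWarnings(
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L,
                    algorithm = "Lloyd")), error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " non-empty clusters")
  list(cluster = unname(km$cluster), centers = km$centers,
       withinss = km$withinss, tot.withinss = km$tot.withinss)
}

#' Classify sites into Type 1 / Type 2 by accessibility persistence
#'
#' Per-site accessibility vectors across the withdrawal time course are
#' scaled by their induced-baseline value (first column), clustered with
#' k-means, and each whole cluster is labelled: Type 1 when the cluster's
#' mean persistence ratio (first withdrawal timepoint over baseline) falls
#' below `persistence_threshold` -- accessibility collapses as soon as the
#' factor is withdrawn -- and Type 2 otherwise (persistent accessibility).
#' Sites with zero baseline cannot be scaled; they are excluded from
#' clustering and reported as `unassigned`.
#'
#' @param profiles matrix sites x timepoints (baseline first), e.g. from
#'   [accessibility_profiles()].
#' @param k number of clusters (default 2).
#' @param seed RNG seed for k-means.
#' @param persistence_threshold ratio separating the classes (default 0.5).
#' @return an object of class `site_typing`: a list with `table` (data.frame
#'   site, cluster, type, persistence), `cluster_summary`, `k`, `seed`,
#'   `threshold`, `timepoints`.
#' @export
classify_types <- function(profiles, k = 2L, seed = 1L,
                           persistence_threshold = 0.5) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 2L)
    stop("profiles need a baseline plus >= 1 withdrawal timepoint")
  if (any(profiles < 0)) stop("accessibility values must be >= 0")
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- sprintf("site_%d", seq_len(nrow(profiles)))
  baseline <- profiles[, 1]
  usable <- baseline > 0
  if (!any(usable)) stop("no site has non-zero baseline accessibility")
  scaled <- profiles[usable, , drop = FALSE] / baseline[usable]
  km <- kmeans_sites(scaled, k = k, seed = seed)
  persistence <- scaled[, 2]
  cl_ratio <- tapply(persistence, km$cluster, mean)
  cl_type <- ifelse(cl_ratio < persistence_threshold, "Type1", "Type2")
  tab <- data.frame(site = ids, cluster = NA_integer_,
                    type = "unassigned",
                    persistence = NA_real_, stringsAsFactors = FALSE)
  tab$cluster[usable] <- km$cluster
  tab$type[usable] <- cl_type[as.character(km$cluster)]
  tab$persistence[usable] <- persistence
  structure(list(table = tab,
                 cluster_summary = data.frame(
                   cluster = as.integer(names(cl_ratio)),
                   mean_persistence = as.numeric(cl_ratio),
                   type = as.character(cl_type),
                   n = as.integer(table(km$cluster)[names(cl_ratio)])),
                 k = k, seed = seed, threshold = persistence_threshold,
                 timepoints = colnames(profiles),
                 n_unassigned = sum(!usable),
                 profiles = profiles),
            class = "site_typing")
}

#' @export
print.site_typing <- function(x, ...) {
  cat("Site typing by accessibility persistence\n")
  cat(sprintf("  %d sites, k = %d, persistence threshold = %g\n",
              nrow(x$table), x$k, x$threshold))
  tt <- table(x$table$type)
  for (ty in names(tt)) cat(sprintf("  %-10s %d\n", ty, tt[[ty]]))
  invisible(x)
}

#' @export
summary.site_typing <- function(object, ...) {
  cat("Site typing summary\n")
  cat("  timepoints:", paste(object$timepoints, collapse = ", "), "\n")
  print(object$cluster_summary, row.names = FALSE)
  if (object$n_unassigned > 0)
    cat(sprintf("  %d site(s) unassigned (zero baseline accessibility)\n",
                object$n_unassigned))
  invisible(object$cluster_summary)
}

#' Plot mean accessibility time courses per site class
#'
#' @param x a `site_typing` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.site_typing <- function(x, ...) {
  types <- sort(unique(x$table$type[x$table$type != "unassigned"]))
  prof <- x$profiles[x$table$type != "unassigned", , drop = FALSE]
  ty <- x$table$type[x$table$type != "unassigned"]
  m <- t(vapply(types, function(t2)
    colMeans(prof[ty == t2, , drop = FALSE] / prof[ty == t2, 1]),
    numeric(ncol(prof))))
  graphics::matplot(t(m), type = "b", pch = 19, lty = 1, xaxt = "n",
                    xlab = "timepoint", ylab = "accessibility / baseline", ...)
  graphics::axis(1, at = seq_len(ncol(prof)), labels = x$timepoints)
  graphics::legend("topright", legend = types, col = seq_along(types),
                   lty = 1, pch = 19, bty = "n")
  invisible(m)
}

#' Call sites accessible per timepoint
#'
#' A site is called accessible at a timepoint when its accessibility scalar
#' exceeds both (i) a background floor -- the background-quantile threshold
#' of that timepoint's track (see [accessibility_threshold()]) -- and (ii) a
#' dynamic-range criterion, `dynamic_fraction` times the cohort median
#' baseline scalar.  The second part matters in deeply covered data, where
#' a site that has lost most of its signal can still sit above genomic
#' background; "loss of accessibility" is loss relative to the bound state.
#'
#' @param profiles matrix sites x timepoints of accessibility scalars
#'   (baseline first), all timepoints in comparable normalized units.
#' @param bg_thresholds per-timepoint background thresholds (recycled if
#'   length 1).
#' @param dynamic_fraction fraction of the median baseline scalar a site
#'   must retain to stay "accessible" (default 0.25).
#' @return logical matrix of the same shape as `profiles`.
#' @export
call_accessible <- function(profiles, bg_thresholds = 0,
                            dynamic_fraction = 0.25) {
  profiles <- as.matrix(profiles)
  bg <- rep_len(bg_thresholds, ncol(profiles))
  thr <- pmax(bg, dynamic_fraction * stats::median(profiles[, 1]))
  sweep(profiles, 2, thr, `>`)
}

#' Pearson chi-square test on a 2x2 accessibility contingency table
#'
#' Uncorrected (no Yates continuity correction) chi-square with 1 degree of
#' freedom, as used to test altered accessibility between conditions.
#'
#' @param table 2x2 matrix of non-negative counts, e.g.
#'   rows = accessible / not accessible, columns = condition A / B.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_accessibility <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) <= 0) stop("grand total must be > 0")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square statistic undefined: zero row or column total")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Enhancer-signature categories from two histone-mark peak sets
#'
#' Each site is placed in exactly one of four mutually exclusive categories
#' by its overlap with H3K4me1 and H3K27ac peak sets.
#'
#' @param sites,k4me1,k27ac `GRanges` objects.
#' @return list with `categories` (factor along sites with levels
#'   `H3K4me1_only`, `H3K27ac_only`, `both`, `neither`) and `fractions`
#'   (named numeric summing to 1; NaN-free only when sites is non-empty).
#' @export
enhancer_categories <- function(sites, k4me1, k27ac) {
  in1 <- overlaps_any(sites, k4me1)
  in2 <- overlaps_any(sites, k27ac)
  cat <- ifelse(in1 & in2, "both",
                ifelse(in1, "H3K4me1_only",
                       ifelse(in2, "H3K27ac_only", "neither")))
  lv <- c("H3K4me1_only", "H3K27ac_only", "both", "neither")
  cat <- factor(cat, levels = lv)
  counts <- table(cat)
  list(categories = cat,
       counts = counts,
       fractions = stats::setNames(as.numeric(counts) / length(sites), lv))
}

#' Enhancer retention per site class
#'
#' Of the sites that carried the full enhancer signature (category `both`)
#' before factor withdrawal, the fraction that still carry it after, broken
#' down by site class.
#'
#' @param before,after factors of enhancer categories over the same site
#'   universe (same length, same order).
#' @param types character vector of site class labels along the same sites.
#' @return named numeric vector of retention fractions per class (NA for a
#'   class with no `both` site before withdrawal).
#' @export
enhancer_retention <- function(before, after, types) {
  if (length(before) != length(after) || length(before) != length(types))
    stop("before, after and types must cover the same site universe")
  vapply(split(seq_along(types), types), function(i) {
    was <- before[i] == "both"
    if (!any(was)) return(NA_real_)
    mean(after[i][was] == "both")
  }, numeric(1))
}

#' PCA of sample accessibility, optionally restricted to bound sites
#'
#' Features (sites) are mean-centered across samples and the samples are
#' projected onto the principal axes.  Component signs are fixed so each
#' component's largest-magnitude loading is positive, making coordinates
#' reproducible.
#'
#' @param x numeric matrix, samples x sites; column `i` must correspond to
#'   `sites[i]` when `sites` is given.
#' @param sites optional `GRanges` locating the feature columns.
#' @param restrict_to optional `GRanges`; when given, only features
#'   overlapping it are used (requires `sites`).
#' @return list with `coordinates` (samples x components), `explained`
#'   (variance fractions, non-increasing), `loadings`, `n_features`.
#' @export
pca_samples <- function(x, sites = NULL, restrict_to = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs >= 2 samples")
  if (!is.null(restrict_to)) {
    if (is.null(sites)) stop("restrict_to requires the sites of the feature columns")
    if (length(sites) != ncol(x))
      stop("sites must have one entry per feature column")
    keep <- overlaps_any(sites, restrict_to)
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 features after restriction")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ## sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x, explained = ev, loadings = pc$rotation,
       n_features = ncol(x))
}
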