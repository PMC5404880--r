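## End-to-end orchestration with a run manifest.

validation_error <- function(msg) {
  structure(class = c("validation_error", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

## stable hash of the effective configuration (timestamp-free)
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}

#' Validate a pipeline configuration
#'
#' @param config a named list (see [run_pipeline()]); unknown fields are an
#'   error, as are inconsistent settings (e.g. consensus support exceeding
#'   the replicate count).
#' @return the config with defaults filled in.
#' @export
validate_config <- function(config = list()) {
  known <- c("seed", "out_dir", "simulate", "consensus", "classify",
             "matrix", "proximity", "signature")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop(validation_error(paste0("unknown config field(s): ",
                                 paste(bad, collapse = ", "))))
  config$seed <- as.integer(config$seed %||% 7L)
  config$simulate <- config$simulate %||% list()
  ## YAML maps arrive as named lists; sim_config wants named vectors
  for (fld in c("chrom_lengths", "type1_decay", "type2_decay",
                "site_width_range", "k27me3_block_width", "mark_probs",
                "mark_retention"))
    if (!is.null(config$simulate[[fld]])) {
      v <- unlist(config$simulate[[fld]])
      config$simulate[[fld]] <- stats::setNames(as.numeric(v), names(v))
    }
  config$consensus <- utils::modifyList(list(min_treatment_support = 2L),
                                        config$consensus %||% list())
  config$classify <- utils::modifyList(
    list(k = 2L, persistence_threshold = 0.5, halfwidth = 250L,
         background_quantile = 0.75, dynamic_fraction = 0.25),
    config$classify %||% list())
  config$matrix <- utils::modifyList(list(window = 1500L, bin_size = 50L),
                                     config$matrix %||% list())
  config$proximity <- utils::modifyList(list(max_distance = 2000),
                                        config$proximity %||% list())
  config$signature <- utils::modifyList(
    list(fold_threshold = 2, sc_expressed_min = 1),
    config$signature %||% list())
  sim_cfg <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
  if (config$consensus$min_treatment_support > sim_cfg$n_treatment_reps)
    stop(validation_error(sprintf(
      "min_treatment_support (%d) exceeds treatment replicates (%d)",
      config$consensus$min_treatment_support, sim_cfg$n_treatment_reps)))
  config$sim_cfg <- sim_cfg
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on simulated data
#'
#' Executes simulate -> consensus -> accessibility matrices -> site typing
#' -> chi-square accessibility test -> TSS annotation -> co-factor
#' proximity -> expression signature, writes the stage outputs as text files
#' under `out_dir`, and returns a manifest.
#'
#' @param config named list (or path to a YAML file) with optional blocks
#'   `seed`, `simulate` (overrides for [sim_config()]), `consensus`
#'   (`min_treatment_support`), `classify` (`k`, `persistence_threshold`,
#'   `halfwidth`, `background_quantile`), `matrix` (`window`, `bin_size`),
#'   `proximity` (`max_distance`), `signature` (`fold_threshold`,
#'   `sc_expressed_min`).
#' @param out_dir output directory (default `config$out_dir` or a temp dir).
#' @param quiet suppress stage logging to stderr.
#' @return invisibly, a list of class `run_manifest` with the stage results
#'   (`consensus`, `typing`, `chi_square`, `tss`, `proximity`, `signature`),
#'   output paths, the config hash and the seed.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("chromPersist_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message("[", ..., "]")
  cfg <- config$sim_cfg
  paths <- list()

  log_stage("simulate")
  truth <- simulate_truth(cfg)
  reps <- simulate_peak_replicates(truth, cfg)
  tracks <- simulate_tracks(truth, cfg, assays = c("atac", "H3K27ac"))
  expr <- simulate_expression(truth, cfg)
  paths$truth <- file.path(out_dir, "truth_sites.bed")
  write_bed(truth$sites, paths$truth)

  log_stage("consensus")
  sites <- consensus_sites(reps$treatment, reps$control,
                           consensus_config(config$consensus$min_treatment_support))
  S4Vectors::mcols(sites)$name <- sprintf("site_%05d", seq_along(sites))
  paths$consensus <- file.path(out_dir, "consensus_sites.bed")
  write_bed(sites, paths$consensus)

  log_stage("matrix")
  atac <- lapply(tracks$atac, normalize_per_million)
  profiles <- accessibility_profiles(atac, sites,
                                     halfwidth = config$classify$halfwidth)
  paths$profiles <- file.path(out_dir, "accessibility_profiles.tsv")
  write.table(data.frame(site = rownames(profiles), profiles,
                         check.names = FALSE),
              paths$profiles, sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("classify")
  typing <- classify_types(profiles, k = config$classify$k,
                           seed = config$seed,
                           persistence_threshold = config$classify$persistence_threshold)
  paths$classification <- file.path(out_dir, "site_classification.tsv")
  write.table(typing$table, paths$classification, sep = "\t", quote = FALSE,
              row.names = FALSE)
  thr <- vapply(atac, accessibility_threshold, numeric(1),
                halfwidth = config$classify$halfwidth,
                q = config$classify$background_quantile, seed = config$seed)
  acc <- call_accessible(profiles, bg_thresholds = thr,
                         dynamic_fraction = config$classify$dynamic_fraction)
  cont <- matrix(c(sum(acc[, 1]), sum(!acc[, 1]), sum(acc[, 2]), sum(!acc[, 2])),
                 nrow = 2,
                 dimnames = list(c("accessible", "inaccessible"),
                                 colnames(profiles)[1:2]))
  chi <- chi_square_accessibility(cont)

  log_stage("annotate")
  tss_ann <- nearest_tss(sites, truth$tss)
  paths$tss <- file.path(out_dir, "tss_annotation.tsv")
  write.table(tss_ann$records, paths$tss, sep = "\t", quote = FALSE,
              row.names = FALSE)

  log_stage("proximity")
  prox <- center_distance_stats(sites, truth$cofactor_peaks,
                                max_distance = config$proximity$max_distance)

  log_stage("signature")
  sig <- expression_signature(expr$table,
                              fold_threshold = config$signature$fold_threshold,
                              sc_expressed_min = config$signature$sc_expressed_min)

  manifest <- structure(list(
    version = as.character(utils::packageVersion("chromPersist")),
    seed = config$seed,
    config_hash = .config_hash(config[setdiff(names(config), "sim_cfg")]),
    paths = paths,
    truth = truth,
    consensus = sites,
    typing = typing,
    accessibility_threshold = thr,
    contingency = cont,
    chi_square = chi,
    tss = tss_ann,
    proximity = prox,
    signature = sig,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  paths$manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(version = manifest$version, seed = manifest$seed,
                        config_hash = manifest$config_hash,
                        outputs = lapply(paths, normalizePath, mustWork = FALSE),
                        timestamp = manifest$timestamp),
                   paths$manifest)
  manifest$paths <- paths
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("chromPersist run", x$config_hash, "(seed", paste0(x$seed, ")"), "\n")
  cat(sprintf("  consensus sites: %d\n", length(x$consensus)))
  tt <- table(x$typing$table$type)
  cat("  site classes:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  cat(sprintf("  accessibility chi-square: X2 = %.1f, p = %.3g\n",
              x$chi_square$statistic, x$chi_square$p_value))
  cat(sprintf("  median |TSS distance|: %d bp\n",
              round(x$tss$summary$median_abs_distance)))
  cat(sprintf("  co-factor median center distance: %s bp (%d matched)\n",
              format(x$proximity$median), x$proximity$n_matched))
  cat(sprintf("  expression signature: %d down, %d up\n",
              length(x$signature$down_regulated), length(x$signature$up_regulated)))
  invisible(x)
}
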