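#' Run the full synthetic-to-QTL pipeline
#'
#' Executes every stage end to end on one seeded synthetic dataset:
#' simulate genotypes, depths, default calls and phenotypes; call co-dominant
#' genotypes with the gamma and normal mixture EM; score both against the
#' default caller; apply the consensus (>95% dominant agreement) and parental
#' consistency filters; merge by provenance priority (default > gamma >
#' normal); append the dominant morphological marker; collapse duplicates and
#' remove distorted markers; build, gap-filter and summarize the linkage map;
#' scan the maturity trait with a permutation threshold; and summarize the
#' top peak's marker association. Marker counts are logged after every
#' filtering step (a monotone non-increasing cascade).
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all artifacts are written
#'   as TSV/YAML files.
#' @param scan_method `"cim"` or `"im"`.
#' @param n_perm permutations for the LOD threshold.
#' @param order_runs restarts for marker ordering.
#' @param step scan grid spacing in cM.
#' @param alpha genome-wide significance level.
#' @param consensus_first apply the consensus filter before the parental
#'   filter (the default order).
#' @param censor_policy how the QTL scan treats censored individuals:
#'   `"include"` keeps them at the end-day value (default), `"exclude"` drops
#'   them.
#' @return list of class `"gras2qtl_run"` with the stage outputs
#'   (`truth`, `depths`, `defaults`, `marker_sets`, `accuracy`, `merged`,
#'   `map`, `map_summary`, `phenotypes`, `scan`, `threshold`, `peaks`,
#'   `association`, `correlation`, `filter_log`).
#' @export
run_pipeline <- function(config, out_dir = NULL, scan_method = c("cim", "im"),
                         n_perm = 1000L, order_runs = 50L, step = 1,
                         alpha = 0.05, consensus_first = TRUE,
                         censor_policy = c("include", "exclude")) {
  scan_method <- match.arg(scan_method)
  censor_policy <- match.arg(censor_policy)
  log_rows <- list()
  note <- function(stage, n) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(stage = stage, n_markers = n,
                                                     stringsAsFactors = FALSE)
  }

  truth <- simulate_f2_genotypes(config)
  depths <- simulate_read_depths(truth, config)
  defaults <- simulate_default_calls(depths, truth, config)
  phen <- simulate_phenotypes(truth, config)

  filter_chain <- function(ms) {
    if (consensus_first) {
      ms <- consensus_filter(ms, defaults$dominant)
      parental_consistency_filter(ms)
    } else {
      ms <- parental_consistency_filter(ms)
      consensus_filter(ms, defaults$dominant)
    }
  }
  gamma_ms <- call_codominant(depths, "gamma")
  normal_ms <- call_codominant(depths, "normal")
  accuracy <- list(
    gamma_vs_default = codominant_accuracy(gamma_ms, defaults$codominant),
    normal_vs_default = codominant_accuracy(normal_ms, defaults$codominant),
    gamma_dominant = dominant_accuracy(gamma_ms, defaults$dominant),
    normal_dominant = dominant_accuracy(normal_ms, defaults$dominant))
  note("called_gamma", n_markers(gamma_ms))
  note("called_normal", n_markers(normal_ms))
  gamma_f <- filter_chain(gamma_ms)
  normal_f <- filter_chain(normal_ms)
  merged <- priority_merge(defaults$codominant, gamma_f, normal_f)
  note("priority_merge", n_markers(merged))

  morph <- simulate_morphological_marker(truth)
  morph_row <- matrix(morph$calls, nrow = 1,
                      dimnames = list(morph$name, names(morph$calls)))
  merged$calls <- rbind(merged$calls, morph_row)
  merged$info <- rbind(merged$info,
                       data.frame(marker = morph$name, source = "morphological",
                                  type = "dominant", source_parent = 2L,
                                  consensus_pct = NA_real_, parental_ok = NA,
                                  distortion_p = NA_real_, converged = NA,
                                  stringsAsFactors = FALSE))
  note("with_morphological", n_markers(merged))

  dedup <- collapse_duplicate_markers(merged)
  note("collapse_duplicates", n_markers(dedup))
  undistorted <- segregation_distortion_filter(dedup)
  note("distortion_filter", n_markers(undistorted))

  map <- build_genetic_map(undistorted, runs = order_runs,
                           seed = config$seed + 100L)
  note("mapped", nrow(map))
  map <- gap_filter(map)
  note("gap_filter", nrow(map))
  map_summary <- summarize_map(map)

  y <- stats::setNames(phen$maturity_time, phen$individual)
  if (censor_policy == "exclude") y <- y[!phen$censored]
  calls <- undistorted$calls
  gp <- genotype_probabilities(map, calls, step = step)
  scan <- if (scan_method == "cim") {
    scan_cim(map, calls, y, step = step, gp = gp)
  } else {
    scan_im(map, calls, y, step = step, gp = gp)
  }
  thr <- permutation_threshold(map, calls, y, n_perm = n_perm, alpha = alpha,
                               method = scan_method, step = step,
                               seed = config$seed + 200L, gp = gp)
  peaks <- find_peaks(scan, thr$threshold)

  association <- NULL
  if (nrow(peaks) > 0) {
    mk <- peaks$marker_left[1]
    if (is.na(mk)) mk <- peaks$marker_right[1]
    if (!is.na(mk) && mk %in% rownames(calls)) {
      association <- class_summary(calls[mk, ],
                                   stats::setNames(phen$maturity_time,
                                                   phen$individual),
                                   censored = stats::setNames(phen$censored,
                                                              phen$individual),
                                   censor_policy = "exclude")
    }
  }
  correlation <- phenotype_correlation(phen$flowering_time, phen$maturity_time,
                                       censored = phen$censored,
                                       censor_policy = "exclude")
  filter_log <- do.call(rbind, log_rows)

  result <- structure(list(config = config, truth = truth, depths = depths,
                           defaults = defaults,
                           marker_sets = list(gamma = gamma_ms,
                                              normal = normal_ms,
                                              gamma_filtered = gamma_f,
                                              normal_filtered = normal_f),
                           accuracy = accuracy, merged = undistorted,
                           map = map, map_summary = map_summary,
                           phenotypes = phen, scan = scan, threshold = thr,
                           peaks = peaks, association = association,
                           correlation = correlation,
                           filter_log = filter_log),
                      class = "gras2qtl_run")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_cm <- paste("seed:", result$config$seed)
  write_run_config(result$config, file.path(out_dir, "run_config.yaml"))
  write_depth_matrix(result$depths, file.path(out_dir, "depths.tsv"), seed_cm)
  write_genotype_matrix(result$merged, file.path(out_dir, "genotypes.tsv"),
                        seed_cm)
  write_map(result$map, file.path(out_dir, "map.tsv"), seed_cm)
  write_phenotypes(result$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                   seed_cm)
  write_scan(result$scan, file.path(out_dir, "scan.tsv"),
             c(seed_cm, paste("threshold:", result$threshold$threshold)))
  write_tsv_with_header(result$filter_log,
                        file.path(out_dir, "filter_log.tsv"), seed_cm)
  write_tsv_with_header(result$merged$info,
                        file.path(out_dir, "marker_qc.tsv"), seed_cm)
  if (nrow(result$peaks) > 0) {
    write_tsv_with_header(result$peaks, file.path(out_dir, "peaks.tsv"),
                          seed_cm)
  }
  invisible(out_dir)
}

#' @export
print.gras2qtl_run <- function(x, ...) {
  cat("gras2qtl pipeline run (seed", x$config$seed, ")\n\n")
  cat("filter cascade:\n")
  print(x$filter_log, row.names = FALSE)
  s <- x$map_summary
  cat(sprintf("\nmap: %d groups, %d markers, %.1f cM, %.2f cM/marker\n",
              s$n_groups, s$n_markers, s$total_length, s$average_distance))
  cat(sprintf("scan (%s): LOD threshold %.2f (alpha %.2f, %d permutations)\n",
              attr(x$scan, "method"), x$threshold$threshold,
              x$threshold$alpha, x$threshold$n_perm))
  if (nrow(x$peaks)) {
    cat("peaks:\n")
    print(x$peaks, row.names = FALSE)
  } else {
    cat("no peaks above threshold\n")
  }
  invisible(x)
}
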