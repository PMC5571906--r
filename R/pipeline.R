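## End-to-end pipeline
## -------------------
## One declarative configuration drives the whole analysis: consensus ->
## annotation -> overlap -> stats, writing tidy CSVs plus a provenance
## manifest (config hash, seed, package version) into a run directory.
## Identical config + inputs give identical outputs.

#' Default pipeline configuration
#'
#' @param peaks,library,metadata Input paths; leave `NULL` to simulate a
#'   dataset under `seed` instead.
#' @param rt_tol,min_frac,min_score,mz_tol,volatility_threshold_c Analysis
#'   thresholds (defaults 0.05 min, 0.5, 700, 0.3 u, 250 degC).
#' @param overlap_pair The two method ids aligned in the overlap stage.
#' @param seed Master seed for simulation.
#' @return Validated config list of class `"vc_config"`.
#' @export
pipeline_config <- function(peaks = NULL, library = NULL, metadata = NULL,
                            rt_tol = 0.05, min_frac = 0.5, min_score = 700,
                            mz_tol = 0.3, volatility_threshold_c = 250,
                            overlap_pair = c("mobile", "td_mix"),
                            seed = 1L) {
  cfg <- list(peaks = peaks, library = library, metadata = metadata,
              rt_tol = rt_tol, min_frac = min_frac, min_score = min_score,
              mz_tol = mz_tol,
              volatility_threshold_c = volatility_threshold_c,
              overlap_pair = overlap_pair, seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  check_pos <- function(field) {
    v <- cfg[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v <= 0) {
      stop("config: '", field, "' must be a single positive number",
           call. = FALSE)
    }
  }
  for (f in c("rt_tol", "min_frac", "min_score", "mz_tol",
              "volatility_threshold_c")) check_pos(f)
  if (cfg$min_frac > 1) {
    stop("config: 'min_frac' must be in (0, 1]", call. = FALSE)
  }
  if (length(cfg$overlap_pair) != 2L) {
    stop("config: 'overlap_pair' must name exactly two methods",
         call. = FALSE)
  }
  for (f in c("peaks", "library", "metadata")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config: input file for '", f, "' not found: ", cfg[[f]],
           call. = FALSE)
    }
  }
  structure(cfg, class = "vc_config")
}

#' Read a pipeline configuration file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]. Validation happens before any computation.
#' @return A validated `"vc_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full method-comparison pipeline
#'
#' Executes, in order: data loading (or simulation under the config seed),
#' per-method consensus profiling, annotation, the cross-method overlap for
#' `overlap_pair`, and the common-vs-unique mixed model; writes per-stage
#' CSVs and a provenance manifest into `out_dir`.
#'
#' @param config A `"vc_config"` (or a path to a YAML config file).
#' @param out_dir Run directory to create.
#' @return Invisibly, a list with `profiles` (annotated, per method),
#'   `summaries`, `match`, `rt_cor`, `area_cor`, `lmm` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$peaks)) {
    ds <- generate_dataset(seed = config$seed)
    peaks <- ds$peaks
    library <- ds$library
    metadata_df <- ds$metadata
    meta_path <- file.path(out_dir, "metadata.csv")
    utils::write.csv(metadata_df, meta_path, row.names = FALSE)
    metadata <- read_compound_metadata(meta_path)
  } else {
    peaks <- read_peak_table(config$peaks)
    library <- read_msp_library(config$library)
    metadata <- read_compound_metadata(config$metadata)
  }

  methods <- unique(peaks$method_id)
  profiles <- list()
  for (m in methods) {
    mp <- peaks[peaks$method_id == m, , drop = FALSE]
    prof <- build_method_profile(mp, rt_tol = config$rt_tol,
                                 min_frac = config$min_frac,
                                 mz_tol = config$mz_tol)
    profiles[[m]] <- annotate_profile(prof, library, metadata,
                                      min_score = config$min_score,
                                      mz_tol = config$mz_tol)
    utils::write.csv(annotations_as_data_frame(profiles[[m]]),
                     file.path(out_dir, paste0("profile_", m, ".csv")),
                     row.names = FALSE)
  }
  summaries <- lapply(profiles, profile_summary)

  pair <- config$overlap_pair
  missing_pair <- setdiff(pair, methods)
  if (length(missing_pair)) {
    stop("overlap stage: method(s) not in the data: ",
         paste(missing_pair, collapse = ", "), call. = FALSE)
  }
  match <- match_across_methods(profiles[[pair[1L]]], profiles[[pair[2L]]],
                                mz_tol = config$mz_tol)
  utils::write.csv(match$pairs, file.path(out_dir, "overlap_pairs.csv"),
                   row.names = FALSE)
  peaks_a <- peaks[peaks$method_id == pair[1L], , drop = FALSE]
  peaks_b <- peaks[peaks$method_id == pair[2L], , drop = FALSE]
  rt_cor <- if (nrow(match$pairs) >= 3L) rt_rank_correlation(match) else NULL
  area_cor <- if (nrow(match$pairs) >= 3L) {
    area_rank_correlation(
      match,
      cluster_relative_mean_areas(profiles[[pair[1L]]], peaks_a),
      cluster_relative_mean_areas(profiles[[pair[2L]]], peaks_b))
  } else NULL

  # abundance model on the richer side (B): are the shared compounds the
  # abundant ones?
  records <- common_unique_records(profiles[[pair[2L]]], match, peaks_b,
                                   side = "b")
  lmm <- if (all(c("common", "unique") %in% records$set_label)) {
    fit_common_vs_unique(records)
  } else NULL
  utils::write.csv(records, file.path(out_dir, "relative_area_records.csv"),
                   row.names = FALSE)

  summary_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(method_id = s$method_id, n_total = s$n_total,
               n_volatile = s$n_volatile,
               pct_volatile = round(s$pct_volatile),
               t(s$n_by_origin))
  }))
  utils::write.csv(summary_df, file.path(out_dir, "profile_summary.csv"),
                   row.names = FALSE)

  write_manifest(config, out_dir,
                 stages = list(
                   n_methods = length(methods),
                   n_peaks = nrow(peaks),
                   n_pairs = nrow(match$pairs),
                   lmm_chi2 = if (is.null(lmm)) NA else lmm$chi2))

  invisible(list(profiles = profiles, summaries = summaries, match = match,
                 rt_cor = rt_cor, area_cor = area_cor, lmm = lmm,
                 out_dir = out_dir))
}

write_manifest <- function(config, out_dir, stages) {
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    package = "vocompare",
    version = as.character(utils::packageVersion("vocompare")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
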