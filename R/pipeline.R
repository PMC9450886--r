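#' Default pipeline configuration
#'
#' Nested list of every tunable constant: tank geometry, frame rate, smoothing
#' window/order (7 and 3), voxel grid (1000 voxels), clustering (k or a scan
#' range, seed, similarity form) and statistics (m = 10,000 resamples, alpha,
#' FDR). All randomness is fanned out from the single root `seed` by fixed
#' per-stage offsets (simulate +1, cluster +2, stats +3).
#'
#' @param out Output directory for all pipeline products.
#' @param seed Root seed.
#' @return Config list accepted by [run_pipeline()].
#' @export
default_config <- function(out = "fishclust_run", seed = 1L) {
  list(
    out = out,
    seed = as.integer(seed),
    geometry = list(side = 15, water_depth = 11.1, voxel_counts = c(10L, 10L, 10L)),
    fps = 30,
    smoothing = list(window = 7L, order = 3L),
    simulate = list(enabled = TRUE, mode = "traces", duration = 360,
                    n_sessions = 2L, persistence = 0.39),
    traces = NULL,          # directory of trace CSVs when simulate disabled
    metadata = NULL,        # metadata CSV when simulate disabled
    calibration = NULL,     # optional calibration CSV (z_air_cm,z_water_cm)
    clustering = list(k = NULL, k_values = NULL, method = "inverse"),
    stats = list(m = 10000L, alpha = 0.05, fdr = TRUE)
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  merge_lists <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        merge_lists(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  merge_lists(base, config)
}

#' Run the full analysis pipeline
#'
#' Composes the stages end to end: (optionally) simulate a cohort, extract the
#' four exploratory features per fish-session, fit the reference cluster model
#' on the first session, assign the remaining sessions to those clusters, and
#' run the permutation statistics (per-session strain-by-sex representation
#' tests; a two-session overlap test for 2 sessions or the longitudinal
#' overlap-score test for more). All intermediate files are written under
#' `config$out` and a JSON run manifest records the config snapshot, per-stage
#' seeds, row counts and warnings; re-running with the same config reproduces
#' every output.
#'
#' @param config Config list (see [default_config()]) or path to a YAML file.
#' @param cohort Optional [cohort_spec()] overriding the simulated design.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  cfg <- read_config(config)
  out_dir <- cfg$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  geometry <- tank_geometry(side = cfg$geometry$side,
                            water_depth = cfg$geometry$water_depth,
                            voxel_counts = cfg$geometry$voxel_counts)
  manifest <- list(config = cfg, seeds = list(root = cfg$seed,
                                              simulate = cfg$seed + 1L,
                                              cluster = cfg$seed + 2L,
                                              stats = cfg$seed + 3L),
                   stages = list(), warnings = character(0))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate or load -----------------------------------------------------
  features <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    if (is.null(cohort)) {
      cohort <- cohort_spec(persistence = cfg$simulate$persistence,
                            n_sessions = cfg$simulate$n_sessions,
                            seed = manifest$seeds$simulate)
    }
    if (identical(cfg$simulate$mode, "features")) {
      sim <- stage("simulate", generate_feature_cohort(cohort))
      features <- sim$features
      meta <- sim$metadata
      utils::write.csv(sim$labels, file.path(out_dir, "true_labels.csv"),
                       row.names = FALSE, quote = FALSE)
    } else {
      sim <- stage("simulate", generate_cohort(cohort, geometry,
                                               duration = cfg$simulate$duration,
                                               fps = cfg$fps))
      trace_dir <- file.path(out_dir, "traces")
      stage("simulate", write_cohort(sim, trace_dir))
      cfg$traces <- trace_dir
      meta <- sim$metadata
    }
    utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE, quote = FALSE)
    manifest$stages$simulate <- list(n_fish = length(unique(meta$fish_id)),
                                     n_rows = nrow(meta))
  } else {
    if (is.null(cfg$metadata)) stop("pipeline stage 'load' failed: no metadata", call. = FALSE)
    meta <- utils::read.csv(cfg$metadata, colClasses = "character")
  }

  # --- extract --------------------------------------------------------------
  if (is.null(features)) {
    correction <- NULL
    if (!is.null(cfg$calibration)) {
      correction <- stage("extract",
                          fit_depth_correction(utils::read.csv(cfg$calibration)))
    }
    files <- list.files(cfg$traces, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!basename(files) %in% c("metadata.csv", "true_labels.csv")]
    traces <- stage("extract", lapply(files, read_trace))
    features <- stage("extract",
                      extract_features_table(traces, geometry, correction,
                                             window = cfg$smoothing$window,
                                             order = cfg$smoothing$order))
  }
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$stages$extract <- list(n_rows = nrow(features))

  # --- cluster reference session --------------------------------------------
  sessions <- sort(unique(features$session))
  ref <- features[features$session == sessions[1], , drop = FALSE]
  model <- stage("cluster",
                 fit_cluster_model(ref, k = cfg$clustering$k,
                                   k_values = cfg$clustering$k_values,
                                   seed = manifest$seeds$cluster,
                                   method = cfg$clustering$method))
  save_cluster_model(model, file.path(out_dir, "model"))
  manifest$stages$cluster <- list(k = model$k,
                                  n_communities = length(unique(model$labels)),
                                  n_min = model$n_min, m_assign = model$m_assign)

  # --- assign all sessions ---------------------------------------------------
  labels <- do.call(rbind, lapply(sessions, function(s) {
    rows <- features[features$session == s, , drop = FALSE]
    lab <- if (s == sessions[1]) {
      model$labels[match(as.character(rows$fish_id), names(model$labels))]
    } else {
      stage("assign", assign_clusters(model, rows))
    }
    data.frame(fish_id = rows$fish_id, session = s, cluster = as.integer(lab),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$stages$assign <- list(n_rows = nrow(labels),
                                 n_sessions = length(sessions))

  # --- stats ------------------------------------------------------------------
  m <- cfg$stats$m
  seed_stats <- manifest$seeds$stats
  stats_rows <- list()
  for (s in sessions) {
    lab_s <- labels[labels$session == s, ]
    meta_s <- meta[meta$session == s, ]
    idx <- match(lab_s$fish_id, meta_s$fish_id)
    if (anyNA(idx)) next
    rep_res <- stage("stats",
                     representation_test(lab_s$cluster,
                                         paste(meta_s$strain[idx], meta_s$sex[idx],
                                               sep = ":"),
                                         m = m, seed = seed_stats))
    stats_rows[[length(stats_rows) + 1L]] <-
      data.frame(test = sprintf("representation_session%s", s),
                 effect_or_cell = paste(rep_res$group, rep_res$cluster, sep = "|"),
                 observed = rep_res$observed, p = rep_res$p,
                 p_adjusted = rep_res$p_adjusted, m = m, seed = seed_stats,
                 stringsAsFactors = FALSE)
  }
  if (length(sessions) >= 2L) {
    wide <- stats::reshape(labels, idvar = "fish_id", timevar = "session",
                           direction = "wide")
    lab_mat <- as.matrix(wide[, -1, drop = FALSE])
    complete <- stats::complete.cases(lab_mat)
    dropped <- sum(!complete)
    if (dropped > 0) {
      manifest$warnings <- c(manifest$warnings,
                             sprintf("%d fish excluded from overlap stats (missing sessions)",
                                     dropped))
    }
    lab_mat <- lab_mat[complete, , drop = FALSE]
    if (length(sessions) == 2L) {
      ov <- stage("stats", two_day_overlap(lab_mat[, 1], lab_mat[, 2],
                                           m = m, seed = seed_stats))
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(test = "two_day_overlap", effect_or_cell = "percent_overlap",
                   observed = ov$percent_overlap, p = ov$result$p,
                   p_adjusted = NA_real_, m = m, seed = seed_stats,
                   stringsAsFactors = FALSE)
    } else {
      ov <- stage("stats", overlap_test(lab_mat, m = m, seed = seed_stats))
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(test = "overlap_score", effect_or_cell = "mean_overlap",
                   observed = ov$observed, p = ov$p, p_adjusted = NA_real_,
                   m = m, seed = seed_stats, stringsAsFactors = FALSE)
    }
  }
  stats_df <- do.call(rbind, stats_rows)
  utils::write.csv(stats_df, file.path(out_dir, "stats.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$stages$stats <- list(n_rows = nrow(stats_df))

  manifest$versions <- list(fishclust = as.character(utils::packageVersion("fishclust")),
                            R = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}
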