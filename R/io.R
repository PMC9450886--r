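# Stable CSV interchange formats: traces (frame,t_s,x_cm,y_cm,z_cm), metadata
# (fish_id,strain,sex,session), features, labels, and the serialized cluster
# model directory.

#' Write and read swim trace CSV files
#'
#' One file per fish-session, named `<fish_id>_<session>.csv`, with header
#' `frame,t_s,x_cm,y_cm,z_cm`.
#'
#' @param trace A [swim_trace()].
#' @param dir Output directory (created if needed).
#' @return The path written, invisibly.
#' @export
write_trace <- function(trace, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s.csv", attr(trace, "fish_id"),
                                 attr(trace, "session")))
  df <- data.frame(frame = seq_len(nrow(trace)) - 1L, t_s = trace$t,
                   x_cm = trace$x, y_cm = trace$y, z_cm = trace$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trace
#' @param path Trace CSV path; fish id and session are parsed from the
#'   file name.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "t_s", "x_cm", "y_cm", "z_cm")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s: expected header %s", path, paste(need, collapse = ",")),
         call. = FALSE)
  }
  base <- sub("\\.csv$", "", basename(path))
  session <- sub("^.*_", "", base)
  fish_id <- sub("_[^_]*$", "", base)
  swim_trace(df$t_s, df$x_cm, df$y_cm, df$z_cm,
             fish_id = fish_id, session = session)
}

#' Write a cohort of traces plus metadata
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in cohort$traces) write_trace(tr, dir)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$labels)) {
    utils::write.csv(cohort$labels, file.path(dir, "true_labels.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Serialize / load a fitted cluster model
#'
#' The model directory holds `params.json` (standardization parameters, k,
#' seed, similarity form, m_assign), `edges.csv` (`i,j,weight`), `labels.csv`
#' (`fish_id,cluster`) and `reference_features.csv` (the standardized reference
#' feature matrix needed for out-of-sample assignment).
#'
#' @param model A [fit_cluster_model()] result.
#' @param dir Model directory.
#' @return `dir` (or the reloaded `cluster_model` for [load_cluster_model()]).
#' @export
save_cluster_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- list(mean = as.list(model$params$mean), sd = as.list(model$params$sd),
                 k = model$k, seed = model$seed, method = model$method,
                 n_min = model$n_min, m_assign = model$m_assign)
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  el <- igraph::as_data_frame(model$graph, what = "edges")
  names(el) <- c("i", "j", "weight")
  utils::write.csv(el, file.path(dir, "edges.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(fish_id = names(model$labels),
                              cluster = as.integer(model$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  ref <- data.frame(fish_id = rownames(model$standardized), model$standardized)
  utils::write.csv(ref, file.path(dir, "reference_features.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname save_cluster_model
#' @export
load_cluster_model <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  el <- utils::read.csv(file.path(dir, "edges.csv"))
  labs <- utils::read.csv(file.path(dir, "labels.csv"),
                          colClasses = c(fish_id = "character"))
  ref <- utils::read.csv(file.path(dir, "reference_features.csv"),
                         colClasses = c(fish_id = "character"))
  std <- as.matrix(ref[, feature_cols()])
  rownames(std) <- ref$fish_id
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = labs$fish_id))
  names(el)[3] <- "weight"
  igraph::E(g)$weight <- el$weight
  g$k <- params$k
  labels <- labs$cluster
  names(labels) <- labs$fish_id
  structure(list(standardized = std,
                 params = list(mean = unlist(params$mean), sd = unlist(params$sd)),
                 graph = g, labels = labels, k = params$k, seed = params$seed,
                 method = params$method, n_min = params$n_min,
                 m_assign = params$m_assign, scan = NULL),
            class = "cluster_model")
}

#' Validate pipeline input files
#'
#' Checks trace CSV headers, monotone frame times, coordinate ranges, metadata
#' vocabulary (strain in AB/TL/TU/WIK, sex in F/M after whitespace
#' normalization) and lists fish with missing sessions. Reports issues; never
#' throws.
#'
#' @param trace_dir Directory of trace CSVs (optional).
#' @param meta_file Metadata CSV path (optional).
#' @param geometry A [tank_geometry()] used for range checks.
#' @return Data frame report with columns `severity`, `where`, `issue`.
#' @export
validate_inputs <- function(trace_dir = NULL, meta_file = NULL,
                            geometry = tank_geometry()) {
  issues <- list()
  note <- function(severity, where, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(severity = severity,
                                                 where = where, issue = issue,
                                                 stringsAsFactors = FALSE)
  }
  meta <- NULL
  if (!is.null(meta_file)) {
    if (!file.exists(meta_file)) {
      note("error", meta_file, "metadata file not found")
    } else {
      meta <- utils::read.csv(meta_file, colClasses = "character")
      need <- c("fish_id", "strain", "sex", "session")
      if (!all(need %in% names(meta))) {
        note("error", meta_file, paste("missing columns:",
                                       paste(setdiff(need, names(meta)), collapse = ", ")))
        meta <- NULL
      } else {
        raw_strain <- meta$strain
        meta$strain <- trimws(meta$strain)
        meta$sex <- trimws(meta$sex)
        if (any(raw_strain != meta$strain)) {
          note("warning", meta_file, "strain values carried surrounding whitespace; normalized")
        }
        bad <- unique(meta$strain[!meta$strain %in% c("AB", "TL", "TU", "WIK")])
        if (length(bad) > 0) {
          note("error", meta_file, paste("unknown strain value(s):", paste(bad, collapse = ", ")))
        }
        bad_sex <- unique(meta$sex[!meta$sex %in% c("F", "M")])
        if (length(bad_sex) > 0) {
          note("error", meta_file, paste("unknown sex value(s):", paste(bad_sex, collapse = ", ")))
        }
        sess <- table(meta$fish_id)
        if (length(unique(sess)) > 1L) {
          short <- names(sess)[sess < max(sess)]
          for (f in short) note("warning", f, "fish is missing one or more sessions")
        }
      }
    }
  }
  if (!is.null(trace_dir)) {
    files <- list.files(trace_dir, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!basename(files) %in% c("metadata.csv", "true_labels.csv")]
    if (length(files) == 0L) note("error", trace_dir, "no trace CSV files found")
    for (f in files) {
      df <- tryCatch(utils::read.csv(f), error = function(e) NULL)
      if (is.null(df)) { note("error", f, "unreadable CSV"); next }
      need <- c("frame", "t_s", "x_cm", "y_cm", "z_cm")
      if (!all(need %in% names(df))) {
        note("error", f, paste("expected header", paste(need, collapse = ",")))
        next
      }
      if (any(diff(df$t_s) <= 0)) {
        note("error", f, sprintf("non-monotone t_s at row %d",
                                 which(diff(df$t_s) <= 0)[1] + 1L))
      }
      xy_out <- df$x_cm < 0 | df$x_cm > geometry$side |
        df$y_cm < 0 | df$y_cm > geometry$side
      if (any(xy_out, na.rm = TRUE)) {
        note("warning", f, sprintf("%d frame(s) outside tank bounds", sum(xy_out, na.rm = TRUE)))
      }
      if (!is.null(meta)) {
        base <- sub("\\.csv$", "", basename(f))
        session <- sub("^.*_", "", base)
        fish_id <- sub("_[^_]*$", "", base)
        if (!any(meta$fish_id == fish_id & meta$session == session)) {
          note("warning", f, "trace has no matching metadata row")
        }
      }
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(severity = character(0), where = character(0),
                      issue = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
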