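# Internal helpers shared across modules.

# Feature column names used throughout the package, in canonical order.
feature_cols <- function() c("bottom_cm", "center_cm", "distance_cm", "percent_explored")

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Extract the 4-column numeric feature matrix from a data frame or matrix,
# keeping row identifiers when present.
as_feature_matrix <- function(features) {
  if (is.matrix(features)) {
    m <- features
    if (is.null(colnames(m))) colnames(m) <- feature_cols()
  } else if (is.data.frame(features)) {
    missing <- setdiff(feature_cols(), names(features))
    if (length(missing) > 0) {
      stop("feature table is missing columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    m <- as.matrix(features[, feature_cols(), drop = FALSE])
    if ("fish_id" %in% names(features)) {
      ids <- as.character(features$fish_id)
      if ("session" %in% names(features) && anyDuplicated(ids) > 0) {
        ids <- paste(ids, features$session, sep = "@")
      }
      rownames(m) <- ids
    }
  } else {
    stop("`features` must be a matrix or data frame", call. = FALSE)
  }
  if (!is.numeric(m)) stop("feature values must be numeric", call. = FALSE)
  if (any(!is.finite(m))) stop("feature values must be finite", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m
}
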