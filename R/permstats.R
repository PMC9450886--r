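#' Permutation p-value
#'
#' Add-one permutation p-value: `p = (b + 1) / (m + 1)` where `b` counts null
#' statistics at least as extreme as the observed one. The two-sided value
#' doubles the smaller tail and is capped at 1. The resolution floor is
#' `1 / (m + 1)`; with the conventional m = 10,000 resamples the smallest
#' reportable p rounds to 0.0001.
#'
#' @param observed Observed statistic (finite scalar).
#' @param null_sample Numeric vector of permutation statistics.
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @return p-value in (0, 1].
#' @examples
#' perm_p(5, rnorm(999), "greater")
#' @export
perm_p <- function(observed, null_sample,
                   alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_scalar(observed, "observed")
  if (length(null_sample) == 0L) stop("`null_sample` is empty", call. = FALSE)
  m <- length(null_sample)
  p_greater <- (sum(null_sample >= observed) + 1) / (m + 1)
  p_less <- (sum(null_sample <= observed) + 1) / (m + 1)
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two_sided = min(1, 2 * min(p_greater, p_less)))
}

# Internal constructor for permutation test results.
perm_result <- function(observed, null_sample, p, seed, statistic = "statistic",
                        alternative = "two_sided") {
  structure(list(observed = observed, null_sample = null_sample,
                 m = length(null_sample), p = p, p_adjusted = NA_real_,
                 seed = seed, statistic = statistic, alternative = alternative),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s): observed = %.6g, p = %.4g (m = %d, seed = %s)\n",
              x$statistic, x$alternative, x$observed, x$p, x$m, format(x$seed)))
  cat(sprintf("  null mean %.6g, sd %.6g\n", mean(x$null_sample),
              stats::sd(x$null_sample)))
  invisible(x)
}

#' Strain-by-sex cluster representation test
#'
#' Tests whether each (group, cluster) cell of the contingency table holds more
#' or fewer fish than expected by chance. The null is built by permuting the
#' cluster-label vector across all fish (group memberships fixed); per-cell
#' two-sided p-values double the smaller tail, and Benjamini-Hochberg FDR is
#' applied across all cells.
#'
#' @param clusters Cluster label per fish (factor or vector).
#' @param groups Group per fish (e.g. `interaction(strain, sex)`).
#' @param m Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @return Data frame with one row per (group, cluster): `group`, `cluster`,
#'   `observed`, `expected` (null mean), `direction`, `p`, `p_adjusted`.
#' @export
representation_test <- function(clusters, groups, m = 10000L, seed = 1) {
  if (length(clusters) != length(groups)) {
    stop("`clusters` and `groups` must have equal length", call. = FALSE)
  }
  if (length(clusters) == 0L) stop("empty table", call. = FALSE)
  if (anyNA(clusters) || anyNA(groups)) stop("missing labels", call. = FALSE)
  gf <- factor(groups); cf <- factor(clusters)
  gi <- as.integer(gf); ci <- as.integer(cf)
  G <- nlevels(gf); C <- nlevels(cf)
  ncell <- G * C
  obs <- tabulate((ci - 1L) * G + gi, ncell)
  null_counts <- with_seed(seed, {
    vapply(seq_len(m), function(r) {
      cir <- ci[sample.int(length(ci))]
      tabulate((cir - 1L) * G + gi, ncell)
    }, integer(ncell))
  })
  ge <- rowSums(null_counts >= obs)
  le <- rowSums(null_counts <= obs)
  p_greater <- (ge + 1) / (m + 1)
  p_less <- (le + 1) / (m + 1)
  p <- pmin(1, 2 * pmin(p_greater, p_less))
  expected <- rowMeans(null_counts)
  out <- data.frame(group = rep(levels(gf), C),
                    cluster = rep(levels(cf), each = G),
                    observed = obs, expected = expected,
                    direction = ifelse(obs >= expected, "over", "under"),
                    p = p, p_adjusted = fdr_adjust(p),
                    stringsAsFactors = FALSE)
  attr(out, "m") <- m; attr(out, "seed") <- seed
  out
}

#' Longitudinal overlap score of one fish
#'
#' Number of unordered pairs of exposures assigned to the same cluster: with 5
#' exposures it ranges from 1 (a single matching pair is forced with 4
#' clusters) to 10 (all pairs match); with 6 exposures, from 2 to 15.
#'
#' @param assignments Vector of cluster labels, one per exposure (>= 2).
#' @return Integer pair count.
#' @examples
#' overlap_score(c("A", "A", "A", "A", "A"))  # 10
#' overlap_score(c("A", "B", "C", "D", "A"))  # 1
#' @export
overlap_score <- function(assignments) {
  if (length(assignments) < 2L) stop("need >= 2 exposures", call. = FALSE)
  if (anyNA(assignments)) stop("missing cluster label", call. = FALSE)
  sum(choose(table(assignments), 2))
}

# Vectorized mean overlap score over the rows of a label matrix.
mean_overlap <- function(M, labels) {
  total <- 0
  for (l in labels) {
    cnt <- rowSums(M == l)
    total <- total + sum(cnt * (cnt - 1) / 2)
  }
  total / nrow(M)
}

#' Permutation test of longitudinal cluster consistency
#'
#' Observed statistic: the mean per-fish overlap score across all exposures.
#' Null: every exposure column except the first is independently permuted
#' across fish (without replacement) and the mean score recomputed; the
#' one-sided p asks whether fish are more consistent than chance.
#'
#' @param assignment_matrix Fish x exposures matrix (or data frame) of cluster
#'   labels.
#' @param m Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @return A `perm_result` with extra elements `scores` (per-fish observed
#'   overlap scores) and `null_mean`/`null_sd`.
#' @export
overlap_test <- function(assignment_matrix, m = 10000L, seed = 1) {
  M <- as.matrix(assignment_matrix)
  if (nrow(M) < 2L) stop("need more than one fish", call. = FALSE)
  if (ncol(M) < 2L) stop("need >= 2 exposures", call. = FALSE)
  if (anyNA(M)) stop("missing cluster label", call. = FALSE)
  labels <- sort(unique(as.vector(M)))
  observed <- mean_overlap(M, labels)
  n <- nrow(M); E <- ncol(M)
  null_sample <- with_seed(seed, {
    vapply(seq_len(m), function(r) {
      Mp <- M
      for (j in 2:E) Mp[, j] <- M[sample.int(n), j]
      mean_overlap(Mp, labels)
    }, numeric(1))
  })
  res <- perm_result(observed, null_sample,
                     perm_p(observed, null_sample, "greater"), seed,
                     statistic = "mean overlap score", alternative = "greater")
  res$scores <- apply(M, 1, overlap_score)
  res$null_mean <- mean(null_sample)
  res$null_sd <- stats::sd(null_sample)
  res
}

#' Two-session cluster overlap test
#'
#' Percent of fish assigned to the same cluster in both sessions, against a
#' null that permutes the second session's labels across fish. Reports the
#' null mean (the "permutation average" overlap).
#'
#' @param labels_day1,labels_day2 Cluster labels, equal length.
#' @param m Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @return List with `percent_overlap`, `null_mean_percent`, and `result`
#'   (a `perm_result` with one-sided p).
#' @export
two_day_overlap <- function(labels_day1, labels_day2, m = 10000L, seed = 1) {
  if (length(labels_day1) != length(labels_day2)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (anyNA(labels_day1) || anyNA(labels_day2)) stop("missing labels", call. = FALSE)
  n <- length(labels_day1)
  observed <- 100 * mean(labels_day1 == labels_day2)
  null_sample <- with_seed(seed, {
    vapply(seq_len(m), function(r) {
      100 * mean(labels_day1 == labels_day2[sample.int(n)])
    }, numeric(1))
  })
  res <- perm_result(observed, null_sample,
                     perm_p(observed, null_sample, "greater"), seed,
                     statistic = "percent same-cluster", alternative = "greater")
  list(percent_overlap = observed, null_mean_percent = mean(null_sample),
       result = res)
}

# Welch t statistic; 0 when the mean difference is 0 even if the spread is 0.
welch_t <- function(x, y) {
  num <- mean(x) - mean(y)
  if (num == 0) return(0)
  den <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  if (den == 0) return(sign(num) * Inf)
  num / den
}

one_sample_t <- function(d) {
  num <- mean(d)
  if (num == 0) return(0)
  den <- stats::sd(d) / sqrt(length(d))
  if (den == 0) return(sign(num) * Inf)
  num / den
}

#' Permutation t-test
#'
#' Unpaired: Welch t with a group-label-shuffling null. Paired: one-sample t of
#' the differences with a sign-flipping null. Two-sided p by default.
#'
#' @param x,y Numeric samples; equal length when `paired`.
#' @param paired Logical.
#' @param m Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @param alternative Passed to [perm_p()].
#' @return A `perm_result`.
#' @export
perm_t_test <- function(x, y, paired = FALSE, m = 10000L, seed = 1,
                        alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group", call. = FALSE)
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
    d <- x - y
    observed <- one_sample_t(d)
    null_sample <- with_seed(seed, {
      vapply(seq_len(m), function(r) {
        one_sample_t(d * sample(c(-1, 1), length(d), replace = TRUE))
      }, numeric(1))
    })
  } else {
    pooled <- c(x, y)
    nx <- length(x)
    observed <- welch_t(x, y)
    null_sample <- with_seed(seed, {
      vapply(seq_len(m), function(r) {
        idx <- sample.int(length(pooled), nx)
        welch_t(pooled[idx], pooled[-idx])
      }, numeric(1))
    })
  }
  perm_result(observed, null_sample, perm_p(observed, null_sample, alternative),
              seed, statistic = if (paired) "paired t" else "Welch t",
              alternative = alternative)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (monotone, capped at 1), with the input range
#' checked: permutation p-values are always in (0, 1].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman correlation with a bootstrap confidence interval
#'
#' Spearman's rank correlation with a percentile bootstrap CI over paired
#' resamples.
#'
#' @param x,y Numeric vectors, equal length >= 4, non-constant.
#' @param n_boot Bootstrap resamples (default 10,000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `rho`, `ci` (length 2), `n_boot`, `seed`.
#' @export
spearman_ci <- function(x, y, n_boot = 10000L, seed = 1, conf = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 4L) stop("need n >= 4", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  alpha <- (1 - conf) / 2
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (stats::sd(xb) == 0 || stats::sd(yb) == 0) return(NA_real_)
      stats::cor(xb, yb, method = "spearman")
    }, numeric(1))
  })
  boot <- boot[!is.na(boot)]
  list(rho = rho,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n_boot = n_boot, seed = seed)
}
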