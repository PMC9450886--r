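#' Reference-anchored feature standardization
#'
#' Centers and scales each of the four features. When `params` is supplied
#' (e.g. from a reference cohort) those means and s.d.s are used unchanged, so
#' new sessions are placed in the reference cohort's standardized space.
#'
#' @param features Feature table (data frame with the four feature columns,
#'   plus optional `fish_id`/`session`) or numeric matrix.
#' @param params Optional list with `mean` and `sd` vectors from a previous
#'   call.
#' @return List with `standardized` (numeric matrix, rownames = fish ids) and
#'   `params`.
#' @export
standardize_features <- function(features, params = NULL) {
  m <- as_feature_matrix(features)
  if (is.null(params)) {
    if (nrow(m) < 2L) stop("need >= 2 rows to estimate standardization", call. = FALSE)
    mu <- colMeans(m)
    sigma <- apply(m, 2, stats::sd)
    if (any(sigma == 0)) {
      stop("zero variance in at least one feature; supply `params`", call. = FALSE)
    }
    params <- list(mean = mu, sd = sigma)
  } else {
    if (!all(c("mean", "sd") %in% names(params)) || any(params$sd <= 0)) {
      stop("`params` must contain positive `sd` and `mean` vectors", call. = FALSE)
    }
  }
  std <- sweep(sweep(m, 2, params$mean), 2, params$sd, "/")
  list(standardized = std, params = params)
}

#' Pairwise similarity between fish
#'
#' Similarity between fish i and j is a strictly decreasing map of their
#' Euclidean distance D in standardized 4-D behavioral space: `1/(1 + D)`
#' (default) or `exp(-D)`. Either way `S = 1` iff `D = 0` and `S` is in (0, 1].
#'
#' @param standardized Numeric matrix of standardized features (rows = fish).
#' @param method `"inverse"` for `1/(1+D)`, `"exponential"` for `exp(-D)`.
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
similarity_matrix <- function(standardized, method = c("inverse", "exponential")) {
  method <- match.arg(method)
  if (any(!is.finite(standardized))) stop("features must be finite", call. = FALSE)
  D <- as.matrix(stats::dist(standardized))
  S <- if (method == "inverse") 1 / (1 + D) else exp(-D)
  diag(S) <- 1
  S
}

# Cross-similarity between new rows and reference rows.
cross_similarity <- function(new_std, ref_std, method = c("inverse", "exponential")) {
  method <- match.arg(method)
  d2 <- outer(rowSums(new_std^2), rowSums(ref_std^2), "+") -
    2 * new_std %*% t(ref_std)
  D <- sqrt(pmax(d2, 0))
  if (method == "inverse") 1 / (1 + D) else exp(-D)
}

#' Build a similarity-weighted k-nearest-neighbor graph
#'
#' Each fish is linked to its `k` most similar fish; the edge set is the union
#' over both directions (so minimum degree is `k`) and edges carry the
#' similarity as weight. Nodes are ordered by sorted node id, and similarity
#' ties are broken toward the lower index in that ordering, making the graph
#' invariant to the row order of the input.
#'
#' @param similarities Symmetric similarity matrix with row/col names as node
#'   ids (defaults to row numbers).
#' @param k Neighbors per node, `1 <= k < n`.
#' @return An undirected weighted [igraph::graph] with a `k` attribute.
#' @export
build_knn_graph <- function(similarities, k) {
  n <- nrow(similarities)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("`k` must satisfy 1 <= k < n", call. = FALSE)
  ids <- rownames(similarities)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(ids)
  S <- similarities[ord, ord, drop = FALSE]
  ids <- ids[ord]
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(s, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(k)]
    from <- c(from, rep.int(i, k)); to <- c(to, nb)
  }
  # union symmetrization: keep each unordered pair once
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  g <- igraph::add_edges(g, rbind(a, b))
  igraph::E(g)$weight <- S[cbind(a, b)]
  g$k <- k
  g
}

#' Louvain community detection with a fixed seed
#'
#' Greedy modularity maximization on the weighted, undirected k-NN graph. The
#' node-visit order is randomized from `seed`, so a fixed seed gives a fixed
#' partition. Communities are relabeled 1, 2, ... by decreasing size (ties by
#' smallest member id).
#'
#' @param graph Weighted undirected [igraph::graph].
#' @param seed Integer seed.
#' @return Named integer vector of community labels (names = node ids).
#' @export
louvain_partition <- function(graph, seed = 1) {
  if (igraph::vcount(graph) == 0L) stop("graph is empty", call. = FALSE)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(graph)))
  relabel_by_size(as.integer(memb), igraph::V(graph)$name)
}

# Relabel integer communities by decreasing size; ties broken by the smallest
# node id they contain. Returns a named vector.
relabel_by_size <- function(memb, ids) {
  sizes <- table(memb)
  first_id <- vapply(names(sizes), function(cl) min(ids[memb == as.integer(cl)]),
                     character(1))
  ord <- order(-as.integer(sizes), first_id)
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(ord)
  out <- new_id[match(memb, as.integer(names(sizes)))]
  names(out) <- ids
  out
}

#' Internal clustering validity indices
#'
#' Calinski-Harabasz (higher better), mean Silhouette width (higher better, via
#' \pkg{cluster}) and Davies-Bouldin (lower better), computed on the
#' standardized feature point cloud against a partition. All are `NA` when the
#' partition has a single community.
#'
#' @param standardized Numeric feature matrix.
#' @param labels Integer community labels, one per row.
#' @return Named numeric vector `c(ch, silhouette, db)`.
#' @export
cluster_indices <- function(standardized, labels) {
  k <- length(unique(labels))
  n <- nrow(standardized)
  if (k < 2L || k >= n) return(c(ch = NA_real_, silhouette = NA_real_, db = NA_real_))
  centroids <- rowsum(standardized, labels) / as.vector(table(labels))
  grand <- colMeans(standardized)
  sizes <- as.vector(table(labels))
  bss <- sum(sizes * rowSums(sweep(centroids, 2, grand)^2))
  wss <- sum((standardized - centroids[as.character(labels) |>
                                         match(rownames(centroids)), ])^2)
  ch <- (bss / (k - 1)) / (wss / (n - k))
  sil <- mean(cluster::silhouette(labels, stats::dist(standardized))[, 3])
  # Davies-Bouldin: mean over clusters of the worst (s_i + s_j) / d_ij
  idx <- match(as.character(labels), rownames(centroids))
  disp <- sqrt(rowsum(rowSums((standardized - centroids[idx, ])^2), labels) / sizes)
  cd <- as.matrix(stats::dist(centroids))
  r <- outer(disp[, 1], disp[, 1], "+") / cd
  diag(r) <- -Inf
  db <- mean(apply(r, 1, max))
  c(ch = ch, silhouette = sil, db = db)
}

#' Scan candidate k values for the k-NN graph
#'
#' For each `k`, builds the graph, runs Louvain, and scores the partition with
#' the three internal validity indices on the standardized point cloud.
#'
#' @param features Feature table or matrix (raw; standardized internally
#'   unless `params` given).
#' @param k_values Integer vector of candidate k.
#' @param seed Seed for the Louvain visit order.
#' @param method Similarity form, see [similarity_matrix()].
#' @param params Optional standardization parameters.
#' @return Data frame `k, n_communities, ch, silhouette, db` (class `k_scan`).
#' @export
scan_k <- function(features, k_values, seed = 1,
                   method = c("inverse", "exponential"), params = NULL) {
  method <- match.arg(method)
  if (length(k_values) == 0L) stop("`k_values` is empty", call. = FALSE)
  std <- standardize_features(features, params)$standardized
  S <- similarity_matrix(std, method)
  # index computation uses rows in the graph's (sorted-id) order
  ord <- order(rownames(std))
  std_sorted <- std[ord, , drop = FALSE]
  rows <- lapply(as.integer(k_values), function(k) {
    g <- build_knn_graph(S, k)
    lab <- louvain_partition(g, seed)
    idx <- cluster_indices(std_sorted, lab)
    data.frame(k = k, n_communities = length(unique(lab)),
               ch = idx["ch"], silhouette = idx["silhouette"], db = idx["db"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("k_scan", "data.frame")
  out
}

#' Choose k from a scan: middle of the best stable regime
#'
#' Ranks every scanned k by the mean rank of the three indices (CH and
#' Silhouette descending, Davies-Bouldin ascending), keeps the ks whose
#' combined rank falls in the best `1/window` quantile, finds the longest
#' contiguous run of kept ks over which the community count is constant, and
#' returns the run's midpoint. Deterministic; if no such run of length >= 2
#' exists, the single best-ranked k is returned with a warning.
#'
#' @param scan A [scan_k()] result.
#' @param window Inverse quantile width of the "optimal" band (default 5, i.e.
#'   the top 20 percent of combined ranks).
#' @return A single k.
#' @export
select_k <- function(scan, window = 5) {
  if (nrow(scan) == 0L) stop("scan is empty", call. = FALSE)
  scan <- scan[order(scan$k), , drop = FALSE]
  defined <- is.finite(scan$ch) & is.finite(scan$silhouette) & is.finite(scan$db)
  if (!any(defined)) stop("no scanned k produced >= 2 communities", call. = FALSE)
  combined <- rowMeans(cbind(rank(-scan$ch, na.last = "keep"),
                             rank(-scan$silhouette, na.last = "keep"),
                             rank(scan$db, na.last = "keep")))
  cutoff <- stats::quantile(combined[defined], 1 / window, names = FALSE)
  eligible <- defined & combined <= cutoff
  # longest contiguous run of eligible rows with constant community count
  best_run <- integer(0)
  run <- integer(0)
  for (i in seq_len(nrow(scan))) {
    extend <- eligible[i] &&
      (length(run) == 0L ||
         scan$n_communities[i] == scan$n_communities[run[1]])
    run <- if (extend) c(run, i) else if (eligible[i]) i else integer(0)
    if (length(run) > length(best_run)) best_run <- run
  }
  if (length(best_run) < 2L) {
    warning("no stable k regime found; returning the single best-ranked k",
            call. = FALSE)
    return(scan$k[defined][which.min(combined[defined])])
  }
  scan$k[best_run[ceiling(length(best_run) / 2)]]
}

#' Fit the reference behavioral cluster model
#'
#' Full clustering procedure on a reference cohort: standardize the four
#' features, compute pairwise similarities, build the k-NN graph (scanning and
#' selecting k if not supplied), run Louvain, and record the assignment
#' neighbor count `m_assign = floor(n_min / 2)` where `n_min` is the size of
#' the smallest community.
#'
#' @param features Reference feature table (one row per fish).
#' @param k Neighbors per node; if `NULL`, chosen by [scan_k()] + [select_k()].
#' @param k_values Candidate ks for the scan when `k` is `NULL`.
#' @param seed Seed for the Louvain visit order.
#' @param method Similarity form.
#' @return An object of class `cluster_model`.
#' @export
fit_cluster_model <- function(features, k = NULL, k_values = NULL, seed = 1,
                              method = c("inverse", "exponential")) {
  method <- match.arg(method)
  std <- standardize_features(features)
  n <- nrow(std$standardized)
  scan <- NULL
  if (is.null(k)) {
    if (is.null(k_values)) {
      k_values <- unique(pmin(pmax(round(seq(0.02 * n, 0.5 * n, length.out = 15)), 2L),
                              n - 1L))
    }
    scan <- scan_k(features, k_values, seed = seed, method = method,
                   params = std$params)
    k <- select_k(scan)
  }
  S <- similarity_matrix(std$standardized, method)
  graph <- build_knn_graph(S, k)
  labels <- louvain_partition(graph, seed)
  n_min <- min(table(labels))
  m_assign <- max(1L, as.integer(floor(n_min / 2)))
  std_sorted <- std$standardized[match(names(labels), rownames(std$standardized)), ,
                                 drop = FALSE]
  structure(list(standardized = std_sorted, params = std$params, graph = graph,
                 labels = labels, k = k, seed = seed, method = method,
                 n_min = n_min, m_assign = m_assign, scan = scan),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("Behavioral cluster model: %d fish, k = %d, %d communities (sizes %s)\n",
              length(x$labels), x$k, length(sizes),
              paste(as.integer(sizes), collapse = "/")))
  cat(sprintf("  assignment neighbors m = %d (half the smallest community, n_min = %d)\n",
              x$m_assign, x$n_min))
  invisible(x)
}

#' Assign new fish-sessions to reference clusters
#'
#' Each new feature row is standardized with the reference parameters, its
#' `m_assign` most similar reference fish are found, and it takes the label
#' held by the largest share of those neighbors. Ties go to the tied community
#' with the larger total similarity, then to the lower community id.
#'
#' @param model A [fit_cluster_model()] result.
#' @param new_features Feature table or matrix for the new sessions.
#' @return Integer vector of cluster labels, one per new row (named by fish id
#'   when available).
#' @export
assign_clusters <- function(model, new_features) {
  if (!inherits(model, "cluster_model")) stop("`model` must be a cluster_model", call. = FALSE)
  new_std <- standardize_features(new_features, model$params)$standardized
  ref <- model$standardized
  m <- model$m_assign
  if (m > nrow(ref)) stop("m_assign exceeds the reference size", call. = FALSE)
  S <- cross_similarity(new_std, ref, model$method)
  labs <- model$labels[match(rownames(ref), names(model$labels))]
  out <- integer(nrow(new_std))
  for (i in seq_len(nrow(new_std))) {
    nb <- order(S[i, ], seq_len(ncol(S)), decreasing = c(TRUE, FALSE),
                method = "radix")[seq_len(m)]
    votes <- table(labs[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      totals <- vapply(top, function(cl) sum(S[i, nb][labs[nb] == as.integer(cl)]),
                       numeric(1))
      top <- top[totals == max(totals)]
      top <- top[order(as.integer(top))][1]
    }
    out[i] <- as.integer(top)
  }
  names(out) <- rownames(new_std)
  out
}

#' Name communities by their behavioral signature
#'
#' Attaches the four archetype names to numeric community ids by matching the
#' cluster-mean feature profile: lowest bottom distance + percent explored is
#' shy; highest center distance among the rest is the wall-hugger; highest
#' distance travelled + percent explored is the active explorer; highest bottom
#' distance with lowest center distance is bold. Requires exactly 4 clusters.
#'
#' @param model A fitted [fit_cluster_model()] with 4 communities.
#' @return Named character vector mapping community id to archetype name.
#' @export
name_clusters <- function(model) {
  labs <- model$labels
  if (length(unique(labs)) != 4L) {
    stop("semantic naming requires exactly 4 communities", call. = FALSE)
  }
  cm <- rowsum(model$standardized, labs) / as.vector(table(labs))
  nm <- rep(NA_character_, 4)
  shy <- which.min(cm[, "bottom_cm"] + cm[, "percent_explored"])
  nm[shy] <- "shy"
  act <- setdiff(order(cm[, "distance_cm"] + cm[, "percent_explored"],
                       decreasing = TRUE), shy)[1]
  nm[act] <- "active_explorer"
  rest <- setdiff(seq_len(4), c(shy, act))
  wall <- rest[which.max(cm[rest, "center_cm"])]
  nm[wall] <- "wall_hugger"
  nm[setdiff(rest, wall)] <- "bold"
  names(nm) <- rownames(cm)
  nm
}
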