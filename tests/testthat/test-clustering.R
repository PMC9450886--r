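# Graph construction, Louvain communities, k selection, and out-of-sample
# assignment.

test_that("standardization is reference-anchored", {
  sp <- small_cohort(n_per_cell = 6, seed = 1)
  f <- generate_feature_cohort(sp)$features
  std <- standardize_features(f)
  expect_equal(unname(colMeans(std$standardized)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(std$standardized, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # same data through stored params reproduces the matrix
  again <- standardize_features(f, std$params)
  expect_equal(again$standardized, std$standardized)
  # a fish at the reference means maps to the origin
  mean_fish <- as.data.frame(as.list(std$params$mean))
  z <- standardize_features(mean_fish, std$params)$standardized
  expect_equal(unname(z[1, ]), rep(0, 4))
  const <- f; const$bottom_cm <- 1
  expect_error(standardize_features(const), "zero variance")
})

test_that("similarity is a strictly decreasing map of distance with unit diagonal", {
  m <- rbind(a = c(0, 0, 0, 0), b = c(1, 0, 0, 0), c = c(3, 0, 0, 0),
             d = c(0, 0, 0, 0))
  S <- similarity_matrix(m)
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_equal(S["a", "d"], 1)      # identical fish
  expect_equal(S["a", "b"], 0.5)    # D = 1
  expect_equal(S["a", "c"], 0.25)   # D = 3
  expect_true(isSymmetric(S))
  Se <- similarity_matrix(m, method = "exponential")
  expect_equal(Se["a", "b"], exp(-1))
  expect_error(similarity_matrix(rbind(c(1, NA, 0, 0), c(0, 0, 0, 0))), "finite")
})

test_that("k-NN graph uses union symmetrization and deterministic tie-breaks", {
  # tight pair plus an outlier, k = 1
  S <- similarity_matrix(rbind(a = c(0, 0, 0, 0), b = c(0.1, 0, 0, 0),
                               c = c(5, 0, 0, 0)))
  g <- build_knn_graph(S, 1)
  edges <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(edges, c("a-b", "b-c"))
  # k = n - 1 gives the complete graph
  g <- build_knn_graph(S, 2)
  expect_equal(igraph::ecount(g), 3)
  # ties broken toward the lower node index in sorted-id order
  S <- matrix(0.2, 3, 3); diag(S) <- 1
  rownames(S) <- colnames(S) <- c("n1", "n2", "n3")
  S["n1", "n2"] <- S["n2", "n1"] <- 0.5
  S["n1", "n3"] <- S["n3", "n1"] <- 0.5  # n1 is tied between n2 and n3
  g <- build_knn_graph(S, 1)
  edges <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(edges, c("n1-n2", "n1-n3"))  # n1 picks n2 (tie), n3 picks n1
  expect_error(build_knn_graph(S, 3), "k")
})

test_that("Louvain recovers planted structure and is seed-stable", {
  # two 10-cliques joined by one edge
  g <- igraph::make_full_graph(10) + igraph::make_full_graph(10)
  g <- igraph::add_edges(g, c(1, 11))
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  igraph::E(g)$weight <- 1
  lab <- louvain_partition(g, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  # complete graph collapses to one community
  gc <- igraph::make_full_graph(12)
  igraph::V(gc)$name <- sprintf("v%02d", 1:12)
  igraph::E(gc)$weight <- 1
  expect_equal(length(unique(louvain_partition(gc, seed = 1))), 1)
  # same seed, same partition
  expect_identical(louvain_partition(g, seed = 99), louvain_partition(g, seed = 99))
  expect_error(louvain_partition(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("Louvain attains the exact maximum modularity on a tiny fixture", {
  # two 4-cliques joined by one edge; brute-force all partitions of 8 nodes
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- sprintf("v%d", 1:8)
  igraph::E(g)$weight <- 1
  best <- max(vapply(all_partitions(8), function(p) {
    igraph::modularity(g, p, weights = igraph::E(g)$weight)
  }, numeric(1)))
  lab <- louvain_partition(g, seed = 1)
  got <- igraph::modularity(g, lab[igraph::V(g)$name], weights = igraph::E(g)$weight)
  expect_equal(got, best, tolerance = 1e-9)
  # and beats the trivial partitions
  expect_gt(got, igraph::modularity(g, rep(1, 8), weights = igraph::E(g)$weight))
  expect_gt(got, igraph::modularity(g, 1:8, weights = igraph::E(g)$weight))
})

test_that("k scan scores partitions and select_k picks the stable regime", {
  f <- planted_features(c(30, 30, 30, 30), sep = 10, seed = 2)
  scan <- scan_k(f, k_values = seq(4, 40, by = 4), seed = 1)
  expect_equal(nrow(scan), 10)
  four <- scan$n_communities == 4
  expect_true(any(four))
  # CH is maximized and DB minimized where the 4 communities are found
  expect_equal(which.max(scan$ch) %in% which(four), TRUE)
  expect_equal(which.min(scan$db) %in% which(four), TRUE)
  k <- select_k(scan)
  expect_true(k %in% scan$k[four])
  # duplicated point-masses: silhouette 1 when 2 communities are returned
  pm <- planted_features(c(10, 10), sep = 20, seed = 3, sd = rep(1e-9, 4))
  scan2 <- scan_k(pm, k_values = c(3, 5, 9), seed = 1)
  two <- scan2$n_communities == 2
  expect_true(all(scan2$silhouette[two] > 0.999))
  # synthetic plateau: midpoint of the eligible constant-count run
  fake <- data.frame(k = 1:10, n_communities = c(2, 4, 4, 4, 4, 4, 2, 2, 2, 2),
                     ch = c(1, 10, 10, 10, 10, 10, 1, 1, 1, 1),
                     silhouette = c(.1, .9, .9, .9, .9, .9, .1, .1, .1, .1),
                     db = c(5, 1, 1, 1, 1, 1, 5, 5, 5, 5))
  class(fake) <- c("k_scan", "data.frame")
  expect_equal(select_k(fake), 4)  # run 2:6, midpoint k = 4
  # no plateau: single best k with a warning
  fake2 <- fake[c(1, 2, 7), ]
  expect_warning(k2 <- select_k(fake2), "no stable")
  expect_equal(k2, 2)
})

test_that("fitting records half the smallest community as assignment neighbors", {
  f <- planted_features(c(82, 100, 120, 124), sep = 12, seed = 4)
  model <- fit_cluster_model(f, k = 60, seed = 1)
  expect_equal(length(unique(model$labels)), 4)
  expect_equal(model$n_min, 82)
  expect_equal(model$m_assign, 41)
  expect_equal(ari(model$labels, attr(f, "truth")[match(names(model$labels), f$fish_id)]), 1)
  # determinism of the whole model
  model2 <- fit_cluster_model(f, k = 60, seed = 1)
  expect_identical(model$labels, model2$labels)
  expect_identical(model$params, model2$params)
  # labels are invariant to row order
  perm <- fishclust:::with_seed(9, sample(nrow(f)))
  model3 <- fit_cluster_model(f[perm, ], k = 60, seed = 1)
  expect_identical(model3$labels, model$labels)
})

test_that("planted two-cluster data is recovered exactly", {
  f <- planted_features(c(40, 60), sep = 12, seed = 5)
  model <- fit_cluster_model(f, seed = 1)  # index-selected k
  expect_equal(length(unique(model$labels)), 2)
  expect_equal(ari(model$labels, attr(f, "truth")[match(names(model$labels), f$fish_id)]), 1)
  # community 1 is the larger one
  expect_equal(unname(table(model$labels)["1"]), 60)
})

test_that("assignment votes among nearest reference neighbors with stated tie rules", {
  f <- planted_features(c(50, 50, 50, 50), sep = 12, seed = 6)
  model <- fit_cluster_model(f, k = 30, seed = 1)
  # a copy of a reference fish lands in its own cluster
  probe <- f[f$fish_id == "f0010", ]
  expect_equal(unname(assign_clusters(model, probe)),
               unname(model$labels["f0010"]))
  # self-assignment reproduces the model's own labels away from boundaries
  self <- assign_clusters(model, f)
  expect_gte(mean(self[names(model$labels)] == model$labels), 0.99)
  # deterministic symmetric tie: resolved toward the lower community id
  sym <- data.frame(fish_id = sprintf("s%d", 1:8))
  sym[fishclust:::feature_cols()] <-
    rbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(-1, 0, -1, 0), c(-1, 0, -1, 0),
          c(0, 1, 0, 1), c(0, 1, 0, 1), c(0, -1, 0, -1), c(0, -1, 0, -1))
  msym <- fit_cluster_model(sym, k = 1, seed = 1)
  center <- data.frame(fish_id = "probe")
  center[fishclust:::feature_cols()] <- as.list(colMeans(sym[, -1]))
  lab1 <- assign_clusters(msym, center)
  expect_identical(lab1, assign_clusters(msym, center))
  expect_equal(unname(lab1), min(unique(msym$labels)))
})

test_that("a persistent cohort keeps its cluster across sessions", {
  fc <- generate_feature_cohort(small_cohort(n_per_cell = 12, n_sessions = 2,
                                             persistence = 1, seed = 7))
  f1 <- fc$features[fc$features$session == 1, ]
  f2 <- fc$features[fc$features$session == 2, ]
  model <- fit_cluster_model(f1, k = 24, seed = 1)
  lab1 <- model$labels
  lab2 <- assign_clusters(model, f2)
  expect_gte(mean(lab1[names(lab2)] == lab2), 0.95)
})

test_that("cluster models round-trip through their serialized directory", {
  f <- planted_features(c(20, 20, 20, 20), sep = 12, seed = 8)
  model <- fit_cluster_model(f, k = 10, seed = 1)
  dir <- withr::local_tempdir()
  save_cluster_model(model, dir)
  expect_true(all(file.exists(file.path(dir, c("params.json", "edges.csv",
                                               "labels.csv", "reference_features.csv")))))
  re <- load_cluster_model(dir)
  expect_equal(re$labels, model$labels)
  expect_equal(re$params$mean, model$params$mean, tolerance = 1e-12)
  expect_equal(re$m_assign, model$m_assign)
  newf <- planted_features(c(5, 5, 5, 5), sep = 12, seed = 9)
  expect_identical(assign_clusters(re, newf), assign_clusters(model, newf))
  # semantic names attach by feature signature
  nm <- name_clusters(model)
  expect_setequal(nm, c("shy", "wall_hugger", "active_explorer", "bold"))
})
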