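# Shared fixtures, all built in code at test time.

geom15 <- function() tank_geometry()

# A small cohort design: 4 strains x 2 sexes, n fish per cell.
small_cohort <- function(n_per_cell = 5, n_sessions = 1, persistence = 0.39,
                         seed = 1, probs = default_archetype_probs()) {
  tab <- default_strain_sex_table()
  tab$n <- n_per_cell
  cohort_spec(strain_sex_table = tab, archetype_probs = probs,
              persistence = persistence, n_sessions = n_sessions, seed = seed)
}

# Uniform archetype mixture for Markov-agreement checks.
uniform_probs <- function() {
  p <- default_archetype_probs()
  p[, c("shy", "wall_hugger", "active_explorer", "bold")] <- 0.25
  p
}

# Archetype means rescaled so the minimum pairwise separation between centers
# is `sep` within-archetype standard deviations (keeps the default geometry of
# the four profiles, widens it).
separated_means <- function(sep = 12) {
  am <- default_archetype_means()
  grand <- colMeans(am$means)
  dev <- sweep(am$means, 2, grand)
  cur <- min(dist(sweep(sweep(dev, 2, grand, "+"), 2, am$sd, "/")))
  sweep(dev * (sep / cur), 2, grand, "+")
}

# Planted Gaussian feature table with given cluster sizes and separation.
planted_features <- function(sizes, sep = 12, seed = 1, sd = NULL) {
  am <- default_archetype_means()
  if (is.null(sd)) sd <- am$sd
  means <- separated_means(sep)[seq_along(sizes), , drop = FALSE]
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  feats <- fishclust:::with_seed(seed, {
    means[lab, , drop = FALSE] +
      matrix(rnorm(n * 4), n, 4) %*% diag(sd)
  })
  df <- data.frame(fish_id = sprintf("f%04d", seq_len(n)))
  df[fishclust:::feature_cols()] <- feats
  attr(df, "truth") <- lab
  df
}

# Independent brute-force pair counter for overlap scores.
brute_overlap <- function(v) {
  s <- 0L
  for (i in seq_len(length(v) - 1L)) {
    for (j in (i + 1L):length(v)) s <- s + (v[i] == v[j])
  }
  s
}

# All set partitions of 1..n as restricted growth strings (for the exact
# modularity oracle on tiny graphs).
all_partitions <- function(n) {
  out <- list()
  rec <- function(codes, maxc) {
    if (length(codes) == n) {
      out[[length(out) + 1L]] <<- codes
      return(invisible())
    }
    for (c in seq_len(maxc + 1L)) rec(c(codes, c), max(maxc, c))
  }
  rec(integer(0), 0L)
  out
}

# Adjusted Rand index between two labelings (closed form from the pair
# contingency table; independent of any clustering package).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
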