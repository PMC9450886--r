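#' Permutation ANOVA for between-subjects and mixed designs
#'
#' F statistics from the least-squares decomposition, with permutation nulls
#' per effect. Between-subjects designs (one or two factors, e.g. the 4 x 2
#' strain-by-sex analysis): Type II sums of squares; main effects permute the
#' response across all rows, the interaction permutes the residuals of the
#' additive model. Mixed designs (one between factor, one within factor with a
#' subject id, e.g. a 2 x 6 sex-by-time-interval analysis): classical
#' split-plot F ratios; the between effect permutes group labels across
#' subjects, while the within effect and the interaction permute each subject's
#' within-level order independently.
#'
#' @param data Data frame in long format.
#' @param response Name of the numeric response column.
#' @param between Character vector of one or two between-subject factor
#'   columns.
#' @param within Optional name of a single within-subject factor column;
#'   requires `subject` and one observation per subject-level combination.
#' @param subject Name of the subject id column (required with `within`).
#' @param m Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @return Data frame of class `perm_anova` with one row per effect:
#'   `effect`, `df1`, `df2`, `F`, `p`.
#' @examples
#' d <- data.frame(strain = rep(c("AB", "TL"), each = 20),
#'                 sex = rep(c("F", "M"), 20), y = rnorm(40))
#' perm_anova(d, "y", between = c("strain", "sex"), m = 99)
#' @export
perm_anova <- function(data, response, between, within = NULL, subject = NULL,
                       m = 10000L, seed = 1) {
  if (!response %in% names(data)) stop("response column not found", call. = FALSE)
  y <- data[[response]]
  if (anyNA(y) || !is.numeric(y)) stop("response must be numeric and complete", call. = FALSE)
  if (is.null(within)) {
    if (length(between) < 1L || length(between) > 2L) {
      stop("between-subjects designs support one or two factors", call. = FALSE)
    }
    perm_anova_between(data, y, between, m, seed)
  } else {
    if (length(between) != 1L || is.null(subject)) {
      stop("mixed designs need exactly one between factor and a subject id",
           call. = FALSE)
    }
    perm_anova_mixed(data, y, between, within, subject, m, seed)
  }
}

# Residual sum of squares of y against the column space spanned by Q.
rss_q <- function(y, Q) sum(y^2) - sum(crossprod(Q, y)^2)

perm_anova_between <- function(data, y, between, m, seed) {
  f <- lapply(between, function(v) {
    fac <- factor(data[[v]])
    if (anyNA(fac)) stop("missing factor levels", call. = FALSE)
    fac
  })
  names(f) <- between
  n <- length(y)
  if (length(f) == 1L) {
    A <- f[[1]]
    if (any(table(A) == 0)) stop("empty cells in the design", call. = FALSE)
    Qa <- qr.Q(qr(stats::model.matrix(~A)))
    df1 <- nlevels(A) - 1L
    df2 <- n - nlevels(A)
    f_stat <- function(yy) {
      rss_a <- rss_q(yy, Qa)
      ((sum(yy^2) - sum(yy)^2 / n - rss_a) / df1) / (rss_a / df2)
    }
    observed <- f_stat(y)
    null_sample <- with_seed(seed, {
      vapply(seq_len(m), function(r) f_stat(y[sample.int(n)]), numeric(1))
    })
    out <- data.frame(effect = between, df1 = df1, df2 = df2, F = observed,
                      p = perm_p(observed, null_sample, "greater"))
  } else {
    A <- f[[1]]; B <- f[[2]]
    if (any(table(A, B) == 0)) stop("empty cells in the design", call. = FALSE)
    Qa <- qr.Q(qr(stats::model.matrix(~A)))
    Qb <- qr.Q(qr(stats::model.matrix(~B)))
    Qab <- qr.Q(qr(stats::model.matrix(~A + B)))
    Qfull <- qr.Q(qr(stats::model.matrix(~A * B)))
    a <- nlevels(A); b <- nlevels(B)
    df <- c(a - 1L, b - 1L, (a - 1L) * (b - 1L))
    df2 <- n - a * b
    fs <- function(yy) {
      r_add <- rss_q(yy, Qab)
      r_full <- rss_q(yy, Qfull)
      mse <- r_full / df2
      c((rss_q(yy, Qb) - r_add) / df[1],
        (rss_q(yy, Qa) - r_add) / df[2],
        (r_add - r_full) / df[3]) / mse
    }
    observed <- fs(y)
    resid_add <- y - Qab %*% crossprod(Qab, y)
    nulls <- with_seed(seed, {
      main <- vapply(seq_len(m), function(r) fs(y[sample.int(n)])[1:2], numeric(2))
      inter <- vapply(seq_len(m), function(r) fs(resid_add[sample.int(n)])[3],
                      numeric(1))
      rbind(main, inter)
    })
    out <- data.frame(effect = c(between, paste(between, collapse = ":")),
                      df1 = df, df2 = df2, F = observed,
                      p = c(perm_p(observed[1], nulls[1, ], "greater"),
                            perm_p(observed[2], nulls[2, ], "greater"),
                            perm_p(observed[3], nulls[3, ], "greater")))
  }
  rownames(out) <- NULL
  attr(out, "m") <- m; attr(out, "seed") <- seed
  class(out) <- c("perm_anova", "data.frame")
  out
}

# Classical split-plot F ratios from a wide subjects x levels matrix.
# g: group index per subject. Returns c(F_between, F_within, F_interaction).
split_plot_f <- function(Y, g) {
  n <- nrow(Y); L <- ncol(Y); G <- length(unique(g))
  gm <- mean(Y)
  s_i <- rowMeans(Y)
  m_g <- as.vector(tapply(s_i, g, mean))
  n_g <- tabulate(g, G)
  l_j <- colMeans(Y)
  ss_b <- L * sum(n_g * (m_g - gm)^2)
  ss_subj <- L * sum((s_i - m_g[g])^2)
  ss_w <- n * sum((l_j - gm)^2)
  cell <- rowsum(Y, g) / n_g
  dev <- sweep(sweep(cell, 1, m_g), 2, l_j) + gm
  ss_int <- sum(n_g * rowSums(dev^2))
  resid <- Y - s_i - cell[g, , drop = FALSE] + m_g[g]
  ss_err <- sum(resid^2)
  df_b <- G - 1L; df_s <- n - G
  df_w <- L - 1L; df_i <- df_b * df_w; df_e <- df_s * df_w
  c(between = (ss_b / df_b) / (ss_subj / df_s),
    within = (ss_w / df_w) / (ss_err / df_e),
    interaction = (ss_int / df_i) / (ss_err / df_e))
}

perm_anova_mixed <- function(data, y, between, within, subject, m, seed) {
  sub <- factor(data[[subject]])
  wf <- factor(data[[within]])
  bf <- factor(data[[between]])
  L <- nlevels(wf)
  n <- nlevels(sub)
  if (any(table(sub, wf) != 1)) {
    stop("mixed designs need exactly one observation per subject and within level",
         call. = FALSE)
  }
  # one group per subject
  g_by_sub <- tapply(as.integer(bf), sub, unique)
  if (any(lengths(g_by_sub) != 1)) {
    stop("each subject must belong to a single between-factor level", call. = FALSE)
  }
  g <- as.integer(unlist(g_by_sub))
  if (any(tabulate(g, nlevels(bf)) == 0)) stop("empty cells in the design", call. = FALSE)
  Y <- matrix(NA_real_, n, L)
  Y[cbind(as.integer(sub), as.integer(wf))] <- y
  observed <- split_plot_f(Y, g)
  df_b <- nlevels(bf) - 1L; df_s <- n - nlevels(bf)
  df_w <- L - 1L; df_i <- df_b * df_w; df_e <- df_s * df_w
  nulls <- with_seed(seed, {
    nb <- vapply(seq_len(m), function(r) split_plot_f(Y, g[sample.int(n)])[1],
                 numeric(1))
    nwi <- vapply(seq_len(m), function(r) {
      Yp <- t(apply(Y, 1, function(row) row[sample.int(L)]))
      split_plot_f(Yp, g)[2:3]
    }, numeric(2))
    list(between = nb, within = nwi[1, ], interaction = nwi[2, ])
  })
  out <- data.frame(effect = c(between, within, paste(between, within, sep = ":")),
                    df1 = c(df_b, df_w, df_i),
                    df2 = c(df_s, df_e, df_e),
                    F = unname(observed),
                    p = c(perm_p(observed[1], nulls$between, "greater"),
                          perm_p(observed[2], nulls$within, "greater"),
                          perm_p(observed[3], nulls$interaction, "greater")))
  rownames(out) <- NULL
  attr(out, "m") <- m; attr(out, "seed") <- seed
  class(out) <- c("perm_anova", "data.frame")
  out
}
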