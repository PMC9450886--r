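#' Behavioral archetype specification
#'
#' Parameters of the correlated random-walk generator for one of the four
#' exploratory archetypes (shy, wall-hugger, active explorer, bold).
#'
#' @param name One of `"shy"`, `"wall_hugger"`, `"active_explorer"`, `"bold"`.
#' @param depth_pref Target height above the bottom, cm, in `[0, water_depth]`.
#' @param wall_affinity Dimensionless strength of the horizontal radial drift;
#'   positive values pull toward the walls, negative toward the center.
#' @param speed_mean,speed_sd Mean and s.d. of the per-frame swim speed, cm/s;
#'   `speed_mean` must be non-negative and `speed_sd >= 0`.
#' @param turn_persistence Directional autocorrelation of the heading,
#'   in `[0, 1)`. Larger values give straighter paths.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, depth_pref, wall_affinity, speed_mean,
                           speed_sd, turn_persistence) {
  name <- match.arg(name, c("shy", "wall_hugger", "active_explorer", "bold"))
  for (v in c(depth_pref, wall_affinity, speed_mean, speed_sd, turn_persistence)) {
    check_scalar(v, "archetype parameter")
  }
  if (speed_mean < 0) stop("`speed_mean` must be non-negative", call. = FALSE)
  if (speed_sd < 0) stop("`speed_sd` must be non-negative", call. = FALSE)
  if (turn_persistence < 0 || turn_persistence >= 1) {
    stop("`turn_persistence` must lie in [0, 1)", call. = FALSE)
  }
  if (depth_pref < 0) stop("`depth_pref` must be non-negative", call. = FALSE)
  structure(list(name = name, depth_pref = depth_pref,
                 wall_affinity = wall_affinity, speed_mean = speed_mean,
                 speed_sd = speed_sd, turn_persistence = turn_persistence),
            class = "archetype_spec")
}

#' Default archetype parameter set
#'
#' Calibrated so features extracted from simulated traces reproduce the
#' qualitative profile of the four clusters: shy fish sit low and explore
#' little; wall-huggers stay far from the center line; active explorers cover
#' the most distance and volume; bold fish swim high, central, and less than
#' average.
#'
#' @param water_depth Water depth, cm; depth preferences are placed inside it.
#' @return Named list of four [archetype_spec()] objects.
#' @export
default_archetypes <- function(water_depth = 11.1) {
  list(
    shy = archetype_spec("shy", depth_pref = 0.8, wall_affinity = 0.2,
                         speed_mean = 1.2, speed_sd = 0.4, turn_persistence = 0.5),
    wall_hugger = archetype_spec("wall_hugger", depth_pref = 0.5 * water_depth,
                                 wall_affinity = 2.0, speed_mean = 4.0,
                                 speed_sd = 1.0, turn_persistence = 0.6),
    active_explorer = archetype_spec("active_explorer",
                                     depth_pref = 0.55 * water_depth,
                                     wall_affinity = 0, speed_mean = 8.0,
                                     speed_sd = 2.0, turn_persistence = 0.8),
    bold = archetype_spec("bold", depth_pref = 0.92 * water_depth,
                          wall_affinity = -1.0, speed_mean = 2.2,
                          speed_sd = 0.8, turn_persistence = 0.5)
  )
}

# Random unit 3-vector.
runit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Simulate one swim trace
#'
#' Correlated random walk inside the water volume: the heading is an AR(1)
#' process with persistence `turn_persistence`, the per-frame speed is drawn
#' from a truncated normal, and two deterministic drifts act on the position -
#' a vertical restoring drift toward `depth_pref` and a horizontal radial drift
#' controlled by `wall_affinity`. Boundaries are reflective, so every
#' coordinate stays inside `[0, side] x [0, side] x [0, water_depth]`.
#'
#' @param archetype An [archetype_spec()].
#' @param geometry A [tank_geometry()].
#' @param duration Trial length, s (default 360, a 6-minute trial).
#' @param fps Frame rate, frames/s (default 30).
#' @param seed Integer seed; fixing it fixes the trace bit-for-bit.
#' @param fish_id,session Identifiers stored on the trace.
#' @param depth_gain Strength of the vertical restoring drift, 1/s.
#' @param wall_gain Speed scale of the radial drift, cm/s per unit affinity.
#' @return A [swim_trace()] with `ceiling(duration * fps)` frames.
#' @export
generate_trace <- function(archetype, geometry, duration = 360, fps = 30,
                           seed = 1, fish_id = "fish", session = "1",
                           depth_gain = 1.5, wall_gain = 2.0) {
  if (!inherits(archetype, "archetype_spec")) {
    stop("`archetype` must be an archetype_spec", call. = FALSE)
  }
  check_scalar(duration, "duration"); check_scalar(fps, "fps")
  if (duration <= 0 || fps <= 0) stop("duration and fps must be positive", call. = FALSE)
  if (archetype$depth_pref > geometry$water_depth) {
    stop("`depth_pref` exceeds the water depth", call. = FALSE)
  }
  n <- ceiling(duration * fps)
  dt <- 1 / fps
  side <- geometry$side
  depth <- geometry$water_depth
  phi <- archetype$turn_persistence
  cx <- side / 2
  with_seed(seed, {
    X <- matrix(NA_real_, n, 3)
    # start near the horizontal center, at the preferred depth
    pos <- c(cx + stats::runif(1, -side / 4, side / 4),
             cx + stats::runif(1, -side / 4, side / 4),
             min(max(archetype$depth_pref, 0), depth))
    dir <- runit3()
    for (i in seq_len(n)) {
      dir <- phi * dir + (1 - phi) * runit3()
      nd <- sqrt(sum(dir^2))
      if (nd < 1e-12) dir <- runit3() else dir <- dir / nd
      speed <- max(0, stats::rnorm(1, archetype$speed_mean, archetype$speed_sd))
      v <- speed * dir
      # vertical restoring drift toward the preferred depth
      v[3] <- v[3] + depth_gain * (archetype$depth_pref - pos[3])
      # horizontal radial drift: outward for positive affinity
      rx <- pos[1] - cx; ry <- pos[2] - cx
      rn <- sqrt(rx^2 + ry^2)
      if (rn > 1e-9) {
        v[1] <- v[1] + wall_gain * archetype$wall_affinity * rx / rn
        v[2] <- v[2] + wall_gain * archetype$wall_affinity * ry / rn
      }
      pos <- pos + v * dt
      # reflective boundaries
      if (pos[1] < 0) pos[1] <- -pos[1] else if (pos[1] > side) pos[1] <- 2 * side - pos[1]
      if (pos[2] < 0) pos[2] <- -pos[2] else if (pos[2] > side) pos[2] <- 2 * side - pos[2]
      if (pos[3] < 0) pos[3] <- -pos[3] else if (pos[3] > depth) pos[3] <- 2 * depth - pos[3]
      pos <- pmin(pmax(pos, 0), c(side, side, depth))
      X[i, ] <- pos
    }
    swim_trace(t = (seq_len(n) - 1) / fps, x = X[, 1], y = X[, 2], z = X[, 3],
               fps = fps, fish_id = fish_id, session = session)
  })
}

#' Cohort design specification
#'
#' @param strain_sex_table Data frame with columns `strain`, `sex`, `n`. The
#'   default is the reference design: AB (F 58 / M 52), TL (F 54 / M 50),
#'   TU (F 58 / M 50), WIK (F 51 / M 53) - 426 fish in total.
#' @param archetype_probs Data frame with columns `strain`, `sex` and one
#'   probability column per archetype (`shy`, `wall_hugger`, `active_explorer`,
#'   `bold`), each row summing to 1. Defaults to mild strain/sex tilts around a
#'   uniform mixture.
#' @param persistence Probability that a fish keeps its archetype on the next
#'   session, in `[0, 1]`. The default 0.39 makes the expected session-to-session
#'   cluster agreement under a uniform 4-archetype mixture equal to
#'   `0.39 + 0.61/4 ~ 0.54`.
#' @param n_sessions Number of sessions per fish.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(strain_sex_table = default_strain_sex_table(),
                        archetype_probs = default_archetype_probs(),
                        persistence = 0.39, n_sessions = 2L, seed = 1L) {
  if (!is.data.frame(strain_sex_table) ||
      !all(c("strain", "sex", "n") %in% names(strain_sex_table)) ||
      nrow(strain_sex_table) == 0L) {
    stop("`strain_sex_table` must be a nonempty data frame with strain, sex, n",
         call. = FALSE)
  }
  if (any(strain_sex_table$n < 0)) stop("counts must be >= 0", call. = FALSE)
  arch <- c("shy", "wall_hugger", "active_explorer", "bold")
  if (!all(c("strain", "sex", arch) %in% names(archetype_probs))) {
    stop("`archetype_probs` must have columns strain, sex and the 4 archetypes",
         call. = FALSE)
  }
  pm <- as.matrix(archetype_probs[, arch])
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-9)) {
    stop("each archetype probability vector must be non-negative and sum to 1",
         call. = FALSE)
  }
  check_scalar(persistence, "persistence")
  if (persistence < 0 || persistence > 1) {
    stop("`persistence` must lie in [0, 1]", call. = FALSE)
  }
  n_sessions <- as.integer(n_sessions)
  if (n_sessions < 1L) stop("`n_sessions` must be >= 1", call. = FALSE)
  structure(list(strain_sex_table = strain_sex_table,
                 archetype_probs = archetype_probs,
                 persistence = persistence, n_sessions = n_sessions,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_strain_sex_table <- function() {
  data.frame(strain = rep(c("AB", "TL", "TU", "WIK"), each = 2),
             sex = rep(c("F", "M"), 4),
             n = c(58, 52, 54, 50, 58, 50, 51, 53))
}

#' @rdname cohort_spec
#' @export
default_archetype_probs <- function() {
  data.frame(strain = rep(c("AB", "TL", "TU", "WIK"), each = 2),
             sex = rep(c("F", "M"), 4),
             shy = c(.22, .18, .42, .38, .22, .16, .24, .20),
             wall_hugger = c(.30, .26, .22, .22, .28, .24, .28, .24),
             active_explorer = c(.22, .30, .14, .20, .24, .34, .24, .32),
             bold = c(.26, .26, .22, .20, .26, .26, .24, .24))
}

# Simulate per-fish archetype labels across sessions: first-order Markov chain
# with probability `persistence` of keeping the previous label, otherwise a
# fresh draw from the fish's (strain, sex) mixture. Assumes RNG state is set.
simulate_labels <- function(spec) {
  arch <- c("shy", "wall_hugger", "active_explorer", "bold")
  tab <- spec$strain_sex_table
  probs <- spec$archetype_probs
  meta <- list(); labels <- list()
  for (r in seq_len(nrow(tab))) {
    n <- tab$n[r]
    if (n == 0) next
    strain <- tab$strain[r]; sex <- tab$sex[r]
    p <- probs[probs$strain == strain & probs$sex == sex, arch]
    if (nrow(p) != 1L) {
      stop(sprintf("no archetype probabilities for (%s, %s)", strain, sex),
           call. = FALSE)
    }
    p <- as.numeric(p)
    ids <- sprintf("%s_%s_%03d", strain, sex, seq_len(n))
    lab <- matrix(NA_character_, n, spec$n_sessions)
    lab[, 1] <- sample(arch, n, replace = TRUE, prob = p)
    if (spec$n_sessions > 1L) {
      for (s in 2:spec$n_sessions) {
        keep <- stats::runif(n) < spec$persistence
        lab[, s] <- ifelse(keep, lab[, s - 1],
                           sample(arch, n, replace = TRUE, prob = p))
      }
    }
    meta[[r]] <- data.frame(fish_id = rep(ids, each = spec$n_sessions),
                            strain = strain, sex = sex,
                            session = rep(seq_len(spec$n_sessions), n),
                            stringsAsFactors = FALSE)
    labels[[r]] <- data.frame(fish_id = rep(ids, each = spec$n_sessions),
                              session = rep(seq_len(spec$n_sessions), n),
                              archetype = as.vector(t(lab)),
                              stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta); labels <- do.call(rbind, labels)
  if (is.null(meta)) stop("cohort is empty", call. = FALSE)
  rownames(meta) <- rownames(labels) <- NULL
  list(metadata = meta, labels = labels)
}

#' Simulate a cohort of swim traces
#'
#' One trace per fish per session. Each fish draws a session-1 archetype from
#' its (strain, sex) mixture and follows a first-order Markov chain across
#' sessions with the given persistence. True archetype labels are returned for
#' recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @param geometry A [tank_geometry()].
#' @param duration,fps Passed to [generate_trace()].
#' @param archetypes Named list of [archetype_spec()]s; defaults to
#'   [default_archetypes()] for the geometry's water depth.
#' @return List with `traces` (named list, `<fish_id>_<session>`), `metadata`
#'   (fish_id, strain, sex, session) and `labels` (fish_id, session, archetype).
#' @export
generate_cohort <- function(spec, geometry = tank_geometry(), duration = 360,
                            fps = 30, archetypes = NULL) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  if (is.null(archetypes)) archetypes <- default_archetypes(geometry$water_depth)
  with_seed(spec$seed, {
    sim <- simulate_labels(spec)
    seeds <- sample.int(.Machine$integer.max - 1L, nrow(sim$labels))
    traces <- vector("list", nrow(sim$labels))
    names(traces) <- paste(sim$labels$fish_id, sim$labels$session, sep = "_")
    for (i in seq_len(nrow(sim$labels))) {
      traces[[i]] <- generate_trace(archetypes[[sim$labels$archetype[i]]],
                                    geometry, duration = duration, fps = fps,
                                    seed = seeds[i],
                                    fish_id = sim$labels$fish_id[i],
                                    session = sim$labels$session[i])
    }
    list(traces = traces, metadata = sim$metadata, labels = sim$labels)
  })
}

#' Default archetype feature means and spreads
#'
#' Per-archetype means of the four exploratory features (rows: shy,
#' wall_hugger, active_explorer, bold; columns: bottom_cm, center_cm,
#' distance_cm, percent_explored) and the common within-archetype standard
#' deviations, chosen so the minimum pairwise separation between archetype
#' centers exceeds 3 within-archetype s.d. in standardized space.
#'
#' @return A list with `means` (4 x 4 matrix) and `sd` (length-4 vector).
#' @export
default_archetype_means <- function() {
  m <- rbind(shy = c(1.5, 5.0, 450, 8),
             wall_hugger = c(4.0, 6.8, 1300, 20),
             active_explorer = c(5.5, 4.8, 2600, 45),
             bold = c(9.0, 2.5, 900, 18))
  colnames(m) <- feature_cols()
  list(means = m, sd = c(bottom_cm = 0.8, center_cm = 0.8,
                         distance_cm = 250, percent_explored = 6))
}

#' Simulate a cohort directly in feature space
#'
#' Fast path that skips trace simulation: archetype labels are generated as in
#' [generate_cohort()] and features are drawn from independent per-archetype
#' Gaussians. Used for planted-cluster recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @param archetype_means 4 x 4 matrix of per-archetype feature means (rows
#'   named by archetype, columns the four features).
#' @param within_sd Per-feature within-archetype s.d. (positive, length 4 or 1).
#' @param seed Optional seed overriding `spec$seed`.
#' @return List with `features` (fish_id, session, four features), `metadata`
#'   and `labels` as in [generate_cohort()].
#' @export
generate_feature_cohort <- function(spec,
                                    archetype_means = default_archetype_means()$means,
                                    within_sd = default_archetype_means()$sd,
                                    seed = NULL) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  if (any(within_sd <= 0)) stop("`within_sd` must be positive", call. = FALSE)
  within_sd <- rep_len(as.numeric(within_sd), 4L)
  if (is.null(seed)) seed <- spec$seed
  with_seed(seed, {
    sim <- simulate_labels(spec)
    n <- nrow(sim$labels)
    mu <- archetype_means[sim$labels$archetype, , drop = FALSE]
    noise <- matrix(stats::rnorm(n * 4), n, 4) %*% diag(within_sd)
    feats <- mu + noise
    features <- data.frame(fish_id = sim$labels$fish_id,
                           session = sim$labels$session,
                           stringsAsFactors = FALSE)
    features[feature_cols()] <- feats
    list(features = features, metadata = sim$metadata, labels = sim$labels)
  })
}

#' Simulate a depth-calibration measurement set
#'
#' Paired depth readings of the same points measured without (`z_air_cm`) and
#' with (`z_water_cm`) water, following `z_air = slope * z_water + intercept`
#' plus Gaussian noise.
#'
#' @param true_slope,true_intercept Linear map parameters.
#' @param n_points Number of calibration points (>= 2; default 100).
#' @param noise_sd Gaussian noise s.d. on `z_air_cm`, cm.
#' @param seed Integer seed.
#' @param range In-water depth range sampled, cm.
#' @return Data frame with columns `z_air_cm`, `z_water_cm`; the generating
#'   parameters are attached as attributes `true_slope`, `true_intercept`,
#'   `noise_sd`.
#' @export
generate_calibration <- function(true_slope, true_intercept, n_points = 100L,
                                 noise_sd = 0, seed = 1, range = c(1, 25)) {
  check_scalar(true_slope, "true_slope"); check_scalar(true_intercept, "true_intercept")
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  with_seed(seed, {
    zw <- stats::runif(n_points, range[1], range[2])
    za <- true_slope * zw + true_intercept + stats::rnorm(n_points, 0, noise_sd)
    structure(data.frame(z_air_cm = za, z_water_cm = zw),
              true_slope = true_slope, true_intercept = true_intercept,
              noise_sd = noise_sd)
  })
}
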