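#' Configuration of the synthetic ground-truth interaction process
#'
#' The ground truth is a discrete-time (1 s) group-conversation process:
#' every participant is at each second either solo or a member of exactly
#' one conversation group, and all co-members of a group interact pairwise
#' (so the per-second contact graph is a disjoint union of cliques — the
#' structure human coders impose when they code group conversations).
#' Each second, each participant independently reconsiders their position
#' with probability `switch_rate`; a mover goes solo with probability
#' `solo_prob` and otherwise joins the group of a uniformly chosen other
#' participant, provided the target group stays within `max_group`.
#' The chain is run for `burn_in_s` seconds before recording so the
#' recorded window starts near the process's long-run regime.
#'
#' The defaults emulate a small stand-up social event: 11 participants
#' observed for 4602 s (76.7 min), with switch and solo parameters chosen
#' so that roughly a fifth of all dyad-seconds are interaction time,
#' conversational spells last tens of seconds to minutes, and a dyad that
#' separates typically re-engages on the scale of minutes — well above
#' the seconds-scale flicker gaps the sensor model introduces, which is
#' the separation the gap-interpolation analysis presumes.
#'
#' @param n_participants Roster size (>= 2).
#' @param window_s Observation length in seconds.
#' @param switch_rate Per-person per-second probability of reconsidering
#'   group membership.
#' @param solo_prob Probability that a mover goes solo rather than joining
#'   another participant's group.
#' @param max_group Maximal conversation-group size (>= 2).
#' @param burn_in_s Unrecorded warm-up seconds.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(n_participants = 11, window_s = 4602,
                         switch_rate = 0.02, solo_prob = 0.15,
                         max_group = 5, burn_in_s = 1000) {
  stopifnot(n_participants >= 2, window_s >= 1, switch_rate >= 0,
            switch_rate <= 1, solo_prob >= 0, solo_prob <= 1, burn_in_s >= 0)
  if (max_group < 2) stop("max_group must be at least 2", call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 window_s = as.integer(window_s),
                 switch_rate = switch_rate, solo_prob = solo_prob,
                 max_group = as.integer(max_group),
                 burn_in_s = as.integer(burn_in_s)),
            class = "truth_config")
}

#' Configuration of the synthetic proximity-sensor observation model
#'
#' Sensors fragment a continuous true interaction into an alternating
#' on/off renewal process with geometric run lengths ("flickering": e.g.
#' a 5-minute conversation recorded as several ~50 s signals separated by
#' ~20 s gaps, as body rotation interrupts the narrow badge beam).
#' In conversation groups of size `k`, a dyad's re-detection hazard (the
#' per-second probability that a lost signal comes back) is scaled by
#' `group_decay^(k-2)`, so each dyad's on-probability decays with group
#' size — the difficulty of capturing every pair in larger groups, where
#' flicker gaps stretch and some dyads go missing. Rare false
#' positives arise between members of distinct co-existing groups at
#' `fp_rate` per eligible dyad-second. If `round_min_duration` is on,
#' detected events shorter than `min_duration_s` are reported with that
#' duration — badge software reports no duration below 10 s.
#'
#' @param on_mean_s Mean length (s) of detected on-runs (> 0).
#' @param off_mean_s Mean length (s) of flicker gaps; 0 means no flicker.
#' @param group_decay Per-extra-group-member detection retention in (0, 1].
#' @param fp_rate False-positive rate per co-located non-interacting
#'   dyad-second.
#' @param round_min_duration Report short events as `min_duration_s`?
#' @param min_duration_s Minimum reported duration (default 10 s).
#' @return A list of class `sensor_config`.
#' @export
sensor_config <- function(on_mean_s = 50, off_mean_s = 20, group_decay = 0.9,
                          fp_rate = 1e-4, round_min_duration = TRUE,
                          min_duration_s = 10) {
  stopifnot(on_mean_s > 0, off_mean_s >= 0, group_decay > 0, group_decay <= 1,
            fp_rate >= 0, fp_rate <= 1, min_duration_s >= 1)
  structure(list(on_mean_s = on_mean_s, off_mean_s = off_mean_s,
                 group_decay = group_decay, fp_rate = fp_rate,
                 round_min_duration = isTRUE(round_min_duration),
                 min_duration_s = as.integer(min_duration_s)),
            class = "sensor_config")
}

#' Simulate a ground-truth interaction log
#'
#' Runs the group-conversation process of [truth_config()] and returns the
#' maximal intervals of pairwise group co-membership as an [event_log()].
#' Deterministic given `seed`.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed.
#' @return An [event_log()] over roster `"1" ... "n"` and window
#'   `[0, window_s)`, whose per-second contact graphs are unions of
#'   cliques (so triadic closure leaves it unchanged).
#' @export
simulate_truth <- function(config = truth_config(), seed = 1) {
  stopifnot(inherits(config, "truth_config"))
  n <- config$n_participants
  S <- config$window_s
  set.seed(as_seed(seed))

  g <- seq_len(n)  # group label per person; singleton label = solo
  step <- function(g) {
    movers <- which(stats::runif(n) < config$switch_rate)
    for (i in movers) {
      if (stats::runif(1) < config$solo_prob) {
        g[i] <- max(g) + 1L  # fresh singleton label
      } else {
        j <- sample(setdiff(seq_len(n), i), 1L)
        if (g[j] != g[i] && sum(g == g[j]) < config$max_group) g[i] <- g[j]
      }
    }
    g
  }
  for (t in seq_len(config$burn_in_s)) g <- step(g)

  pair_i <- utils::combn(n, 2L)
  active_prev <- rep(FALSE, ncol(pair_i))
  run_start <- integer(ncol(pair_i))
  events <- list(); n_ev <- 0L
  for (t in seq_len(S)) {
    g <- step(g)
    active <- g[pair_i[1, ]] == g[pair_i[2, ]]
    opened <- which(active & !active_prev)
    closed <- which(!active & active_prev)
    run_start[opened] <- t - 1L
    for (d in closed) {
      n_ev <- n_ev + 1L
      events[[n_ev]] <- c(pair_i[1, d], pair_i[2, d], run_start[d], t - 1L)
    }
    active_prev <- active
  }
  for (d in which(active_prev)) {
    n_ev <- n_ev + 1L
    events[[n_ev]] <- c(pair_i[1, d], pair_i[2, d], run_start[d], S)
  }
  ev <- if (n_ev > 0L) {
    m <- do.call(rbind, events)
    data.frame(id_a = as.character(m[, 1]), id_b = as.character(m[, 2]),
               start = m[, 3], end = m[, 4], stringsAsFactors = FALSE)
  } else {
    data.frame(id_a = character(), id_b = character(),
               start = integer(), end = integer())
  }
  event_log(ev, roster = as.character(seq_len(n)), window = c(0L, S))
}

# component (conversation-group) size of the clique containing person `id`
# on each constant-activity segment of a clique-structured truth log
segment_group_sizes <- function(truth) {
  bounds <- sort(unique(c(truth$start, truth$end)))
  if (length(bounds) < 2L) {
    return(list(start = integer(), end = integer(), deg = NULL))
  }
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  ids <- roster(truth)
  deg <- matrix(0L, nrow = length(seg_start), ncol = length(ids),
                dimnames = list(NULL, ids))
  ia <- match(truth$id_a, ids); ib <- match(truth$id_b, ids)
  for (s in seq_along(seg_start)) {
    act <- truth$start <= seg_start[s] & truth$end >= seg_end[s]
    if (any(act)) {
      tab <- tabulate(c(ia[act], ib[act]), nbins = length(ids))
      deg[s, ] <- tab
    }
  }
  list(start = seg_start, end = seg_end, deg = deg)
}

#' Pass a ground-truth log through the sensor observation model
#'
#' Applies the flicker, group-size-decay, false-positive and
#' minimum-duration mechanisms of [sensor_config()] to a truth log.
#' Deterministic given `seed`.
#'
#' @param truth Ground-truth [event_log()] (clique-structured per second).
#' @param config A [sensor_config()].
#' @param seed Integer seed.
#' @return The sensor-observed [event_log()] over the same roster/window.
#' @export
observe <- function(truth, config = sensor_config(), seed = 1) {
  stopifnot(inherits(config, "sensor_config"))
  truth <- as_event_log(truth)
  set.seed(as_seed(seed))
  w <- obs_window(truth)
  segs <- segment_group_sizes(truth)
  ids <- roster(truth)

  p_off <- if (config$off_mean_s > 0) min(1, 1 / config$on_mean_s) else 0
  p_on <- if (config$off_mean_s > 0) min(1, 1 / config$off_mean_s) else 1
  stat_on <- if (p_off + p_on > 0) p_on / (p_on + p_off) else 1

  pieces <- list(); n_p <- 0L
  for (e in seq_len(nrow(truth))) {
    len <- truth$end[e] - truth$start[e]
    # per-second conversation-group size over the event (piecewise constant)
    ksec <- integer(len)
    covering <- which(segs$start < truth$end[e] & segs$end > truth$start[e])
    for (sg in covering) {
      lo <- max(segs$start[sg], truth$start[e]) - truth$start[e] + 1L
      hi <- min(segs$end[sg], truth$end[e]) - truth$start[e]
      ksec[lo:hi] <- 1L + segs$deg[sg, truth$id_a[e]]
    }
    # two-state flicker chain; re-detection hazard thinned with group size
    p_on_k <- p_on * config$group_decay^(pmax(0L, ksec - 2L))
    state <- integer(len)
    s <- as.integer(stats::runif(1) < stat_on * config$group_decay^(max(0L, ksec[1] - 2L)))
    flips <- stats::runif(len)
    for (t in seq_len(len)) {
      state[t] <- s
      s <- if (s == 1L) as.integer(flips[t] >= p_off) else as.integer(flips[t] < p_on_k[t])
    }
    if (!any(state == 1L)) next
    r <- rle(state)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths  # 0-based within event
    on_runs <- which(r$values == 1L)
    for (k in on_runs) {
      n_p <- n_p + 1L
      pieces[[n_p]] <- data.frame(
        id_a = truth$id_a[e], id_b = truth$id_b[e],
        start = truth$start[e] + run_start[k], end = truth$start[e] + run_end[k],
        stringsAsFactors = FALSE)
    }
  }

  # false positives between members of distinct co-existing groups
  if (config$fp_rate > 0 && length(segs$start) > 0L) {
    for (s in seq_along(segs$start)) {
      in_group <- which(segs$deg[s, ] > 0L)
      if (length(in_group) < 2L) next
      cand <- utils::combn(in_group, 2L)
      # keep only cross-group pairs: co-members are adjacent in a clique log
      seg_events <- truth$start <= segs$start[s] & truth$end >= segs$end[s]
      adj <- paste(truth$id_a[seg_events], truth$id_b[seg_events])
      keys <- paste(ids[cand[1, ]], ids[cand[2, ]])
      cross <- which(!(keys %in% adj))
      if (length(cross) == 0L) next
      seg_len <- segs$end[s] - segs$start[s]
      n_cells <- length(cross) * seg_len
      n_hits <- stats::rbinom(1, n_cells, config$fp_rate)
      if (n_hits == 0L) next
      cells <- sample.int(n_cells, n_hits)
      d_idx <- cross[((cells - 1L) %% length(cross)) + 1L]
      t_idx <- segs$start[s] + ((cells - 1L) %/% length(cross))
      n_p <- n_p + 1L
      pieces[[n_p]] <- data.frame(
        id_a = ids[cand[1, d_idx]], id_b = ids[cand[2, d_idx]],
        start = t_idx, end = t_idx + 1L, stringsAsFactors = FALSE)
    }
  }

  ev <- do.call(rbind, pieces)
  if (is.null(ev)) {
    ev <- data.frame(id_a = character(), id_b = character(),
                     start = integer(), end = integer())
  }
  out <- event_log(ev, roster = ids, window = w)

  if (config$round_min_duration && nrow(out) > 0L) {
    df <- as.data.frame(out)
    short <- (df$end - df$start) < config$min_duration_s
    df$end[short] <- pmin(df$start[short] + config$min_duration_s, w[2])
    df <- df[df$end > df$start, , drop = FALSE]
    out <- event_log(df, roster = ids, window = w)
  }
  out
}

#' Simulate two noisy human raters
#'
#' Each rater is an independent perturbation of the truth: whole events
#' are missed with probability `miss_prob`, and retained events' start and
#' end times are jittered by rounded Gaussian noise (clipped to the window,
#' order preserved). Useful for exercising [cohens_kappa()] and
#' [merge_rater_codings()].
#'
#' @param truth Ground-truth [event_log()].
#' @param miss_prob Per-event miss probability.
#' @param jitter_sd SD (s) of boundary jitter.
#' @param seed Integer seed.
#' @return A list with elements `a` and `b`, each an [event_log()].
#' @export
simulate_raters <- function(truth, miss_prob = 0.05, jitter_sd = 3, seed = 1) {
  stopifnot(miss_prob >= 0, miss_prob <= 1, jitter_sd >= 0)
  truth <- as_event_log(truth)
  set.seed(as_seed(seed))
  w <- obs_window(truth)
  one <- function() {
    df <- as.data.frame(truth)
    if (nrow(df) == 0L) return(event_log(df, roster = roster(truth), window = w))
    df <- df[stats::runif(nrow(df)) >= miss_prob, , drop = FALSE]
    if (nrow(df) > 0L && jitter_sd > 0) {
      df$start <- df$start + round(stats::rnorm(nrow(df), 0, jitter_sd))
      df$end <- df$end + round(stats::rnorm(nrow(df), 0, jitter_sd))
      df$start <- pmax(w[1], pmin(df$start, w[2] - 1L))
      df$end <- pmax(df$start + 1L, pmin(df$end, w[2]))
    }
    event_log(df, roster = roster(truth), window = w)
  }
  list(a = one(), b = one())
}

#' Generate duration-driven self-reported nominations
#'
#' Draws each directed nomination independently with probability
#' `plogis(intercept + slope_per_min * minutes)`, the generative
#' counterpart of [fit_duration_logit()]. Defaults are a weak baseline
#' nomination propensity rising with contact time.
#'
#' @param x Weighted contact matrix (minutes).
#' @param intercept Log-odds of nomination at zero contact.
#' @param slope_per_min Log-odds increase per interaction minute.
#' @param seed Integer seed.
#' @return A directed binary nomination matrix (zero diagonal).
#' @export
generate_self_reports <- function(x, intercept = -2.16, slope_per_min = 0.02,
                                  seed = 1) {
  set.seed(as_seed(seed))
  p <- stats::plogis(intercept + slope_per_min * x)
  y <- matrix(stats::rbinom(length(p), 1, p), nrow(x), ncol(x),
              dimnames = dimnames(x))
  diag(y) <- 0
  y
}

#' Build a complete synthetic validation world
#'
#' Bundles a ground-truth log, its sensor observation, optional rater
#' codings and optional self-report nominations, all generated from one
#' master seed. Component seeds are derived by a stable hash of the master
#' seed and the component name, so adding components never perturbs
#' existing streams.
#'
#' @param truth_cfg A [truth_config()].
#' @param sensor_cfg A [sensor_config()].
#' @param raters `NULL`, or a list with `miss_prob` and `jitter_sd`.
#' @param reports `NULL`, or a list with `intercept` and `slope_per_min`.
#' @param seed Master integer seed.
#' @return A list of class `synthetic_world`: `truth`, `observed`,
#'   optionally `raters` and `nominations`, plus the configs and seed.
#' @examples
#' w <- make_world(seed = 7)
#' validate_contacts(w$observed, w$truth, list(step_interpolate(75)))
#' @export
make_world <- function(truth_cfg = truth_config(), sensor_cfg = sensor_config(),
                       raters = NULL, reports = NULL, seed = 1) {
  truth <- simulate_truth(truth_cfg, seed = derive_seed(seed, "truth"))
  observed <- observe(truth, sensor_cfg, seed = derive_seed(seed, "observe"))
  world <- list(truth = truth, observed = observed,
                truth_cfg = truth_cfg, sensor_cfg = sensor_cfg, seed = seed)
  if (!is.null(raters)) {
    world$raters <- simulate_raters(truth, miss_prob = raters$miss_prob %||% 0.05,
                                    jitter_sd = raters$jitter_sd %||% 3,
                                    seed = derive_seed(seed, "raters"))
  }
  if (!is.null(reports)) {
    x <- aggregate_minutes(observed)
    world$nominations <- generate_self_reports(
      x, intercept = reports$intercept %||% -2.16,
      slope_per_min = reports$slope_per_min %||% 0.02,
      seed = derive_seed(seed, "reports"))
  }
  structure(world, class = "synthetic_world")
}

#' Write a synthetic world's artifacts to a directory
#'
#' Writes truth/observed (and, if present, rater) event-log CSVs, the
#' nomination matrix CSV, and a provenance JSON recording configs and
#' seeds.
#'
#' @param world A [make_world()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_event_log(world$truth, file.path(dir, "truth.csv"))
  write_event_log(world$observed, file.path(dir, "observed.csv"))
  if (!is.null(world$raters)) {
    write_event_log(world$raters$a, file.path(dir, "rater_a.csv"))
    write_event_log(world$raters$b, file.path(dir, "rater_b.csv"))
  }
  if (!is.null(world$nominations)) {
    write_adjacency_csv(world$nominations, file.path(dir, "nominations.csv"))
  }
  jsonlite::write_json(
    list(seed = world$seed,
         truth_config = unclass(world$truth_cfg),
         sensor_config = unclass(world$sensor_cfg),
         package_version = as.character(utils::packageVersion("contactvalid"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# stable component-seed derivation; stays below 2^31
derive_seed <- function(master, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)) * 131)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

as_seed <- function(seed) {
  seed <- as.numeric(seed)
  if (is.na(seed)) stop("seed must be a number", call. = FALSE)
  as.integer(seed %% 2147483647)
}
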