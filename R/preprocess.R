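#' Cleaning strategies for flickering proximity-sensor signals
#'
#' Proximity badges fragment continuous interactions into short on-intervals
#' separated by gaps ("flickering") and can miss dyads inside larger groups.
#' Three standard strategies address this, each an `event_log -> event_log`
#' map:
#'
#' * [filter_min_duration()] deletes events strictly shorter than a cutoff.
#' * [interpolate_gaps()] merges same-dyad events whose separating gap is at
#'   most (inclusive) a cutoff, transitively along chains, so the result is
#'   idempotent for a fixed cutoff.
#' * [close_triads()] imputes a B--C contact for every second in which some A
#'   is simultaneously in contact with both B and C; one iteration applies
#'   this simultaneously from the pre-iteration state, and iterating reaches
#'   the per-second clique (connected-component) fixpoint.
#'
#' @param log An [event_log()].
#' @param cutoff_s Minimal duration in seconds; events with
#'   `duration < cutoff_s` are removed (strict inequality).
#' @return An [event_log()] over the same roster and window.
#' @examples
#' log <- event_log(data.frame(id_a = c("1", "1"), id_b = c("2", "2"),
#'                             start = c(0, 25), end = c(10, 40)))
#' interpolate_gaps(log, 20)   # gap of 15 s bridged -> one event [0, 40)
#' filter_min_duration(log, 20)  # both events shorter than 20 s -> empty
#' @export
filter_min_duration <- function(log, cutoff_s) {
  log <- as_event_log(log)
  if (length(cutoff_s) != 1L || is.na(cutoff_s) || cutoff_s < 0) {
    stop("cutoff_s must be a single non-negative number", call. = FALSE)
  }
  keep <- (log$end - log$start) >= cutoff_s
  new_event_log(as.data.frame(log)[keep, , drop = FALSE],
                roster(log), obs_window(log))
}

#' @rdname filter_min_duration
#' @param max_gap_s Maximal gap in seconds; same-dyad events at most this
#'   far apart (inclusive) are merged into one event spanning both.
#' @export
interpolate_gaps <- function(log, max_gap_s) {
  log <- as_event_log(log)
  if (length(max_gap_s) != 1L || is.na(max_gap_s) || max_gap_s < 0) {
    stop("max_gap_s must be a single non-negative number", call. = FALSE)
  }
  if (nrow(log) <= 1L) return(log)
  df <- as.data.frame(log)
  df <- df[order(dyad_key(df$id_a, df$id_b), df$start), ]
  key <- dyad_key(df$id_a, df$id_b)
  # one transitive pass over start-sorted events: gap <= max_gap merges
  out_i <- integer(nrow(df))
  n_out <- 0L
  cur <- 1L
  cur_end <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (key[i] == key[cur] && df$start[i] - cur_end <= max_gap_s) {
      cur_end <- max(cur_end, df$end[i])
    } else {
      n_out <- n_out + 1L
      out_i[n_out] <- cur
      df$end[cur] <- cur_end
      cur <- i
      cur_end <- df$end[i]
    }
  }
  n_out <- n_out + 1L
  out_i[n_out] <- cur
  df$end[cur] <- cur_end
  event_log(df[out_i[seq_len(n_out)], , drop = FALSE],
            roster = roster(log), window = obs_window(log))
}

#' @rdname filter_min_duration
#' @param iterations Number of closure iterations (`>= 0`). Within one
#'   iteration all open triads of the pre-iteration state are closed
#'   simultaneously, so the result does not depend on any update order.
#' @export
close_triads <- function(log, iterations = 1L) {
  log <- as_event_log(log)
  if (length(iterations) != 1L || is.na(iterations) || iterations < 0) {
    stop("iterations must be a single non-negative integer", call. = FALSE)
  }
  iterations <- as.integer(iterations)
  if (iterations == 0L || nrow(log) == 0L) return(log)
  ids <- roster(log)
  n <- length(ids)

  # The per-second contact graph is constant between event boundaries, so
  # work on maximal constant-activity segments instead of single seconds.
  bounds <- sort(unique(c(log$start, log$end)))
  seg_start <- bounds[-length(bounds)]
  seg_end <- bounds[-1]
  ia <- match(log$id_a, ids)
  ib <- match(log$id_b, ids)

  pieces <- vector("list", length(seg_start))
  for (s in seq_along(seg_start)) {
    active <- log$start <= seg_start[s] & log$end >= seg_end[s]
    if (!any(active)) next
    A <- matrix(0, n, n)
    A[cbind(ia[active], ib[active])] <- 1
    A[cbind(ib[active], ia[active])] <- 1
    for (k in seq_len(iterations)) {
      A2 <- ((A + A %*% A) > 0) * 1
      diag(A2) <- 0
      if (all(A2 == A)) break
      A <- A2
    }
    idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    pieces[[s]] <- data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                              start = seg_start[s], end = seg_end[s],
                              stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, pieces)
  event_log(ev, roster = ids, window = obs_window(log))
}

#' Processing pipelines: ordered sequences of cleaning steps
#'
#' A processing config is an ordered list of steps built with
#' [step_min_duration()], [step_interpolate()] and [step_triadic_closure()].
#' Order is significant: deleting short events before interpolating can
#' discard fragments that interpolation would have stitched into long
#' interactions. [apply_pipeline()] applies the steps in declared order and
#' records provenance in the result's `"pipeline"` attribute.
#'
#' @param cutoff_s,max_gap_s,iterations Step parameters, as in
#'   [filter_min_duration()], [interpolate_gaps()], [close_triads()].
#' @return A step object (a named list with `kind` and `value`), or for
#'   [apply_pipeline()] the processed [event_log()].
#' @examples
#' log <- event_log(data.frame(id_a = "1", id_b = "2",
#'                             start = c(0, 60), end = c(40, 100)))
#' apply_pipeline(log, list(step_interpolate(75), step_min_duration(55)))
#' @export
step_min_duration <- function(cutoff_s) {
  stopifnot(cutoff_s >= 0)
  structure(list(kind = "min_duration", value = cutoff_s), class = "contact_step")
}

#' @rdname step_min_duration
#' @export
step_interpolate <- function(max_gap_s) {
  stopifnot(max_gap_s >= 0)
  structure(list(kind = "interpolate", value = max_gap_s), class = "contact_step")
}

#' @rdname step_min_duration
#' @export
step_triadic_closure <- function(iterations = 1L) {
  stopifnot(iterations >= 0)
  structure(list(kind = "triadic_closure", value = as.integer(iterations)),
            class = "contact_step")
}

apply_step <- function(log, step) {
  switch(step$kind,
    min_duration = filter_min_duration(log, step$value),
    interpolate = interpolate_gaps(log, step$value),
    triadic_closure = close_triads(log, step$value),
    stop("unknown processing step '", step$kind, "'", call. = FALSE)
  )
}

#' @rdname step_min_duration
#' @param log An [event_log()].
#' @param steps List of step objects (possibly empty: identity).
#' @export
apply_pipeline <- function(log, steps = list()) {
  log <- as_event_log(log)
  if (inherits(steps, "contact_step")) steps <- list(steps)
  for (s in steps) {
    if (!is.list(s) || is.null(s$kind)) {
      stop("each pipeline step needs a 'kind'", call. = FALSE)
    }
    log <- apply_step(log, s)
  }
  attr(log, "pipeline") <- steps
  log
}

#' Read a processing/sweep configuration from YAML or JSON
#'
#' The file holds an ordered `steps:` list, each entry with a `kind`
#' (`min_duration`, `interpolate`, `triadic_closure`) and its parameter
#' (`cutoff_s`, `max_gap_s` or `iterations`), and optionally a `sweep:`
#' block with `strategy`, `grid` and `criterion`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A list with elements `steps` (list of step objects) and `sweep`
#'   (list or `NULL`).
#' @export
read_processing_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  steps <- lapply(cfg$steps %||% list(), function(s) {
    kind <- s$kind %||% stop("config step without 'kind'", call. = FALSE)
    switch(kind,
      min_duration = step_min_duration(s$cutoff_s %||% s$value),
      interpolate = step_interpolate(s$max_gap_s %||% s$value),
      triadic_closure = step_triadic_closure(s$iterations %||% s$value %||% 1L),
      stop("unknown processing step '", kind, "' in config", call. = FALSE)
    )
  })
  list(steps = steps, sweep = cfg$sweep)
}

#' Sweep a cleaning strategy's parameter against ground truth
#'
#' Applies one strategy over a grid of parameter values, scores each value's
#' output against a ground-truth log at dyad-second resolution, and reports
#' the accuracy (or sensitivity+specificity) curve with its optimum
#' (ties broken toward the smallest parameter value).
#'
#' @param observed Sensor [event_log()].
#' @param truth Ground-truth [event_log()]; must share roster and window
#'   with `observed`.
#' @param strategy One of `"min_duration"`, `"interpolate"`,
#'   `"triadic_closure"`.
#' @param grid Numeric vector of cutoff values (seconds) or iteration counts.
#' @param criterion Optimization criterion: `"accuracy"` (each dyad-second
#'   weighted equally) or `"youden"` (sensitivity + specificity).
#' @return A tibble of class `sweep_result`: one row per grid value with the
#'   confusion counts and validity metrics, plus attributes `optimum`
#'   (best value), `criterion`, and `strategy`.
#' @examples
#' truth <- event_log(data.frame(id_a = "1", id_b = "2", start = 0, end = 100))
#' obs <- event_log(data.frame(id_a = c("1", "1"), id_b = c("2", "2"),
#'                             start = c(0, 60), end = c(40, 100)),
#'                  window = c(0, 100))
#' sweep_strategy(obs, truth, "interpolate", c(0, 10, 30))
#' @export
sweep_strategy <- function(observed, truth,
                           strategy = c("interpolate", "min_duration", "triadic_closure"),
                           grid, criterion = c("accuracy", "youden")) {
  strategy <- match.arg(strategy)
  criterion <- match.arg(criterion)
  observed <- as_event_log(observed)
  truth <- as_event_log(truth)
  check_compatible(observed, truth)
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)

  truth_r <- rasterize(truth)
  step_fun <- switch(strategy,
    min_duration = step_min_duration,
    interpolate = step_interpolate,
    triadic_closure = step_triadic_closure
  )
  rows <- purrr::map(grid, function(v) {
    proc <- apply_step(observed, step_fun(v))
    cc <- confusion_counts(rasterize(proc), truth_r)
    dplyr::bind_cols(tibble::tibble(value = v), cc, validity_metrics(cc))
  })
  out <- dplyr::bind_rows(rows)
  score <- if (criterion == "accuracy") out$accuracy else out$youden_sum
  best <- which(score == max(score, na.rm = TRUE))[1]
  out <- tibble::new_tibble(out, nrow = nrow(out), class = "sweep_result",
                            optimum = out$value[best], criterion = criterion,
                            strategy = strategy)
  out
}

check_compatible <- function(a, b) {
  if (!setequal(roster(a), roster(b))) {
    stop("event logs have different rosters", call. = FALSE)
  }
  if (!identical(obs_window(a), obs_window(b))) {
    stop("event logs have different observation windows", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("# %s sweep (criterion: %s), optimum at %g\n",
              attr(x, "strategy"), attr(x, "criterion"), attr(x, "optimum")))
  NextMethod()
}
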