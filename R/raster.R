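#' Rasterize an event log to dyad-second indicators
#'
#' Transforms the interval representation to the linear time dimension on
#' which validity is assessed: a binary matrix with one row per unordered
#' roster dyad (all `D = N(N-1)/2` of them, even never-active ones) and one
#' column per second of the observation window. Entry `(d, i)` is 1 exactly
#' when second `i` (half-open convention: an event `[start, end)` covers
#' seconds `start .. end-1`) is covered by an event of dyad `d`.
#'
#' @param log An [event_log()] with a finite window and roster of >= 2.
#' @return An integer 0/1 matrix of class `dyad_raster`, with dyad keys as
#'   rownames and attributes `window` and `dyads` (two-column data frame).
#' @examples
#' log <- event_log(data.frame(id_a = "1", id_b = "2", start = 0, end = 10),
#'                  window = c(0, 60))
#' sum(rasterize(log))  # 10 active dyad-seconds
#' @export
rasterize <- function(log) {
  log <- as_event_log(log)
  w <- obs_window(log)
  S <- w[2] - w[1]
  dy <- roster_dyads(roster(log))
  keys <- dyad_key(dy$id_a, dy$id_b)
  m <- matrix(0L, nrow = nrow(dy), ncol = S, dimnames = list(keys, NULL))
  if (nrow(log) > 0L && S > 0L) {
    row_idx <- match(dyad_key(log$id_a, log$id_b), keys)
    for (e in seq_len(nrow(log))) {
      cols <- (log$start[e] - w[1] + 1L):(log$end[e] - w[1])
      m[row_idx[e], cols] <- 1L
    }
  }
  structure(m, class = c("dyad_raster", "matrix", "array"),
            window = w, dyads = dy)
}

#' Recover an event log from a dyad-second raster
#'
#' Inverse of [rasterize()]: maximal runs of ones in each dyad row become
#' events, so `rasterize(events_from_raster(r))` is identically `r`.
#'
#' @param raster A `dyad_raster`.
#' @return An [event_log()] over the raster's roster and window.
#' @export
events_from_raster <- function(raster) {
  w <- attr(raster, "window")
  dy <- attr(raster, "dyads")
  ev <- vector("list", nrow(raster))
  for (d in seq_len(nrow(raster))) {
    r <- rle(as.integer(raster[d, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    on <- r$values == 1L
    if (any(on)) {
      ev[[d]] <- data.frame(id_a = dy$id_a[d], id_b = dy$id_b[d],
                            start = w[1] + starts[on], end = w[1] + ends[on],
                            stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev)) {
    ev <- data.frame(id_a = character(), id_b = character(),
                     start = integer(), end = integer())
  }
  event_log(ev, roster = unique(c(dy$id_a, dy$id_b)), window = w)
}

#' Aggregate an event log to a weighted contact matrix
#'
#' Sums each dyad's event durations over the whole collection period and
#' expresses them in minutes: the symmetric adjacency matrix whose entry
#' (i, j) is the number of minutes i and j spent in contact. Diagonal zero.
#'
#' @param log An [event_log()].
#' @return A symmetric numeric matrix (minutes) over the roster.
#' @examples
#' log <- event_log(data.frame(id_a = "1", id_b = "2", start = 0, end = 120))
#' aggregate_minutes(log)
#' @export
aggregate_minutes <- function(log) {
  log <- as_event_log(log)
  ids <- roster(log)
  x <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(log) > 0L) {
    mins <- tapply((log$end - log$start) / 60,
                   dyad_key(log$id_a, log$id_b), sum)
    parts <- strsplit(names(mins), "--", fixed = TRUE)
    i <- match(vapply(parts, `[`, "", 1L), ids)
    j <- match(vapply(parts, `[`, "", 2L), ids)
    x[cbind(i, j)] <- as.numeric(mins)
    x[cbind(j, i)] <- as.numeric(mins)
  }
  x
}

#' Descriptive summary of a contact event log
#'
#' Event-level, dyad-level and individual-level duration statistics:
#' the number of events; mean and SD of event durations (seconds); mean and
#' SD of aggregated dyadic duration (minutes; by default over dyads with
#' nonzero contact, since the share of silent dyads is usually reported
#' separately); and mean and SD of each participant's total interaction
#' time (minutes; each event counts toward both participants, so the grand
#' individual total is twice the summed event time). Sample SDs (n-1).
#'
#' @param log An [event_log()].
#' @param include_zero_dyads If `TRUE`, silent roster dyads enter the
#'   dyadic-duration statistics as zeros.
#' @return A one-row tibble of class `log_summary`.
#' @export
summarize_log <- function(log, include_zero_dyads = FALSE) {
  log <- as_event_log(log)
  durs <- log$end - log$start
  x <- aggregate_minutes(log)
  dyadic <- x[upper.tri(x)]
  if (!include_zero_dyads) dyadic <- dyadic[dyadic > 0]
  indiv <- rowSums(x)
  out <- tibble::tibble(
    n_events = nrow(log),
    duration_mean_s = if (length(durs)) mean(durs) else NA_real_,
    duration_sd_s = if (length(durs) > 1) stats::sd(durs) else NA_real_,
    dyadic_mean_min = if (length(dyadic)) mean(dyadic) else NA_real_,
    dyadic_sd_min = if (length(dyadic) > 1) stats::sd(dyadic) else NA_real_,
    individual_mean_min = if (length(indiv)) mean(indiv) else NA_real_,
    individual_sd_min = if (length(indiv) > 1) stats::sd(indiv) else NA_real_
  )
  class(out) <- c("log_summary", class(out))
  out
}
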