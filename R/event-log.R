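#' Dyadic contact event logs
#'
#' An `event_log` is a tibble of time-stamped dyadic contact intervals — the
#' record an active proximity badge produces: columns `id_a`, `id_b` (the two
#' participants, stored canonically with the lower identifier first), `start`
#' and `end` (integer seconds from the observation origin, half-open
#' `[start, end)` so `duration = end - start`). The tibble carries two
#' attributes: `roster`, the set of participant identifiers under
#' observation (possibly larger than the set appearing in events), and
#' `window`, the half-open observation interval `c(t0, t1)` in seconds.
#'
#' Construction always *normalizes*: dyads are canonicalized, events of the
#' same dyad that overlap or abut (zero gap) are merged — at 1-second
#' resolution a zero-length gap is indistinguishable from a continuous
#' signal — and events are sorted by start time, then dyad.
#'
#' @param events A data frame with columns `id_a`, `id_b`, `start`, `end`.
#'   Identifiers are coerced to character; times must be non-negative
#'   integer-valued seconds.
#' @param roster Optional character vector of participant identifiers. Must
#'   contain every identifier appearing in `events`; defaults to exactly
#'   those identifiers.
#' @param window Optional numeric vector `c(t0, t1)` delimiting the
#'   half-open observation interval in seconds. Defaults to
#'   `c(min(start), max(end))`. All events must lie within it.
#'
#' @return A tibble of class `event_log` with columns
#'   `id_a`, `id_b`, `start`, `end`, sorted and merged as described.
#' @examples
#' log <- event_log(data.frame(id_a = c("5", "1"), id_b = c("3", "10"),
#'                             start = c(0, 1), end = c(12, 29)))
#' log
#' roster(log)
#' obs_window(log)
#' @export
event_log <- function(events, roster = NULL, window = NULL) {
  events <- as_event_df(events)
  validate_events(events)
  events <- canonicalize_dyads(events)

  ids_seen <- unique(c(events$id_a, events$id_b))
  if (is.null(roster)) {
    roster <- ids_seen
  } else {
    roster <- unique(as.character(roster))
    missing <- setdiff(ids_seen, roster)
    if (length(missing) > 0L) {
      stop("roster is missing identifiers appearing in events: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  roster <- roster[order_ids(roster)]

  if (is.null(window)) {
    window <- if (nrow(events) > 0L) c(min(events$start), max(events$end)) else c(0, 0)
  }
  window <- as.integer(round(window))
  if (length(window) != 2L || window[2] < window[1]) {
    stop("window must be c(t0, t1) with t1 >= t0", call. = FALSE)
  }
  if (nrow(events) > 0L &&
      (min(events$start) < window[1] || max(events$end) > window[2])) {
    stop("events fall outside the observation window [",
         window[1], ", ", window[2], ")", call. = FALSE)
  }

  events <- merge_same_dyad(events)
  events <- events[order(events$start, dyad_key(events$id_a, events$id_b)), ]
  new_event_log(events, roster, window)
}

new_event_log <- function(events, roster, window) {
  out <- tibble::new_tibble(
    as.list(events),
    nrow = nrow(events),
    class = "event_log",
    roster = roster,
    window = as.integer(window)
  )
  out
}

#' @rdname event_log
#' @param x An object to convert or query.
#' @export
as_event_log <- function(x, roster = NULL, window = NULL) {
  if (inherits(x, "event_log") && is.null(roster) && is.null(window)) return(x)
  event_log(as.data.frame(x),
            roster = roster %||% attr(x, "roster"),
            window = window %||% attr(x, "window"))
}

#' @rdname event_log
#' @export
roster <- function(x) attr(x, "roster")

#' @rdname event_log
#' @export
obs_window <- function(x) attr(x, "window")

#' @export
as.data.frame.event_log <- function(x, ...) {
  data.frame(id_a = x$id_a, id_b = x$id_b, start = x$start, end = x$end,
             stringsAsFactors = FALSE)
}

#' @export
print.event_log <- function(x, ...) {
  w <- obs_window(x)
  cat(sprintf("# Contact event log: %d events, %d participants, window [%d, %d) s\n",
              nrow(x), length(roster(x)), w[1], w[2]))
  NextMethod()
}

# -- internal helpers ---------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

as_event_df <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  needed <- c("id_a", "id_b", "start", "end")
  miss <- setdiff(needed, names(events))
  if (length(miss) > 0L) {
    stop("events must have columns id_a, id_b, start, end (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  data.frame(
    id_a = as.character(events$id_a),
    id_b = as.character(events$id_b),
    start = as.integer(round(as.numeric(events$start))),
    end = as.integer(round(as.numeric(events$end))),
    stringsAsFactors = FALSE
  )
}

validate_events <- function(events) {
  if (nrow(events) == 0L) return(invisible(events))
  if (anyNA(events)) stop("events contain missing values", call. = FALSE)
  bad <- which(events$end <= events$start)
  if (length(bad) > 0L) {
    stop("event ", bad[1], ": end (", events$end[bad[1]],
         ") must be after start (", events$start[bad[1]], ")", call. = FALSE)
  }
  self <- which(events$id_a == events$id_b)
  if (length(self) > 0L) {
    stop("event ", self[1], ": a participant cannot interact with themselves (id ",
         events$id_a[self[1]], ")", call. = FALSE)
  }
  if (any(events$start < 0L)) stop("negative start times", call. = FALSE)
  invisible(events)
}

# Numeric order when every id parses as a number, else lexicographic.
order_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids)
}

id_rank <- function(ids, universe) {
  match(ids, universe[order_ids(universe)])
}

canonicalize_dyads <- function(events) {
  if (nrow(events) == 0L) return(events)
  universe <- unique(c(events$id_a, events$id_b))
  ra <- id_rank(events$id_a, universe)
  rb <- id_rank(events$id_b, universe)
  swap <- ra > rb
  if (any(swap)) {
    tmp <- events$id_a[swap]
    events$id_a[swap] <- events$id_b[swap]
    events$id_b[swap] <- tmp
  }
  events
}

dyad_key <- function(a, b) paste(a, b, sep = "--")

# Merge same-dyad events that overlap or abut (next start <= current end).
merge_same_dyad <- function(events) {
  if (nrow(events) <= 1L) return(events)
  events <- events[order(dyad_key(events$id_a, events$id_b), events$start), ]
  key <- dyad_key(events$id_a, events$id_b)
  keep_start <- events$start
  keep_end <- events$end
  out <- vector("list", nrow(events))
  n_out <- 0L
  cur <- 1L
  for (i in seq_len(nrow(events))[-1]) {
    if (key[i] == key[cur] && keep_start[i] <= keep_end[cur]) {
      keep_end[cur] <- max(keep_end[cur], keep_end[i])
    } else {
      n_out <- n_out + 1L
      out[[n_out]] <- cur
      cur <- i
    }
  }
  n_out <- n_out + 1L
  out[[n_out]] <- cur
  idx <- unlist(out[seq_len(n_out)])
  data.frame(
    id_a = events$id_a[idx], id_b = events$id_b[idx],
    start = keep_start[idx], end = keep_end[idx],
    stringsAsFactors = FALSE
  )
}

# All unordered roster dyads in canonical order, as a two-column data frame.
roster_dyads <- function(roster) {
  roster <- roster[order_ids(roster)]
  n <- length(roster)
  if (n < 2L) stop("roster must contain at least 2 participants", call. = FALSE)
  idx <- utils::combn(n, 2L)
  data.frame(id_a = roster[idx[1, ]], id_b = roster[idx[2, ]],
             stringsAsFactors = FALSE)
}
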