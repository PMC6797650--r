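#' Read and write contact event logs as CSV
#'
#' The on-disk layout is the standard badge edgelist: a header
#' `start,id_a,id_b,end` followed by one interval per row. Three time
#' dialects are supported and auto-detected: plain integer seconds,
#' clock times `HH:MM:SS` (interpreted as seconds of day; rows whose end
#' precedes the start — a midnight crossing — are rejected, date-stamped
#' input is required for multi-day recordings), and ISO date-times
#' `YYYY-MM-DDTHH:MM:SS` (converted to seconds from the earliest
#' timestamp's midnight, UTC).
#'
#' `write_event_log()` always writes integer seconds, so
#' `read_event_log(write_event_log(log))` reproduces `log` exactly.
#'
#' @param source Path or text connection of a CSV with columns
#'   `start,id_a,id_b,end` (any column order).
#' @param dialect One of `"auto"`, `"seconds"`, `"hms"`, `"datetime"`.
#' @param roster,window Passed on to [event_log()].
#' @return [read_event_log()] returns an [event_log()];
#'   [write_event_log()] invisibly returns its `log` argument.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("start,id_a,id_b,end", "18:19:46,3,5,18:19:58"), path)
#' read_event_log(path)
#' @export
read_event_log <- function(source, dialect = c("auto", "seconds", "hms", "datetime"),
                           roster = NULL, window = NULL) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("start", "id_a", "id_b", "end")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0L) {
    stop("event-log CSV must have columns start,id_a,id_b,end (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(event_log(data.frame(id_a = character(), id_b = character(),
                                start = integer(), end = integer()),
                     roster = roster, window = window))
  }
  if (dialect == "auto") dialect <- detect_time_dialect(raw$start[1])
  start <- parse_times(raw$start, dialect)
  end <- parse_times(raw$end, dialect)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("could not parse time on data row ", bad[1], " ('", raw$start[bad[1]],
         "' / '", raw$end[bad[1]], "') as dialect '", dialect, "'", call. = FALSE)
  }
  if (dialect == "datetime") {
    origin <- min(start)
    origin <- origin - (origin %% 86400)  # midnight of first day
    start <- start - origin
    end <- end - origin
  }
  if (dialect == "hms" && any(end < start)) {
    i <- which(end < start)[1]
    stop("data row ", i, ": end clock time precedes start — recordings that ",
         "cross midnight need date-stamped times (YYYY-MM-DDTHH:MM:SS)",
         call. = FALSE)
  }
  event_log(data.frame(id_a = raw$id_a, id_b = raw$id_b,
                       start = start, end = end, stringsAsFactors = FALSE),
            roster = roster, window = window)
}

#' @rdname read_event_log
#' @param log An [event_log()].
#' @param destination Path or connection to write to.
#' @export
write_event_log <- function(log, destination) {
  log <- as_event_log(log)
  df <- data.frame(start = log$start, id_a = log$id_a,
                   id_b = log$id_b, end = log$end)
  readr::write_csv(df, destination, progress = FALSE)
  invisible(log)
}

detect_time_dialect <- function(sample) {
  if (grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}$", sample)) return("datetime")
  if (grepl("^\\d{1,2}:\\d{2}:\\d{2}$", sample)) return("hms")
  if (grepl("^\\d+$", sample)) return("seconds")
  stop("cannot detect time dialect from value '", sample,
       "'; pass dialect explicitly", call. = FALSE)
}

parse_times <- function(x, dialect) {
  switch(dialect,
    seconds = suppressWarnings(as.integer(x)),
    hms = {
      ok <- grepl("^\\d{1,2}:\\d{2}:\\d{2}$", x)
      parts <- matrix(NA_integer_, nrow = length(x), ncol = 3)
      sp <- strsplit(x[ok], ":", fixed = TRUE)
      parts[ok, ] <- t(vapply(sp, function(p) as.integer(p), integer(3)))
      out <- parts[, 1] * 3600L + parts[, 2] * 60L + parts[, 3]
      out
    },
    datetime = {
      t <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
      t2 <- as.POSIXct(x, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
      t[is.na(t)] <- t2[is.na(t)]
      as.integer(round(as.numeric(t)))
    },
    stop("unknown dialect '", dialect, "'", call. = FALSE)
  )
}

#' Read and write square contact/nomination matrices
#'
#' Adjacency CSVs carry participant identifiers in the header row and the
#' first column. [read_adjacency_csv()] returns a numeric matrix with those
#' identifiers as dimnames; [write_adjacency_csv()] is its inverse.
#' [read_nomination_csv()] additionally accepts a long-form edge list with
#' columns `from,to` and binarizes.
#'
#' @param path File path.
#' @return A square numeric matrix with identifier dimnames.
#' @export
read_adjacency_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(sort(colnames(m)), sort(ids))) {
    stop("adjacency CSV header and identifier column disagree", call. = FALSE)
  }
  m <- m[, ids, drop = FALSE]
  m
}

#' @rdname read_adjacency_csv
#' @param m Square matrix with identifier dimnames.
#' @export
write_adjacency_csv <- function(m, path) {
  df <- cbind(data.frame(id = rownames(m), stringsAsFactors = FALSE),
              as.data.frame(m, check.names = FALSE))
  readr::write_csv(df, path, progress = FALSE)
  invisible(m)
}

#' @rdname read_adjacency_csv
#' @param ids Optional roster for long-form input.
#' @export
read_nomination_csv <- function(path, ids = NULL) {
  head1 <- readr::read_csv(path, n_max = 1, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (identical(names(head1)[1:2], c("from", "to"))) {
    edges <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
    ids <- ids %||% sort(unique(c(edges$from, edges$to)))
    y <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    y[cbind(match(edges$from, ids), match(edges$to, ids))] <- 1
    diag(y) <- 0
    return(y)
  }
  read_adjacency_csv(path)
}

#' Export a weighted contact network as GraphML
#'
#' Writes the weighted contact matrix as an undirected `igraph` graph whose
#' edge attribute `minutes` carries interaction time.
#'
#' @param x Weighted contact matrix from [aggregate_minutes()].
#' @param path Output path.
#' @export
write_contact_graphml <- function(x, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(x, mode = "undirected",
                                           weighted = "minutes", diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
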