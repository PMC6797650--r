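# Independent brute-force oracles and fixture builders. These deliberately
# work second-by-second on raw matrices, never through the interval code
# they are used to check.

table1_csv <- function() {
  c("start,id_a,id_b,end",
    "18:19:46,3,5,18:19:58",
    "18:19:47,1,10,18:20:15",
    "18:19:47,1,8,18:22:32",
    "18:19:49,10,8,18:22:35",
    "18:19:53,2,5,18:20:37",
    "18:20:04,6,11,18:20:14")
}

quick_log <- function(id_a, id_b, start, end, roster = NULL, window = NULL) {
  event_log(data.frame(id_a = as.character(id_a), id_b = as.character(id_b),
                       start = start, end = end, stringsAsFactors = FALSE),
            roster = roster, window = window)
}

# random normalized log on a small roster
random_log <- function(n_ids = 5, S = 120, n_events = 12, window = c(0, S)) {
  ids <- as.character(seq_len(n_ids))
  pairs <- t(utils::combn(ids, 2))
  k <- sample(nrow(pairs), n_events, replace = TRUE)
  start <- sample.int(S - 2L, n_events, replace = TRUE) - 1L
  len <- sample.int(20L, n_events, replace = TRUE)
  end <- pmin(start + len, S)
  keep <- end > start
  event_log(data.frame(id_a = pairs[k, 1], id_b = pairs[k, 2],
                       start = start, end = end)[keep, ],
            roster = ids, window = window)
}

# oracle: gap interpolation as per-second raster fill — every same-dyad
# zero-run of length <= max_gap flanked by ones becomes ones
oracle_interpolate_raster <- function(raster, max_gap) {
  out <- raster
  for (d in seq_len(nrow(raster))) {
    row <- raster[d, ]
    r <- rle(as.integer(row))
    pos <- cumsum(r$lengths)
    for (j in seq_along(r$values)) {
      if (r$values[j] == 0L && j > 1L && j < length(r$values) &&
          r$lengths[j] <= max_gap) {
        out[d, (pos[j] - r$lengths[j] + 1L):pos[j]] <- 1L
      }
    }
  }
  out
}

# oracle: one triadic-closure iteration, per second, via explicit triples
oracle_close_once <- function(raster, ids) {
  dy <- attr(raster, "dyads")
  out <- raster
  n <- length(ids)
  key <- function(a, b) {
    k <- paste(a, b, sep = "--")
    ifelse(k %in% rownames(raster), k, paste(b, a, sep = "--"))
  }
  for (s in seq_len(ncol(raster))) {
    for (a in ids) {
      partners <- ids[vapply(ids, function(b) {
        b != a && raster[key(a, b), s] == 1L
      }, logical(1))]
      if (length(partners) >= 2L) {
        cmb <- utils::combn(partners, 2)
        for (c2 in seq_len(ncol(cmb))) {
          out[key(cmb[1, c2], cmb[2, c2]), s] <- 1L
        }
      }
    }
  }
  out
}

oracle_close_raster <- function(raster, ids, iterations) {
  for (i in seq_len(iterations)) raster <- oracle_close_once(raster, ids)
  raster
}

# oracle: double-loop confusion tally
oracle_confusion <- function(obs, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (d in seq_len(nrow(obs))) {
    for (s in seq_len(ncol(obs))) {
      o <- obs[d, s]; v <- truth[d, s]
      if (o == 1L && v == 1L) tp <- tp + 1L
      else if (o == 1L && v == 0L) fp <- fp + 1L
      else if (o == 0L && v == 1L) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

dyad_rows <- function(log) {
  paste(log$id_a, log$id_b, log$start, log$end)
}
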