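#' Dyad-second confusion counts
#'
#' Compares a sensor raster against a ground-truth raster cell by cell over
#' all `D x S` dyad-seconds: a cell is a true positive when both indicate
#' contact, a false positive when only the sensor does, a false negative
#' when only the truth does, and a true negative when neither does. The
#' four counts always sum to `D x S`.
#'
#' @param observed,truth `dyad_raster` objects (see [rasterize()]) of
#'   identical shape and dyad indexing, or [event_log()]s (rasterized
#'   internally).
#' @return A one-row tibble of class `confusion_counts` with integer
#'   columns `tp`, `fp`, `fn`, `tn`.
#' @examples
#' truth <- event_log(data.frame(id_a = "1", id_b = "2", start = 0, end = 50),
#'                    window = c(0, 100))
#' obs <- event_log(data.frame(id_a = "1", id_b = "2", start = 20, end = 60),
#'                  window = c(0, 100))
#' confusion_counts(rasterize(obs), rasterize(truth))
#' @export
confusion_counts <- function(observed, truth) {
  if (inherits(observed, "event_log")) observed <- rasterize(observed)
  if (inherits(truth, "event_log")) truth <- rasterize(truth)
  if (!identical(dim(observed), dim(truth)) ||
      !identical(rownames(observed), rownames(truth))) {
    stop("observed and truth rasters must have identical shape and dyad indexing",
         call. = FALSE)
  }
  tp <- sum(observed == 1L & truth == 1L)
  fp <- sum(observed == 1L & truth == 0L)
  fn <- sum(observed == 0L & truth == 1L)
  tn <- sum(observed == 0L & truth == 0L)
  new_confusion_counts(tp, fp, fn, tn)
}

new_confusion_counts <- function(tp, fp, fn, tn) {
  out <- tibble::tibble(tp = as.double(tp), fp = as.double(fp),
                        fn = as.double(fn), tn = as.double(tn))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Validity metrics from confusion counts
#'
#' Sensitivity is the true-positive rate `tp / (tp + fn)`: the proportion of
#' ground-truth interaction seconds the sensor detected. Specificity is the
#' true-negative rate `tn / (tn + fp)`. Accuracy,
#' `(tp + tn) / (tp + fp + fn + tn)`, is the proportion of all dyad-seconds
#' classified correctly and weights every second equally; it is the default
#' optimization criterion for cutoff sweeps. `youden_sum` is the companion
#' relative index sensitivity + specificity. A ratio whose denominator is
#' zero is returned as `NA` (undefined, not an error); all-zero counts are
#' rejected.
#'
#' @param counts A `confusion_counts` row (or anything with named entries
#'   `tp`, `fp`, `fn`, `tn`).
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `accuracy`, `youden_sum` (proportions in `[0, 1]`, `[0, 2]`).
#' @examples
#' validity_metrics(data.frame(tp = 25326, fn = 25674, fp = 6086, tn = 196025))
#' @export
validity_metrics <- function(counts) {
  tp <- as.double(counts[["tp"]]); fp <- as.double(counts[["fp"]])
  fn <- as.double(counts[["fn"]]); tn <- as.double(counts[["tn"]])
  if (anyNA(c(tp, fp, fn, tn)) || any(c(tp, fp, fn, tn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  total <- tp + fp + fn + tn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(
    sensitivity = sens,
    specificity = spec,
    accuracy = (tp + tn) / total,
    youden_sum = sens + spec
  )
}

#' Merge two raters' codings at a split time
#'
#' Combines two independent codings of the same observation so each rater
#' accounts for one part of the coded time: rater A's events restricted to
#' `[t0, split_time)` and rater B's to `[split_time, t1)`, events straddling
#' the boundary truncated, and the result re-normalized.
#'
#' @param log_a,log_b [event_log()]s sharing roster and window.
#' @param split_time Boundary in seconds, inside the window.
#' @return An [event_log()].
#' @export
merge_rater_codings <- function(log_a, log_b, split_time) {
  log_a <- as_event_log(log_a)
  log_b <- as_event_log(log_b)
  check_compatible(log_a, log_b)
  w <- obs_window(log_a)
  if (split_time < w[1] || split_time > w[2]) {
    stop("split_time must lie within the observation window", call. = FALSE)
  }
  clip <- function(df, lo, hi) {
    df <- as.data.frame(df)
    df$start <- pmax(df$start, lo)
    df$end <- pmin(df$end, hi)
    df[df$end > df$start, , drop = FALSE]
  }
  ev <- rbind(clip(log_a, w[1], split_time), clip(log_b, split_time, w[2]))
  event_log(ev, roster = roster(log_a), window = w)
}

#' Cohen's kappa for two binary coders
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and expected agreement `p_e` from the two
#' coders' marginal label frequencies. When the marginals make agreement
#' certain (`p_e = 1`, both coders constant with the same label), perfect
#' agreement is reported as `kappa = 1`; a constant coder disagreeing is
#' undefined and returned as `NA`.
#'
#' Used here on dyad-second indicators over a doubly-coded overlap window,
#' consistent with the second-level validity framework.
#'
#' @param labels_a,labels_b Equal-length binary (0/1 or logical) vectors,
#'   length >= 2.
#' @return A single number in `[-1, 1]` (or `NA`).
#' @examples
#' cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 0.5
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  a <- as.integer(labels_a)
  b <- as.integer(labels_b)
  if (length(a) != length(b)) stop("label sequences differ in length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 labels", call. = FALSE)
  if (anyNA(a) || anyNA(b) || !all(c(a, b) %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  n <- length(a)
  p_o <- mean(a == b)
  p1a <- mean(a); p1b <- mean(b)
  p_e <- p1a * p1b + (1 - p1a) * (1 - p1b)
  if (p_e >= 1) {
    return(if (p_o == 1) 1 else NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Validate a sensor log against ground truth
#'
#' The end-to-end construct-validity check: applies an optional processing
#' pipeline to the sensor log, rasterizes both logs to dyad-second
#' indicators, and reports confusion counts and validity metrics for the
#' raw and the processed data.
#'
#' @param observed Sensor [event_log()].
#' @param truth Ground-truth [event_log()] (shared roster and window).
#' @param steps Processing pipeline (list of steps; see
#'   [step_min_duration()]); empty list for raw-only validation.
#' @return A list of class `validity_report` with elements `raw` and
#'   `processed`, each a one-row tibble of counts + metrics, and `steps`.
#' @examples
#' truth <- event_log(data.frame(id_a = "1", id_b = "2", start = 0, end = 100))
#' obs <- event_log(data.frame(id_a = c("1", "1"), id_b = c("2", "2"),
#'                             start = c(0, 60), end = c(40, 100)),
#'                  window = c(0, 100))
#' validate_contacts(obs, truth, list(step_interpolate(75)))
#' @export
validate_contacts <- function(observed, truth, steps = list()) {
  observed <- as_event_log(observed)
  truth <- as_event_log(truth)
  check_compatible(observed, truth)
  truth_r <- rasterize(truth)
  score <- function(log) {
    cc <- confusion_counts(rasterize(log), truth_r)
    dplyr::bind_cols(cc, validity_metrics(cc))
  }
  raw <- score(observed)
  processed <- if (length(steps) > 0L) score(apply_pipeline(observed, steps)) else raw
  structure(list(raw = raw, processed = processed, steps = steps),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  fmt <- function(m) {
    sprintf("sens %.1f%%, spec %.1f%%, acc %.1f%% (tp %.0f, fp %.0f, fn %.0f, tn %.0f)",
            100 * m$sensitivity, 100 * m$specificity, 100 * m$accuracy,
            m$tp, m$fp, m$fn, m$tn)
  }
  cat("Construct-validity report (dyad-second level)\n")
  cat("  raw:       ", fmt(x$raw), "\n")
  if (length(x$steps) > 0L) {
    lab <- paste(vapply(x$steps, function(s) paste0(s$kind, "(", s$value, ")"), ""),
                 collapse = " -> ")
    cat("  processed: ", fmt(x$processed), "\n")
    cat("  pipeline:  ", lab, "\n")
  }
  invisible(x)
}

#' Export validation results
#'
#' `write_validation_report()` serializes a [validate_contacts()] report to
#' JSON (counts, metrics and pipeline provenance).
#' `write_confusion_table()` writes the 2x2 classification table as CSV in
#' the conventional layout — rows: truth positive/negative; columns:
#' observed positive/negative.
#'
#' @param report A `validity_report`.
#' @param path Output path.
#' @export
write_validation_report <- function(report, path) {
  steps <- lapply(report$steps, function(s) list(kind = s$kind, value = s$value))
  jsonlite::write_json(
    list(raw = as.list(report$raw), processed = as.list(report$processed),
         pipeline = steps),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_validation_report
#' @param counts A `confusion_counts` row.
#' @export
write_confusion_table <- function(counts, path) {
  df <- data.frame(
    truth = c("positive", "negative"),
    observed_positive = c(counts[["tp"]], counts[["fp"]]),
    observed_negative = c(counts[["fn"]], counts[["tn"]])
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
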