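#' Symmetrize a directed nomination matrix
#'
#' Self-reported interaction nominations are directed (row nominates
#' column). For robustness analyses an undirected tie can be declared when
#' at least one member nominates (`"weak"`, logical OR with the transpose)
#' or only when both do (`"strong"`, logical AND). `"none"` returns the
#' matrix unchanged. Entrywise, `strong(y) <= y <= weak(y)` always holds.
#'
#' @param y Square binary matrix, zero diagonal. `NA` rows/columns
#'   (non-responders) propagate through.
#' @param mode `"none"`, `"weak"` or `"strong"`.
#' @return A binary matrix of the same shape.
#' @export
symmetrize <- function(y, mode = c("none", "weak", "strong")) {
  mode <- match.arg(mode)
  check_nomination(y)
  out <- switch(mode,
    none = y,
    weak = (y + t(y) > 0) * 1,
    strong = (y * t(y) > 0) * 1
  )
  if (mode == "weak") out[is.na(y) & is.na(t(y))] <- NA
  out
}

check_nomination <- function(y) {
  if (!is.matrix(y) || nrow(y) != ncol(y)) {
    stop("nomination matrix must be square", call. = FALSE)
  }
  vals <- y[!is.na(y)]
  if (!all(vals %in% c(0, 1))) stop("nominations must be binary 0/1", call. = FALSE)
  if (any(diag(y) != 0, na.rm = TRUE)) stop("diagonal must be zero", call. = FALSE)
  invisible(y)
}

#' Reciprocity of a directed nomination network
#'
#' The fraction of directed ties whose reverse tie is also present.
#'
#' @param y Square binary nomination matrix.
#' @return A proportion in `[0, 1]`.
#' @examples
#' y <- matrix(0, 4, 4); y[1, 2] <- y[2, 1] <- y[1, 3] <- 1
#' reciprocity(y)  # 2/3
#' @export
reciprocity <- function(y) {
  check_nomination(y)
  ties <- sum(y, na.rm = TRUE)
  if (ties == 0) stop("nomination matrix has no ties", call. = FALSE)
  sum(y * t(y), na.rm = TRUE) / ties
}

#' Compare contact durations between nominated and non-nominated dyads
#'
#' Pooled-variance two-sample t test (and Cohen's d with pooled SD) of
#' dyad-level interaction minutes between dyads with and without a
#' self-reported tie. The unit is the undirected dyad; a dyad counts as
#' nominated under the chosen symmetrization of the directed reports.
#' Dyads involving participants with missing reports are dropped.
#'
#' @param x Weighted contact matrix (minutes), as from
#'   [aggregate_minutes()].
#' @param y Directed binary nomination matrix over the same roster.
#' @param mode Symmetrization used to define "nominated" (default weak:
#'   either member reported the interaction).
#' @return A one-row tibble of class `duration_group_test`: `t`
#'   (non-nominated minus nominated, so large contact in nominated dyads
#'   gives negative t), `df`, `p_value`, `cohens_d` (sign of nominated
#'   minus non-nominated mean), group means and sizes.
#' @export
duration_by_nomination_test <- function(x, y, mode = "weak") {
  check_rosters(x, y)
  ys <- symmetrize(y, mode)
  ut <- upper.tri(x)
  dur <- x[ut]
  nom <- ys[ut]
  keep <- !is.na(nom)
  dur <- dur[keep]; nom <- nom[keep]
  g0 <- dur[nom == 0]; g1 <- dur[nom == 1]
  if (length(g0) < 2L || length(g1) < 2L) {
    stop("need at least 2 dyads in each nomination group", call. = FALSE)
  }
  if (stats::var(g0) == 0 && stats::var(g1) == 0) {
    stop("both groups have zero variance; t statistic undefined", call. = FALSE)
  }
  tt <- stats::t.test(g0, g1, var.equal = TRUE)
  sd_pool <- sqrt(((length(g0) - 1) * stats::var(g0) +
                   (length(g1) - 1) * stats::var(g1)) /
                  (length(g0) + length(g1) - 2))
  out <- tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    cohens_d = (mean(g1) - mean(g0)) / sd_pool,
    mean_nominated = mean(g1),
    mean_not_nominated = mean(g0),
    n_nominated = length(g1),
    n_not_nominated = length(g0)
  )
  class(out) <- c("duration_group_test", class(out))
  out
}

check_rosters <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("x and y differ in size", call. = FALSE)
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y))) {
    stop("x and y rosters disagree", call. = FALSE)
  }
  invisible(TRUE)
}

#' Logistic regression of nominations on contact duration
#'
#' Fits, by maximum likelihood, the probability that a nomination is
#' reported as a logistic function of the dyad's interaction duration in
#' minutes. The default unit of analysis is the directed dyad: all
#' `N(N-1)` ordered pairs, the undirected duration entering both
#' directions, rows with a missing outcome (non-responding nominator)
#' dropped listwise. With `unit = "symmetrized"` the `N(N-1)/2` undirected
#' dyads are used with the outcome symmetrized by `mode`.
#'
#' @param x Weighted contact matrix (minutes).
#' @param y Directed binary nomination matrix; `NA` rows for
#'   non-responders.
#' @param unit `"directed"` or `"symmetrized"`.
#' @param mode Symmetrization when `unit = "symmetrized"`.
#' @return An object of class `duration_logit` wrapping the [stats::glm()]
#'   fit, with [generics::tidy()] and [generics::glance()] methods.
#'   `glance()` reports the log-likelihood, the intercept-only
#'   log-likelihood, and McFadden's pseudo R-squared
#'   `1 - logLik / logLik_null`.
#' @examples
#' set.seed(1)
#' ids <- as.character(1:20)
#' x <- matrix(0, 20, 20, dimnames = list(ids, ids))
#' x[upper.tri(x)] <- rexp(190, 1 / 20)
#' x <- x + t(x)
#' y <- generate_self_reports(x, intercept = -2.16, slope_per_min = 0.02, seed = 2)
#' fit <- fit_duration_logit(x, y)
#' generics::tidy(fit)
#' generics::glance(fit)
#' @export
fit_duration_logit <- function(x, y, unit = c("directed", "symmetrized"),
                               mode = "weak") {
  unit <- match.arg(unit)
  check_rosters(x, y)
  if (unit == "directed") {
    off <- row(y) != col(y)
    dat <- data.frame(nominated = y[off], minutes = x[off])
  } else {
    ys <- symmetrize(y, mode)
    ut <- upper.tri(y)
    dat <- data.frame(nominated = ys[ut], minutes = x[ut])
  }
  dat <- dat[!is.na(dat$nominated), , drop = FALSE]
  if (length(unique(dat$nominated)) < 2L) {
    stop("outcome must contain both nominated and non-nominated dyads",
         call. = FALSE)
  }
  degenerate <- stats::var(dat$minutes) == 0
  form <- if (degenerate) nominated ~ 1 else nominated ~ minutes
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  if (!degenerate && !fit$converged) {
    stop("logistic fit did not converge (possible perfect separation)",
         call. = FALSE)
  }
  if (!degenerate) {
    # near-zero residual variance on fitted probs 0/1 signals separation
    p <- stats::fitted(fit)
    if (all(p < 1e-8 | p > 1 - 1e-8)) {
      stop("perfect separation: fitted probabilities all 0 or 1", call. = FALSE)
    }
  }
  null_fit <- stats::glm(nominated ~ 1, family = stats::binomial(), data = dat)
  structure(
    list(fit = fit, null_fit = null_fit, unit = unit, n = nrow(dat),
         degenerate_predictor = degenerate),
    class = "duration_logit"
  )
}

#' @export
print.duration_logit <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf("Logistic model of nominations on contact minutes (%s dyads, n = %d)\n",
              x$unit, x$n))
  if (x$degenerate_predictor) {
    cat("  [duration constant: slope indeterminate, intercept-only fit]\n")
  }
  print(generics::tidy(x))
  cat(sprintf("  logLik %.2f, null logLik %.2f, McFadden R2 %.3f\n",
              g$logLik, g$null_logLik, g$mcfadden_r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy duration_logit
#' @export
tidy.duration_logit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = if (x$degenerate_predictor) "(Intercept)" else c("(Intercept)", "minutes"),
    estimate = unname(s[, 1]),
    std_error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p_value = unname(s[, 4])
  )
}

#' @method glance duration_logit
#' @export
glance.duration_logit <- function(x, ...) {
  ll <- as.numeric(stats::logLik(x$fit))
  ll0 <- as.numeric(stats::logLik(x$null_fit))
  tibble::tibble(
    logLik = ll,
    null_logLik = ll0,
    mcfadden_r2 = 1 - ll / ll0,
    n = x$n,
    unit = x$unit
  )
}

#' Deviance comparison of two duration-logit fits
#'
#' Descriptive deviance difference `chi^2 = 2 |logLik_a - logLik_b|` between
#' two models fit to the same outcome vector (typically the same
#' nominations predicted from differently processed duration matrices).
#' Because such models are not nested, this is reported as a descriptive
#' index with a caller-supplied reference df rather than a formal nested
#' likelihood-ratio test.
#'
#' @param result_a,result_b `duration_logit` objects on the same outcome.
#' @param df Reference degrees of freedom for the comparison (default 2).
#' @return A one-row tibble with `chisq`, `df`, `better` (which fit has the
#'   higher log-likelihood) and `p_value` under the reference df.
#' @export
compare_fits <- function(result_a, result_b, df = 2) {
  if (result_a$n != result_b$n) {
    stop("fits are based on different numbers of dyads", call. = FALSE)
  }
  la <- as.numeric(stats::logLik(result_a$fit))
  lb <- as.numeric(stats::logLik(result_b$fit))
  chisq <- 2 * abs(la - lb)
  tibble::tibble(
    chisq = chisq,
    df = df,
    better = if (la >= lb) "a" else "b",
    p_value = stats::pchisq(chisq, df = df, lower.tail = FALSE)
  )
}
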