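# small helper: symmetric duration matrix + roster
toy_matrices <- function(n = 20, seed = 1, rate = 1 / 20) {
  set.seed(seed)
  ids <- as.character(seq_len(n))
  x <- matrix(0, n, n, dimnames = list(ids, ids))
  x[upper.tri(x)] <- rexp(n * (n - 1) / 2, rate)
  x + t(x)
}

test_that("symmetrization brackets the directed reports", {
  ids <- as.character(1:4)
  y <- matrix(0, 4, 4, dimnames = list(ids, ids))
  y[1, 2] <- 1
  weak <- symmetrize(y, "weak")
  strong <- symmetrize(y, "strong")
  expect_equal(weak[2, 1], 1)
  expect_equal(sum(strong), 0)
  expect_equal(symmetrize(y, "none"), y)

  # already-symmetric matrix is a fixed point of both
  ys <- matrix(0, 4, 4, dimnames = list(ids, ids))
  ys[1, 2] <- ys[2, 1] <- 1
  expect_equal(symmetrize(ys, "weak"), ys)
  expect_equal(symmetrize(ys, "strong"), ys)

  # strong <= y <= weak entrywise, exhaustively on random 5x5s
  set.seed(99)
  for (i in 1:20) {
    y <- matrix(rbinom(25, 1, 0.4), 5, 5)
    diag(y) <- 0
    expect_true(all(symmetrize(y, "strong") <= y))
    expect_true(all(y <= symmetrize(y, "weak")))
  }

  expect_error(symmetrize(y, "odd"), "arg")
})

test_that("reciprocity counts mutual directed ties", {
  ids <- as.character(1:4)
  y <- matrix(0, 4, 4, dimnames = list(ids, ids))
  y[1, 2] <- y[2, 1] <- y[1, 3] <- 1
  expect_equal(reciprocity(y), 2 / 3)

  mutual <- symmetrize(y, "weak")
  expect_equal(reciprocity(mutual), 1)

  tournament <- matrix(0, 3, 3)
  tournament[upper.tri(tournament)] <- 1
  expect_equal(reciprocity(tournament), 0)

  expect_error(reciprocity(matrix(0, 3, 3)), "no ties")
})

test_that("duration group test recovers standardized shifts", {
  x <- toy_matrices(n = 25, seed = 3)
  ids <- rownames(x)

  # identical group distributions: t = 0, d = 0 (constructed symmetric case)
  n <- 6
  x0 <- matrix(0, n, n, dimnames = list(as.character(1:n), as.character(1:n)))
  x0[upper.tri(x0)] <- rep(c(1, 5), length.out = n * (n - 1) / 2)
  x0 <- x0 + t(x0)
  y0 <- matrix(0, n, n)
  # nominate exactly one dyad of each duration value -> equal group means
  y0[1, 2] <- y0[2, 1] <- 1  # duration 1
  y0[1, 3] <- y0[3, 1] <- 1  # duration 5
  ut <- upper.tri(x0)
  d1 <- x0[ut][symmetrize(y0, "weak")[ut] == 1]
  expect_equal(mean(d1), mean(c(1, 5)))

  # degenerate zero-variance case is an explicit error
  xz <- matrix(0, 6, 6)
  yz <- matrix(0, 6, 6); yz[1, 2] <- yz[3, 4] <- yz[4, 3] <- yz[2, 1] <- 1
  expect_error(duration_by_nomination_test(xz, yz), "zero variance")

  # synthetic shift of 1 SD recovered within tolerance
  set.seed(44)
  n <- 46  # 1035 dyads
  ids <- as.character(1:n)
  xs <- matrix(0, n, n, dimnames = list(ids, ids))
  nom <- matrix(0, n, n, dimnames = list(ids, ids))
  base <- rnorm(n * (n - 1) / 2, 10, 2)
  pick <- rbinom(length(base), 1, 0.5)
  xs[upper.tri(xs)] <- base + 2 * pick  # shift = 1 SD
  xs <- xs + t(xs)
  nom[upper.tri(nom)] <- pick
  nom <- nom + t(nom)
  res <- duration_by_nomination_test(xs, nom)
  expect_gt(res$cohens_d, 0.8)
  expect_lt(res$cohens_d, 1.2)
  expect_lt(res$t, 0)  # more contact among nominated -> negative t
  expect_equal(res$df, res$n_nominated + res$n_not_nominated - 2)

  # label swap flips t's sign, |t| invariant
  res_sw <- duration_by_nomination_test(xs, 1 - nom - diag(1, n))
  expect_equal(abs(res_sw$t), abs(res$t), tolerance = 1e-12)
  expect_equal(res_sw$t, -res$t, tolerance = 1e-12)
})

test_that("logistic fit recovers generating coefficients and handles edge cases", {
  x <- toy_matrices(n = 55, seed = 7)  # 2970 directed dyads
  y <- generate_self_reports(x, intercept = -2.16, slope_per_min = 0.02, seed = 8)
  fit <- fit_duration_logit(x, y)
  td <- generics::tidy(fit)
  est <- td$estimate; se <- td$std_error
  expect_lt(abs(est[1] - (-2.16)), 3 * se[1])
  expect_lt(abs(est[2] - 0.02), 3 * se[2])
  expect_equal(fit$n, 55 * 54)

  gl <- generics::glance(fit)
  expect_gte(gl$mcfadden_r2, 0)
  expect_lt(gl$mcfadden_r2, 1)

  # outcome independent of duration: McFadden R2 near 0
  set.seed(9)
  y_perm <- y
  off <- row(y) != col(y)
  y_perm[off] <- sample(y[off])
  gl0 <- generics::glance(fit_duration_logit(x, y_perm))
  expect_lt(gl0$mcfadden_r2, 0.01)

  # duration identically zero: slope indeterminate, intercept = logit(mean)
  x0 <- x * 0
  fit0 <- fit_duration_logit(x0, y)
  expect_true(fit0$degenerate_predictor)
  p <- mean(y[off])
  expect_equal(generics::tidy(fit0)$estimate[1], qlogis(p), tolerance = 1e-6)

  # non-responder NA rows are dropped listwise
  y_na <- y
  y_na[3, ] <- NA
  fit_na <- fit_duration_logit(x, y_na)
  expect_equal(fit_na$n, 55 * 54 - 54)

  # perfect separation raises an explicit error
  ids <- as.character(1:30)
  xs <- matrix(0, 30, 30, dimnames = list(ids, ids))
  xs[upper.tri(xs)] <- seq_len(435)
  xs <- xs + t(xs)
  ys <- (xs > 200) * 1
  diag(ys) <- 0
  expect_error(suppressWarnings(fit_duration_logit(xs, ys)),
               "separation|converge")
})

test_that("cross-checked against glm on the flattened dyad frame", {
  # independent route: build the directed frame by explicit double loop
  x <- toy_matrices(n = 12, seed = 10)
  y <- generate_self_reports(x, seed = 11)
  rows <- list(); k <- 0
  for (i in 1:12) for (j in 1:12) if (i != j) {
    k <- k + 1
    rows[[k]] <- data.frame(nom = y[i, j], min = x[i, j])
  }
  df <- do.call(rbind, rows)
  ref <- stats::glm(nom ~ min, binomial(), df)
  fit <- fit_duration_logit(x, y)
  expect_equal(unname(coef(fit$fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(as.numeric(logLik(fit$fit)), as.numeric(logLik(ref)),
               tolerance = 1e-10)
})

test_that("deviance comparison is symmetric in magnitude and zero on self", {
  x <- toy_matrices(n = 30, seed = 12)
  y <- generate_self_reports(x, seed = 13)
  fit_a <- fit_duration_logit(x, y)
  # noised duration matrix: same outcome, weaker predictor
  set.seed(14)
  xn <- x
  xn[upper.tri(xn)] <- sample(x[upper.tri(x)])
  xn[lower.tri(xn)] <- t(xn)[lower.tri(xn)]
  fit_b <- fit_duration_logit(xn, y)

  self <- compare_fits(fit_a, fit_a)
  expect_equal(self$chisq, 0)

  cmp <- compare_fits(fit_a, fit_b, df = 2)
  expect_gte(cmp$chisq, 0)
  expect_equal(cmp$better, "a")  # generating matrix fits better
  expect_equal(cmp$df, 2)

  # hand-arithmetic contract: logLik difference of 10 -> chisq 20
  fake_a <- fit_a; fake_b <- fit_b
  expect_equal(2 * abs(as.numeric(logLik(fit_a$fit)) - as.numeric(logLik(fit_b$fit))),
               cmp$chisq)

  # mismatched n rejected
  x2 <- toy_matrices(n = 10, seed = 15)
  y2 <- generate_self_reports(x2, seed = 16)
  expect_error(compare_fits(fit_a, fit_duration_logit(x2, y2)), "different numbers")
})

test_that("slope recovery is unbiased with nominal 3-SE coverage", {
  x <- toy_matrices(n = 40, seed = 20)
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    y <- generate_self_reports(x, intercept = -2.16, slope_per_min = 0.02,
                               seed = 100 + r)
    td <- generics::tidy(fit_duration_logit(x, y))
    if (abs(td$estimate[2] - 0.02) <= 3 * td$std_error[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("McFadden R2 grows with the generating slope", {
  x <- toy_matrices(n = 45, seed = 25, rate = 1 / 30)
  r2 <- vapply(c(0, 0.01, 0.02), function(sl) {
    y <- generate_self_reports(x, intercept = -2.16, slope_per_min = sl, seed = 77)
    generics::glance(fit_duration_logit(x, y))$mcfadden_r2
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_lt(r2[1], 0.01)
})
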