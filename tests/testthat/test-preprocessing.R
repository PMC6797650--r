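test_that("minimal-duration filtering uses a strict 'shorter than' rule", {
  log <- quick_log(c("1", "1"), c("2", "3"), c(0, 0), c(19, 20),
                   roster = c("1", "2", "3"))
  out <- filter_min_duration(log, 20)
  # the 19 s event is deleted, the 20 s event retained
  expect_equal(nrow(out), 1L)
  expect_equal(out$id_b, "3")

  # cutoff 0 is the identity
  expect_equal(as.data.frame(filter_min_duration(log, 0)), as.data.frame(log))
  expect_error(filter_min_duration(log, -1), "non-negative")

  # output is a subset; positives non-increasing in the cutoff
  set.seed(5)
  lg <- random_log()
  prev <- Inf
  for (cut in c(0, 5, 10, 20, 50)) {
    f <- filter_min_duration(lg, cut)
    expect_true(all(dyad_rows(f) %in% dyad_rows(lg)))
    pos <- sum(rasterize(f))
    expect_lte(pos, prev)
    prev <- pos
  }
})

test_that("gap interpolation merges inclusively, transitively, idempotently", {
  # gap of 15 <= 20 -> one event spanning both and the gap
  log <- quick_log(c("1", "1"), c("2", "2"), c(0, 25), c(10, 40))
  out <- interpolate_gaps(log, 20)
  expect_equal(as.data.frame(out),
               data.frame(id_a = "1", id_b = "2", start = 0L, end = 40L))

  # boundary-inclusive chain: gaps of exactly 75 merge across the chain
  chain <- quick_log(rep("1", 3), rep("2", 3), c(0, 85, 170), c(10, 95, 180))
  out <- interpolate_gaps(chain, 75)
  expect_equal(as.data.frame(out),
               data.frame(id_a = "1", id_b = "2", start = 0L, end = 180L))
  # one second wider and nothing merges
  expect_equal(nrow(interpolate_gaps(chain, 74)), 3L)

  expect_error(interpolate_gaps(log, -5), "non-negative")

  set.seed(9)
  for (i in 1:10) {
    lg <- random_log()
    g <- sample(c(0, 3, 10, 25), 1)
    m <- interpolate_gaps(lg, g)
    # idempotence
    expect_equal(as.data.frame(interpolate_gaps(m, g)), as.data.frame(m))
    # active seconds only grow
    expect_true(all(rasterize(m) >= rasterize(lg)))
    # monotone in the gap parameter
    m2 <- interpolate_gaps(lg, g + 10)
    expect_true(all(rasterize(m2) >= rasterize(m)))
  }
})

test_that("interval interpolation equals the per-second raster-fill oracle", {
  set.seed(101)
  for (i in 1:60) {
    lg <- random_log(n_ids = sample(3:6, 1), S = sample(60:120, 1),
                     n_events = sample(5:15, 1))
    g <- sample(0:30, 1)
    got <- rasterize(interpolate_gaps(lg, g))
    want <- oracle_interpolate_raster(rasterize(lg), g)
    expect_identical(unclass(got)[, ], unclass(want)[, ])
  }
})

test_that("triadic closure intersects intervals and reaches clique fixpoints", {
  # A-B on [0,100), A-C on [50,150): B-C imputed on the overlap [50,100)
  log <- quick_log(c("A", "A"), c("B", "C"), c(0, 50), c(100, 150))
  out <- close_triads(log, 1)
  bc <- out[out$id_a == "B" & out$id_b == "C", ]
  expect_equal(bc$start, 50L)
  expect_equal(bc$end, 100L)

  # 0 iterations is the identity
  expect_equal(as.data.frame(close_triads(log, 0)), as.data.frame(log))

  # clique-structured logs are fixpoints for any iteration count
  clique <- quick_log(c("A", "A", "B"), c("B", "C", "C"),
                      c(0, 0, 0), c(60, 60, 60))
  expect_equal(as.data.frame(close_triads(clique, 3)), as.data.frame(clique))

  # path A-B-C-D: iteration 1 adds A-C, B-D; iteration 2 completes the
  # 4-clique; iteration 3 changes nothing further
  path <- quick_log(c("A", "B", "C"), c("B", "C", "D"),
                    c(0, 0, 0), c(50, 50, 50))
  it1 <- close_triads(path, 1)
  expect_equal(nrow(it1), 5L)  # + A-C and B-D
  expect_false(any(it1$id_a == "A" & it1$id_b == "D"))
  it2 <- close_triads(path, 2)
  expect_equal(nrow(it2), 6L)  # full clique
  it3 <- close_triads(path, 3)
  expect_equal(as.data.frame(it3), as.data.frame(it2))

  # active seconds never shrink across iterations
  set.seed(13)
  lg <- random_log(n_ids = 6)
  prev <- sum(rasterize(lg))
  for (k in 1:3) {
    cur <- sum(rasterize(close_triads(lg, k)))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("interval closure equals the per-second brute-force oracle", {
  set.seed(202)
  for (i in 1:25) {
    n_ids <- sample(4:6, 1)
    lg <- random_log(n_ids = n_ids, S = sample(40:120, 1),
                     n_events = sample(6:14, 1))
    k <- sample(1:3, 1)
    got <- rasterize(close_triads(lg, k))
    want <- oracle_close_raster(rasterize(lg), roster(lg), k)
    expect_identical(unclass(got)[, ], unclass(want)[, ])
  }
})

test_that("pipelines apply steps in declared order", {
  log <- quick_log(c("1", "1"), c("2", "2"), c(0, 60), c(40, 100))

  # interpolate(75) then min_duration(55): merged to [0,100), retained
  out <- apply_pipeline(log, list(step_interpolate(75), step_min_duration(55)))
  expect_equal(as.data.frame(out),
               data.frame(id_a = "1", id_b = "2", start = 0L, end = 100L))

  # reversed order deletes both 40 s fragments first: empty output
  rev <- apply_pipeline(log, list(step_min_duration(55), step_interpolate(75)))
  expect_equal(nrow(rev), 0L)

  # empty config is the identity; provenance is recorded
  idp <- apply_pipeline(log, list())
  expect_equal(as.data.frame(idp), as.data.frame(log))
  expect_equal(attr(out, "pipeline"),
               list(step_interpolate(75), step_min_duration(55)))

  expect_error(apply_pipeline(log, list(list(kind = "polish", value = 1))),
               "unknown processing step")
})

test_that("processing configs load from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("steps:",
               "  - kind: interpolate",
               "    max_gap_s: 75",
               "  - kind: min_duration",
               "    cutoff_s: 55",
               "sweep:",
               "  strategy: interpolate",
               "  grid: [0, 15, 30]",
               "  criterion: accuracy"), yml)
  cfg <- read_processing_config(yml)
  expect_equal(length(cfg$steps), 2L)
  expect_equal(cfg$steps[[1]]$kind, "interpolate")
  expect_equal(cfg$steps[[2]]$value, 55)
  expect_equal(cfg$sweep$strategy, "interpolate")

  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"steps": [{"kind": "triadic_closure", "iterations": 2}]}', js)
  cfg2 <- read_processing_config(js)
  expect_equal(cfg2$steps[[1]]$value, 2L)

  writeLines('{"steps": [{"kind": "sparkle"}]}', js)
  expect_error(read_processing_config(js), "unknown processing step")
})

test_that("sweeps score each grid point and find the optimum", {
  truth <- quick_log("1", "2", 0, 100, roster = c("1", "2"), window = c(0, 100))

  # observed = truth: min-duration optimum at 0 with accuracy 1
  sw <- sweep_strategy(truth, truth, "min_duration", c(0, 10, 20))
  expect_equal(attr(sw, "optimum"), 0)
  expect_equal(sw$accuracy[1], 1)
  expect_equal(nrow(sw), 3L)

  # flickered observation: interpolation improves accuracy over baseline
  obs <- quick_log(rep("1", 3), rep("2", 3), c(0, 40, 70), c(30, 60, 100),
                   roster = c("1", "2"), window = c(0, 100))
  sw2 <- sweep_strategy(obs, truth, "interpolate", c(0, 5, 10, 20))
  expect_true(max(sw2$accuracy) > sw2$accuracy[1])
  expect_equal(attr(sw2, "optimum"), 10)  # both gaps bridged at 10

  # ties break toward the smallest grid value
  sw3 <- sweep_strategy(obs, truth, "interpolate", c(10, 20))
  expect_equal(attr(sw3, "optimum"), 10)

  # mismatched windows are rejected
  obs2 <- quick_log("1", "2", 0, 50, roster = c("1", "2"), window = c(0, 50))
  expect_error(sweep_strategy(obs2, truth, "interpolate", 0), "window")
  expect_error(sweep_strategy(obs, truth, "interpolate", numeric(0)), "non-empty")
})
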