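test_that("two synthetic bumps are detected at their centers", {
  # the canonical two-peak geometry: centers 0.65 and 1.95 on a length-2.6
  # grid, amplitude twice the detection threshold, width 0.2
  f <- makeProfileFixture(L = 2.6, dx = 0.01, centers = c(0.65, 1.95),
                          amplitude = 1, width = 0.2)
  pk <- detectPeaks(f$a, f$x, theta_peak = 0.5)
  expect_identical(nrow(pk), 2L)
  expect_lt(max(abs(pk$x - c(0.65, 1.95))), 0.01 + 1e-12)
})

test_that("a profile below threshold yields no peaks, narrow blips are ignored", {
  f <- makeProfileFixture(amplitude = 0.4)
  expect_identical(nrow(detectPeaks(f$a, f$x, theta_peak = 0.5)), 0L)
  # a one-node spike is narrower than w_min
  a <- rep(0, 101); a[51] <- 1
  x <- seq(0, 1, by = 0.01)
  expect_identical(nrow(detectPeaks(a, x, w_min = 0.04)), 0L)
})

test_that("detectPeaks agrees with the brute-force oracle on random profiles", {
  set.seed(42)
  x <- seq(0, 4, by = 0.01)
  for (rep in seq_len(100)) {
    nb <- sample(0:4, 1)
    a <- rep(runif(1, 0, 0.3), length(x))
    if (nb > 0) {
      ctrs <- runif(nb, 0.2, 3.8)
      for (cc in ctrs) a <- a + runif(1, 0.3, 1.2) *
          exp(-((x - cc) / runif(1, 0.05, 0.3))^2)
    }
    a <- pmax(a + runif(length(x), -0.05, 0.05), 0)
    pk <- detectPeaks(a, x, theta_peak = 0.5, w_min = 0.04)
    oracle <- toothwave:::detectPeaksBruteForce(a, x, theta_peak = 0.5,
                                               w_min = 0.04)
    expect_identical(nrow(pk), oracle$count)
    if (oracle$count) expect_equal(pk$x, oracle$x)
  }
})

test_that("overlapping bump supports are rejected when disjointness is requested", {
  expect_error(makeProfileFixture(centers = c(1.0, 1.2), width = 0.2),
               "overlap")
  expect_silent(makeProfileFixture(centers = c(1.0, 1.2), width = 0.2,
                                   disjoint = FALSE))
})

test_that("an imposed-speed front fixture is recovered within 1%", {
  cgf <- makeChronogramFixture("front", speed = 0.02, x0 = 3, t_end = 80)
  ff <- frontSpeed(cgf, level = 0.5)
  expect_lt(abs(ff$speed - 0.02) / 0.02, 0.01)
  expect_gt(ff$speed, 0)   # moving anteriorly
  # deterministic generation
  cgf2 <- makeChronogramFixture("front", speed = 0.02, x0 = 3, t_end = 80)
  expect_identical(fieldMatrix(cgf, "activator"), fieldMatrix(cgf2, "activator"))
})

test_that("a constant-in-time chronogram yields an empty event log", {
  cg <- makeChronogramFixture("bumps", t_end = 60)
  expect_identical(eventCount(trackEvents(cg)), 0L)
})

test_that("front fitting needs crossings in at least half the frames", {
  cg <- makeChronogramFixture("bumps", t_end = 60)  # no 0.5-crossing front
  expect_error(frontSpeed(cg, level = 2), "crossing")
  expect_error(frontSpeed(cg, t_window = c(0, 3)), "at least 5 frames")
})

test_that("a merge is logged as fusion when the merged peak persists, and never double-logged", {
  # hand-built chronogram: two peaks drift together and merge at t = 30
  dx <- 0.01; x <- seq(0, 3, by = dx); times <- 0:80
  A <- matrix(0, length(times), length(x))
  for (j in seq_along(times)) {
    t <- times[j]
    d <- max(0.8 - 0.02 * t, 0.18)   # center separation shrinks, then holds
    A[j, ] <- exp(-((x - (1.5 - d / 2)) / 0.15)^2) +
      exp(-((x - (1.5 + d / 2)) / 0.15)^2)
  }
  zero <- matrix(0, length(times), length(x))
  cg <- toothwave:::newChronogram(times, rep(length(x), length(times)), dx,
    A, zero, zero, zero, matrix(0L, length(times), length(x)),
    rep(0, length(times)), list(), 1L)
  ev <- trackEvents(cg)
  expect_identical(eventCount(ev, "fusion"), 1L)
  expect_identical(eventCount(ev, "erasure"), 0L)
  # if instead the merged object dies immediately, the merge becomes
  # erasure(s) of its constituents and no fusion is logged
  A2 <- A
  merge_j <- which(sapply(seq_along(times), function(j) {
    nrow(detectPeaks(A2[j, ], x)) == 1
  }))[1]
  A2[(merge_j + 3):nrow(A2), ] <- 0
  cg2 <- toothwave:::newChronogram(times, rep(length(x), length(times)), dx,
    A2, zero, zero, zero, matrix(0L, length(times), length(x)),
    rep(0, length(times)), list(), 1L)
  ev2 <- trackEvents(cg2)
  expect_identical(eventCount(ev2, "fusion"), 0L)
  expect_gte(eventCount(ev2, "erasure"), 1L)
})

test_that("a recovery references a prior erasure at an overlapping site", {
  # peak exists, disappears, then reappears at the same place
  dx <- 0.01; x <- seq(0, 2, by = dx); times <- 0:120
  A <- matrix(0, length(times), length(x))
  bump <- exp(-((x - 1) / 0.15)^2)
  A[times <= 40, ] <- matrix(bump, sum(times <= 40), length(x), byrow = TRUE)
  A[times >= 80, ] <- matrix(bump, sum(times >= 80), length(x), byrow = TRUE)
  zero <- matrix(0, length(times), length(x))
  cg <- toothwave:::newChronogram(times, rep(length(x), length(times)), dx,
    A, zero, zero, zero, matrix(0L, length(times), length(x)),
    rep(0, length(times)), list(), 1L)
  ev <- trackEvents(cg)
  expect_identical(eventCount(ev, "erasure"), 1L)
  expect_identical(eventCount(ev, "recovery"), 1L)
  expect_identical(eventCount(ev, "birth"), 0L)
  evd <- events(ev)
  expect_lt(evd$time[evd$type == "erasure"], evd$time[evd$type == "recovery"])
})

test_that("event logs serialize to JSON", {
  # reuse the erasure/recovery fixture so the log is non-empty
  dx <- 0.01; x <- seq(0, 2, by = dx); times <- 0:120
  A <- matrix(0, length(times), length(x))
  bump <- exp(-((x - 1) / 0.15)^2)
  A[times <= 40, ] <- matrix(bump, sum(times <= 40), length(x), byrow = TRUE)
  A[times >= 80, ] <- matrix(bump, sum(times >= 80), length(x), byrow = TRUE)
  zero <- matrix(0, length(times), length(x))
  cg <- toothwave:::newChronogram(times, rep(length(x), length(times)), dx,
    A, zero, zero, zero, matrix(0L, length(times), length(x)),
    rep(0, length(times)), list(), 1L)
  ev <- trackEvents(cg)
  expect_gt(eventCount(ev), 0L)
  path <- tempfile(fileext = ".json")
  writeEventsJSON(ev, path)
  back <- jsonlite::fromJSON(path)
  expect_identical(nrow(back$events), nrow(events(ev)))
  expect_setequal(back$events$type, events(ev)$type)
})
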