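# a censoring-free cohort with risks spread over the four categories
ccFreeFixture <- function(n = 120, seed = 55) {
  set.seed(seed)
  base <- runif(n, 0.01, 0.35)
  upd <- pmin(pmax(base + rnorm(n, 0, 0.05), 0), 1)
  event <- runif(n) < base
  time <- ifelse(event, runif(n, 0.5, 9.5), 10.5)  # all followed past 10
  list(base = base, upd = upd, time = time, event = event)
}

test_that("KM event weights reduce to indicators without censoring", {
  fx <- ccFreeFixture()
  w <- kmEventWeights(fx$time, fx$event, tStar = 10)
  expect_equal(w, as.numeric(fx$event))
  # censored-early subjects get fractional weights in (0, 1)
  t2 <- c(1, 2, 3, 11, 11, 11, 11, 11)
  e2 <- c(FALSE, TRUE, TRUE, rep(FALSE, 5))
  w2 <- kmEventWeights(t2, e2, tStar = 10)
  expect_gt(w2[1], 0); expect_lt(w2[1], 1)
  expect_equal(w2[2:3], c(1, 1))
  expect_equal(w2[4:8], rep(0, 5))
})

test_that("reclassification tables cross-tabulate and carry KM events", {
  fx <- ccFreeFixture()
  tab <- buildReclassTable(fx$base, fx$base, fx$time, fx$event)
  expect_equal(sum(tab$counts), length(fx$base))
  expect_true(all(tab$counts[upper.tri(tab$counts)] == 0))
  expect_true(all(tab$counts[lower.tri(tab$counts)] == 0))
  # censoring-free: expected events equal observed events per cell
  tab2 <- buildReclassTable(fx$base, fx$upd, fx$time, fx$event)
  cb <- riskCategory(fx$base); cu <- riskCategory(fx$upd)
  for (i in 1:4) for (j in 1:4) {
    k <- as.integer(cb) == i & as.integer(cu) == j
    expect_equal(tab2$expectedEvents[i, j], sum(fx$event[k]),
                 tolerance = 1e-10)
  }
  expect_error(buildReclassTable(fx$base, fx$upd, fx$time, fx$event,
                                 tStar = -1))
})

test_that("a hand-tallied 12-subject fixture cross-tabulates exactly", {
  base <- c(0.05, 0.08, 0.12, 0.13, 0.16, 0.19, 0.22, 0.30,
            0.11, 0.17, 0.09, 0.21)
  upd <- c(0.06, 0.11, 0.12, 0.09, 0.21, 0.19, 0.22, 0.18,
           0.16, 0.12, 0.05, 0.25)
  time <- rep(11, 12); event <- rep(FALSE, 12)
  tab <- buildReclassTable(base, upd, time, event)
  expect_equal(sum(tab$counts), 12)
  expect_equal(tab$counts["low", "low"], 2)                        # 1, 11
  expect_equal(tab$counts["low", "intermediate_low"], 1)           # 2
  expect_equal(tab$counts["intermediate_low", "low"], 1)           # 4
  expect_equal(tab$counts["intermediate_low", "intermediate_low"], 1)
  expect_equal(tab$counts["intermediate_low", "intermediate_high"], 1)
  expect_equal(tab$counts["intermediate_high", "high"], 1)         # 5
  expect_equal(tab$counts["intermediate_high", "intermediate_high"], 1)
  expect_equal(tab$counts["intermediate_high", "intermediate_low"], 1)
  expect_equal(tab$counts["high", "high"], 2)                      # 7, 12
  expect_equal(tab$counts["high", "intermediate_high"], 1)         # 8
})

test_that("category NRI matches direct counting when censoring-free", {
  fx <- ccFreeFixture(n = 200, seed = 56)
  nri <- categoryNRI(buildReclassTable(fx$base, fx$upd, fx$time,
                                       fx$event))
  oracle <- bruteForceNRI(fx$base, fx$upd, fx$event)
  expect_equal(nri$events, oracle$events, tolerance = 1e-10)
  expect_equal(nri$nonevents, oracle$nonevents, tolerance = 1e-10)
  expect_equal(nri$total, nri$events + nri$nonevents, tolerance = 1e-12)
})

test_that("NRI identities: zero on identity, antisymmetric on swap", {
  fx <- ccFreeFixture(n = 150, seed = 57)
  id <- categoryNRI(buildReclassTable(fx$base, fx$base, fx$time,
                                      fx$event))
  expect_equal(id$events, 0); expect_equal(id$nonevents, 0)
  ab <- categoryNRI(buildReclassTable(fx$base, fx$upd, fx$time, fx$event))
  ba <- categoryNRI(buildReclassTable(fx$upd, fx$base, fx$time, fx$event))
  expect_equal(ab$events, -ba$events, tolerance = 1e-10)
  expect_equal(ab$nonevents, -ba$nonevents, tolerance = 1e-10)
  # component sum equals the total for arbitrary inputs
  for (s in 1:4) {
    fy <- ccFreeFixture(n = 80, seed = 60 + s)
    cens <- seq_along(fy$time) %% 3 == 0
    fy$time[cens] <- runif(sum(cens), 1, 8); fy$event[cens] <- FALSE
    z <- categoryNRI(buildReclassTable(fy$base, fy$upd, fy$time,
                                       fy$event))
    expect_equal(z$total, z$events + z$nonevents, tolerance = 1e-12)
  }
})

test_that("the constructed all-up toy yields NRI_events = 1", {
  # 10 events all moving up one category, 90 non-events static
  base <- c(rep(0.12, 10), rep(0.05, 90))
  upd <- c(rep(0.17, 10), rep(0.05, 90))
  event <- c(rep(TRUE, 10), rep(FALSE, 90))
  time <- ifelse(event, 5, 10.5)
  nri <- categoryNRI(buildReclassTable(base, upd, time, event))
  expect_equal(nri$events, 1.0)
  expect_equal(nri$nonevents, 0.0)
  expect_equal(nri$total, 1.0)
})

test_that("zero expected events is a defined error", {
  base <- rep(0.05, 10); time <- rep(10.5, 10); event <- rep(FALSE, 10)
  expect_error(categoryNRI(buildReclassTable(base, base, time, event)),
               "undefined")
})

test_that("IDI matches the discrimination-slope definition", {
  fx <- ccFreeFixture(n = 150, seed = 58)
  v <- idi(fx$base, fx$upd, fx$time, fx$event)
  slope <- function(r) mean(r[fx$event]) - mean(r[!fx$event])
  expect_equal(v$idi, slope(fx$upd) - slope(fx$base), tolerance = 1e-12)
  expect_equal(v$idiPercent, 100 * v$idi)
  expect_identical(idi(fx$base, fx$base, fx$time, fx$event)$idi, 0)
  # events' mean risk up 0.05, non-events' down 0.01 -> IDI 0.06
  base <- c(rep(0.10, 4), rep(0.10, 6))
  upd <- base + c(rep(0.05, 4), rep(-0.01, 6))
  ev <- c(rep(TRUE, 4), rep(FALSE, 6))
  tm <- ifelse(ev, 3, 10.5)
  v2 <- idi(base, upd, tm, ev)
  expect_equal(v2$idi, 0.06, tolerance = 1e-12)
  expect_equal(v2$idiPercent, 6.0, tolerance = 1e-9)
})

test_that("permuting the marker increments gives a near-zero mean IDI", {
  fx <- ccFreeFixture(n = 200, seed = 59)
  delta <- fx$upd - fx$base  # the marker's contribution to the risk
  set.seed(123)
  vals <- vapply(1:40, function(i) {
    upd0 <- pmin(pmax(fx$base + sample(delta), 0), 1)
    idi(fx$base, upd0, fx$time, fx$event)$idi
  }, 0)
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("the bias-corrected intermediate NRI needs intermediate subjects", {
  base <- rep(0.05, 20); upd <- base
  time <- rep(10.5, 20); event <- rep(FALSE, 20)
  expect_error(intermediateNRI(base, upd, time, event), "intermediate")
})

test_that("bootstrapCI is deterministic, exact for constants, and sane", {
  cst <- function(idx) c(m = 1.23)
  ci <- bootstrapCI(cst, n = 50, B = 100, seed = 4)
  expect_equal(unname(ci["m", ]), c(1.23, 1.23))
  set.seed(31)
  x <- rnorm(100)
  mfun <- function(idx) c(m = mean(x[idx]))
  ci1 <- bootstrapCI(mfun, n = 100, B = 1000, seed = 9)
  ci2 <- bootstrapCI(mfun, n = 100, B = 1000, seed = 9)
  expect_identical(ci1, ci2)
  width <- ci1["m", "ucl"] - ci1["m", "lcl"]
  expect_lt(abs(width - 2 * 1.96 / sqrt(100)) / (2 * 1.96 / sqrt(100)),
            0.2)
  # excessive failure rate aborts
  bad <- function(idx) stop("boom")
  expect_error(bootstrapCI(bad, n = 10, B = 100, seed = 1), "failed")
})
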