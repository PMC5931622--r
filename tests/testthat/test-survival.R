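test_that("fitCoxModel matches an independent partial-likelihood solver", {
  set.seed(61)
  n <- 18
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.2 * exp(0.8 * x))
  df <- handCohortDF(n, time = time, event = rep(TRUE, n))
  fit <- fitCoxModel(CohortTable(df), x, modelSpec("1a"))
  expect_equal(log(fit$hr$hr), bruteForceCoxBeta(x, time, rep(1, n)),
               tolerance = 1e-6)
})

test_that("duplicating every subject leaves the HR unchanged", {
  sim <- smallCohort(n = 400, seed = 5)
  df <- as.data.frame(sim$cohort)
  z <- sim$grsZ
  f1 <- fitCoxModel(sim$cohort, z, modelSpec("1a"))
  df2 <- rbind(df, df); df2$id <- sprintf("d%04d", seq_len(nrow(df2)))
  f2 <- fitCoxModel(CohortTable(df2), c(z, z), modelSpec("1a"))
  # replication preserves the partial likelihood up to the Efron tie
  # correction the duplicated event times introduce
  expect_equal(f2$hr$hr, f1$hr$hr, tolerance = 1e-3)
})

test_that("hazard ratios are invariant to the time unit", {
  sim <- smallCohort(n = 500, seed = 6)
  df <- as.data.frame(sim$cohort)
  f1 <- fitCoxModel(sim$cohort, sim$grsZ, modelSpec("1a"))
  df$followup_time <- df$followup_time * 365.25
  f2 <- fitCoxModel(CohortTable(df), sim$grsZ, modelSpec("1a"))
  expect_equal(f2$hr$hr, f1$hr$hr, tolerance = 1e-8)
})

test_that("the model suites nest as specified", {
  sa <- modelSpec("1a"); sb <- modelSpec("1b")
  sc <- modelSpec("2c"); sd <- modelSpec("2d")
  expect_equal(sa$covariates, character(0))
  expect_true(all(sb$covariates %in% sc$covariates))
  expect_true(all(sc$covariates %in% sd$covariates))
  expect_equal(sa$grsForm, "per_sd")
  expect_equal(sd$grsForm, "tertiles")
  sim <- smallCohort(n = 2500, seed = 29, hr = 1.6)
  tert <- assignTertiles(sim$scores$GRS12,
                         as.character(sim$cohort$ancestry))
  f <- fitCoxModel(sim$cohort, tert, modelSpec("2b"))
  expect_equal(f$hr$term, c("grsT2", "grsT3"))
  expect_true(all(f$hr$lcl < f$hr$hr & f$hr$hr < f$hr$ucl))
})

test_that("the PH diagnostic behaves under null and violation", {
  sim <- smallCohort(n = 2000, seed = 37, hr = 1.5)
  chk <- phCheck(sim$cohort, sim$grsZ, modelSpec("1a"))
  expect_true(chk$p > 0 && chk$p <= 1)
  expect_error(phCheck(sim$cohort, rep(1, nrow(sim$cohort))),
               "constant")
  # a strongly time-varying effect is flagged
  set.seed(101)
  n <- 3000
  z <- rnorm(n)
  u <- runif(n)
  tEvent <- ifelse(z > 0, qexp(u, 0.25), qexp(u, 0.02))  # early risk if z>0
  df <- handCohortDF(n, time = pmin(tEvent, 9), event = tEvent <= 9)
  df$pc1 <- rnorm(n)
  viol <- phCheck(CohortTable(df), z, modelSpec("1a", nPCs = 1))
  expect_lt(viol$p, 0.01)
})

test_that("Harrell's C equals exhaustive pair enumeration", {
  expect_equal(harrellsC(c(3, 2, 1), time = 1:3, event = rep(TRUE, 3)), 1)
  expect_equal(harrellsC(rep(1, 5), time = 1:5, event = rep(TRUE, 5)), 0.5)
  set.seed(15)
  for (rep in 1:4) {
    n <- 15
    risk <- sample(1:5, n, replace = TRUE)  # with risk ties
    time <- round(rexp(n, 0.2), 2)
    event <- runif(n) < 0.6
    if (sum(event) < 2) next
    expect_equal(harrellsC(risk, time, event),
                 bruteForceC(risk, time, event))
  }
})

test_that("reversing the risk ranking flips C around one half", {
  set.seed(16)
  n <- 40
  risk <- rnorm(n)  # continuous: no ties
  time <- rexp(n); event <- rep(TRUE, n)
  expect_equal(harrellsC(risk, time, event) +
                 harrellsC(-risk, time, event), 1)
})

test_that("KM event probability matches hand product-limit tables", {
  # 10 subjects, 2 events before t, no censoring
  time <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  event <- c(TRUE, TRUE, rep(FALSE, 8))
  expect_equal(kmEventProb(time, c(rep(TRUE, 10)), tStar = 2.5), 0.2)
  # censoring-free: matches the empirical CDF at any horizon
  set.seed(8)
  t2 <- rexp(30)
  for (ts in c(0.5, 1, 2))
    expect_equal(kmEventProb(t2, rep(TRUE, 30), ts), mean(t2 <= ts))
  # staggered censoring, 8 subjects, against the hand KM oracle
  t3 <- c(1, 2, 2.5, 3, 4, 4.5, 6, 7)
  e3 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(kmEventProb(t3, e3, tStar = 6.5), handKM(t3, e3, 6.5))
  # survival is non-increasing in the horizon
  ps <- vapply(seq(0.5, 7, by = 0.5), function(ts)
    kmEventProb(t3, e3, ts), 0)
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("extrapolation extends the curve with the final-year hazard", {
  time <- c(2, 4, 5, 6, 7, 8, 8.5, 8.7)
  event <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  pIn <- kmEventProb(time, event, tStar = 8.7)
  pOut <- kmEventProb(time, event, tStar = 10)
  expect_gt(pOut, pIn)
  expect_lt(pOut, 1)
  expect_error(kmEventProb(time, event, tStar = 10, extrapolate = FALSE),
               "extrapolate")
  # all censored, beyond data, without extrapolation: defined error
  expect_error(kmEventProb(c(1, 2), c(FALSE, FALSE), 10,
                           extrapolate = FALSE), "extrapolate")
})

test_that("Hosmer-Lemeshow is zero when equal risks match the events", {
  set.seed(91)
  n <- 400
  p <- rep(0.3, n)
  event <- rep(c(TRUE, FALSE), c(120, 280))  # exactly n x 0.3 events
  time <- ifelse(event, runif(n, 0, 9), 10.5)
  hl <- hosmerLemeshow(p, time, event, bins = 10, tStar = 10)
  expect_equal(hl$binsUsed, 1)  # all risks equal: bins merge
  expect_lt(hl$chi2, 1e-8)
  # a grossly miscalibrated model is rejected
  set.seed(92)
  p2 <- runif(n, 0.05, 0.6)
  ev2 <- runif(n) < p2
  t2 <- ifelse(ev2, runif(n, 0, 9), 10.5)
  hlBad <- hosmerLemeshow(p2 / 3, t2, ev2, bins = 10, tStar = 10)
  expect_lt(hlBad$p, 0.001)
  expect_equal(hlBad$df, hlBad$binsUsed - 1)
})

test_that("age-adjusted Poisson rates respect symmetry and nulls", {
  # two tertiles with identical event/person-time profiles
  df <- handCohortDF(90, time = rep(c(2, 3, 4), 30),
                     event = rep(c(TRUE, FALSE, FALSE), 30))
  tert <- rep(1:3, each = 30)
  r <- ageAdjustedRates(CohortTable(df), tert)
  expect_equal(r$rate[1], r$rate[2], tolerance = 1e-6)
  expect_equal(r$rate[2], r$rate[3], tolerance = 1e-6)
  # age unrelated to hazard: adjusted rates approximate crude rates
  set.seed(44)
  n <- 3000
  tert2 <- sample(1:3, n, replace = TRUE)
  rate <- c(0.01, 0.02, 0.04)[tert2]
  tEv <- rexp(n, rate)
  df2 <- handCohortDF(n, time = pmin(tEv, 8), event = tEv <= 8,
                      risk_age = runif(n, 30, 79))
  r2 <- ageAdjustedRates(CohortTable(df2), tert2)
  crude <- vapply(1:3, function(k) {
    i <- tert2 == k
    1000 * sum(df2$event[i]) / sum(df2$followup_time[i])
  }, 0)
  expect_equal(r2$rate, crude, tolerance = 0.12)
  # a doubled true rate is recovered
  expect_gt(r2$rate[3] / r2$rate[2], 1.5)
  expect_lt(r2$rate[3] / r2$rate[2], 2.7)
})
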