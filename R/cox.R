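#' Cox model suite specifications
#'
#' The eight fitted models cross the score form (suite 1: per-SD
#' continuous; suite 2: ancestry-specific tertiles, lowest tertile as
#' referent) with four nested covariate tiers: (a) ancestry PCs only;
#' (b) plus the individual Framingham components (age, sex, total
#' cholesterol, HDL-C, systolic and diastolic blood pressure, smoking,
#' diabetes); (c) plus family history; (d) plus education, body-mass
#' index, anti-hypertensive and lipid-lowering treatment and alcohol.
#'
#' @param name One of "1a","1b","1c","1d","2a","2b","2c","2d".
#' @param nPCs Number of leading ancestry PCs to adjust for (default 6).
#' @return A list of class \code{"modelSpec"} with \code{name},
#'   \code{grsForm} and \code{covariates}.
#' @export
modelSpec <- function(name = c("1a", "1b", "1c", "1d",
                               "2a", "2b", "2c", "2d"), nPCs = 6) {
  name <- match.arg(name)
  tier <- substr(name, 2, 2)
  covs <- character(0)                                    # tier a: PCs only
  if (tier %in% c("b", "c", "d"))
    covs <- c(covs, "age", "sex", "total_chol", "hdl", "sbp", "dbp",
              "smoker", "diabetes")
  if (tier %in% c("c", "d")) covs <- c(covs, "family_history")
  if (tier == "d") covs <- c(covs, "education", "bmi", "bp_treated",
                             "lipid_treated", "alcohol")
  structure(list(name = name,
                 grsForm = if (startsWith(name, "1")) "per_sd" else "tertiles",
                 covariates = covs, nPCs = nPCs),
            class = "modelSpec")
}

#' Fit one Cox model of a GRS on incident CHD
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for the
#' score plus the covariate tier of \code{spec}. For
#' \code{grsForm = "per_sd"} pass the standardized score in \code{score};
#' for tertiles pass the integer tertile labels.
#'
#' @param cohort A \code{CohortTable} (single ancestry stratum, or any
#'   subset with PCs valid within it).
#' @param score Standardized score or tertile labels, one per subject.
#' @param spec A \code{\link{modelSpec}}.
#' @return A list of class \code{"coxFit"}: \code{fit} (the
#'   \code{coxph} object), \code{hr} (data.frame of term, hr, lcl, ucl,
#'   se, p for the score terms), \code{n}, \code{events},
#'   \code{loglik}, \code{spec}.
#' @export
fitCoxModel <- function(cohort, score, spec = modelSpec("1a")) {
  df <- as.data.frame(cohort)
  stopifnot(length(score) == nrow(df))
  if (sum(df$event, na.rm = TRUE) < 1) stop("no events in cohort")
  if (spec$grsForm == "per_sd") {
    df$grs <- as.numeric(score)
    grsTerms <- "grs"
  } else {
    df$grs <- factor(score, levels = 1:3,
                     labels = c("T1", "T2", "T3"))
    grsTerms <- c("grsT2", "grsT3")
  }
  pcs <- pcColumns(df, spec$nPCs)
  rhs <- paste(c("grs", pcs, spec$covariates), collapse = " + ")
  keep <- stats::complete.cases(
    df[, c("followup_time", "event", "grs", pcs, spec$covariates),
       drop = FALSE])
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(followup_time, event) ~", rhs)),
    data = df[keep, , drop = FALSE], ties = "efron")
  beta <- stats::coef(fit)
  if (anyNA(beta)) stop("rank-deficient design in model ", spec$name)
  if (any(abs(beta[grsTerms]) > 10))
    stop("monotone likelihood (separation) for the score in model ",
         spec$name)
  se <- sqrt(diag(stats::vcov(fit)))[grsTerms]
  z <- stats::qnorm(0.975)
  hr <- data.frame(term = grsTerms,
                   hr = exp(beta[grsTerms]),
                   lcl = exp(beta[grsTerms] - z * se),
                   ucl = exp(beta[grsTerms] + z * se),
                   se = se,
                   p = 2 * stats::pnorm(-abs(beta[grsTerms] / se)),
                   row.names = NULL)
  structure(list(fit = fit, hr = hr, n = fit$n, events = fit$nevent,
                 loglik = fit$loglik, spec = spec),
            class = "coxFit")
}

#' @export
print.coxFit <- function(x, ...) {
  cat("Cox model", x$spec$name, "-", x$n, "subjects,", x$events,
      "events\n")
  h <- x$hr
  for (i in seq_len(nrow(h)))
    cat(sprintf("  %s: HR %.2f (%.2f-%.2f)\n",
                h$term[i], h$hr[i], h$lcl[i], h$ucl[i]))
  invisible(x)
}

#' Proportional-hazards diagnostic: GRS x follow-up time interaction
#'
#' Refits the model with a time-transform interaction term
#' (score x t) and returns the Wald p-value of that term; values below
#' \code{flagBelow} flag a PH violation.
#'
#' @param cohort A \code{CohortTable}.
#' @param score Standardized score (continuous).
#' @param spec A \code{\link{modelSpec}} (per-SD form).
#' @param flagBelow Flag threshold (default 0.10).
#' @return List with \code{p} and logical \code{flagged}.
#' @export
phCheck <- function(cohort, score, spec = modelSpec("1a"),
                    flagBelow = 0.10) {
  df <- as.data.frame(cohort)
  df$grs <- as.numeric(score)
  if (stats::sd(df$grs, na.rm = TRUE) == 0)
    stop("constant score has no time interaction")
  pcs <- pcColumns(df, spec$nPCs)
  rhs <- paste(c("grs", "tt(grs)", pcs, spec$covariates), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(followup_time, event) ~", rhs)),
    data = df, ties = "efron", tt = function(x, t, ...) x * t)
  i <- grep("^tt\\(grs\\)", names(stats::coef(fit)))
  se <- sqrt(diag(stats::vcov(fit)))[i]
  p <- unname(2 * stats::pnorm(-abs(stats::coef(fit)[i] / se)))
  list(p = p, flagged = p < flagBelow)
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable pair under right censoring, the
#' subject with the earlier event carries the higher predicted risk;
#' risk ties count 0.5. Computed via \code{survival::concordance}.
#'
#' @param risk Predicted risk (higher = worse).
#' @param time,event Follow-up and event indicator.
#' @return Concordance in [0, 1].
#' @export
harrellsC <- function(risk, time, event) {
  stopifnot(length(risk) >= 2)
  cc <- survival::concordance(
    survival::Surv(time, event) ~ risk, reverse = TRUE, timewt = "n")
  counts <- cc$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs")
  unname(cc$concordance)
}

#' Paired-bootstrap comparison of two C statistics
#'
#' Resamples subjects with replacement, recomputes both concordances on
#' each replicate and returns a two-sided percentile p-value for the
#' difference (updated minus base).
#'
#' @param riskBase,riskUpdated The two risk vectors.
#' @param time,event Follow-up and event indicator.
#' @param B Bootstrap replicates.
#' @param seed Seed.
#' @return List with \code{cBase}, \code{cUpdated}, \code{delta},
#'   \code{ci} and \code{p}.
#' @export
compareCStatistics <- function(riskBase, riskUpdated, time, event,
                               B = 500, seed = 1) {
  c0 <- harrellsC(riskBase, time, event)
  c1 <- harrellsC(riskUpdated, time, event)
  n <- length(time)
  set.seed(seed)
  deltas <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    harrellsC(riskUpdated[i], time[i], event[i]) -
      harrellsC(riskBase[i], time[i], event[i])
  }, 0)
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  list(cBase = c0, cUpdated = c1, delta = c1 - c0,
       ci = unname(stats::quantile(deltas, c(0.025, 0.975))),
       p = min(p, 1))
}

#' Kaplan-Meier event probability by a horizon, with extrapolation
#'
#' Product-limit event probability by \code{tStar}. When \code{tStar}
#' exceeds the last observed time the survival curve is extended under
#' a constant hazard equal to the average cumulative-hazard increment
#' over the final observed year (the follow-up is shorter than the
#' 10-year reporting horizon, so 10-year risks are extrapolated).
#'
#' @param time,event Follow-up and event indicator.
#' @param tStar Horizon (years).
#' @param extrapolate Allow extension beyond the data (default TRUE).
#' @return Event probability in [0, 1].
#' @export
kmEventProb <- function(time, event, tStar = 10, extrapolate = TRUE) {
  stopifnot(tStar > 0, length(time) == length(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  S <- stats::stepfun(sf$time, c(1, sf$surv))
  tmax <- max(time)
  if (tStar <= tmax) return(1 - S(tStar))
  if (!extrapolate)
    stop("horizon beyond observed follow-up and extrapolate = FALSE")
  Smax <- S(tmax)
  if (Smax <= 0) return(1)
  win <- min(1, tmax)
  h <- (-log(Smax) + log(S(tmax - win))) / win  # avg hazard, final year
  1 - Smax * exp(-h * (tStar - tmax))
}

#' Hosmer-Lemeshow calibration test over Kaplan-Meier expected events
#'
#' Subjects are binned by deciles of predicted risk (default 10 bins;
#' empty bins arising from ties are merged with a neighbour and the
#' realized bin count reported). Observed events per bin are
#' \code{n_b} times the bin's KM event probability at \code{tStar};
#' expected events are the summed predicted risks. The statistic is
#' \code{sum (O - E)^2 / (E (1 - E / n_b))} on \code{bins - 1} degrees
#' of freedom.
#'
#' @param predRisk Predicted event probabilities by \code{tStar}.
#' @param time,event Follow-up and event indicator.
#' @param bins Number of risk strata (default 10).
#' @param tStar Horizon (default 10 years).
#' @return List with \code{chi2}, \code{df}, \code{p},
#'   \code{binsUsed} and the per-bin table.
#' @export
hosmerLemeshow <- function(predRisk, time, event, bins = 10, tStar = 10) {
  n <- length(predRisk)
  stopifnot(n >= bins, length(time) == n, length(event) == n)
  br <- unique(stats::quantile(predRisk, seq(0, 1, length.out = bins + 1),
                               type = 7, names = FALSE))
  g <- if (length(br) < 2) rep(1L, n)  # constant risks: one stratum
  else cut(predRisk, br, include.lowest = TRUE, labels = FALSE)
  ids <- sort(unique(g))
  tab <- do.call(rbind, lapply(ids, function(b) {
    i <- g == b
    data.frame(bin = b, n = sum(i),
               observed = sum(i) * kmEventProb(time[i], event[i], tStar),
               expected = sum(predRisk[i]))
  }))
  binsUsed <- nrow(tab)
  if (binsUsed < bins)
    message("merged ", bins - binsUsed, " empty risk bin(s)")
  denom <- tab$expected * (1 - tab$expected / tab$n)
  chi2 <- sum((tab$observed - tab$expected)^2 / pmax(denom, 1e-12))
  df <- binsUsed - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       binsUsed = binsUsed, table = tab)
}

#' Age-adjusted incidence rates by score tertile
#'
#' Poisson regression of event counts on tertile indicators and age
#' with log person-time offset; rates are predicted at the cohort mean
#' age and reported per 1,000 person-years with delta-method SEs.
#'
#' @param cohort A \code{CohortTable}.
#' @param tertiles Integer tertile labels (1-3).
#' @return data.frame with \code{tertile}, \code{rate} (per 1,000
#'   person-years) and \code{se}.
#' @export
ageAdjustedRates <- function(cohort, tertiles) {
  df <- as.data.frame(cohort)
  df$tertile <- factor(tertiles, levels = 1:3)
  if (any(tapply(df$followup_time, df$tertile, sum, default = 0) == 0))
    stop("tertile with zero person-time")
  fit <- stats::glm(event ~ tertile + age + offset(log(followup_time)),
                    family = stats::poisson(), data = df)
  V <- stats::vcov(fit)
  mAge <- mean(df$age)
  out <- lapply(1:3, function(t3) {
    x <- c(1, as.numeric(t3 == 2), as.numeric(t3 == 3), mAge)
    eta <- sum(x * stats::coef(fit))
    seEta <- sqrt(drop(t(x) %*% V %*% x))
    data.frame(tertile = t3, rate = 1000 * exp(eta),
               se = 1000 * exp(eta) * seEta)
  })
  do.call(rbind, out)
}
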