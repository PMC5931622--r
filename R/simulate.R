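#' Default per-ancestry covariate profiles
#'
#' Means/SDs and proportions that emulate the published baseline
#' characteristics of a large multi-ethnic primary-prevention cohort
#' (African-American, Latino, East-Asian strata): age distribution,
#' sex mix, lipids, blood pressure, smoking, diabetes, treatment and
#' family-history prevalences.
#'
#' @return A named list (one element per ancestry) of profile lists.
#' @export
defaultCovariateProfiles <- function() {
  list(
    AFR = list(age = c(57.1, 9.7), female = 0.697,
               total_chol = c(190.4, 38.0), hdl = c(55.5, 15.1),
               sbp = c(128.9, 15.6), dbp = c(76.8, 10.0),
               smoking = c(never = 0.593, former = 0.327, current = 0.080),
               diabetes = 0.243, bp_treated = 0.568, lipid_treated = 0.372,
               family_history = 0.243, bmi = c(29.7, 6.4),
               college = 0.784, alcohol = c(2.5, 5.1)),
    LAT = list(age = c(55.3, 10.2), female = 0.726,
               total_chol = c(195.3, 37.2), hdl = c(53.6, 14.3),
               sbp = c(124.9, 15.3), dbp = c(74.1, 9.9),
               smoking = c(never = 0.650, former = 0.295, current = 0.055),
               diabetes = 0.195, bp_treated = 0.385, lipid_treated = 0.324,
               family_history = 0.250, bmi = c(28.4, 6.0),
               college = 0.651, alcohol = c(2.9, 5.2)),
    EA = list(age = c(55.6, 10.0), female = 0.686,
              total_chol = c(196.3, 36.1), hdl = c(57.5, 15.0),
              sbp = c(123.0, 15.7), dbp = c(73.6, 10.2),
              smoking = c(never = 0.775, former = 0.195, current = 0.030),
              diabetes = 0.175, bp_treated = 0.386, lipid_treated = 0.323,
              family_history = 0.210, bmi = c(24.7, 4.3),
              college = 0.830, alcohol = c(1.7, 3.8)))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults
#' emulate the study conditions of the multi-ethnic cohort the analyses
#' target: n = 11,242 split AFR/LAT/EA as 2,089/4,349/4,804; covariates
#' per \code{\link{defaultCovariateProfiles}}; a 4-SNP haplotype B at
#' frequency 0.15; a GRS log-hazard of log(1.15) per SD; a Weibull
#' baseline calibrated so about 4\% of subjects have an event by year 9;
#' administrative censoring at 9 years plus exponential dropout tuned to
#' a mean follow-up near 8.7 years.
#'
#' @param n Cohort size.
#' @param ancestryMix Named proportions over AFR/LAT/EA (normalized).
#' @param variantFreqs Optional named per-rsid effect-allele
#'   frequencies in (0, 1); by default non-haplotype variants get
#'   deterministic frequencies evenly spaced over [0.1, 0.9] and the
#'   four haplotype members get 0.35/0.30/0.45/0.40.
#' @param haplotypeBFreq Haplotype-B frequency in (0, 1).
#' @param covariateProfile Per-ancestry profile list.
#' @param grsLogHrPerSd True log hazard ratio per SD of the effect
#'   score.
#' @param covariateLogHrs Named log hazard ratios of the covariates
#'   (applied to centred values; \code{sex_male} and
#'   \code{smoker_current} are indicator terms).
#' @param effectScore Which score drives the hazard
#'   (\code{"GRS12"}/\code{"GRS51"}).
#' @param baselineShape,baselineScale Weibull baseline; scale \code{NA}
#'   means "calibrate to \code{targetEventRate} by year 9".
#' @param targetEventRate Calibration target event proportion.
#' @param adminCensorYears Administrative censoring horizon.
#' @param dropoutRate Exponential dropout hazard per year.
#' @param seed Integer seed.
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(n = 11242,
                      ancestryMix = c(AFR = 2089, LAT = 4349, EA = 4804),
                      variantFreqs = NULL,
                      haplotypeBFreq = 0.15,
                      covariateProfile = defaultCovariateProfiles(),
                      grsLogHrPerSd = log(1.15),
                      covariateLogHrs = c(age = 0.07, sex_male = 0.40,
                                          total_chol = 0.004, hdl = -0.02,
                                          sbp = 0.012, smoker_current = 0.60,
                                          diabetes = 0.60),
                      effectScore = c("GRS12", "GRS51"),
                      baselineShape = 1.2, baselineScale = NA_real_,
                      targetEventRate = 0.04,
                      adminCensorYears = 9, dropoutRate = 0.0074,
                      seed = 1L) {
  effectScore <- match.arg(effectScore)
  stopifnot(n >= 1, haplotypeBFreq > 0, haplotypeBFreq < 1,
            baselineShape > 0, dropoutRate >= 0, adminCensorYears > 0)
  if (!is.null(variantFreqs))
    stopifnot(all(variantFreqs >= 0 & variantFreqs < 1))
  mix <- ancestryMix / sum(ancestryMix)
  structure(list(n = as.integer(n), ancestryMix = mix,
                 variantFreqs = variantFreqs,
                 haplotypeBFreq = haplotypeBFreq,
                 covariateProfile = covariateProfile,
                 grsLogHrPerSd = grsLogHrPerSd,
                 covariateLogHrs = covariateLogHrs,
                 effectScore = effectScore,
                 baselineShape = baselineShape,
                 baselineScale = baselineScale,
                 targetEventRate = targetEventRate,
                 adminCensorYears = adminCensorYears,
                 dropoutRate = dropoutRate,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# Per-rsid effect-allele frequencies for a weight set under a config.
resolveVariantFreqs <- function(config, weights) {
  v <- variantWeights(weights)
  if (!is.null(config$variantFreqs)) {
    miss <- setdiff(v$rsid, names(config$variantFreqs))
    if (length(miss))
      stop("no simulation frequency for: ", paste(miss, collapse = ", "))
    return(config$variantFreqs[v$rsid])
  }
  hap <- v$haplotype_member
  f <- numeric(nrow(v))
  nh <- sum(!hap)
  f[!hap] <- seq(0.1, 0.9, length.out = max(nh, 2))[seq_len(nh)]
  f[hap] <- c(0.35, 0.30, 0.45, 0.40)[seq_len(sum(hap))]
  stats::setNames(f, v$rsid)
}

#' Simulate Hardy-Weinberg genotypes with one haplotype block
#'
#' Non-haplotype variants are independent \code{Binomial(2, f)} dosages.
#' The four haplotype members are generated jointly: each individual
#' draws two haplotypes, each being haplotype B (effect alleles at all
#' four members) with probability \code{haplotypeBFreq}, otherwise an
#' independent background haplotype whose per-member allele frequency is
#' chosen so the marginal effect-allele frequency matches \code{f}.
#'
#' @param config A \code{\link{simConfig}}.
#' @param weights A \code{WeightSet} naming the variants to simulate.
#' @return A \code{GenotypeMatrix} (counted allele = effect allele).
#' @export
simulateGenotypes <- function(config, weights) {
  v <- variantWeights(weights)
  f <- resolveVariantFreqs(config, weights)
  n <- config$n
  d <- matrix(NA_real_, nrow(v), n,
              dimnames = list(v$rsid, sprintf("sim%05d", seq_len(n))))
  nonhap <- which(!v$haplotype_member)
  for (i in nonhap)
    d[i, ] <- stats::rbinom(n, 2, f[v$rsid[i]])
  hapRows <- which(v$haplotype_member)
  if (length(hapRows)) {
    hb <- config$haplotypeBFreq
    fh <- f[v$rsid[hapRows]]
    if (any(fh < hb))
      stop("haplotype member marginal frequency below haplotype frequency")
    q <- (fh - hb) / (1 - hb)  # background-haplotype allele frequency
    d[hapRows, ] <- 0
    bCopies <- integer(n)
    for (copy in 1:2) {
      isB <- stats::rbinom(n, 1, hb) == 1
      bCopies <- bCopies + isB
      alleles <- vapply(q, function(qj)
        ifelse(isB, 1L, stats::rbinom(n, 1, qj)), integer(n))
      d[hapRows, ] <- d[hapRows, , drop = FALSE] + t(alleles)
    }
  }
  out <- GenotypeMatrix(d, countedAllele = v$effect_allele,
                        otherAllele = v$other_allele)
  if (length(hapRows)) metadata(out)$haplotypeBCopies <- bCopies
  out
}

rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Simulate baseline covariates with per-ancestry profiles
#'
#' Continuous covariates are (truncated) normal with the profile's
#' mean/SD; binary covariates Bernoulli; smoking multinomial over
#' never/former/current; six ancestry PCs standard normal. Covariates
#' are independent given ancestry (the emulated tables publish only
#' marginals).
#'
#' @param config A \code{\link{simConfig}}.
#' @return A \code{CohortTable} with a placeholder follow-up
#'   (\code{followup_time = 1}, \code{event = FALSE}) to be overwritten
#'   by \code{\link{simulateOutcomes}}.
#' @export
simulateCovariates <- function(config) {
  n <- config$n
  anc <- sample(names(config$ancestryMix), n, replace = TRUE,
                prob = config$ancestryMix)
  out <- vector("list", length(config$ancestryMix))
  names(out) <- names(config$ancestryMix)
  for (g in names(out)) {
    i <- which(anc == g)
    if (!length(i)) next
    p <- config$covariateProfile[[g]]
    if (is.null(p)) stop("no covariate profile for ancestry ", g)
    if (any(vapply(p[c("age", "total_chol", "hdl", "sbp", "dbp")],
                   function(z) z[2] < 0, TRUE)))
      stop("negative SD in covariate profile for ", g)
    m <- length(i)
    df <- data.frame(
      idx = i,
      ancestry = g,
      age = if (p$age[2] == 0) rep(p$age[1], m) else
        rtruncnorm(m, p$age[1], p$age[2], 30, 79),
      sex = ifelse(stats::rbinom(m, 1, p$female) == 1, "female", "male"),
      total_chol = rtruncnorm(m, p$total_chol[1], p$total_chol[2], 80, 500),
      hdl = rtruncnorm(m, p$hdl[1], p$hdl[2], 10, 150),
      sbp = rtruncnorm(m, p$sbp[1], p$sbp[2], 70, 260),
      dbp = rtruncnorm(m, p$dbp[1], p$dbp[2], 40, 160),
      smoker = sample(names(p$smoking), m, replace = TRUE,
                      prob = p$smoking),
      diabetes = stats::rbinom(m, 1, p$diabetes) == 1,
      bp_treated = stats::rbinom(m, 1, p$bp_treated) == 1,
      lipid_treated = stats::rbinom(m, 1, p$lipid_treated) == 1,
      family_history = stats::rbinom(m, 1, p$family_history) == 1,
      bmi = rtruncnorm(m, p$bmi[1], p$bmi[2], 14, 70),
      education = ifelse(stats::rbinom(m, 1, p$college) == 1,
                         "college", "less_than_college"),
      alcohol = pmax(stats::rnorm(m, p$alcohol[1], p$alcohol[2]), 0),
      prior_cvd = FALSE,
      stringsAsFactors = FALSE)
    out[[g]] <- df
  }
  df <- do.call(rbind, out)
  df <- df[order(df$idx), , drop = FALSE]
  df$idx <- NULL
  df$id <- sprintf("sim%05d", seq_len(n))
  for (k in 1:6) df[[paste0("pc", k)]] <- stats::rnorm(n)
  df$followup_time <- 1
  df$event <- FALSE
  CohortTable(df)
}

# linear predictor of the outcome model on centred covariates
outcomeLinearPredictor <- function(cohort, grsZ, config) {
  df <- as.data.frame(cohort)
  b <- config$covariateLogHrs
  ctr <- function(x) x - mean(x)
  lp <- config$grsLogHrPerSd * grsZ
  lp <- lp + b["age"] * ctr(df$age) +
    b["sex_male"] * ctr(as.numeric(df$sex == "male")) +
    b["total_chol"] * ctr(df$total_chol) + b["hdl"] * ctr(df$hdl) +
    b["sbp"] * ctr(df$sbp) +
    b["smoker_current"] * ctr(as.numeric(as.character(df$smoker) == "current")) +
    b["diabetes"] * ctr(as.numeric(df$diabetes))
  unname(lp)
}

# scale of the Weibull baseline such that the mean event probability by
# `horizon` equals the target rate, given the cohort's linear predictors
calibrateBaselineScale <- function(lp, shape, horizon, target) {
  f <- function(logScale) {
    H <- (horizon / exp(logScale))^shape
    mean(1 - exp(-H * exp(lp))) - target
  }
  exp(stats::uniroot(f, c(log(1e-2), log(1e6)))$root)
}

#' Simulate survival outcomes under a Weibull proportional-hazards model
#'
#' Hazard = Weibull(shape, scale) baseline times
#' \code{exp(grsLogHrPerSd * z + covariate terms)}; event times by
#' inverse-transform sampling; observed time is the minimum of the event
#' time, an exponential dropout time and the administrative censoring
#' horizon.
#'
#' @param cohort A \code{CohortTable} of covariates.
#' @param grsZ Standardized score driving the hazard.
#' @param config A \code{\link{simConfig}}.
#' @return The cohort with \code{followup_time} and \code{event}
#'   replaced; the realized baseline scale is kept in
#'   \code{metadata(x)$baselineScale}.
#' @export
simulateOutcomes <- function(cohort, grsZ, config) {
  n <- nrow(cohort)
  stopifnot(length(grsZ) == n, config$baselineShape > 0)
  lp <- outcomeLinearPredictor(cohort, grsZ, config)
  scale <- config$baselineScale
  if (is.na(scale))
    scale <- calibrateBaselineScale(lp, config$baselineShape,
                                    min(9, config$adminCensorYears),
                                    config$targetEventRate)
  if (scale <= 0) stop("non-positive Weibull scale")
  u <- stats::runif(n)
  tEvent <- scale * (-log(u) * exp(-lp))^(1 / config$baselineShape)
  tDrop <- if (config$dropoutRate > 0)
    stats::rexp(n, config$dropoutRate) else rep(Inf, n)
  tObs <- pmin(tEvent, tDrop, config$adminCensorYears)
  df <- as.data.frame(cohort)
  df$followup_time <- pmax(tObs, 1e-6)
  df$event <- tEvent <= pmin(tDrop, config$adminCensorYears)
  out <- CohortTable(df)
  metadata(out)$baselineScale <- scale
  out
}

#' Simulate a complete analysis-ready cohort
#'
#' Seeds the generator, simulates genotypes and covariates, computes
#' both scores, standardizes the effect score within ancestry, and
#' draws survival outcomes.
#'
#' @param config A \code{\link{simConfig}}.
#' @param weights A \code{WeightSet}.
#' @return List with \code{cohort} (a \code{CohortTable}),
#'   \code{genotypes}, \code{scores} (list of \code{ScoreVector}s),
#'   \code{grsZ} (standardized effect score) and \code{config}.
#' @export
simulateCohort <- function(config, weights) {
  set.seed(config$seed)
  geno <- simulateGenotypes(config, weights)
  cov <- simulateCovariates(config)
  sc <- list(GRS12 = computeGRS(geno, weights, "GRS12"),
             GRS51 = computeGRS(geno, weights, "GRS51"))
  z <- standardizeScores(sc[[config$effectScore]], cov$ancestry)
  cohort <- simulateOutcomes(cov, z, config)
  list(cohort = cohort, genotypes = geno, scores = sc, grsZ = z,
       config = config)
}
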