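WILSON_COEF_MD5 <- "672924d87243835d8fab1ba37efd0b81"

#' Wilson categorical Framingham coefficients
#'
#' Loads the sex-specific coefficient table of the categorical
#' (risk-factor category) Framingham 10-year CHD function: per-year age
#' effect (plus a quadratic term in women), total-cholesterol, HDL-C and
#' blood-pressure category effects, diabetes and current-smoking effects,
#' the population mean linear predictor and the 10-year baseline
#' survival. The table ships as a versioned CSV; a user-supplied file
#' with the same layout may be substituted (its checksum is reported via
#' the \code{"md5"} attribute; the shipped file is verified).
#'
#' @param path Optional path to an alternative coefficient CSV.
#' @return A data.frame with columns \code{sex}, \code{term},
#'   \code{level}, \code{beta} and an \code{md5} attribute.
#' @export
wilsonCoefficients <- function(path = NULL) {
  shipped <- is.null(path)
  if (shipped)
    path <- system.file("extdata", "wilson_frs_coefficients.csv",
                        package = "grsCHD", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (shipped && !identical(md5, WILSON_COEF_MD5))
    stop("shipped Framingham coefficient file fails its checksum")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "term", "level", "beta") %in% colnames(tab)),
            all(c("male", "female") %in% tab$sex))
  attr(tab, "md5") <- md5
  tab
}

# JNC-style blood-pressure category from SBP and DBP (higher one governs)
bpCategory <- function(sbp, dbp) {
  sc <- cut(sbp, c(-Inf, 120, 130, 140, 160, Inf), right = FALSE,
            labels = c("optimal", "normal", "high_normal", "stage1",
                       "stage2_4"))
  dc <- cut(dbp, c(-Inf, 80, 85, 90, 100, Inf), right = FALSE,
            labels = c("optimal", "normal", "high_normal", "stage1",
                       "stage2_4"))
  lev <- levels(sc)
  factor(lev[pmax(as.integer(sc), as.integer(dc))], levels = lev)
}

tcCategory <- function(tc)
  cut(tc, c(-Inf, 160, 200, 240, 280, Inf), right = FALSE,
      labels = c("lt160", "160to199", "200to239", "240to279", "ge280"))

hdlCategory <- function(hdl)
  cut(hdl, c(-Inf, 35, 45, 50, 60, Inf), right = FALSE,
      labels = c("lt35", "35to44", "45to49", "50to59", "ge60"))

#' Framingham 10-year CHD risk (Wilson categorical equation)
#'
#' Sex-specific linear predictor over risk-factor categories, converted
#' to a 10-year probability via the baseline survival:
#' \code{p = 1 - S0^exp(L - Lbar)}. Any missing component raises an
#' error (such subjects are excluded at cohort assembly).
#'
#' @param cohort A \code{CohortTable} or data.frame with columns
#'   \code{age} (30-79), \code{sex}, \code{total_chol}, \code{hdl},
#'   \code{sbp}, \code{dbp}, \code{smoker}, \code{diabetes}.
#' @param coefficients Coefficient table from
#'   \code{\link{wilsonCoefficients}}.
#' @return Numeric vector of 10-year CHD probabilities in [0, 1].
#' @export
frs10yr <- function(cohort, coefficients = wilsonCoefficients()) {
  df <- as.data.frame(cohort)
  comp <- df[, FRS_COMPONENTS, drop = FALSE]
  if (anyNA(comp))
    stop("missing Framingham component(s) for ",
         sum(rowSums(is.na(comp)) > 0), " subject(s)")
  if (any(df$age < 30 | df$age > 79))
    stop("age outside [30, 79]")
  if (any(df$total_chol <= 0 | df$hdl <= 0 | df$sbp <= 0 | df$dbp <= 0))
    stop("lipid and blood-pressure values must be positive")
  cf <- function(sex, term, level)
    coefficients$beta[coefficients$sex == sex & coefficients$term == term &
                      coefficients$level == level]
  sexes <- as.character(df$sex)
  tc <- as.character(tcCategory(df$total_chol))
  hd <- as.character(hdlCategory(df$hdl))
  bp <- as.character(bpCategory(df$sbp, df$dbp))
  smoking <- as.character(df$smoker) == "current"
  p <- numeric(nrow(df))
  for (s in unique(sexes)) {
    i <- which(sexes == s)
    lp <- cf(s, "age", "linear") * df$age[i] +
      cf(s, "age_sq", "quadratic") * df$age[i]^2 +
      vapply(tc[i], function(l) cf(s, "total_chol", l), 0) +
      vapply(hd[i], function(l) cf(s, "hdl", l), 0) +
      vapply(bp[i], function(l) cf(s, "bp", l), 0) +
      ifelse(df$diabetes[i], cf(s, "diabetes", "yes"), 0) +
      ifelse(smoking[i], cf(s, "smoker", "yes"), 0)
    p[i] <- 1 - cf(s, "s0_10yr", "constant") ^
      exp(lp - cf(s, "lp_mean", "constant"))
  }
  unname(p)
}

#' Map a 10-year risk to the four clinical categories
#'
#' Left-closed cut points: [0, 0.10) low; [0.10, 0.15) intermediate-low;
#' [0.15, 0.20) intermediate-high; [0.20, 1] high.
#'
#' @param p Probabilities in [0, 1].
#' @return Factor with levels low, intermediate_low, intermediate_high,
#'   high.
#' @export
riskCategory <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("risk probabilities must lie in [0, 1]")
  cut(p, c(-Inf, 0.10, 0.15, 0.20, Inf), right = FALSE,
      labels = RISK_CATEGORIES)
}

# Baseline cumulative hazard of a Cox fit at tStar, extrapolating past
# the last observed time with the average hazard over the final
# observed year.
baselineCumHaz <- function(fit, tStar) {
  bh <- survival::basehaz(fit, centered = TRUE)
  tmax <- max(bh$time)
  H <- stats::approxfun(bh$time, bh$hazard, method = "constant",
                        yleft = 0, rule = 2)
  if (tStar <= tmax) return(H(tStar))
  h <- (H(tmax) - H(max(tmax - 1, 0))) / min(1, tmax)
  H(tmax) + h * (tStar - tmax)
}

#' 10-year risk from a refit survival model (FRS components +/- GRS)
#'
#' Fits a Cox model on the cohort's own follow-up containing the
#' individual Framingham components (and, if supplied, a standardized
#' GRS), then converts each subject's linear predictor to a 10-year
#' probability using the baseline cumulative hazard, extrapolated past
#' the end of follow-up under a constant hazard equal to the average
#' hazard over the final observed year.
#'
#' @param cohort A \code{CohortTable}.
#' @param grsZ Optional numeric standardized score; when supplied the
#'   model is the "FRS + GRS" updated model.
#' @param tStar Horizon in years (default 10).
#' @return Numeric risk vector with the fitted \code{coxph} object in
#'   attribute \code{"fit"}.
#' @export
updatedRisk <- function(cohort, grsZ = NULL, tStar = 10) {
  df <- as.data.frame(cohort)
  df$smoker <- factor(as.character(df$smoker), levels = SMOKING_LEVELS)
  rhs <- "age + sex + total_chol + hdl + sbp + dbp + smoker + diabetes"
  if (!is.null(grsZ)) {
    df$grs_z <- as.numeric(grsZ)
    rhs <- paste(rhs, "+ grs_z")
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(followup_time, event) ~", rhs)),
    data = df, ties = "efron", x = TRUE)
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("updated risk model did not converge")
  lp <- fit$linear.predictors  # centered at the mean covariate vector
  H10 <- baselineCumHaz(fit, tStar)
  risk <- 1 - exp(-H10 * exp(lp))
  attr(risk, "fit") <- fit
  risk
}
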