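#' Construct a CohortTable
#'
#' Coerces a data.frame of per-individual covariates and follow-up into a
#' validated \code{CohortTable}. Required columns: \code{id},
#' \code{ancestry}, \code{age}, \code{sex}, \code{total_chol} (mg/dL),
#' \code{hdl} (mg/dL), \code{sbp}, \code{dbp} (mmHg), \code{smoker}
#' (never/former/current), \code{diabetes}, \code{followup_time} (years),
#' \code{event}. Ancestry principal components are columns
#' \code{pc1..pcK}.
#'
#' @param df A data.frame or DataFrame.
#' @return A \code{CohortTable}.
#' @export
CohortTable <- function(df) {
  df <- DataFrame(df, check.names = FALSE)
  df$id <- as.character(df$id)
  df$ancestry <- factor(as.character(df$ancestry), levels = ANCESTRY_LEVELS)
  df$sex <- factor(as.character(df$sex), levels = c("female", "male"))
  df$smoker <- factor(as.character(df$smoker), levels = SMOKING_LEVELS)
  for (b in intersect(c("diabetes", "event", "prior_cvd", "bp_treated",
                        "lipid_treated", "family_history"), colnames(df)))
    df[[b]] <- as.logical(df[[b]])
  new("CohortTable", df)
}

#' Read / write a phenotype-covariate CSV
#'
#' @param path CSV file with the \code{CohortTable} columns.
#' @return \code{readPhenotypes}: a \code{CohortTable}.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  CohortTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readPhenotypes
#' @param x A \code{CohortTable}.
#' @export
writePhenotypes <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Names of the principal-component columns of a cohort
#' @param x A \code{CohortTable} or data.frame.
#' @param k Number of leading PCs wanted (default all present).
#' @export
pcColumns <- function(x, k = Inf) {
  pcs <- grep("^pc[0-9]+$", colnames(x), value = TRUE)
  pcs <- pcs[order(as.integer(sub("^pc", "", pcs)))]
  utils::head(pcs, k)
}

FRS_COMPONENTS <- c("age", "sex", "total_chol", "hdl", "sbp", "dbp",
                    "smoker", "diabetes")

#' Sequential cohort-assembly filters
#'
#' Applies, in fixed order, the exclusions used to assemble an analytic
#' primary-prevention cohort: (1) age outside [\code{minAge},
#' \code{maxAge}]; (2) prior cardiovascular disease; (3) missing data on
#' any Framingham risk component (age, sex, total and HDL cholesterol,
#' systolic/diastolic blood pressure, smoking, diabetes). Counts at each
#' step are logged; the order is deterministic and independent of row
#' order.
#'
#' @param rows A data.frame or \code{CohortTable} of candidate subjects.
#' @param minAge,maxAge Inclusive age window (default 30-79).
#' @return A list with \code{cohort} (a \code{CohortTable}) and
#'   \code{log}, a named integer vector of exclusion counts
#'   (\code{age}, \code{prior_cvd}, \code{missing_frs}).
#' @export
applyCohortFilters <- function(rows, minAge = 30, maxAge = 79) {
  df <- as.data.frame(rows)
  n0 <- nrow(df)
  bad_age <- is.na(df$age) | df$age < minAge | df$age > maxAge
  df <- df[!bad_age, , drop = FALSE]
  cvd <- if ("prior_cvd" %in% colnames(df))
    !is.na(df$prior_cvd) & df$prior_cvd else rep(FALSE, nrow(df))
  df <- df[!cvd, , drop = FALSE]
  frs <- df[, intersect(FRS_COMPONENTS, colnames(df)), drop = FALSE]
  miss <- rowSums(is.na(frs)) > 0 |
    length(setdiff(FRS_COMPONENTS, colnames(df))) > 0
  df <- df[!miss, , drop = FALSE]
  log <- c(age = sum(bad_age), prior_cvd = sum(cvd),
           missing_frs = sum(miss))
  stopifnot(sum(log) == n0 - nrow(df))
  list(cohort = CohortTable(df), log = log)
}
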