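#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

ANCESTRY_LEVELS <- c("AFR", "LAT", "EA", "EUR")
SMOKING_LEVELS <- c("never", "former", "current")
RISK_CATEGORIES <- c("low", "intermediate_low", "intermediate_high", "high")

#' WeightSet: a variant-to-weight map with a haplotype definition
#'
#' A \code{WeightSet} holds, for each scored variant, its rsid, effect and
#' other allele, per-allele log-hazard weight, membership flags for the 12-
#' and 51-marker scores, and (optionally) an imputation quality. A separate
#' slot describes the four-SNP ALOX5AP haplotype B unit scored with its own
#' weight.
#'
#' @slot variants A \code{DataFrame} with columns \code{rsid},
#'   \code{effect_allele}, \code{other_allele}, \code{weight},
#'   \code{in_grs12}, \code{in_grs51}, \code{haplotype_member} and
#'   optionally \code{imputation_r2}.
#' @slot haplotype A list with elements \code{rsid} (length-4 character),
#'   \code{effect_allele} (length-4 character), \code{weight} (scalar,
#'   default 0.131) and \code{mode} (\code{"presence"} or
#'   \code{"min_dosage"}).
#' @slot excluded A \code{DataFrame} of variants dropped at read time
#'   (imputation r-squared below the quality threshold), kept for logging.
#' @export
setClass("WeightSet",
  representation(variants = "DataFrame", haplotype = "list",
                 excluded = "DataFrame"))

setValidity("WeightSet", function(object) {
  v <- object@variants
  need <- c("rsid", "effect_allele", "other_allele", "weight",
            "in_grs12", "in_grs51", "haplotype_member")
  if (!all(need %in% colnames(v)))
    return(paste("missing variant columns:",
                 paste(setdiff(need, colnames(v)), collapse = ", ")))
  if (anyDuplicated(v$rsid)) return("duplicate rsid in WeightSet")
  if (any(!is.finite(v$weight))) return("non-finite weight")
  if (any(v$effect_allele == v$other_allele))
    return("effect allele equals other allele")
  h <- object@haplotype
  if (length(h) && !is.null(h$rsid)) {
    if (length(h$rsid) != 4L) return("haplotype must have exactly 4 members")
    if (!is.numeric(h$weight) || h$weight < 0)
      return("haplotype weight must be a non-negative scalar")
    if (!h$mode %in% c("presence", "min_dosage"))
      return("haplotype mode must be 'presence' or 'min_dosage'")
  }
  TRUE
})

#' GenotypeMatrix: effect-allele dosages per variant and sample
#'
#' Thin wrapper around \code{SummarizedExperiment}: one assay
#' \code{"dosage"} (variants in rows, samples in columns) holding allele
#' counts in \{0, 1, 2\} with \code{NA} marking missing genotypes (never
#' silently zeroed), and a \code{counted_allele} column in \code{rowData}
#' recording which allele the dosage counts.
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("GenotypeMatrix needs a 'dosage' assay")
  d <- SummarizedExperiment::assay(object, "dosage")
  ok <- is.na(d) | (d >= 0 & d <= 2)
  if (!all(ok)) return("dosages must lie in [0, 2] or be NA")
  if (!"counted_allele" %in% colnames(rowData(object)))
    return("rowData needs a 'counted_allele' column")
  if (is.null(rownames(object))) return("variants must be named (rsid)")
  if (anyDuplicated(rownames(object))) return("duplicate rsid")
  if (anyDuplicated(colnames(object))) return("duplicate sample id")
  TRUE
})

#' CohortTable: per-individual covariates, follow-up and event status
#'
#' Extends \code{S4Vectors::DataFrame}; validity enforces the columns the
#' survival analyses require. \code{ancestry} uses levels AFR (African),
#' LAT (Latino), EA (East Asian) and EUR (European); \code{smoker} uses
#' never/former/current; follow-up time is in years.
#'
#' @export
setClass("CohortTable", contains = "DFrame")

COHORT_REQUIRED <- c("id", "ancestry", "age", "sex", "total_chol", "hdl",
                     "sbp", "dbp", "smoker", "diabetes",
                     "followup_time", "event")

setValidity("CohortTable", function(object) {
  miss <- setdiff(COHORT_REQUIRED, colnames(object))
  if (length(miss))
    return(paste("missing cohort columns:", paste(miss, collapse = ", ")))
  if (nrow(object)) {
    if (any(object$followup_time <= 0, na.rm = TRUE))
      return("followup_time must be > 0")
    if (!all(stats::na.omit(as.character(object$ancestry)) %in% ANCESTRY_LEVELS))
      return("unknown ancestry level")
    if (anyDuplicated(object$id)) return("duplicate subject id")
  }
  TRUE
})

#' ScoreVector: per-individual genetic risk scores
#'
#' @slot score Named numeric vector of per-individual scores (names are
#'   sample ids); \code{NA} where too many constituent genotypes were
#'   missing.
#' @slot scoreName Either \code{"GRS12"} or \code{"GRS51"}.
#' @slot nVariantsUsed Integer vector: number of non-haplotype variants
#'   that contributed to each individual's score.
#' @export
setClass("ScoreVector",
  representation(score = "numeric", scoreName = "character",
                 nVariantsUsed = "integer"))

setValidity("ScoreVector", function(object) {
  if (length(object@scoreName) != 1L ||
      !object@scoreName %in% c("GRS12", "GRS51"))
    return("scoreName must be 'GRS12' or 'GRS51'")
  if (length(object@nVariantsUsed) != length(object@score))
    return("nVariantsUsed length mismatch")
  TRUE
})
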