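#' Construct a WeightSet
#'
#' @param variants A data.frame-like table with columns \code{rsid},
#'   \code{effect_allele}, \code{other_allele}, \code{weight},
#'   \code{in_grs12}, \code{in_grs51}, \code{haplotype_member} and
#'   optionally \code{imputation_r2}.
#' @param haplotypeWeight Weight applied to the haplotype term
#'   (default 0.131, the published ALOX5AP haplotype B weight).
#' @param haplotypeMode \code{"presence"} (haplotype term is 0/1; the
#'   default) or \code{"min_dosage"} (0/1/2, the minimum oriented dosage
#'   over the four members).
#' @param excluded Variants dropped before scoring (kept for the log).
#' @return A \code{WeightSet}.
#' @export
WeightSet <- function(variants, haplotypeWeight = 0.131,
                      haplotypeMode = c("presence", "min_dosage"),
                      excluded = NULL) {
  haplotypeMode <- match.arg(haplotypeMode)
  v <- DataFrame(variants)
  if (is.null(v$weight) && !is.null(v$beta)) {
    v$weight <- v$beta
    v$beta <- NULL
  }
  v$rsid <- as.character(v$rsid)
  v$effect_allele <- toupper(as.character(v$effect_allele))
  v$other_allele <- toupper(as.character(v$other_allele))
  v$weight <- as.numeric(v$weight)
  for (f in c("in_grs12", "in_grs51", "haplotype_member"))
    v[[f]] <- as.logical(v[[f]])
  hap_rows <- which(v$haplotype_member)
  hap <- list()
  if (length(hap_rows)) {
    if (length(hap_rows) != 4L)
      stop("haplotype_member must flag exactly 4 variants, got ",
           length(hap_rows))
    hap <- list(rsid = v$rsid[hap_rows],
                effect_allele = v$effect_allele[hap_rows],
                weight = haplotypeWeight, mode = haplotypeMode)
  }
  if (is.null(excluded))
    excluded <- v[0, , drop = FALSE]
  new("WeightSet", variants = v, haplotype = hap,
      excluded = DataFrame(excluded))
}

#' Read a variant-weight table
#'
#' Reads a tab-separated weight table (columns \code{rsid},
#' \code{effect_allele}, \code{other_allele}, \code{beta},
#' \code{in_grs12}, \code{in_grs51}, \code{haplotype_member},
#' \code{imputation_r2}) and applies the imputation-quality rule:
#' variants with imputation r-squared below \code{minImputationR2}
#' (default 0.85) are excluded from scoring and retained in the
#' \code{excluded} slot. Directly genotyped variants may leave
#' \code{imputation_r2} empty (treated as perfect).
#'
#' @param path Path to the TSV file.
#' @param minImputationR2 Exclusion threshold on imputation quality.
#' @param ... Passed to \code{\link{WeightSet}} (e.g. \code{haplotypeMode}).
#' @return A \code{WeightSet}.
#' @export
readWeights <- function(path, minImputationR2 = 0.85, ...) {
  if (!file.exists(path)) stop("weight file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty weight table: ", path)
  need <- c("rsid", "effect_allele", "other_allele", "beta",
            "in_grs12", "in_grs51", "haplotype_member")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("weight table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$rsid))
    stop("duplicate rsid in weight table: ",
         paste(unique(tab$rsid[duplicated(tab$rsid)]), collapse = ", "))
  if (any(!is.finite(suppressWarnings(as.numeric(tab$beta)))))
    stop("non-numeric beta in weight table")
  tab$weight <- as.numeric(tab$beta)
  tab$beta <- NULL
  if (is.null(tab$imputation_r2)) tab$imputation_r2 <- NA_real_
  drop <- !is.na(tab$imputation_r2) & tab$imputation_r2 < minImputationR2
  if (any(drop))
    message(sum(drop), " variant(s) excluded for imputation r2 < ",
            minImputationR2, ": ", paste(tab$rsid[drop], collapse = ", "))
  WeightSet(tab[!drop, , drop = FALSE], excluded = tab[drop, , drop = FALSE],
            ...)
}

#' @rdname accessors
#' @export
setMethod("variantWeights", "WeightSet", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("haplotypeDefinition", "WeightSet", function(x) x@haplotype)

#' @export
setMethod("length", "WeightSet", function(x) nrow(x@variants))

setMethod("show", "WeightSet", function(object) {
  v <- object@variants
  cat("WeightSet with", nrow(v), "scored variants",
      sprintf("(%d excluded by imputation quality)\n", nrow(object@excluded)))
  cat("  GRS12 members:", sum(v$in_grs12), "+ haplotype;",
      "GRS51 members:", sum(v$in_grs51), "+ haplotype\n")
  h <- object@haplotype
  if (length(h))
    cat("  haplotype:", paste(h$rsid, h$effect_allele, sep = "-",
                              collapse = ", "),
        sprintf("(weight %.3f, mode %s)\n", h$weight, h$mode))
})

# Variants contributing to one of the two scores (haplotype handled apart).
scoreMembers <- function(weights, which = c("GRS51", "GRS12")) {
  which <- match.arg(which)
  v <- variantWeights(weights)
  flag <- if (which == "GRS12") v$in_grs12 else v$in_grs51
  v[flag & !v$haplotype_member, , drop = FALSE]
}
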