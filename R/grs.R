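#' Orient a dosage to the effect allele
#'
#' Weights apply to the effect allele; an observed dosage counted on the
#' other allele is flipped to \code{2 - d}. Palindromic (A/T or C/G)
#' variants cannot be strand-resolved without a frequency hint and raise
#' an error in strict mode.
#'
#' @param dosage Observed dosage(s) in [0, 2] (NA allowed).
#' @param countedAllele Allele the observed dosage counts. \code{NA}
#'   means the dosage is already on the effect allele.
#' @param effectAllele,otherAllele Alleles from the weight table.
#' @param strict Error on palindromic or unmatched alleles (default TRUE).
#' @return Dosage of the effect allele.
#' @export
orientDosage <- function(dosage, countedAllele, effectAllele, otherAllele,
                         strict = TRUE) {
  if (is.na(countedAllele)) return(dosage)  # orientation vouched upstream
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  if (strict && otherAllele == comp[effectAllele])
    stop("strand-ambiguous palindromic variant (", effectAllele, "/",
         otherAllele, ") with no frequency hint")
  if (countedAllele == effectAllele) return(dosage)
  if (countedAllele == otherAllele) return(2 - dosage)
  # counted allele matches neither as written: try the complementary strand
  if (comp[countedAllele] == effectAllele) return(dosage)
  if (comp[countedAllele] == otherAllele) return(2 - dosage)
  stop("counted allele ", countedAllele, " matches neither ",
       effectAllele, " nor ", otherAllele)
}

#' Haplotype copy count from four constituent dosages
#'
#' In \code{presence} mode the haplotype term is 1 when every member
#' carries at least one effect allele (so at least one copy of the
#' haplotype is possible under any phasing), else 0. In
#' \code{min_dosage} mode the term is the minimum oriented dosage, an
#' upper bound on the number of haplotype copies in unphased data.
#' Any missing constituent makes the haplotype count 0 with a warning.
#'
#' @param fourDosages Numeric vector of 4 oriented dosages.
#' @param mode \code{"presence"} or \code{"min_dosage"}.
#' @return Integer in \{0, 1\} (presence) or \{0, 1, 2\} (min_dosage).
#' @export
haplotypeCopies <- function(fourDosages, mode = c("presence", "min_dosage")) {
  mode <- match.arg(mode)
  stopifnot(length(fourDosages) == 4L)
  if (anyNA(fourDosages)) {
    warning("missing haplotype constituent; haplotype treated as absent")
    return(0L)
  }
  m <- min(fourDosages)
  if (mode == "presence") as.integer(m >= 1) else as.integer(m)
}

# Oriented dosage matrix for the given variants, with the missing-dosage
# policy applied: individuals missing more than maxMissing of the scored
# variants get NA scores; otherwise a missing dosage is imputed as twice
# the effect-allele frequency among non-missing samples at that variant.
orientedDosageMatrix <- function(genotypes, variantTable, strict = TRUE) {
  d <- dosages(genotypes)
  ca <- countedAlleles(genotypes)
  miss <- setdiff(variantTable$rsid, rownames(d))
  if (length(miss))
    stop("variant(s) absent from genotypes: ", paste(miss, collapse = ", "))
  out <- matrix(NA_real_, nrow(variantTable), ncol(d),
                dimnames = list(variantTable$rsid, colnames(d)))
  for (i in seq_len(nrow(variantTable))) {
    rs <- variantTable$rsid[i]
    out[i, ] <- orientDosage(d[rs, ], ca[[rs]],
                             variantTable$effect_allele[i],
                             variantTable$other_allele[i], strict = strict)
  }
  out
}

#' Compute a weighted multi-locus genetic risk score
#'
#' Score = sum over member variants of (weight x effect-allele dosage)
#' plus the haplotype weight times the haplotype copy count
#' (\code{\link{haplotypeCopies}}). Individuals missing more than
#' \code{maxMissing} (default 10\%) of the scored variants get an
#' \code{NA} score; other missing dosages are imputed as twice the
#' effect-allele frequency among non-missing samples at that variant,
#' which keeps scores on a common scale.
#'
#' @param genotypes A \code{GenotypeMatrix}.
#' @param weights A \code{WeightSet}.
#' @param which \code{"GRS51"} (47 variants + haplotype) or
#'   \code{"GRS12"} (8 variants + haplotype).
#' @param maxMissing Maximum tolerated fraction of missing member
#'   variants per individual.
#' @param strict Passed to \code{\link{orientDosage}}.
#' @return A \code{ScoreVector}.
#' @rdname computeGRS
#' @export
setMethod("computeGRS", signature(genotypes = "GenotypeMatrix",
                                  weights = "WeightSet"),
  function(genotypes, weights, which = c("GRS51", "GRS12"),
           maxMissing = 0.1, strict = TRUE) {
    which <- match.arg(which)
    members <- scoreMembers(weights, which)
    minimum <- if (which == "GRS12") 8L else 1L
    if (nrow(members) < minimum)
      stop(which, " requires >= ", minimum, " non-haplotype variants, got ",
           nrow(members))
    od <- orientedDosageMatrix(genotypes, members, strict = strict)
    nmiss <- colSums(is.na(od))
    nUsed <- as.integer(nrow(od) - nmiss)
    tooMissing <- nmiss > maxMissing * nrow(od)
    # impute residual missing dosages at 2 x effect-allele frequency
    if (any(is.na(od))) {
      af <- rowMeans(od, na.rm = TRUE) / 2
      for (i in which(rowSums(is.na(od)) > 0))
        od[i, is.na(od[i, ])] <- 2 * af[i]
    }
    score <- as.numeric(crossprod(od, members$weight))
    hap <- haplotypeDefinition(weights)
    if (length(hap)) {
      v <- variantWeights(weights)
      hd <- orientedDosageMatrix(
        genotypes, v[v$haplotype_member, , drop = FALSE], strict = strict)
      hcopies <- suppressWarnings(
        apply(hd, 2, haplotypeCopies, mode = hap$mode))
      if (anyNA(hd))
        warning("missing haplotype constituent(s); haplotype treated as ",
                "absent for the affected individual(s)")
      score <- score + hap$weight * hcopies
    }
    score[tooMissing] <- NA_real_
    new("ScoreVector", score = stats::setNames(score, colnames(od)),
        scoreName = which, nVariantsUsed = nUsed)
  })

#' @rdname accessors
#' @export
setMethod("scores", "ScoreVector", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("scoreName", "ScoreVector", function(x) x@scoreName)
#' @rdname accessors
#' @export
setMethod("nVariantsUsed", "ScoreVector", function(x) x@nVariantsUsed)
#' @export
setMethod("length", "ScoreVector", function(x) length(x@score))

setMethod("show", "ScoreVector", function(object) {
  s <- object@score
  cat(object@scoreName, "for", length(s), "individuals; mean",
      sprintf("%.3f", mean(s, na.rm = TRUE)), "sd",
      sprintf("%.3f", stats::sd(s, na.rm = TRUE)),
      if (anyNA(s)) sprintf("(%d NA)", sum(is.na(s))) else "", "\n")
})

#' Standardize scores within ancestry groups
#'
#' Within each group the score is centred and scaled to unit variance
#' (denominator n - 1), so model coefficients are per within-group SD.
#'
#' @param x Numeric scores (or a \code{ScoreVector}).
#' @param groups Grouping labels (ancestry), one per individual.
#' @return Numeric z-scores.
#' @export
standardizeScores <- function(x, groups) {
  if (is(x, "ScoreVector")) x <- scores(x)
  groups <- as.character(groups)
  stopifnot(length(x) == length(groups))
  out <- rep(NA_real_, length(x))
  for (g in unique(groups)) {
    i <- which(groups == g)
    s <- stats::sd(x[i], na.rm = TRUE)
    if (is.na(s) || s == 0) stop("zero within-group variance in group ", g)
    out[i] <- (x[i] - mean(x[i], na.rm = TRUE)) / s
  }
  names(out) <- names(x)
  out
}

#' Ancestry-specific tertiles of a score
#'
#' Cuts at the within-group 33.33\% and 66.67\% empirical quantiles
#' (type-7 interpolation); values tied with a cut point go to the lower
#' tertile.
#'
#' @param x Numeric scores (or a \code{ScoreVector}).
#' @param groups Grouping labels, one per individual.
#' @return Integer labels in \{1, 2, 3\} (NA scores stay NA).
#' @export
assignTertiles <- function(x, groups) {
  if (is(x, "ScoreVector")) x <- scores(x)
  groups <- as.character(groups)
  stopifnot(length(x) == length(groups))
  out <- rep(NA_integer_, length(x))
  for (g in unique(groups)) {
    i <- which(groups == g)
    xi <- x[i]
    ok <- !is.na(xi)
    if (sum(ok) < 3L) stop("group ", g, " has fewer than 3 scored subjects")
    q <- stats::quantile(xi[ok], c(1, 2) / 3, type = 7, names = FALSE)
    if (q[1] == q[2] && stats::sd(xi[ok]) == 0)
      stop("all scores equal in group ", g)
    out[i][ok] <- 1L + (xi[ok] > q[1]) + (xi[ok] > q[2])
  }
  names(out) <- names(x)
  out
}
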