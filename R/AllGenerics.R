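#' @rdname computeGRS
#' @export
setGeneric("computeGRS", function(genotypes, weights,
                                  which = c("GRS51", "GRS12"), ...)
  standardGeneric("computeGRS"))

#' Accessors for package classes
#'
#' \code{dosages} returns the dosage matrix (variants x samples);
#' \code{countedAlleles} the allele each row's dosage counts;
#' \code{variantWeights} the variant table of a \code{WeightSet};
#' \code{haplotypeDefinition} its haplotype block; \code{scores} the
#' numeric score vector of a \code{ScoreVector}.
#'
#' @param x An object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("countedAlleles", function(x) standardGeneric("countedAlleles"))
#' @rdname accessors
#' @export
setGeneric("variantWeights", function(x) standardGeneric("variantWeights"))
#' @rdname accessors
#' @export
setGeneric("haplotypeDefinition", function(x) standardGeneric("haplotypeDefinition"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("scoreName", function(x) standardGeneric("scoreName"))
#' @rdname accessors
#' @export
setGeneric("nVariantsUsed", function(x) standardGeneric("nVariantsUsed"))
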