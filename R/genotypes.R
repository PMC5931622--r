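#' Construct a GenotypeMatrix
#'
#' @param dosage Numeric matrix of allele counts in \{0,1,2\} (NA =
#'   missing), variants in rows (rownames = rsid), samples in columns.
#' @param countedAllele Character vector, one per variant: the allele the
#'   dosage counts. \code{NA} means "assume the score's effect allele"
#'   (the convention for bare dosage tables).
#' @param otherAllele Optional character vector of the non-counted allele.
#' @return A \code{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, countedAllele = NA_character_,
                           otherAllele = NA_character_) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) stop("dosage rows must be named by rsid")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  rd <- DataFrame(
    counted_allele = toupper(rep_len(as.character(countedAllele), nrow(dosage))),
    other_allele = toupper(rep_len(as.character(otherAllele), nrow(dosage))))
  new("GenotypeMatrix",
      SummarizedExperiment(assays = list(dosage = dosage), rowData = rd))
}

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix",
          function(x) SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("countedAlleles", "GenotypeMatrix",
          function(x) stats::setNames(rowData(x)$counted_allele, rownames(x)))

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dosages(object)
  cat("GenotypeMatrix:", nrow(d), "variants x", ncol(d), "samples;",
      sum(is.na(d)), "missing genotypes\n")
})

# Best-guess rounding of an imputed dosage: nearest integer, ties (x.5)
# rounded half away from zero, clamped to [0, 2].
bestGuessDosage <- function(ds) {
  out <- floor(abs(ds) + 0.5) * sign(ds)
  pmin(pmax(out, 0), 2)
}

#' Read genotypes from VCF or a plain dosage table
#'
#' For VCF input, per-sample genotypes come from the \code{DS} (dosage)
#' field when present, rounded to the nearest integer ("best-guess"),
#' otherwise from hard \code{GT} calls; the ALT allele is the counted
#' allele. Multi-allelic records are rejected. For \code{dosage_table}
#' input the file is a TSV with samples in rows and rsids in columns;
#' missing cells stay \code{NA} (masked, never zeroed) and the counted
#' allele is taken to be the effect allele of whatever weight table the
#' matrix is later scored against.
#'
#' @param path Input file.
#' @param format \code{"vcf"} or \code{"dosage_table"}.
#' @return A \code{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "dosage_table") return(readDosageTable(path))
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  if (any(nalt != 1L))
    stop("multi-allelic record(s) without a resolvable counted allele: ",
         paste(rownames(vcf)[nalt != 1L], collapse = ", "))
  altc <- as.character(unlist(alt))
  refc <- as.character(VariantAnnotation::ref(vcf))
  g <- VariantAnnotation::geno(vcf)
  # a declared-but-unused FORMAT field comes back as an all-NA matrix
  if ("DS" %in% names(g) && !all(is.na(g$DS))) {
    ds <- g$DS
    storage.mode(ds) <- "double"
    d <- bestGuessDosage(ds)
  } else if ("GT" %in% names(g)) {
    gt <- g$GT
    d <- apply(gt, c(1, 2), function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/")[[1]]
      if (any(a %in% c(".", ""))) return(NA_real_)
      sum(a == "1")
    })
  } else stop("VCF has neither DS nor GT FORMAT fields")
  if (anyDuplicated(rownames(d))) stop("duplicate variant id in VCF")
  if (anyDuplicated(colnames(d))) stop("duplicate sample id in VCF")
  GenotypeMatrix(d, countedAllele = altc, otherAllele = refc)
}

#' @rdname readGenotypes
#' @export
readDosageTable <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  d <- t(as.matrix(tab))  # file is samples x rsids; store variants x samples
  storage.mode(d) <- "double"
  if (anyDuplicated(rownames(d))) stop("duplicate rsid in dosage table")
  if (anyDuplicated(colnames(d))) stop("duplicate sample id in dosage table")
  GenotypeMatrix(d)
}

#' Write a GenotypeMatrix as a dosage table (samples x rsids TSV)
#'
#' Round-trips through \code{readDosageTable} losslessly, including the
#' missingness mask.
#'
#' @param x A \code{GenotypeMatrix}.
#' @param path Output file.
#' @export
writeDosageTable <- function(x, path) {
  d <- t(dosages(x))
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
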