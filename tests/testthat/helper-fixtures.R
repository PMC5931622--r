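# Fixtures built in code at test time.

shippedWeightsPath <- function()
  system.file("extdata", "synthetic_weights_51snp.tsv", package = "grsCHD")

shippedWeights <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(readWeights(shippedWeightsPath()))
    cache
  }
})

# A tiny weight table: k non-haplotype variants (+ optional haplotype).
toyWeightTable <- function(k = 3, betas = NULL, withHaplotype = TRUE,
                           grs12 = TRUE) {
  if (is.null(betas)) betas <- seq(0.05, 0.25, length.out = k)
  alleles <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  main <- data.frame(
    rsid = sprintf("rs%03d", seq_len(k)),
    effect_allele = vapply(seq_len(k),
                           function(i) alleles[[1 + (i - 1) %% 4]][1], ""),
    other_allele = vapply(seq_len(k),
                          function(i) alleles[[1 + (i - 1) %% 4]][2], ""),
    beta = betas, in_grs12 = grs12, in_grs51 = TRUE,
    haplotype_member = FALSE, imputation_r2 = NA_real_)
  if (!withHaplotype) return(main)
  hap <- data.frame(
    rsid = paste0("rsH", 1:4),
    effect_allele = c("A", "A", "G", "A"),
    other_allele = c("C", "G", "A", "G"),
    beta = 0, in_grs12 = grs12, in_grs51 = TRUE,
    haplotype_member = TRUE, imputation_r2 = NA_real_)
  rbind(main, hap)
}

toyWeights <- function(...) WeightSet(toyWeightTable(...))

# A small analysis-ready cohort via the package generator.
smallCohort <- function(n = 800, seed = 42, hr = 1.6, ...) {
  cfg <- simConfig(n = n, seed = seed, grsLogHrPerSd = log(hr), ...)
  simulateCohort(cfg, shippedWeights())
}

# A minimal valid cohort data.frame built by hand.
handCohortDF <- function(n, time, event, risk_age = NULL) {
  data.frame(
    id = sprintf("h%03d", seq_len(n)),
    ancestry = "AFR",
    age = if (is.null(risk_age)) rep(55, n) else risk_age,
    sex = rep(c("female", "male"), length.out = n),
    total_chol = 190, hdl = 55, sbp = 125, dbp = 75,
    smoker = "never", diabetes = FALSE,
    followup_time = time, event = event,
    stringsAsFactors = FALSE)
}

writeTempVcf <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}

vcfHeader <- c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3")
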