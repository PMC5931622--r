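test_that("dosages orient onto the effect allele", {
  expect_equal(orientDosage(2, "A", "A", "G"), 2)   # identity
  expect_equal(orientDosage(2, "G", "A", "G"), 0)   # complement
  expect_equal(orientDosage(1, NA, "A", "G"), 1)    # already oriented
  # complementary-strand report resolves when unambiguous
  expect_equal(orientDosage(2, "T", "A", "G"), 2)
  expect_equal(orientDosage(2, "C", "A", "G"), 0)
  # palindromic variant is ambiguous in strict mode
  expect_error(orientDosage(1, "G", "G", "C"), "palindromic")
  expect_error(orientDosage(1, "A", "A", "T"), "palindromic")
})

test_that("haplotype copies follow the presence / min-dosage rules", {
  expect_equal(haplotypeCopies(c(2, 2, 2, 2), "presence"), 1L)
  expect_equal(haplotypeCopies(c(1, 0, 2, 1), "presence"), 0L)
  expect_equal(haplotypeCopies(c(2, 1, 2, 2), "min_dosage"), 1L)
  expect_equal(haplotypeCopies(c(2, 2, 2, 2), "min_dosage"), 2L)
  expect_warning(h <- haplotypeCopies(c(2, NA, 2, 2), "presence"),
                 "missing")
  expect_equal(h, 0L)
})

test_that("computeGRS reproduces a hand-summed toy score", {
  # (beta, d) = (0.1,1), (0.05,2), (0.3,0) plus haplotype present
  w <- toyWeights(3, betas = c(0.1, 0.05, 0.3))
  d <- matrix(c(1, 2, 0, 2, 2, 2, 2), ncol = 1,
              dimnames = list(c("rs001", "rs002", "rs003",
                                paste0("rsH", 1:4)), "s1"))
  g <- GenotypeMatrix(d)  # counted allele = effect allele
  sv <- computeGRS(g, w, "GRS51")
  expect_equal(unname(scores(sv)), 0.1 + 0.10 + 0 + 0.131)
  # all dosages zero, no haplotype: empty-risk individual scores 0
  g0 <- GenotypeMatrix(matrix(0, 7, 1, dimnames = dimnames(d)))
  expect_equal(unname(scores(computeGRS(g0, w, "GRS51"))), 0)
  # single variant beta 0.2, dosage 2, no haplotype
  w1 <- WeightSet(toyWeightTable(1, betas = 0.2, withHaplotype = FALSE))
  g1 <- GenotypeMatrix(matrix(2, 1, 1, dimnames = list("rs001", "s1")))
  expect_equal(unname(scores(computeGRS(g1, w1, "GRS51"))), 0.4)
})

test_that("computeGRS equals the per-individual brute-force oracle", {
  set.seed(99)
  for (rep in 1:3) {
    tab <- toyWeightTable(16, betas = round(runif(16, -0.1, 0.3), 3))
    w <- WeightSet(tab)
    rsids <- c(sprintf("rs%03d", 1:16), paste0("rsH", 1:4))
    d <- matrix(sample(0:2, 20 * 20, replace = TRUE), 20, 20,
                dimnames = list(rsids, sprintf("s%02d", 1:20)))
    # scramble which allele was counted at half the sites
    flip <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    ca <- ifelse(flip, tab$other_allele, tab$effect_allele)
    g <- GenotypeMatrix(d, countedAllele = ca)
    expected <- bruteForceGRS(d, stats::setNames(ca, rsids), tab)
    expect_equal(unname(scores(computeGRS(g, w, "GRS51"))), expected)
  }
})

test_that("scores are linear in the weights and ignore zero-weight variants", {
  set.seed(7)
  tab <- toyWeightTable(6, betas = runif(6, 0, 0.3), withHaplotype = FALSE)
  d <- matrix(sample(0:2, 6 * 15, replace = TRUE), 6, 15,
              dimnames = list(tab$rsid, sprintf("s%02d", 1:15)))
  g <- GenotypeMatrix(d)
  s1 <- scores(computeGRS(g, WeightSet(tab), "GRS51"))
  tab2 <- tab; tab2$beta <- 3 * tab2$beta
  expect_equal(scores(computeGRS(g, WeightSet(tab2), "GRS51")), 3 * s1)
  tab3 <- rbind(tab, within(tab[1, ], { rsid <- "rs999"; beta <- 0 }))
  d3 <- rbind(d, rs999 = sample(0:2, 15, replace = TRUE))
  expect_equal(scores(computeGRS(GenotypeMatrix(d3), WeightSet(tab3),
                                 "GRS51")), s1)
  # score bound: 0 <= score <= 2 * sum(|beta|) + 2 * 0.131
  expect_true(all(s1 >= 0 & s1 <= 2 * sum(abs(tab$beta)) + 2 * 0.131))
})

test_that("missingness policy: NA above 10%, frequency-imputation below", {
  tab <- toyWeightTable(20, betas = rep(0.1, 20), withHaplotype = FALSE)
  d <- matrix(1, 20, 10, dimnames = list(tab$rsid, sprintf("s%02d", 1:10)))
  d[1:3, 1] <- NA            # 15% missing for s01 -> NA score
  d[1, 2] <- NA              # 5% missing for s02 -> imputed
  g <- GenotypeMatrix(d)
  sv <- computeGRS(g, WeightSet(tab), "GRS51")
  expect_true(is.na(scores(sv)[["s01"]]))
  # rs001 non-missing dosages are all 1 -> af 0.5 -> impute 2*0.5 = 1
  expect_equal(unname(scores(sv)[["s02"]]), 20 * 0.1 * 1)
  expect_equal(unname(nVariantsUsed(sv)[1:2]), c(17L, 19L))
})

test_that("GRS12 demands its eight flagged variants", {
  tab <- toyWeightTable(5, grs12 = FALSE)
  tab$in_grs12[1:3] <- TRUE
  d <- matrix(1, 9, 2, dimnames = list(tab$rsid, c("a", "b")))
  expect_error(computeGRS(GenotypeMatrix(d), WeightSet(tab), "GRS12"),
               ">= 8")
})

test_that("standardization is per group with unit sample SD", {
  z <- standardizeScores(c(1, 2, 3), rep("AFR", 3))
  expect_equal(unname(z), c(-1, 0, 1))
  x <- c(1, 5, 9, 2, 2.5, 3)
  gr <- rep(c("AFR", "EA"), each = 3)
  z2 <- standardizeScores(x, gr)
  expect_equal(as.vector(tapply(z2, gr, mean)), c(0, 0))
  expect_equal(as.vector(tapply(z2, gr, sd)), c(1, 1))
  expect_equal(standardizeScores(x + 5, gr), z2)  # location invariance
  expect_error(standardizeScores(c(1, 1, 1), rep("g", 3)), "variance")
})

test_that("tertiles split within group, ties going low", {
  x <- c(10, 20, 30, 40, 50, 60, 70, 80, 90)
  t1 <- assignTertiles(x, rep("AFR", 9))
  expect_equal(as.vector(table(t1)), c(3L, 3L, 3L))
  expect_equal(unname(t1), rep(1:3, each = 3))
  # four tied values straddling the upper cut all go low
  x2 <- c(1, 2, 5, 5, 5, 5, 8, 9, 10)
  t2 <- assignTertiles(x2, rep("AFR", 9))
  expect_true(all(t2[x2 == 5] == t2[x2 == 5][1]))
  # disjoint-range groups are labelled independently
  xa <- c(1, 2, 3, 4, 5, 6); xb <- xa + 100
  lab <- assignTertiles(c(xa, xb), rep(c("AFR", "EA"), each = 6))
  expect_equal(lab[1:6], lab[7:12])
  expect_error(assignTertiles(rep(1, 5), rep("g", 5)), "equal")
})
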