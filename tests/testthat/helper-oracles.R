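# Independent brute-force oracles used to cross-check the implementation.

# Harrell's C by exhaustive pair enumeration (censoring-aware
# comparability, risk ties 0.5). A pair with tied follow-up is
# comparable only when exactly one member has the event (that member
# is known to fail first); tied event times are not comparable.
bruteForceC <- function(risk, time, event) {
  n <- length(risk)
  num <- den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] == event[j]) next
      a <- if (event[i]) i else j
      b <- if (event[i]) j else i
    } else {
      a <- if (time[i] < time[j]) i else j  # earlier subject
      b <- if (time[i] < time[j]) j else i
      if (!event[a]) next
    }
    den <- den + 1
    if (risk[a] > risk[b]) num <- num + 1
    else if (risk[a] == risk[b]) num <- num + 0.5
  }
  num / den
}

# Category NRI by direct counting on censoring-free data.
bruteForceNRI <- function(baseRisk, updatedRisk, event) {
  cb <- as.integer(grsCHD::riskCategory(baseRisk))
  cu <- as.integer(grsCHD::riskCategory(updatedRisk))
  up <- cu > cb; dn <- cu < cb
  e <- as.logical(event)
  list(events = (sum(up & e) - sum(dn & e)) / sum(e),
       nonevents = (sum(dn & !e) - sum(up & !e)) / sum(!e))
}

# Per-individual brute-force GRS: loop over variants, flip to effect
# allele, weighted sum, plus haplotype presence term.
bruteForceGRS <- function(dosage, countedAllele, weightTab, hapWeight = 0.131) {
  if (is.null(weightTab$weight)) weightTab$weight <- weightTab$beta
  n <- ncol(dosage)
  members <- weightTab[!weightTab$haplotype_member, , drop = FALSE]
  hap <- weightTab[weightTab$haplotype_member, , drop = FALSE]
  out <- numeric(n)
  for (s in seq_len(n)) {
    acc <- 0
    for (k in seq_len(nrow(members))) {
      rs <- members$rsid[k]
      d <- dosage[rs, s]
      ca <- countedAllele[[rs]]
      if (!is.na(ca) && ca == members$other_allele[k]) d <- 2 - d
      acc <- acc + members$weight[k] * d
    }
    if (nrow(hap) == 4) {
      hd <- numeric(4)
      for (k in 1:4) {
        rs <- hap$rsid[k]
        d <- dosage[rs, s]
        ca <- countedAllele[[rs]]
        if (!is.na(ca) && ca == hap$other_allele[k]) d <- 2 - d
        hd[k] <- d
      }
      if (min(hd) >= 1) acc <- acc + hapWeight
    }
    out[s] <- acc
  }
  out
}

# Fixed-effects pooling as weighted least squares: lnhr ~ 1 with
# weights 1/se^2 solved by the normal equations.
wlsPoolOracle <- function(lnhr, se) {
  W <- diag(1 / se^2, length(se))
  X <- matrix(1, length(se), 1)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% lnhr)
  list(lnhr = drop(beta), se = sqrt(drop(solve(t(X) %*% W %*% X))))
}

# Cox partial log-likelihood for a single covariate, no ties assumed;
# maximized by golden-section search as an independent solver.
bruteForceCoxBeta <- function(x, time, event) {
  pl <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
    ll
  }
  stats::optimize(pl, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
}

# Hand product-limit estimator (no ties handling beyond shared times).
handKM <- function(time, event, tStar) {
  ut <- sort(unique(time[event == 1]))
  S <- 1
  for (t in ut[ut <= tStar]) {
    d <- sum(time == t & event == 1)
    r <- sum(time >= t)
    S <- S * (1 - d / r)
  }
  1 - S
}
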