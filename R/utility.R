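#' Events prevented under assumed statin efficacy
#'
#' Expected 10-year events times the assumed relative risk reduction
#' (default 0.24), rounded half-up to one decimal as reported.
#'
#' @param expectedEvents Expected events (>= 0).
#' @param rrr Relative risk reduction (default 0.24).
#' @return One-decimal number of events prevented.
#' @export
eventsPrevented <- function(expectedEvents, rrr = 0.24) {
  if (any(expectedEvents < 0)) stop("expected events must be >= 0")
  roundHalfUp(expectedEvents * rrr, 1)
}

#' Number needed to treat to prevent one event
#'
#' Treated count divided by events prevented, rounded to the nearest
#' integer (half-up).
#'
#' @param treated Individuals treated (A).
#' @param prevented Events prevented (C, > 0).
#' @return Integer NNT.
#' @export
nnt <- function(treated, prevented) {
  if (any(prevented <= 0)) stop("no finite NNT when events prevented is 0")
  as.integer(roundHalfUp(treated / prevented, 0))
}

#' Efficiency of two-stage vs one-stage screening
#'
#' Ratio of the one-stage NNT to the two-stage NNT, one decimal.
#'
#' @param nntOneStage,nntTwoStage The two NNTs.
#' @return One-decimal efficiency ratio.
#' @export
screeningComparison <- function(nntOneStage, nntTwoStage) {
  if (any(nntTwoStage == 0)) stop("two-stage NNT of 0")
  roundHalfUp(nntOneStage / nntTwoStage, 1)
}

#' Up-reclassified subset of a reclassification table
#'
#' Among subjects at intermediate baseline risk, those whose updated
#' category is higher than their baseline one: returns their count (A)
#' and their Kaplan-Meier expected 10-year events (B).
#'
#' @param table A \code{\link{buildReclassTable}} result.
#' @return List with \code{treated} (A) and \code{expectedEvents} (B).
#' @export
upreclassifiedSubset <- function(table) {
  mid <- 2:3  # intermediate_low, intermediate_high rows
  up <- upper.tri(table$counts)
  sel <- up; sel[-mid, ] <- FALSE
  list(treated = sum(table$counts[sel]),
       expectedEvents = sum(table$expectedEvents[sel]))
}

#' One-stage vs two-stage screening table
#'
#' Builds the screening-arm rows for one stratum: the one-stage arm
#' treats every subject at intermediate baseline risk (A = their count,
#' B = their KM expected 10-year events); each two-stage arm treats
#' only the subjects a score up-reclassifies out of intermediate risk.
#' Columns follow the published arithmetic: C = B x rrr (one decimal),
#' D = A / C (nearest integer), efficiency = one-stage D / arm D (one
#' decimal).
#'
#' @param baseRisk Baseline (FRS) risks.
#' @param updatedRisks Named list of updated risk vectors, one per
#'   score (e.g. \code{list(GRS12 = ..., GRS51 = ...)}).
#' @param time,event Follow-up and event indicator.
#' @param tStar Horizon (default 10).
#' @param rrr Assumed relative risk reduction (default 0.24).
#' @return data.frame with columns \code{arm}, \code{treated},
#'   \code{expected_events}, \code{events_prevented}, \code{nnt},
#'   \code{efficiency}.
#' @export
screeningTable <- function(baseRisk, updatedRisks, time, event,
                           tStar = 10, rrr = 0.24) {
  mid <- riskCategory(baseRisk) %in%
    c("intermediate_low", "intermediate_high")
  A1 <- sum(mid)
  B1 <- if (A1) A1 * kmEventProb(time[mid], event[mid], tStar) else 0
  rows <- list(data.frame(arm = "one_stage", treated = A1,
                          expected_events = B1))
  for (nm in names(updatedRisks)) {
    tab <- buildReclassTable(baseRisk, updatedRisks[[nm]], time, event,
                             tStar)
    ab <- upreclassifiedSubset(tab)
    rows <- c(rows, list(data.frame(
      arm = paste0("two_stage_", tolower(nm)),
      treated = ab$treated, expected_events = ab$expectedEvents)))
  }
  out <- do.call(rbind, rows)
  out$events_prevented <- eventsPrevented(out$expected_events, rrr)
  out$nnt <- vapply(seq_len(nrow(out)), function(i)
    if (out$events_prevented[i] > 0)
      nnt(out$treated[i], out$events_prevented[i]) else NA_integer_, 1L)
  out$efficiency <- NA_real_
  if (!is.na(out$nnt[1]))
    for (i in which(!is.na(out$nnt)))
      out$efficiency[i] <- screeningComparison(out$nnt[1], out$nnt[i])
  out
}
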