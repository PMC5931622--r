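#' Subject-level Kaplan-Meier event weights
#'
#' Fractional 10-year event weights for censored data: subjects with an
#' observed event by \code{tStar} weigh 1; subjects followed event-free
#' past \code{tStar} weigh 0; subjects censored at \code{c < tStar}
#' weigh the conditional KM probability of an event by \code{tStar}
#' given survival to \code{c}. On censoring-free data the weights are
#' exactly the event indicators.
#'
#' @param time,event Follow-up and event indicator.
#' @param tStar Horizon (default 10).
#' @return Numeric weights in [0, 1].
#' @export
kmEventWeights <- function(time, event, tStar = 10) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  S <- stats::stepfun(sf$time, c(1, sf$surv))
  tmax <- max(time)
  StStar <- if (tStar <= tmax) S(tStar) else {
    Smax <- S(tmax)
    if (Smax <= 0) 0 else {
      win <- min(1, tmax)
      h <- (-log(Smax) + log(S(tmax - win))) / win
      Smax * exp(-h * (tStar - tmax))
    }
  }
  w <- numeric(length(time))
  w[event & time <= tStar] <- 1
  cens <- !event & time < tStar
  Sc <- vapply(time[cens], S, 0)
  w[cens] <- ifelse(Sc > 0, (Sc - StStar) / Sc, 1)
  pmin(pmax(w, 0), 1)
}

#' Cross-tabulate risk categories under two models
#'
#' 4x4 table of subjects by (base category, updated category) with each
#' cell's expected 10-year events from the cell's own Kaplan-Meier
#' estimate (cell n times the KM event probability at \code{tStar}).
#'
#' @param baseRisk,updatedRisk 10-year risks under the two models.
#' @param time,event Follow-up and event indicator.
#' @param tStar Horizon (default 10).
#' @return List of class \code{"reclassTable"}: \code{counts},
#'   \code{eventProb}, \code{expectedEvents} (all 4x4), \code{n}.
#' @export
buildReclassTable <- function(baseRisk, updatedRisk, time, event,
                              tStar = 10) {
  stopifnot(tStar > 0,
            length(baseRisk) == length(updatedRisk),
            length(baseRisk) == length(time))
  cb <- riskCategory(baseRisk)
  cu <- riskCategory(updatedRisk)
  counts <- table(base = cb, updated = cu)
  prob <- matrix(0, 4, 4, dimnames = dimnames(counts))
  for (i in 1:4) for (j in 1:4) {
    k <- cb == RISK_CATEGORIES[i] & cu == RISK_CATEGORIES[j]
    if (any(k))
      prob[i, j] <- kmEventProb(time[k], event[k], tStar)
  }
  structure(list(counts = unclass(counts), eventProb = prob,
                 expectedEvents = unclass(counts) * prob,
                 n = length(cb), tStar = tStar),
            class = "reclassTable")
}

#' @export
print.reclassTable <- function(x, ...) {
  cat("Reclassification table (", x$n, " subjects; expected events at ",
      x$tStar, "y in brackets)\n", sep = "")
  m <- matrix(sprintf("%d [%.1f]", x$counts, x$expectedEvents), 4, 4,
              dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  invisible(x)
}

#' Category-based net reclassification improvement
#'
#' Event and non-event masses per cell come from the table's KM-expected
#' events: \code{NRI_events = P(up | event) - P(down | event)},
#' \code{NRI_nonevents = P(down | nonevent) - P(up | nonevent)}, total
#' is their sum.
#'
#' @param table A \code{\link{buildReclassTable}} result.
#' @return List of class \code{"nriResult"} with \code{events},
#'   \code{nonevents}, \code{total}.
#' @export
categoryNRI <- function(table) {
  ev <- table$expectedEvents
  ne <- table$counts - ev
  if (sum(ev) <= 0)
    stop("zero expected events; event component of the NRI is undefined")
  up <- upper.tri(ev)
  dn <- lower.tri(ev)
  nriE <- (sum(ev[up]) - sum(ev[dn])) / sum(ev)
  nriN <- (sum(ne[dn]) - sum(ne[up])) / sum(ne)
  structure(list(events = nriE, nonevents = nriN, total = nriE + nriN),
            class = "nriResult")
}

#' @export
print.nriResult <- function(x, ...) {
  cat(sprintf("NRI: events %.3f, non-events %.3f, total %.3f\n",
              x$events, x$nonevents, x$total))
  invisible(x)
}

nriOn <- function(baseRisk, updatedRisk, time, event, subset = NULL,
                  tStar = 10) {
  if (!is.null(subset)) {
    baseRisk <- baseRisk[subset]; updatedRisk <- updatedRisk[subset]
    time <- time[subset]; event <- event[subset]
  }
  categoryNRI(buildReclassTable(baseRisk, updatedRisk, time, event, tStar))
}

#' Bias-corrected NRI in the baseline-intermediate subset
#'
#' The raw NRI restricted to subjects whose baseline category is
#' intermediate overstates marker value, because refitting alone moves
#' subjects off the category boundaries. The correction estimates that
#' null movement by resampling: for each of \code{Bnull} replicates the
#' base model is refit on a bootstrap sample (via \code{refitFun}), its
#' predictions on the original cohort replace the updated risks, and
#' the resulting null NRI is averaged and subtracted, component-wise,
#' from the raw estimate.
#'
#' @param baseRisk,updatedRisk 10-year risks under the two models.
#' @param time,event Follow-up and event indicator.
#' @param refitFun \code{function(idx)} returning base-model risks for
#'   the full cohort after refitting on subjects \code{idx}; when
#'   \code{NULL} the uncorrected subset NRI is returned.
#' @param Bnull Null replicates (default 100).
#' @param tStar Horizon (default 10).
#' @param seed Seed for the resampling.
#' @return An \code{"nriResult"} with attribute \code{"raw"} (the
#'   uncorrected subset NRI) and \code{"nullMean"}.
#' @export
intermediateNRI <- function(baseRisk, updatedRisk, time, event,
                            refitFun = NULL, Bnull = 100, tStar = 10,
                            seed = 1) {
  mid <- riskCategory(baseRisk) %in%
    c("intermediate_low", "intermediate_high")
  if (!any(mid)) stop("no subjects at intermediate baseline risk")
  raw <- nriOn(baseRisk, updatedRisk, time, event, mid, tStar)
  if (is.null(refitFun)) return(raw)
  n <- length(baseRisk)
  set.seed(seed)
  nulls <- vapply(seq_len(Bnull), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    nullRisk <- refitFun(idx)
    z <- nriOn(baseRisk, nullRisk, time, event, mid, tStar)
    c(z$events, z$nonevents, z$total)
  }, numeric(3))
  nullMean <- rowMeans(nulls)
  out <- structure(list(events = raw$events - nullMean[1],
                        nonevents = raw$nonevents - nullMean[2],
                        total = raw$total - nullMean[3]),
                   class = "nriResult")
  attr(out, "raw") <- raw
  attr(out, "nullMean") <- nullMean
  out
}

#' Integrated discrimination improvement on censored data
#'
#' Difference in discrimination slopes between the updated and base
#' models, where the mean risks among events and non-events are
#' weighted by subject-level Kaplan-Meier 10-year event weights
#' (\code{\link{kmEventWeights}}) to handle censoring. Reported both on
#' the probability scale and times 100 (percent scale).
#'
#' @param baseRisk,updatedRisk 10-year risks under the two models.
#' @param time,event Follow-up and event indicator.
#' @param tStar Horizon (default 10).
#' @return List with \code{idi} and \code{idiPercent}.
#' @export
idi <- function(baseRisk, updatedRisk, time, event, tStar = 10) {
  stopifnot(all(baseRisk >= 0 & baseRisk <= 1),
            all(updatedRisk >= 0 & updatedRisk <= 1))
  w <- kmEventWeights(time, event, tStar)
  if (sum(w) <= 0) stop("no (expected) events; IDI undefined")
  slope <- function(r)
    sum(w * r) / sum(w) - sum((1 - w) * r) / sum(1 - w)
  v <- slope(updatedRisk) - slope(baseRisk)
  list(idi = v, idiPercent = 100 * v)
}

#' Percentile bootstrap confidence intervals for reclassification metrics
#'
#' Resamples subjects with replacement and recomputes the metric
#' end-to-end on each replicate (including every Kaplan-Meier step, so
#' the intervals reflect KM uncertainty). Replicates where the metric
#' fails (e.g. an empty category) are dropped; more than
#' \code{maxFailFrac} failures aborts.
#'
#' @param statFun \code{function(idx)} returning a named numeric vector
#'   of metric components for subjects \code{idx}.
#' @param n Number of subjects.
#' @param B Bootstrap replicates (>= 100).
#' @param seed Seed (resampling is deterministic given it).
#' @param maxFailFrac Tolerated failure fraction (default 0.2).
#' @return Matrix with rows = metric components, columns
#'   \code{lcl}/\code{ucl} (2.5/97.5 percentiles), plus attribute
#'   \code{"B_ok"}.
#' @export
bootstrapCI <- function(statFun, n, B = 1000, seed = 1,
                        maxFailFrac = 0.2) {
  stopifnot(B >= 100)
  set.seed(seed)
  reps <- lapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(statFun(idx), error = function(e) NULL)
  })
  ok <- !vapply(reps, is.null, TRUE)
  if (mean(!ok) > maxFailFrac)
    stop("metric failed on ", sum(!ok), " of ", B,
         " bootstrap replicates")
  m <- do.call(rbind, reps[ok])
  ci <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  colnames(ci) <- c("lcl", "ucl")
  attr(ci, "B_ok") <- sum(ok)
  ci
}
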