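#' Read / write a pipeline run configuration
#'
#' A run configuration is a YAML file with keys \code{weights} (path to
#' the weight TSV), \code{sim} (arguments for \code{\link{simConfig}}),
#' \code{models}, \code{scores}, \code{bootstrapB}, \code{BnullNRI} and
#' \code{seed}. It round-trips through serialization.
#'
#' @param path YAML file.
#' @return \code{readRunConfig}: the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(models = c("1a", "1b", "1c", "1d",
                              "2a", "2b", "2c", "2d"),
                   scores = c("GRS12", "GRS51"),
                   bootstrapB = 200L, BnullNRI = 50L, seed = 1L,
                   sim = list())
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

#' @rdname readRunConfig
#' @param config A configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# risk vectors for one cohort: base = Cox refit on the FRS components,
# updated = the same fit plus each standardized score
cohortRisks <- function(cohort, zByScore, tStar = 10) {
  base <- updatedRisk(cohort, NULL, tStar)
  upd <- lapply(zByScore, function(z) updatedRisk(cohort, z, tStar))
  list(base = base, updated = upd)
}

evaluateStratum <- function(cohort, zByScore, bootstrapB = 200,
                            BnullNRI = 50, seed = 1, tStar = 10) {
  df <- as.data.frame(cohort)
  time <- df$followup_time; event <- df$event
  rk <- cohortRisks(cohort, zByScore, tStar)
  out <- list()
  for (nm in names(zByScore)) {
    upd <- rk$updated[[nm]]
    cc <- compareCStatistics(rk$base, upd, time, event,
                             B = max(100, bootstrapB %/% 2),
                             seed = childSeed(seed, 1))
    hlB <- hosmerLemeshow(rk$base, time, event, tStar = tStar)
    hlU <- hosmerLemeshow(upd, time, event, tStar = tStar)
    tab <- buildReclassTable(rk$base, upd, time, event, tStar)
    nriFull <- categoryNRI(tab)
    nriCI <- bootstrapCI(function(idx) {
      z <- nriOn(rk$base, upd, time, event, idx, tStar)
      c(events = z$events, nonevents = z$nonevents, total = z$total)
    }, n = nrow(df), B = max(100, bootstrapB), seed = childSeed(seed, 2))
    refitFun <- local({
      coh <- df
      function(idx) {
        # monotone-likelihood warnings on individual bootstrap
        # replicates are expected resampling noise
        fit <- suppressWarnings(survival::coxph(
          survival::Surv(followup_time, event) ~ age + sex + total_chol +
            hdl + sbp + dbp + smoker + diabetes,
          data = coh[idx, , drop = FALSE], ties = "efron"))
        H10 <- baselineCumHaz(fit, tStar)
        lp <- drop(stats::predict(fit, newdata = coh, type = "lp"))
        1 - exp(-H10 * exp(lp))
      }
    })
    nriMid <- intermediateNRI(rk$base, upd, time, event,
                              refitFun = refitFun, Bnull = BnullNRI,
                              tStar = tStar, seed = childSeed(seed, 3))
    idiRes <- idi(rk$base, upd, time, event, tStar)
    idiCI <- bootstrapCI(function(idx) {
      v <- idi(rk$base[idx], upd[idx], time[idx], event[idx], tStar)
      c(idi = v$idiPercent)
    }, n = nrow(df), B = max(100, bootstrapB), seed = childSeed(seed, 4))
    out[[nm]] <- list(cStat = cc, hlBase = hlB, hlUpdated = hlU,
                      reclass = tab, nriFull = nriFull, nriFullCI = nriCI,
                      nriIntermediate = nriMid, idi = idiRes,
                      idiCI = idiCI)
  }
  out$risks <- rk
  out
}

#' Run the full simulate-score-evaluate-report pipeline
#'
#' Simulates a cohort, computes both scores, fits the per-ancestry Cox
#' model suites, pools them by fixed-effects meta-analysis, evaluates
#' discrimination/calibration/reclassification per stratum and
#' combined, builds the screening comparison, and (optionally) writes
#' the result tables plus a JSON manifest. Deterministic given the
#' configuration seed.
#'
#' @param config A configuration list (see \code{\link{readRunConfig}})
#'   or a \code{\link{simConfig}} (then \code{weights} must be given).
#' @param weights A \code{WeightSet}; overrides \code{config$weights}.
#' @param outDir Output directory (created); \code{NULL} = don't write.
#' @return Invisibly, a list with \code{hazardRatios} (long-format
#'   model-by-stratum HR table including pooled rows),
#'   \code{evaluation} (per-stratum metric objects), \code{screening}
#'   (per-stratum screening tables), \code{sim} and \code{config}.
#' @export
runPipeline <- function(config, weights = NULL, outDir = NULL) {
  if (inherits(config, "simConfig"))
    config <- list(sim = unclass(config), seed = config$seed)
  cfg <- config
  for (k in c("models", "scores", "bootstrapB", "BnullNRI"))
    if (is.null(cfg[[k]]))
      cfg[[k]] <- list(models = c("1a", "1b", "1c", "1d",
                                  "2a", "2b", "2c", "2d"),
                       scores = c("GRS12", "GRS51"),
                       bootstrapB = 200L, BnullNRI = 50L)[[k]]
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(weights)) {
    if (is.null(cfg$weights)) stop("no weight set supplied")
    weights <- readWeights(cfg$weights)
  }
  simArgs <- cfg$sim
  simArgs$seed <- cfg$seed
  sc <- do.call(simConfig, simArgs)
  sim <- simulateCohort(sc, weights)
  cohort <- sim$cohort
  df <- as.data.frame(cohort)
  anc <- as.character(df$ancestry)
  zBy <- lapply(sim$scores[cfg$scores], standardizeScores, groups = anc)
  tertBy <- lapply(sim$scores[cfg$scores], assignTertiles, groups = anc)

  hrRows <- list()
  for (s in cfg$scores) for (m in cfg$models) {
    spec <- modelSpec(m)
    perStratum <- list()
    for (g in unique(anc)) {
      i <- anc == g
      sub <- CohortTable(df[i, , drop = FALSE])
      sscore <- if (spec$grsForm == "per_sd") zBy[[s]][i] else tertBy[[s]][i]
      fit <- fitCoxModel(sub, sscore, spec)
      perStratum[[g]] <- cbind(stratum = g, score = s, model = m,
                               fit$hr[, c("term", "hr", "lcl", "ucl")])
    }
    strat <- do.call(rbind, perStratum)
    pooled <- do.call(rbind, lapply(split(strat, strat$term), function(d) {
      pm <- poolFixed(d[, c("hr", "lcl", "ucl")])
      data.frame(stratum = "combined", score = s, model = m,
                 term = d$term[1], hr = pm$hr, lcl = pm$lcl, ucl = pm$ucl)
    }))
    hrRows[[paste(s, m)]] <- rbind(strat, pooled)
  }
  hazardRatios <- do.call(rbind, c(hrRows, make.row.names = FALSE))

  evaluation <- list()
  screening <- list()
  strata <- c(as.list(unique(anc)), list(unique(anc)))
  names(strata) <- c(unique(anc), "combined")
  for (g in names(strata)) {
    i <- anc %in% strata[[g]]
    sub <- CohortTable(df[i, , drop = FALSE])
    zSub <- lapply(zBy, `[`, i)
    evaluation[[g]] <- evaluateStratum(sub, zSub,
                                       bootstrapB = cfg$bootstrapB,
                                       BnullNRI = cfg$BnullNRI,
                                       seed = childSeed(cfg$seed,
                                                        match(g, names(strata))))
    rk <- evaluation[[g]]$risks
    screening[[g]] <- screeningTable(rk$base, rk$updated,
                                     df$followup_time[i], df$event[i])
  }
  res <- list(hazardRatios = hazardRatios, evaluation = evaluation,
              screening = screening, sim = sim, config = cfg)
  if (!is.null(outDir)) reportTables(res, outDir)
  invisible(res)
}

#' Write pipeline result tables
#'
#' Emits \code{hazard_ratios.csv} (model x score x stratum, HRs to two
#' decimals), \code{model_evaluation.csv} (C statistics, calibration,
#' NRI/IDI with bootstrap CIs, two decimals), \code{screening.csv}
#' (screening arithmetic under its own rounding rules) and
#' \code{manifest.json} (package version, seed, file checksums). A
#' rerun on the same results writes identical bytes.
#'
#' @param results A \code{\link{runPipeline}} result.
#' @param outDir Output directory.
#' @return Invisibly, the written paths.
#' @export
reportTables <- function(results, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(outDir, "hazard_ratios.csv")
  hr <- results$hazardRatios
  for (cl in c("hr", "lcl", "ucl")) hr[[cl]] <- sprintf("%.2f", hr[[cl]])
  utils::write.csv(hr, f1, row.names = FALSE, quote = FALSE)

  evRows <- list()
  for (g in names(results$evaluation)) {
    ev <- results$evaluation[[g]]
    for (s in setdiff(names(ev), "risks")) {
      e <- ev[[s]]
      evRows[[paste(g, s)]] <- data.frame(
        stratum = g, score = s,
        c_base = sprintf("%.3f", e$cStat$cBase),
        c_updated = sprintf("%.3f", e$cStat$cUpdated),
        c_diff_p = sprintf("%.2f", e$cStat$p),
        hl_chi2_base = sprintf("%.1f (%d); %.2f", e$hlBase$chi2,
                               e$hlBase$df, e$hlBase$p),
        hl_chi2_updated = sprintf("%.1f (%d); %.2f", e$hlUpdated$chi2,
                                  e$hlUpdated$df, e$hlUpdated$p),
        idi = sprintf("%.2f (%.2f-%.2f)", e$idi$idiPercent,
                      e$idiCI["idi", "lcl"], e$idiCI["idi", "ucl"]),
        nri_events = sprintf("%.2f (%.2f-%.2f)", e$nriFull$events,
                             e$nriFullCI["events", "lcl"],
                             e$nriFullCI["events", "ucl"]),
        nri_nonevents = sprintf("%.2f (%.2f-%.2f)", e$nriFull$nonevents,
                                e$nriFullCI["nonevents", "lcl"],
                                e$nriFullCI["nonevents", "ucl"]),
        nri_total = sprintf("%.2f (%.2f-%.2f)", e$nriFull$total,
                            e$nriFullCI["total", "lcl"],
                            e$nriFullCI["total", "ucl"]),
        nri_intermediate_corrected = sprintf("%.2f",
                                             e$nriIntermediate$total))
    }
  }
  f2 <- file.path(outDir, "model_evaluation.csv")
  utils::write.csv(do.call(rbind, c(evRows, make.row.names = FALSE)),
                   f2, row.names = FALSE, quote = FALSE)

  f3 <- file.path(outDir, "screening.csv")
  scr <- do.call(rbind, lapply(names(results$screening), function(g)
    cbind(stratum = g, results$screening[[g]])))
  scr$expected_events <- sprintf("%.1f", scr$expected_events)
  utils::write.csv(scr, f3, row.names = FALSE, quote = FALSE)

  files <- c(f1, f2, f3)
  manifest <- list(package = "grsCHD",
                   version = as.character(utils::packageVersion("grsCHD")),
                   seed = results$config$seed,
                   models = results$config$models,
                   scores = results$config$scores,
                   checksums = as.list(tools::md5sum(files)))
  f4 <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, f4, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, f4))
}
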