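Z975 <- 1.959964

#' Back-transform a printed HR and 95\% CI to log scale
#'
#' \code{lnhr = log(hr)}; \code{se = (log(ucl) - log(lcl)) / (2 x
#' 1.959964)} under normal theory on the log scale.
#'
#' @param hr,lcl,ucl Hazard ratio and its 95\% bounds (all > 0,
#'   \code{lcl < hr < ucl}).
#' @return List with \code{lnhr} and \code{se}.
#' @export
ciToSE <- function(hr, lcl, ucl) {
  if (any(c(hr, lcl, ucl) <= 0) || !(lcl < hr && hr < ucl))
    stop("need 0 < lcl < hr < ucl")
  list(lnhr = log(hr), se = (log(ucl) - log(lcl)) / (2 * Z975))
}

#' Inverse-variance fixed-effects meta-analysis of hazard ratios
#'
#' Pools per-stratum log hazard ratios with weights \code{1/se^2}
#' (fixed effects: the strata come from one source population) and
#' tests heterogeneity with Cochran's Q on \code{k - 1} degrees of
#' freedom; \code{I2 = max(0, (Q - df)/Q)}.
#'
#' @param estimates data.frame with columns \code{label}, \code{hr},
#'   \code{lcl}, \code{ucl} (or precomputed \code{lnhr}, \code{se}).
#' @return List of class \code{"metaFixed"}: \code{hr}, \code{lcl},
#'   \code{ucl}, \code{lnhr}, \code{se}, \code{Q}, \code{df},
#'   \code{pHet}, \code{I2}, \code{k}.
#' @export
poolFixed <- function(estimates) {
  est <- as.data.frame(estimates)
  if (nrow(est) == 0L) stop("no estimates to pool")
  if (!all(c("lnhr", "se") %in% colnames(est))) {
    bt <- mapply(ciToSE, est$hr, est$lcl, est$ucl, SIMPLIFY = FALSE)
    est$lnhr <- vapply(bt, `[[`, 0, "lnhr")
    est$se <- vapply(bt, `[[`, 0, "se")
  }
  w <- 1 / est$se^2
  lnhr <- sum(w * est$lnhr) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (est$lnhr - lnhr)^2)
  df <- nrow(est) - 1
  structure(list(hr = exp(lnhr),
                 lcl = exp(lnhr - Z975 * se),
                 ucl = exp(lnhr + Z975 * se),
                 lnhr = lnhr, se = se,
                 Q = Q, df = df,
                 pHet = if (df > 0)
                   stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
                 I2 = if (Q > 0) max(0, (Q - df) / Q) else 0,
                 k = nrow(est)),
            class = "metaFixed")
}

#' @export
print.metaFixed <- function(x, ...) {
  cat(sprintf("Fixed-effects pool of %d strata: HR %.2f (%.2f-%.2f)\n",
              x$k, x$hr, x$lcl, x$ucl))
  if (x$df > 0)
    cat(sprintf("  heterogeneity: Q = %.2f on %d df, p = %.2f, I2 = %.0f%%\n",
                x$Q, x$df, x$pHet, 100 * x$I2))
  invisible(x)
}
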