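# Kaplan-Meier curves and two-group log-rank tests, as used to compare
# progression-free and overall survival between PD-L1 x EMT strata. The
# estimators are delegated to the survival package (survfit/survdiff);
# this module fixes the conventions (events before censorings at ties,
# two-group Mantel-Haenszel chi-square with 1 df) and the result shape.

#' Kaplan-Meier product-limit estimate
#'
#' At tied times, events are processed before censorings (the standard
#' product-limit convention).
#'
#' @param times non-negative event/censoring times.
#' @param events 0/1 event indicators (1 = event).
#' @return data.frame of class \code{km_curve}: time, n_risk, n_event,
#'   n_censor, survival (right-continuous step function values).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times and events lengths differ")
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' chi-square = U^2 / V with U the summed observed-minus-expected events in
#' one group over the pooled event times and V the summed hypergeometric
#' variance; p from the chi-square distribution with 1 df.
#'
#' @param times non-negative times.
#' @param events 0/1 event indicators.
#' @param group two-level group label per sample.
#' @return list of class \code{logrank_result}: chi_square, df, p_value,
#'   observed, expected (named per group), n (per group).
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2L) stop("log-rank test needs exactly 2 groups")
  if (sum(events) == 0) stop("log-rank statistic undefined with no events")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(chi_square = unname(sd$chisq), df = 1L,
                 p_value = max(p, .Machine$double.xmin),
                 observed = stats::setNames(as.numeric(sd$obs), levels(group)),
                 expected = stats::setNames(as.numeric(sd$exp), levels(group)),
                 n = stats::setNames(as.numeric(sd$n), levels(group))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square %.4f (df %d), p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Survival analysis across PD-L1 x EMT strata
#'
#' One Kaplan-Meier curve per combined stratum plus the headline contrasts:
#' EMT-high vs EMT-low within PD-L1-high, and separately within PD-L1-low.
#' Marginal PD-L1 and EMT splits are also contrasted. Degenerate contrasts
#' (an empty group, or no events) are skipped with a warning.
#'
#' @param cohort data.frame with sample_id and the endpoint columns
#'   (\code{pfs_time}/\code{pfs_event} or \code{os_time}/\code{os_event}).
#' @param strata data.frame from \code{\link{assign_strata}}.
#' @param endpoint \code{"pfs"} or \code{"os"}.
#' @return list: curves (per combined stratum), contrasts (named
#'   \code{logrank_result} or NULL where skipped).
#' @export
km_by_strata <- function(cohort, strata, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(cohort)))
    stop("cohort lacks ", tcol, "/", ecol)
  df <- merge(cohort[, c("sample_id", tcol, ecol)], strata, by = "sample_id")
  df <- df[is.finite(df[[tcol]]) & !is.na(df[[ecol]]), , drop = FALSE]

  curves <- lapply(split(df, df$combined), function(d)
    km_estimate(d[[tcol]], d[[ecol]]))

  contrast <- function(d, g) {
    g <- droplevels(as.factor(g))
    if (nlevels(g) != 2L || sum(d[[ecol]]) == 0) {
      warning("contrast skipped: empty group or no events")
      return(NULL)
    }
    logrank_test(d[[tcol]], d[[ecol]], g)
  }
  hi <- df[df$pdl1_group %in% "high", , drop = FALSE]
  lo <- df[df$pdl1_group %in% "low", , drop = FALSE]
  contrasts <- list(
    pdl1_high_vs_low = contrast(df, df$pdl1_group),
    emt_high_vs_low = contrast(df, df$emt_group),
    emt_within_pdl1_high = contrast(hi, hi$emt_group),
    emt_within_pdl1_low = contrast(lo, lo$emt_group)
  )
  list(endpoint = endpoint, curves = curves, contrasts = contrasts)
}
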