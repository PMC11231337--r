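# Cohort stratification, response-group statistics and ROC cutpoints.

#' Median split into high/low groups
#'
#' high iff value > median; values equal to the median go to the low group;
#' missing values stay unassigned (NA).
#'
#' @param values numeric vector with >= 2 non-missing values.
#' @return factor with levels \code{low}, \code{high}.
#' @export
median_split <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2L) stop("median split needs >= 2 non-missing values")
  med <- stats::median(values[ok])
  out <- ifelse(values > med, "high", "low")
  out[!ok] <- NA
  factor(out, levels = c("low", "high"))
}

#' Tumor proportion score split
#'
#' PD-L1-high is defined as TPS >= cutoff (default 1, boundary inclusive).
#'
#' @param tps numeric vector of tumor proportion scores in [0, 100].
#' @param cutoff threshold percentage, default 1.
#' @return factor with levels \code{low}, \code{high}.
#' @export
tps_split <- function(tps, cutoff = 1) {
  if (any(tps < 0 | tps > 100, na.rm = TRUE))
    stop("TPS values must lie in [0, 100]")
  out <- ifelse(tps >= cutoff, "high", "low")
  factor(out, levels = c("low", "high"))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-corrected rho via average ranks on pairwise-complete observations;
#' two-sided p from the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman correlation needs >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = min(max(p, .Machine$double.xmin), 1), n = n)
}

#' Compare two groups of values
#'
#' Unpaired two-tailed tests: Welch t-test or Mann-Whitney (Wilcoxon
#' rank-sum).
#'
#' @param a,b numeric vectors.
#' @param method \code{"t_test"} (Welch) or \code{"mann_whitney"}.
#' @return list: \code{statistic}, \code{p_value}, \code{method},
#'   \code{n_a}, \code{n_b}, \code{mean_a}, \code{mean_b}.
#' @export
compare_groups <- function(a, b, method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (method == "t_test") {
    if (length(a) < 2L || length(b) < 2L)
      stop("t-test needs >= 2 values per group")
    ht <- stats::t.test(a, b, var.equal = FALSE)
  } else {
    if (length(a) < 1L || length(b) < 1L)
      stop("mann-whitney needs >= 1 value per group")
    ht <- suppressWarnings(stats::wilcox.test(a, b))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, method = method,
       n_a = length(a), n_b = length(b), mean_a = mean(a), mean_b = mean(b))
}

#' ROC operating points over all candidate thresholds
#'
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' marker values plus one sentinel below the minimum and one above the
#' maximum. A sample is called positive iff marker >= threshold;
#' sensitivity = TP/(TP+FN) and specificity = TN/(TN+FP) against the binary
#' outcome.
#'
#' @param marker numeric vector.
#' @param outcome 0/1 vector (1 = event/positive class).
#' @return data.frame: threshold, sensitivity, specificity.
#' @export
roc_points <- function(marker, outcome) {
  ok <- is.finite(marker) & !is.na(outcome)
  marker <- marker[ok]; outcome <- outcome[ok]
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (length(unique(outcome)) < 2L)
    stop("both outcome classes must be present")
  u <- sort(unique(marker))
  if (length(u) < 2L) stop("marker is constant; no cutpoint exists")
  thresholds <- c(u[1L] - 1,
                  if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
                  u[length(u)] + 1)
  n_pos <- sum(outcome == 1); n_neg <- sum(outcome == 0)
  sens <- vapply(thresholds, function(t) sum(marker >= t & outcome == 1), numeric(1)) / n_pos
  spec <- vapply(thresholds, function(t) sum(marker < t & outcome == 0), numeric(1)) / n_neg
  data.frame(threshold = thresholds, sensitivity = sens, specificity = spec)
}

#' ROC cutpoint by minimal Euclidean distance to the ideal corner
#'
#' Selects the candidate threshold minimizing
#' sqrt((1 - sensitivity)^2 + (1 - specificity)^2). Ties are broken by the
#' larger Youden index (sensitivity + specificity - 1), then by the smaller
#' threshold. For markers whose low values predict the event, set
#' \code{low_predicts = TRUE}: the marker is negated internally and the
#' returned threshold is mapped back to the original scale, where the
#' positive call becomes marker <= threshold.
#'
#' @param marker numeric vector.
#' @param outcome 0/1 vector.
#' @param low_predicts logical; negate the marker before the ROC.
#' @return list of class \code{roc_cutpoint}: threshold, sensitivity,
#'   specificity, distance, youden, direction.
#' @export
euclidean_cutpoint <- function(marker, outcome, low_predicts = FALSE) {
  m <- if (low_predicts) -marker else marker
  pts <- roc_points(m, outcome)
  dist <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  youden <- pts$sensitivity + pts$specificity - 1
  ord <- order(dist, -youden, pts$threshold)
  best <- ord[1L]
  structure(list(
    threshold = if (low_predicts) -pts$threshold[best] else pts$threshold[best],
    sensitivity = pts$sensitivity[best],
    specificity = pts$specificity[best],
    distance = dist[best],
    youden = youden[best],
    direction = if (low_predicts) "<=" else ">="
  ), class = "roc_cutpoint")
}

#' @export
print.roc_cutpoint <- function(x, ...) {
  cat(sprintf("ROC cutpoint: marker %s %.4g (sens %.3f, spec %.3f, distance %.4f)\n",
              x$direction, x$threshold, x$sensitivity, x$specificity, x$distance))
  invisible(x)
}

#' Ellipsoid tumor volume from caliper diameters
#'
#' volume (mm^3) = longest diameter x shortest diameter^2 / 2.
#'
#' @param longest_mm,shortest_mm diameters in mm, non-negative.
#' @return volume in mm^3.
#' @export
tumor_volume <- function(longest_mm, shortest_mm) {
  if (any(longest_mm < 0) || any(shortest_mm < 0))
    stop("diameters must be non-negative")
  if (any(shortest_mm > longest_mm))
    warning("shortest diameter exceeds longest; check argument order")
  longest_mm * shortest_mm^2 / 2
}

#' Assign PD-L1 x EMT strata
#'
#' Median splits (or a TPS cutoff for IHC PD-L1) of the PD-L1 measure and
#' the EMT score, combined into four strata.
#'
#' @param sample_id character vector.
#' @param pdl1 numeric PD-L1 measure (expression or TPS).
#' @param emt numeric EMT score (or H-score proxy).
#' @param pdl1_split \code{"median"} or \code{"tps"}.
#' @param tps_cutoff cutoff when \code{pdl1_split = "tps"}.
#' @return data.frame: sample_id, pdl1_group, emt_group, combined.
#' @export
assign_strata <- function(sample_id, pdl1, emt,
                          pdl1_split = c("median", "tps"), tps_cutoff = 1) {
  pdl1_split <- match.arg(pdl1_split)
  pg <- if (pdl1_split == "median") median_split(pdl1) else
    tps_split(pdl1, cutoff = tps_cutoff)
  eg <- median_split(emt)
  combined <- ifelse(is.na(pg) | is.na(eg), NA,
                     paste0("pdl1_", as.character(pg), ".emt_", as.character(eg)))
  data.frame(sample_id = sample_id, pdl1_group = pg, emt_group = eg,
             combined = combined, stringsAsFactors = FALSE)
}
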