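# Signed two-sample Kolmogorov-Smirnov EMT score.
#
# For one sample, the expression values of the matched epithelial genes and
# the matched mesenchymal genes form two empirical distributions. With F_E
# and F_M their ECDFs on the pooled support, the score is
#   +max(F_E - F_M)  if that maximum exceeds max(F_M - F_E),
#   -max(F_M - F_E)  otherwise,
# so a positive score means the mesenchymal values sit above the epithelial
# ones (mesenchymal-shifted phenotype) and a negative score the reverse.

#' Evaluate an empirical cumulative distribution function
#'
#' Right-continuous convention: F(x) = (number of values <= x) / n.
#'
#' @param values non-empty numeric vector.
#' @param grid numeric vector of evaluation points.
#' @return numeric vector of F(grid), non-decreasing, in [0, 1].
#' @export
ecdf_eval <- function(values, grid) {
  if (length(values) == 0L) stop("values must be non-empty")
  if (!all(is.finite(values))) stop("values must be finite")
  vapply(grid, function(x) sum(values <= x), numeric(1)) / length(values)
}

#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' Computes the two one-sided KS statistics between the epithelial and
#' mesenchymal value distributions on the pooled support and returns the
#' larger one with a sign: positive when the mesenchymal distribution is
#' shifted upward relative to the epithelial one. When the two one-sided
#' statistics tie, the sign is taken from a comparison of mean pooled ranks
#' (mesenchymal higher -> positive; exactly tied -> 0).
#'
#' @param epi_values numeric vector, epithelial-arm expression values.
#' @param mes_values numeric vector, mesenchymal-arm expression values.
#' @return list with \code{score}, \code{d_plus} (max of F_E - F_M) and
#'   \code{d_minus} (max of F_M - F_E).
#' @export
signed_ks <- function(epi_values, mes_values) {
  if (length(epi_values) == 0L || length(mes_values) == 0L)
    stop("both value sets must be non-empty")
  if (!all(is.finite(epi_values)) || !all(is.finite(mes_values)))
    stop("values must be finite")
  grid <- sort(unique(c(epi_values, mes_values)))
  f_e <- ecdf_eval(epi_values, grid)
  f_m <- ecdf_eval(mes_values, grid)
  d_plus <- max(f_e - f_m)
  d_minus <- max(f_m - f_e)
  # one-sided sup differences can be negative when one ECDF dominates;
  # the score only ever takes the dominant non-negative branch
  if (d_plus > d_minus) {
    score <- d_plus
  } else if (d_minus > d_plus) {
    score <- -d_minus
  } else {
    pooled <- c(epi_values, mes_values)
    r <- rank(pooled)
    mean_epi <- mean(r[seq_along(epi_values)])
    mean_mes <- mean(r[-seq_along(epi_values)])
    score <- if (mean_mes > mean_epi) d_plus
             else if (mean_epi > mean_mes) -d_minus
             else 0
  }
  list(score = score, d_plus = max(d_plus, 0), d_minus = max(d_minus, 0))
}

#' EMT score for a single sample
#'
#' Extracts the sample's expression values for the matched epithelial and
#' mesenchymal signature genes, drops non-finite values, and applies the
#' signed KS statistic. The result is flagged invalid when either arm has
#' fewer than \code{min_genes} usable genes.
#'
#' @param mat expression matrix (genes x samples, log2 scale).
#' @param sample_id sample column to score.
#' @param sig \code{emt_signature}.
#' @param min_genes minimum matched genes per arm (default 10).
#' @return one-row data.frame: sample_id, score, d_plus, d_minus,
#'   n_epi_used, n_mes_used, valid.
#' @export
emt_score_sample <- function(mat, sample_id, sig, min_genes = 10L) {
  if (!sample_id %in% colnames(mat)) stop("unknown sample: ", sample_id)
  epi <- mat[rownames(mat) %in% sig$epithelial, sample_id]
  mes <- mat[rownames(mat) %in% sig$mesenchymal, sample_id]
  epi <- epi[is.finite(epi)]
  mes <- mes[is.finite(mes)]
  valid <- length(epi) >= min_genes && length(mes) >= min_genes
  if (!valid) {
    return(data.frame(sample_id = sample_id, score = NA_real_,
                      d_plus = NA_real_, d_minus = NA_real_,
                      n_epi_used = length(epi), n_mes_used = length(mes),
                      valid = FALSE, stringsAsFactors = FALSE))
  }
  ks <- signed_ks(epi, mes)
  data.frame(sample_id = sample_id, score = ks$score, d_plus = ks$d_plus,
             d_minus = ks$d_minus, n_epi_used = length(epi),
             n_mes_used = length(mes), valid = TRUE, stringsAsFactors = FALSE)
}

#' EMT scores for every sample of a cohort
#'
#' @inheritParams emt_score_sample
#' @return data.frame with one row per sample, in the matrix column order.
#' @export
emt_score_cohort <- function(mat, sig, min_genes = 10L) {
  validate_expression_matrix(mat)
  res <- lapply(colnames(mat), emt_score_sample, mat = mat, sig = sig,
                min_genes = min_genes)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
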