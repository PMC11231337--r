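# Signature scores: mean over signature genes of the per-gene z-score of
# log2 fold-change across the cohort. Because z-scoring removes each gene's
# location and scale, the fold-change reference (cohort mean vs median)
# cancels and the score is invariant to per-gene affine transforms.

#' Per-gene log2 fold-change against a cohort reference
#'
#' On log2-scale data a difference of values is a log2 fold-change, so this
#' subtracts each gene's cohort reference statistic from its row.
#'
#' @param mat expression matrix, log2 scale.
#' @param reference \code{"cohort_mean"} or \code{"cohort_median"}.
#' @return matrix of the same shape.
#' @export
log2fc <- function(mat, reference = c("cohort_mean", "cohort_median")) {
  reference <- match.arg(reference)
  if (ncol(mat) < 2L) stop("fold-change reference undefined for a single sample")
  ref <- switch(reference,
                cohort_mean = rowMeans(mat),
                cohort_median = apply(mat, 1L, stats::median))
  sweep(mat, 1L, ref, "-")
}

#' Per-gene z-scores across samples
#'
#' (x - mean) / sd per gene row, with sample sd (n - 1 denominator).
#' Zero-variance genes cannot be z-scored; their rows are set to NA and
#' flagged in the \code{"zero_variance"} attribute so downstream signature
#' means exclude them.
#'
#' @param mat expression matrix with >= 2 samples.
#' @return z-scored matrix with attribute \code{zero_variance} (logical per gene).
#' @export
zscore_by_gene <- function(mat) {
  if (ncol(mat) < 2L) stop("z-scores need >= 2 samples")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, stats::sd)
  zero <- sdv == 0
  if (any(zero))
    warning(sprintf("%d zero-variance gene(s) excluded from z-scoring", sum(zero)))
  z <- sweep(mat, 1L, mu, "-")
  z <- sweep(z, 1L, ifelse(zero, NA_real_, sdv), "/")
  attr(z, "zero_variance") <- zero
  z
}

#' Score one gene signature across a cohort
#'
#' score(sample) = mean over matched, non-degenerate signature genes of the
#' z-scored log2 fold-change. By construction each score column has cohort
#' mean zero when all samples are scored.
#'
#' @param mat expression matrix, log2 scale.
#' @param genes character vector of signature gene symbols.
#' @param reference fold-change reference; immaterial to the result (see
#'   \code{\link{log2fc}}), kept for transparency.
#' @param min_genes minimum matched non-degenerate genes (default 3).
#' @return data.frame: sample_id, score, n_genes_used, valid.
#' @export
signature_score <- function(mat, genes, reference = "cohort_mean", min_genes = 3L) {
  validate_expression_matrix(mat)
  hit <- resolve_genes(genes, mat)$present
  if (length(hit) == 0L) {
    return(data.frame(sample_id = colnames(mat), score = NA_real_,
                      n_genes_used = 0L, valid = FALSE, stringsAsFactors = FALSE))
  }
  fc <- log2fc(mat[hit, , drop = FALSE], reference = reference)
  z <- suppressWarnings(zscore_by_gene(fc))
  usable <- !attr(z, "zero_variance")
  n_used <- sum(usable)
  valid <- n_used >= min_genes
  score <- if (n_used > 0L) colMeans(z[usable, , drop = FALSE]) else
    rep(NA_real_, ncol(mat))
  data.frame(sample_id = colnames(mat), score = if (valid) score else NA_real_,
             n_genes_used = n_used, valid = valid, stringsAsFactors = FALSE)
}

#' Score several signatures into one wide table
#'
#' @param mat expression matrix.
#' @param sets named list of gene vectors (e.g. from \code{\link{load_gmt}}).
#' @param reference fold-change reference.
#' @param min_genes minimum matched genes per signature.
#' @return data.frame with sample_id and one score column per signature.
#' @export
score_signatures <- function(mat, sets, reference = "cohort_mean", min_genes = 3L) {
  out <- data.frame(sample_id = colnames(mat), stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    s <- signature_score(mat, sets[[nm]], reference = reference,
                         min_genes = min_genes)
    out[[nm]] <- s$score
  }
  out
}
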