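# End-to-end cohort analyses: score -> stratify -> compare -> correlate ->
# survival, emitting a deterministic, JSON-serialisable report.

comparison_or_null <- function(a, b, method = "t_test") {
  min_n <- if (method == "t_test") 2L else 1L
  if (sum(is.finite(a)) < min_n || sum(is.finite(b)) < min_n) return(NULL)
  compare_groups(a, b, method = method)
}

correlation_or_null <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NULL)
  spearman_cor(x, y)
}

provenance_block <- function(...) {
  inputs <- list(...)
  hash <- vapply(inputs, function(x) {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(x, tf, compress = FALSE)
    unname(tools::md5sum(tf))
  }, character(1))
  list(input_md5 = as.list(hash),
       package_version = as.character(utils::packageVersion("emtici")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Full RNA-seq cohort analysis
#'
#' Runs the complete analysis on an expression matrix plus clinical table:
#' per-sample EMT scores; median splits of PD-L1 expression and EMT score;
#' PR-vs-PD comparison of the EMT score and of each immune signature score
#' within each PD-L1 stratum; Spearman correlation of PD-L1 expression with
#' EMT score within PR and within PD; correlations of the immune signature
#' scores with the EMT score by stratum x response; and Kaplan-Meier +
#' log-rank survival for the PD-L1 split, the EMT split, and the EMT split
#' within each PD-L1 stratum.
#'
#' @param expr expression matrix (genes x samples, log2 scale).
#' @param meta cohort data.frame (see \code{\link{read_cohort}}) with a
#'   \code{pdl1_expr} column.
#' @param signature \code{emt_signature}; default the bundled tumor-tissue
#'   signature.
#' @param immune_sets named list of immune gene sets; default the bundled
#'   CTL/TREG/M1/M2 sets.
#' @param min_genes minimum matched genes per EMT arm.
#' @param endpoints survival endpoints to analyze.
#' @return report list: scores, strata, comparisons, correlations,
#'   survival, provenance.
#' @export
run_rnaseq_cohort <- function(expr, meta, signature = NULL, immune_sets = NULL,
                              min_genes = 10L, endpoints = "pfs") {
  validate_expression_matrix(expr)
  meta <- validate_cohort(meta)
  if (!"pdl1_expr" %in% names(meta)) stop("meta lacks a 'pdl1_expr' column")
  if (is.null(signature))
    signature <- load_emt_signature(bundled_signature_path("emt"), "TUMOR")
  if (is.null(immune_sets))
    immune_sets <- load_gmt(bundled_signature_path("immune"))

  scores <- emt_score_cohort(expr, signature, min_genes = min_genes)
  sig_scores <- score_signatures(expr, immune_sets)
  tab <- merge(merge(scores, sig_scores, by = "sample_id"), meta,
               by = "sample_id")
  tab <- tab[order(tab$sample_id), , drop = FALSE]
  scored <- tab[tab$valid, , drop = FALSE]

  strata <- assign_strata(scored$sample_id, scored$pdl1_expr, scored$score)
  scored <- merge(scored, strata, by = "sample_id")
  scored <- scored[order(scored$sample_id), , drop = FALSE]

  has_resp <- "response" %in% names(scored) && any(!is.na(scored$response))
  if (!has_resp) warning("no response labels; comparison sections skipped")

  measures <- c(emt_score = "score",
                stats::setNames(names(immune_sets), names(immune_sets)))
  comparisons <- list()
  correlations <- list()
  if (has_resp) {
    for (pg in c("low", "high")) {
      sub <- scored[scored$pdl1_group %in% pg, , drop = FALSE]
      pr <- sub[sub$response %in% "PR", , drop = FALSE]
      pd <- sub[sub$response %in% "PD", , drop = FALSE]
      comparisons[[paste0("pdl1_", pg)]] <- lapply(measures, function(col)
        comparison_or_null(pr[[col]], pd[[col]]))
    }
    for (rg in c("PR", "PD")) {
      sub <- scored[scored$response %in% rg, , drop = FALSE]
      correlations[[paste0("pdl1_vs_emt.", rg)]] <-
        correlation_or_null(sub$pdl1_expr, sub$score)
    }
    for (pg in c("low", "high")) for (rg in c("PR", "PD")) {
      sub <- scored[scored$pdl1_group %in% pg & scored$response %in% rg, ,
                    drop = FALSE]
      correlations[[paste0("immune_vs_emt.pdl1_", pg, ".", rg)]] <-
        lapply(stats::setNames(nm = names(immune_sets)), function(nm)
          correlation_or_null(sub[[nm]], sub$score))
    }
  }

  surv <- list()
  for (ep in endpoints) {
    tcol <- paste0(ep, "_time")
    if (tcol %in% names(meta))
      surv[[ep]] <- km_by_strata(meta, strata, endpoint = ep)
  }

  list(signature = signature$name,
       n_samples = nrow(tab), n_scored = nrow(scored),
       scores = scored[, c("sample_id", "score", "d_plus", "d_minus",
                           "n_epi_used", "n_mes_used", names(immune_sets),
                           "pdl1_group", "emt_group", "combined")],
       comparisons = comparisons, correlations = correlations,
       survival = surv,
       provenance = provenance_block(expr = expr, meta = meta,
                                     signature = signature))
}

#' Full IHC cohort analysis
#'
#' TPS >= 1 PD-L1 split; per-marker ROC Euclidean-distance H-score
#' cutpoints against progression (PD vs non-PD); marker-high/low groups;
#' Spearman correlations of the PD-L1 H-score with each EMT-marker H-score
#' by response group; and OS/PFS Kaplan-Meier + log-rank by combined
#' PD-L1 x marker status. E-cadherin is treated as inversely related to the
#' mesenchymal phenotype: its ROC is built on the negated marker and its
#' "high" group is the low-expression side.
#'
#' @param meta IHC cohort data.frame with \code{pdl1_tps},
#'   \code{hscore_*} columns, response and survival endpoints.
#' @param markers H-score marker names (without the \code{hscore_} prefix).
#' @param tps_cutoff PD-L1-high TPS threshold, default 1.
#' @param endpoints survival endpoints.
#' @return report list: cutpoints, groups, correlations, survival,
#'   provenance.
#' @export
run_ihc_cohort <- function(meta,
                           markers = c("slug", "twist1", "vimentin", "ecadherin"),
                           tps_cutoff = 1, endpoints = c("os", "pfs")) {
  meta <- validate_cohort(meta)
  if (!"pdl1_tps" %in% names(meta)) stop("meta lacks a 'pdl1_tps' column")
  pdl1_group <- tps_split(meta$pdl1_tps, cutoff = tps_cutoff)
  outcome_pd <- as.integer(meta$response %in% "PD")

  cutpoints <- list()
  marker_groups <- data.frame(sample_id = meta$sample_id,
                              pdl1_group = pdl1_group,
                              stringsAsFactors = FALSE)
  for (mk in markers) {
    col <- paste0("hscore_", mk)
    if (!col %in% names(meta)) {
      warning("marker column absent, skipped: ", col)
      next
    }
    low_pred <- mk == "ecadherin"
    cp <- tryCatch(euclidean_cutpoint(meta[[col]], outcome_pd,
                                      low_predicts = low_pred),
                   error = function(e) {
                     warning("cutpoint failed for ", mk, ": ",
                             conditionMessage(e))
                     NULL
                   })
    cutpoints[[mk]] <- cp
    if (!is.null(cp)) {
      call_high <- if (low_pred) meta[[col]] <= cp$threshold
                   else meta[[col]] >= cp$threshold
      marker_groups[[mk]] <- factor(ifelse(call_high, "high", "low"),
                                    levels = c("low", "high"))
    }
  }

  resp_groups <- list(all = rep(TRUE, nrow(meta)),
                      CR_PR = meta$response %in% c("CR", "PR"),
                      SD = meta$response %in% "SD",
                      PD = meta$response %in% "PD")
  correlations <- list()
  if ("hscore_pdl1" %in% names(meta)) {
    for (rg in names(resp_groups)) {
      sub <- meta[resp_groups[[rg]], , drop = FALSE]
      correlations[[rg]] <- lapply(stats::setNames(nm = markers), function(mk) {
        col <- paste0("hscore_", mk)
        if (!col %in% names(sub)) return(NULL)
        correlation_or_null(sub$hscore_pdl1, sub[[col]])
      })
    }
  }

  surv <- list()
  for (ep in endpoints) {
    if (!paste0(ep, "_time") %in% names(meta)) next
    surv[[ep]] <- list()
    for (mk in intersect(markers, names(marker_groups))) {
      strata <- data.frame(sample_id = meta$sample_id,
                           pdl1_group = pdl1_group,
                           emt_group = marker_groups[[mk]],
                           combined = paste0("pdl1_", pdl1_group, ".",
                                             mk, "_", marker_groups[[mk]]),
                           stringsAsFactors = FALSE)
      surv[[ep]][[mk]] <- withCallingHandlers(
        km_by_strata(meta, strata, endpoint = ep),
        warning = function(w) invokeRestart("muffleWarning"))
    }
  }

  list(n_samples = nrow(meta), cutpoints = cutpoints,
       groups = marker_groups, correlations = correlations,
       survival = surv, provenance = provenance_block(meta = meta))
}

#' Serialize an analysis report to JSON
#'
#' @param report list from \code{\link{run_rnaseq_cohort}} or
#'   \code{\link{run_ihc_cohort}}.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}
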