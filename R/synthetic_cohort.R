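# Seeded synthetic immunotherapy cohorts.
#
# A single latent EMT axis e ~ N(0,1) per patient drives everything:
# epithelial signature genes load negatively and mesenchymal genes
# positively on e; PD-L1 expression is correlated with e; and the clinical
# couplings (progression odds, progression-free-survival hazard, immune
# signature loadings) act only within the PD-L1-high stratum. That
# stratum-restricted structure is the generative ground truth against which
# the scoring and survival pipeline is validated.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the analyzed RNA-seq cohort: 234 patients, an EMT
#' signature of 145 epithelial + 170 mesenchymal genes, four 20-gene immune
#' signatures, and 2000 background genes.
#'
#' @param n_patients cohort size.
#' @param n_epi_genes,n_mes_genes EMT signature arm sizes.
#' @param n_immune_genes genes per immune signature (CTL/TREG/M1/M2).
#' @param n_background_genes unstructured noise genes.
#' @param emt_loading per-gene loading of the latent EMT axis on signature
#'   genes (log2 units; negative on the epithelial arm, positive on the
#'   mesenchymal arm).
#' @param noise_sd per-gene residual sd (log2 units).
#' @param pdl1_emt_corr correlation of the latent PD-L1 variable with the
#'   latent EMT axis.
#' @param response_effect log-odds of progressive disease per unit latent
#'   EMT, active only in the PD-L1-high stratum.
#' @param hazard_effect log hazard of progression per unit latent EMT,
#'   active only in the PD-L1-high stratum.
#' @param immune_coupling magnitude of the immune-gene loading on latent
#'   EMT within PD-L1-high patients (CTL negative, Treg/M2 positive,
#'   M1 unloaded).
#' @param censor_rate approximate fraction of independently censored
#'   follow-up under the baseline hazard.
#' @param baseline_pfs_scale baseline mean progression-free survival, months.
#' @param os_scale_factor overall-survival scale relative to PFS scale.
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @return validated list of class \code{synthetic_cohort_config}.
#' @export
synthetic_cohort_config <- function(n_patients = 234L,
                                    n_epi_genes = 145L,
                                    n_mes_genes = 170L,
                                    n_immune_genes = 20L,
                                    n_background_genes = 2000L,
                                    emt_loading = 1.0,
                                    noise_sd = 1.0,
                                    pdl1_emt_corr = 0.2,
                                    response_effect = 1.0,
                                    hazard_effect = 0.8,
                                    immune_coupling = 0.8,
                                    censor_rate = 0.2,
                                    baseline_pfs_scale = 6,
                                    os_scale_factor = 2,
                                    seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_epi_genes = as.integer(n_epi_genes),
              n_mes_genes = as.integer(n_mes_genes),
              n_immune_genes = as.integer(n_immune_genes),
              n_background_genes = as.integer(n_background_genes),
              emt_loading = emt_loading, noise_sd = noise_sd,
              pdl1_emt_corr = pdl1_emt_corr,
              response_effect = response_effect,
              hazard_effect = hazard_effect,
              immune_coupling = immune_coupling,
              censor_rate = censor_rate,
              baseline_pfs_scale = baseline_pfs_scale,
              os_scale_factor = os_scale_factor,
              seed = as.integer(seed))
  if (cfg$n_patients < 4L) stop("n_patients must be >= 4")
  if (cfg$n_epi_genes < 1L || cfg$n_mes_genes < 1L)
    stop("signature arm sizes must be positive")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$baseline_pfs_scale <= 0 || cfg$os_scale_factor <= 0)
    stop("survival scales must be > 0")
  if (abs(cfg$pdl1_emt_corr) >= 1) stop("pdl1_emt_corr must be in (-1, 1)")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  structure(cfg, class = "synthetic_cohort_config")
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

sim_gene_names <- function(cfg, signature, immune_sets) {
  if (is.null(signature)) {
    sig_path <- bundled_signature_path("emt")
    signature <- load_emt_signature(sig_path, "TUMOR")
  }
  if (is.null(immune_sets)) {
    immune_sets <- load_gmt(bundled_signature_path("immune"))
  }
  take <- function(genes, n, prefix) {
    if (length(genes) >= n) genes[seq_len(n)]
    else c(genes, sprintf("%s%04d", prefix, seq_len(n - length(genes))))
  }
  list(signature = signature,
       epi = take(signature$epithelial, cfg$n_epi_genes, "SIMEPI"),
       mes = take(signature$mesenchymal, cfg$n_mes_genes, "SIMMES"),
       immune = lapply(stats::setNames(nm = names(immune_sets)), function(nm)
         take(immune_sets[[nm]], cfg$n_immune_genes, paste0("SIM", nm))))
}

sim_survival <- function(n, scale, log_hazard, censor_rate) {
  rate <- exp(log_hazard) / scale
  t_event <- stats::rexp(n, rate = rate)
  if (censor_rate > 0) {
    c_rate <- (censor_rate / (1 - censor_rate)) / scale
    t_cens <- stats::rexp(n, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
}

#' Generate a synthetic RNA-seq immunotherapy cohort
#'
#' Draws a latent EMT axis per patient and builds (1) a log2-scale
#' expression matrix with oppositely-loaded epithelial/mesenchymal signature
#' genes, stratum-coupled immune signature genes, a CD274 row tied to the
#' latent PD-L1 variable, and background noise genes; (2) a clinical table
#' with PD-L1 expression, best response (PR/PD), and censored PFS/OS; and
#' (3) the ground-truth table used by recovery tests.
#'
#' @param config \code{\link{synthetic_cohort_config}}.
#' @param signature optional \code{emt_signature} supplying gene names
#'   (default: bundled tumor-tissue signature).
#' @param immune_sets optional named list of immune gene sets (default:
#'   bundled CTL/TREG/M1/M2).
#' @return list with \code{expr} (matrix), \code{meta} (data.frame),
#'   \code{truth} (data.frame) and \code{config}.
#' @export
generate_cohort <- function(config = synthetic_cohort_config(),
                            signature = NULL, immune_sets = NULL) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  genes <- sim_gene_names(config, signature, immune_sets)
  with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("S%04d", seq_len(n))
    e <- stats::rnorm(n)
    rho <- config$pdl1_emt_corr
    p_lat <- rho * e + sqrt(1 - rho^2) * stats::rnorm(n)
    pdl1_expr <- 5 + p_lat
    pdl1_high <- p_lat > stats::median(p_lat)

    gene_block <- function(gnames, loading_per_sample) {
      mu <- stats::rnorm(length(gnames), mean = 5, sd = 1)
      noise <- matrix(stats::rnorm(length(gnames) * n, sd = config$noise_sd),
                      nrow = length(gnames))
      m <- mu + outer(rep(1, length(gnames)), loading_per_sample) + noise
      rownames(m) <- gnames
      m
    }
    beta <- config$emt_loading
    kap <- config$immune_coupling
    imm_sign <- c(CTL = -1, TREG = 1, M1 = 0, M2 = 1)
    blocks <- list(
      gene_block(genes$epi, -beta * e),
      gene_block(genes$mes, +beta * e)
    )
    for (nm in names(genes$immune)) {
      s <- if (nm %in% names(imm_sign)) imm_sign[[nm]] else 0
      blocks[[length(blocks) + 1L]] <-
        gene_block(genes$immune[[nm]], s * kap * e * pdl1_high)
    }
    if (config$n_background_genes > 0L) {
      bg <- sprintf("BG%05d", seq_len(config$n_background_genes))
      blocks[[length(blocks) + 1L]] <- gene_block(bg, rep(0, n))
    }
    expr <- do.call(rbind, blocks)
    expr <- rbind(expr, CD274 = pdl1_expr)
    colnames(expr) <- ids

    lin_resp <- config$response_effect * e * pdl1_high
    prob_pd <- stats::plogis(lin_resp)
    response <- ifelse(stats::runif(n) < prob_pd, "PD", "PR")
    log_haz <- config$hazard_effect * e * pdl1_high
    pfs <- sim_survival(n, config$baseline_pfs_scale, log_haz, config$censor_rate)
    os <- sim_survival(n, config$baseline_pfs_scale * config$os_scale_factor,
                       log_haz, config$censor_rate)

    meta <- data.frame(sample_id = ids, pdl1_expr = pdl1_expr,
                       response = response,
                       pfs_time = pfs$time, pfs_event = pfs$event,
                       os_time = os$time, os_event = os$event,
                       stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = ids, latent_emt = e,
                        latent_pdl1 = p_lat,
                        pdl1_high = pdl1_high,
                        prob_pd = prob_pd,
                        hazard_multiplier = exp(log_haz),
                        stringsAsFactors = FALSE)
    list(expr = validate_expression_matrix(expr),
         meta = validate_cohort(meta), truth = truth, config = config)
  })
}

#' Generate a synthetic IHC immunotherapy cohort
#'
#' Per patient: integer H-scores in [0, 300] for Slug, Twist1, vimentin and
#' E-cadherin loaded on the latent EMT axis (E-cadherin negatively), a
#' zero-inflated PD-L1 tumor proportion score plus a PD-L1 H-score, best
#' response (CR/PR/SD/PD), and censored PFS/OS with the stratum-restricted
#' couplings defined on the TPS >= 1 stratum.
#'
#' @param config \code{\link{synthetic_cohort_config}}; the default cohort
#'   size is 90.
#' @return list with \code{meta} (data.frame incl. hscore_* columns),
#'   \code{truth}, \code{config}.
#' @export
generate_ihc_cohort <- function(config = synthetic_cohort_config(n_patients = 90L)) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  with_seed(config$seed + 1L, {
    n <- config$n_patients
    ids <- sprintf("I%04d", seq_len(n))
    e <- stats::rnorm(n)
    rho <- config$pdl1_emt_corr
    p_lat <- rho * e + sqrt(1 - rho^2) * stats::rnorm(n)

    hscore <- function(loading) {
      raw <- round(150 + 60 * loading + stats::rnorm(n, sd = 40))
      as.integer(pmin(pmax(raw, 0), 300))
    }
    h_slug <- hscore(e); h_twist <- hscore(e); h_vim <- hscore(e)
    h_ecad <- hscore(-e); h_pdl1 <- hscore(p_lat)

    tps <- ifelse(stats::runif(n) < 0.35, 0,
                  pmin(pmax(round(100 * stats::plogis(1.2 * p_lat)), 1), 100))
    tps_high <- tps >= 1

    lin_resp <- config$response_effect * e * tps_high
    prob_pd <- stats::plogis(lin_resp)
    u <- stats::runif(n)
    response <- ifelse(u < prob_pd, "PD",
                       sample(c("PR", "SD", "CR"), n, replace = TRUE,
                              prob = c(0.65, 0.25, 0.10)))
    log_haz <- config$hazard_effect * e * tps_high
    pfs <- sim_survival(n, config$baseline_pfs_scale, log_haz, config$censor_rate)
    os <- sim_survival(n, config$baseline_pfs_scale * config$os_scale_factor,
                       log_haz, config$censor_rate)

    meta <- data.frame(sample_id = ids, pdl1_tps = tps,
                       hscore_pdl1 = h_pdl1, hscore_slug = h_slug,
                       hscore_twist1 = h_twist, hscore_vimentin = h_vim,
                       hscore_ecadherin = h_ecad,
                       response = response,
                       pfs_time = pfs$time, pfs_event = pfs$event,
                       os_time = os$time, os_event = os$event,
                       stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = ids, latent_emt = e, latent_pdl1 = p_lat,
                        tps_high = tps_high, prob_pd = prob_pd,
                        hazard_multiplier = exp(log_haz),
                        stringsAsFactors = FALSE)
    list(meta = validate_cohort(meta), truth = truth, config = config)
  })
}
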