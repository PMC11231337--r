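# Independent brute-force oracles and small fixture builders.
# These deliberately avoid calling the package's own primitives.

# brute-force signed two-sample KS: evaluate both ECDFs at every pooled
# value by explicit counting, then apply the sign convention
bf_signed_ks <- function(epi, mes) {
  pooled <- c(epi, mes)
  d_plus <- -Inf
  d_minus <- -Inf
  for (x in pooled) {
    fe <- sum(epi <= x) / length(epi)
    fm <- sum(mes <= x) / length(mes)
    d_plus <- max(d_plus, fe - fm)
    d_minus <- max(d_minus, fm - fe)
  }
  d_plus <- max(d_plus, 0)
  d_minus <- max(d_minus, 0)
  if (d_plus > d_minus) {
    score <- d_plus
  } else if (d_minus > d_plus) {
    score <- -d_minus
  } else {
    r <- rank(pooled)
    me <- mean(r[seq_along(epi)])
    mm <- mean(r[length(epi) + seq_along(mes)])
    score <- if (mm > me) d_plus else if (me > mm) -d_minus else 0
  }
  list(score = score, d_plus = d_plus, d_minus = d_minus)
}

# brute-force ROC Euclidean cutpoint: enumerate the candidate thresholds
# directly and scan with explicit tie-breaking
bf_cutpoint <- function(marker, outcome) {
  u <- sort(unique(marker))
  cand <- c(u[1] - 1,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (t in cand) {
    tp <- sum(marker >= t & outcome == 1)
    fn <- sum(marker < t & outcome == 1)
    tn <- sum(marker < t & outcome == 0)
    fp <- sum(marker >= t & outcome == 0)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    y <- sens + spec - 1
    if (is.null(best) || d < best$distance - 1e-15 ||
        (abs(d - best$distance) <= 1e-15 &&
         (y > best$youden + 1e-15 ||
          (abs(y - best$youden) <= 1e-15 && t < best$threshold)))) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   distance = d, youden = y)
    }
  }
  best
}

# small expression matrix with named genes/samples
toy_matrix <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  m
}

# write a temporary GMT file from named gene lists
write_tmp_gmt <- function(sets) {
  path <- tempfile(fileext = ".gmt")
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1)), path)
  path
}

# random expression matrix with a planted EMT signature for scoring tests
random_signature_matrix <- function(n_epi = 15, n_mes = 20, n_bg = 30,
                                    n_samples = 10) {
  genes <- c(sprintf("E%02d", seq_len(n_epi)), sprintf("M%02d", seq_len(n_mes)),
             sprintf("B%02d", seq_len(n_bg)))
  m <- matrix(rnorm(length(genes) * n_samples, mean = 5),
              nrow = length(genes),
              dimnames = list(genes, sprintf("S%02d", seq_len(n_samples))))
  sig <- emt_signature("toy", sprintf("E%02d", seq_len(n_epi)),
                       sprintf("M%02d", seq_len(n_mes)))
  list(mat = m, sig = sig)
}
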