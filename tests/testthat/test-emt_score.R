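test_that("ecdf_eval implements the right-continuous ECDF", {
  expect_equal(ecdf_eval(c(1, 2, 3), c(1, 2, 3)), c(1/3, 2/3, 1))
  expect_equal(ecdf_eval(c(1, 1, 2), 1), 2/3)
  expect_equal(ecdf_eval(c(1, 2, 3), 0.5), 0)
  expect_error(ecdf_eval(numeric(0), 1), "non-empty")
  # non-decreasing on any grid
  v <- rnorm(20)
  f <- ecdf_eval(v, sort(rnorm(50)))
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("signed_ks matches hand-derived cases and the sign convention", {
  # complete separation, mesenchymal above epithelial -> +1
  expect_equal(signed_ks(c(1, 2, 3), c(4, 5, 6))$score, 1)
  # mirror case -> -1
  expect_equal(signed_ks(c(4, 5, 6), c(1, 2, 3))$score, -1)
  # interleaved values: F_E - F_M peaks at 0.25, F_M never exceeds F_E
  r <- signed_ks(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(r$d_plus, 0.25)
  expect_equal(r$d_minus, 0)
  expect_equal(r$score, 0.25)
  # identical distributions -> 0
  expect_equal(signed_ks(c(1, 2, 3), c(1, 2, 3))$score, 0)
  expect_error(signed_ks(numeric(0), 1), "non-empty")
  expect_error(signed_ks(c(1, NA), c(2, 3)), "finite")
})

test_that("signed_ks equals the brute-force oracle on random pairs", {
  set.seed(101)
  for (i in 1:1000) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    # integer draws force heavy ties
    epi <- sample(1:10, n1, replace = TRUE) + ifelse(runif(1) < 0.5, 0, rnorm(n1))
    mes <- sample(1:10, n2, replace = TRUE) + ifelse(runif(1) < 0.5, 0, rnorm(n2))
    got <- signed_ks(epi, mes)
    want <- bf_signed_ks(epi, mes)
    expect_identical(got$score, want$score)
    expect_identical(got$d_plus, want$d_plus)
    expect_identical(got$d_minus, want$d_minus)
  }
})

test_that("signed_ks satisfies bounds, antisymmetry and separation", {
  set.seed(202)
  for (i in 1:300) {
    a <- sample(1:8, sample(1:30, 1), replace = TRUE)
    b <- sample(1:8, sample(1:30, 1), replace = TRUE)
    r <- signed_ks(a, b)
    expect_true(abs(r$score) <= 1)
    expect_true(r$d_plus >= 0 && r$d_minus >= 0)
    separated <- max(a) < min(b) || max(b) < min(a)
    expect_identical(abs(r$score) == 1, separated)
    if (r$d_plus != r$d_minus)
      expect_equal(signed_ks(b, a)$score, -r$score)
  }
})

test_that("shift of the mesenchymal values never decreases the score", {
  set.seed(303)
  for (i in 1:100) {
    epi <- rnorm(sample(5:30, 1))
    mes <- rnorm(sample(5:30, 1))
    base <- signed_ks(epi, mes)$score
    shifted <- signed_ks(epi, mes + runif(1, 0, 3))$score
    expect_gte(shifted, base)
  }
})

test_that("per-sample scoring extracts arms and applies coverage rules", {
  fx <- random_signature_matrix(n_epi = 5, n_mes = 5, n_samples = 3)
  m <- fx$mat
  # sample s1: mesenchymal genes all above epithelial -> +1
  m[fx$sig$epithelial, "S01"] <- 1:5
  m[fx$sig$mesenchymal, "S01"] <- 11:15
  r <- emt_score_sample(m, "S01", fx$sig, min_genes = 5)
  expect_equal(r$score, 1)
  expect_equal(r$n_epi_used, 5)
  expect_true(r$valid)

  # too few matched genes -> invalid, score undefined
  r2 <- emt_score_sample(m, "S01", fx$sig, min_genes = 10)
  expect_false(r2$valid)
  expect_true(is.na(r2$score))

  # constant expression -> identical ECDFs -> 0
  m[, "S02"] <- 5
  expect_equal(emt_score_sample(m, "S02", fx$sig, min_genes = 5)$score, 0)
  expect_error(emt_score_sample(m, "nope", fx$sig), "unknown sample")
})

test_that("cohort scores are rank-invariant and order-independent", {
  set.seed(404)
  fx <- random_signature_matrix(n_samples = 6)
  sc <- emt_score_cohort(fx$mat, fx$sig, min_genes = 5)
  # strictly increasing per-sample transform leaves every score unchanged
  m2 <- fx$mat
  m2[, 3] <- exp(m2[, 3] / 2)
  m2[, 5] <- 10 * m2[, 5] + 1
  sc2 <- emt_score_cohort(m2, fx$sig, min_genes = 5)
  expect_equal(sc2$score, sc$score)
  # permuting samples permutes but does not change results
  perm <- sample(ncol(fx$mat))
  sc3 <- emt_score_cohort(fx$mat[, perm], fx$sig, min_genes = 5)
  expect_equal(sc3[order(sc3$sample_id), ]$score,
               sc[order(sc$sample_id), ]$score)
})

test_that("cohort scoring agrees with the per-sample brute-force oracle", {
  set.seed(505)
  fx <- random_signature_matrix(n_epi = 40, n_mes = 60, n_bg = 100,
                                n_samples = 50)
  sc <- emt_score_cohort(fx$mat, fx$sig)
  for (i in seq_len(nrow(sc))) {
    s <- sc$sample_id[i]
    want <- bf_signed_ks(fx$mat[fx$sig$epithelial, s],
                         fx$mat[fx$sig$mesenchymal, s])
    expect_identical(sc$score[i], want$score)
  }
})
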