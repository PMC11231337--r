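test_that("median_split sends median ties to the low group", {
  expect_identical(as.character(median_split(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(median_split(c(5, 5, 5, 5))), rep("low", 4))
  expect_identical(as.character(median_split(c(1, 2, 3))),
                   c("low", "low", "high"))
  s <- median_split(c(1, NA, 3, 4))
  expect_true(is.na(s[2]))
  expect_error(median_split(c(NA, NA)), ">= 2")
  # groups always partition the non-missing samples, high never larger
  # than low when ties sit at the median
  set.seed(3)
  for (i in 1:50) {
    v <- sample(1:5, 20, replace = TRUE)
    g <- median_split(v)
    expect_equal(sum(is.na(g)), 0)
    if (any(v == median(v))) expect_lte(sum(g == "high"), sum(g == "low"))
  }
})

test_that("TPS split is boundary-inclusive at the cutoff", {
  expect_identical(as.character(tps_split(c(1, 0, 50), cutoff = 1)),
                   c("high", "low", "high"))
  expect_identical(as.character(tps_split(50, cutoff = 50)), "high")
  expect_error(tps_split(120), "\\[0, 100\\]")
})

test_that("spearman_cor matches hand-computed rank correlations", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  r <- spearman_cor(1:4, c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  # cross-check rho and t-approximation p against cor.test
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(15); y <- x + rnorm(15, sd = 2)
    got <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
  # invariance under strictly increasing transforms
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman_cor(exp(x), y^3 + y)$rho,
               spearman_cor(x, y^3 + y)$rho)
  expect_true(is.na(spearman_cor(rep(1, 5), rnorm(5))$rho))
  expect_error(spearman_cor(1:2, 1:2), ">= 3")
})

test_that("group comparisons use Welch t and exact-style Mann-Whitney", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), "mann_whitney")
  expect_equal(same$p_value, 1)
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3), "t_test")$statistic, 0)
  sep <- compare_groups(c(1, 2), c(101, 102), "t_test")
  expect_lt(sep$p_value, 0.05)
  expect_equal(sep$p_value, t.test(c(1, 2), c(101, 102))$p.value)
  expect_error(compare_groups(1, c(1, 2), "t_test"), ">= 2")
})

test_that("roc_points covers sentinels and is monotone in threshold", {
  marker <- c(0.1, 0.2, 0.8, 0.9); outcome <- c(0, 0, 1, 1)
  pts <- roc_points(marker, outcome)
  at <- function(t) pts[which.min(abs(pts$threshold - t)), ]
  expect_equal(at(0.5)$sensitivity, 1)
  expect_equal(at(0.5)$specificity, 1)
  expect_equal(pts$sensitivity[1], 1)  # below min: all positive
  expect_equal(pts$specificity[1], 0)
  expect_equal(pts$sensitivity[nrow(pts)], 0)  # above max
  expect_equal(pts$specificity[nrow(pts)], 1)
  expect_true(all(diff(pts$sensitivity) <= 0))
  expect_true(all(diff(pts$specificity) >= 0))
  expect_error(roc_points(marker, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("euclidean_cutpoint equals exhaustive search on random instances", {
  set.seed(21)
  for (i in 1:500) {
    n <- sample(4:50, 1)
    marker <- sample(0:30, n, replace = TRUE)  # ties on purpose
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) outcome[1:2] <- c(0, 1)
    got <- euclidean_cutpoint(marker, outcome)
    want <- bf_cutpoint(marker, outcome)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$distance, want$distance)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("cutpoint handles separation, inverted markers and null markers", {
  cp <- euclidean_cutpoint(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cp$distance, 0)
  # low marker values predicting the event: negate-and-map-back
  cp2 <- euclidean_cutpoint(c(10, 9, 2, 1), c(0, 0, 1, 1), low_predicts = TRUE)
  expect_equal(cp2$distance, 0)
  expect_identical(cp2$direction, "<=")
  expect_true(all(c(2, 1) <= cp2$threshold) && all(c(10, 9) > cp2$threshold))
  # independent marker: no crash, distance stays below sqrt(2)
  set.seed(5)
  cp3 <- euclidean_cutpoint(rnorm(200), rbinom(200, 1, 0.5))
  expect_lt(cp3$distance, sqrt(2))
  expect_gt(cp3$distance, 0.5)  # nothing near-perfect under independence
})

test_that("cutpoint coordinates agree with pROC closest.topleft", {
  set.seed(31)
  marker <- rnorm(60)
  outcome <- rbinom(60, 1, plogis(marker))
  if (length(unique(outcome)) < 2) outcome[1:2] <- c(0, 1)
  got <- euclidean_cutpoint(marker, outcome)
  ref <- pROC::coords(pROC::roc(outcome, marker, direction = "<",
                                quiet = TRUE),
                      "best", best.method = "closest.topleft",
                      ret = c("threshold", "sensitivity", "specificity"))
  expect_equal(got$sensitivity, ref$sensitivity[1])
  expect_equal(got$specificity, ref$specificity[1])
})

test_that("tumor volume follows the caliper formula", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(6, 6), 108)
  expect_equal(tumor_volume(0, 0), 0)
  expect_warning(tumor_volume(5, 10), "argument order")
  expect_error(tumor_volume(-1, 1), "non-negative")
})

test_that("assign_strata combines PD-L1 and EMT groups into a partition", {
  set.seed(9)
  n <- 40
  st <- assign_strata(sprintf("s%02d", 1:n), rnorm(n), rnorm(n))
  expect_equal(nrow(st), n)
  expect_true(all(st$combined %in%
    c("pdl1_low.emt_low", "pdl1_low.emt_high",
      "pdl1_high.emt_low", "pdl1_high.emt_high")))
  expect_identical(st$combined,
                   paste0("pdl1_", st$pdl1_group, ".emt_", st$emt_group))
  tps_st <- assign_strata(c("a", "b", "c"), c(0, 1, 80), c(1, 2, 3),
                          pdl1_split = "tps")
  expect_identical(as.character(tps_st$pdl1_group), c("low", "high", "high"))
})
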