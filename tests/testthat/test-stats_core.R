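test_that("Mann-Whitney matches hand-enumerated small cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  r <- mann_whitney(c(1, 3), c(2, 4))
  expect_equal(r$U, 1)
  expect_equal(r$p, 2 / 3, tolerance = 1e-12)
  x <- c(2, 5, 9)
  r <- mann_whitney(x, x)  # identical multisets
  expect_equal(r$U, length(x)^2 / 2)
  expect_equal(r$p, 1, tolerance = 1e-6)
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
  expect_error(mann_whitney(c(NA_real_, NA_real_), 1:3), "non-empty")
})

test_that("exact Mann-Whitney branch agrees with full permutation enumeration", {
  set.seed(41)
  for (rep in 1:25) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:min(5, 8 - n1), 1)
    x <- round(rnorm(n1), 6)  # continuous, untied
    y <- round(rnorm(n2) + runif(1, -1, 1), 6)
    got <- mann_whitney(x, y)
    want <- mw_oracle(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("large-sample Mann-Whitney matches the tie/continuity-corrected z-test", {
  set.seed(42)
  for (rep in 1:10) {
    x <- sample(1:8, 20, replace = TRUE)  # heavy ties
    y <- sample(2:9, 25, replace = TRUE)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = TRUE))
    expect_identical(got$method, "normal")
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact NB test reproduces conditional-binomial worked examples", {
  expect_equal(exact_nb_test(5, 0, c(1e6, 1e6), dispersion = 0)$p, 2 * 0.5^5)
  # identical counts in both groups: symmetric, p = 1
  for (phi in c(0, 0.1, 0.5)) {
    r <- exact_nb_test(c(3, 7), c(3, 7), rep(1e6, 4), dispersion = phi)
    expect_equal(r$p, 1)
  }
  # proportions equal under unequal libsizes
  r <- exact_nb_test(c(3, 3), c(6, 6), c(1e5, 1e5, 2e5, 2e5), dispersion = 0)
  expect_gt(r$p, 0.8)
  # zero total is flat, not an error
  r <- exact_nb_test(c(0, 0), c(0, 0), rep(1e6, 4))
  expect_true(r$flat)
  expect_equal(r$p, 1)
  expect_error(exact_nb_test(c(-1, 2), c(1, 1), rep(1, 4)), "non-negative")
  expect_error(exact_nb_test(c(1.5, 2), c(1, 1), rep(1, 4)), "non-negative")
})

test_that("exact NB test agrees with edgeR's exact test on equal libsizes", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  counts <- matrix(rnbinom(400, mu = 80, size = 5), nrow = 20)
  counts[1, 11:20] <- counts[1, 11:20] + 120
  group <- rep(1:2, each = 10)
  libs <- rep(5e5, 20)
  phi <- 0.2
  suppressMessages({
    d <- edgeR::DGEList(counts = counts, group = group, lib.size = libs)
    et <- edgeR::exactTest(d, dispersion = phi)
  })
  ours <- vapply(seq_len(nrow(counts)), function(i)
    exact_nb_test(counts[i, 11:20], counts[i, 1:10], libs, phi)$p, numeric(1))
  # same test family, different two-sided convention: require close agreement
  expect_equal(cor(log10(ours), log10(et$table$PValue)), 1, tolerance = 0.01)
  expect_lt(max(abs(ours - et$table$PValue)), 0.12)
  expect_lt(ours[1], 1e-4)
})

test_that("method-of-moments dispersion recovers simulated truth", {
  set.seed(11)
  n <- 40
  libs <- rep(1e6, n)
  pois <- matrix(rpois(2000 * n, lambda = 60), nrow = 2000)
  est <- estimate_dispersion(pois, libs)
  expect_lte(est$common, 0.05)
  nb <- matrix(rnbinom(2000 * n, mu = 60, size = 1 / 0.4), nrow = 2000)
  est_nb <- estimate_dispersion(nb, libs)
  expect_equal(est_nb$common, 0.4, tolerance = 0.1)
  const <- matrix(5, 3, 4)
  expect_equal(unname(estimate_dispersion(const, rep(1, 4))$per_feature),
               rep(0, 3))
  expect_error(estimate_dispersion(matrix(1, 2, 1), 1), "2 samples")
})

test_that("ROC/AUC handles separation, partial concordance and ties", {
  r <- roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE), ci = FALSE)
  expect_equal(r$auc, 1)
  r <- roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE), ci = FALSE)
  expect_equal(r$auc, 0.75)
  r <- roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3), ci = FALSE)
  expect_equal(r$auc, 0.5)
  expect_true(r$degenerate)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(roc_auc(rep(NA_real_, 4), c(TRUE, TRUE, FALSE, FALSE)),
               "missing")
})

test_that("ROC invariants: curve shape, reversal, U-statistic and trapezoid equivalence", {
  set.seed(12)
  for (rep in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    sc <- rnorm(n1 + n2)  # untied
    lab <- c(rep(TRUE, n1), rep(FALSE, n2))
    r <- roc_auc(sc, lab, ci = FALSE)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(utils::tail(r$points$fpr, 1), 1)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
    # trapezoid area over the curve equals the rank-based AUC
    expect_equal(trapezoid_auc(r$points), r$auc, tolerance = 1e-12)
    # AUC is the normalized Mann-Whitney U
    expect_equal(r$auc, mann_whitney(sc[lab], sc[!lab])$U / (n1 * n2))
    # label/score reversal
    expect_equal(roc_auc(-sc, lab, ci = FALSE)$auc, 1 - r$auc)
  }
})

test_that("AUC matches pROC and the bootstrap interval brackets it", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(60) + rep(c(1, 0), c(25, 35))
  lab <- rep(c(TRUE, FALSE), c(25, 35))
  r <- roc_auc(sc, lab, n_boot = 500, seed = 99)
  ref <- suppressMessages(pROC::auc(pROC::roc(lab, sc, quiet = TRUE)))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  # seeded bootstrap is reproducible and does not touch the global RNG
  before <- .Random.seed
  r2 <- roc_auc(sc, lab, n_boot = 500, seed = 99)
  expect_identical(before, .Random.seed)
  expect_equal(r2$ci_low, r$ci_low)
})

test_that("qPCR fold change follows the delta-Ct log2 convention", {
  r <- qpcr_fold_change(-2.678, -4.0)
  expect_equal(r$log2_fc, 1.322)
  expect_equal(r$fc_linear, 2.5, tolerance = 0.001)
  expect_identical(r$direction, "up")
  r <- qpcr_fold_change(c(1, 1), c(1, 1))
  expect_equal(r$fc_linear, 1)
  expect_identical(r$direction, "flat")
  r <- qpcr_fold_change(1, 2)
  expect_equal(r$log2_fc, -1)
  expect_equal(r$fc_linear, 2)
  expect_identical(r$direction, "down")
  expect_error(qpcr_fold_change(numeric(), 1), "non-empty")
})

test_that("cohort summary percentages are consistent and tests behave", {
  meta <- cohort_demographics("discovery")
  s <- cohort_summary(meta)
  for (v in c("sex", "smoking", "comorbidity")) {
    expect_equal(sum(s$overall_pct[s$variable == v]), 100, tolerance = 0.1)
    expect_equal(sum(s$benign_pct[s$variable == v]), 100, tolerance = 0.1)
  }
  expect_equal(sum(s$nsclc_pct[s$variable == "stage"]), 100, tolerance = 0.1)
  expect_true(all(s$test[s$variable == "sex" & s$level == "male"] %in%
                    c("chi_squared", "fisher_exact")))
  # degenerate one-sample cohort: percentages 100, no p-values
  one <- sample_meta(data.frame(sample_id = "S1", group = "benign", stage = "",
                                age = 70, sex = "male", smoking = "yes",
                                comorbidity = "no"))
  s1 <- cohort_summary(one)
  expect_equal(s1$overall_pct[s1$variable == "sex" & s1$level == "male"], 100)
  expect_true(all(is.na(s1$p_value)))
  expect_error(cohort_summary(one[0, ]), "empty")
})
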