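# Brute-force Mann-Whitney oracle: P(score_D > score_N) + 0.5 P(tie)
# over all diseased-normal pairs.
pairwise_auc <- function(d, n) {
  cmp <- outer(d, n, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("empirical AUC equals the pairwise ranking probability", {
  r <- empirical_roc(c(3, 5, 1, 4), c("AD", "AD", "NC", "NC"))
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(utils::tail(r$points$tpr, 1), 1)

  # perfectly separated and all-tied extremes
  expect_equal(empirical_roc(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE))$auc,
               1.0)
  expect_equal(empirical_roc(rep(4, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)

  # random instances with heavy ties, exact oracle
  set.seed(31)
  for (i in 1:25) {
    n_d <- sample(2:100, 1); n_n <- sample(2:100, 1)
    pool <- sample(20, n_d + n_n, replace = TRUE) +
            sample(c(0, 0.5), n_d + n_n, replace = TRUE)
    d <- pool[seq_len(n_d)]; n <- pool[-seq_len(n_d)]
    r <- empirical_roc(c(d, n), rep(c("diseased", "normal"), c(n_d, n_n)))
    expect_equal(r$auc, pairwise_auc(d, n))
    # ROC invariants
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    trap <- sum(diff(r$points$fpr) *
                (utils::head(r$points$tpr, -1) +
                 utils::tail(r$points$tpr, -1)) / 2)
    expect_equal(r$auc, trap)
  }
  expect_error(empirical_roc(1:3, c("AD", "AD", "AD")), "ROC undefined")
})

test_that("AUC is invariant under monotone transforms and class flips", {
  set.seed(17)
  s <- rnorm(80); lab <- rep(c("AD", "NC"), 40)
  base <- empirical_roc(s, lab)$auc
  expect_equal(empirical_roc(exp(s), lab)$auc, base)
  expect_equal(empirical_roc(atan(3 * s) + 10, lab)$auc, base)
  expect_equal(empirical_roc(rank(s, ties.method = "average"), lab)$auc, base)
  flipped <- ifelse(lab == "AD", "NC", "AD")
  expect_equal(empirical_roc(-s, flipped)$auc, base)
})

test_that("empirical AUC matches the independent pROC computation", {
  set.seed(23)
  s <- c(rnorm(60, 1), rnorm(40))
  lab <- rep(c("AD", "NC"), c(60, 40))
  ours <- empirical_roc(s, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = s, levels = c("NC", "AD"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("binormal Az has the closed-form symmetries", {
  d1 <- gaussian_density(10, 2); d2 <- gaussian_density(10, 3)
  expect_equal(binormal_az(d1, d1), 0.5)
  expect_equal(binormal_az(d1, d2), binormal_az(d2, d1))
  seps <- seq(0, 5, by = 0.5)
  az <- vapply(seps, function(s)
    binormal_az(gaussian_density(10, 2), gaussian_density(10 - s, 3)),
    numeric(1L))
  expect_true(all(diff(az) > 0))
})

test_that("binormal Az agrees with a Monte-Carlo draw-comparison oracle", {
  set.seed(1007)
  cases <- list(mtl = c(14697.2, 2511.1, 17943.8, 2052.8),
                hippocampus = c(5962.1, 1025.3, 7238.4, 870.0))
  for (p in cases) {
    closed <- binormal_az(gaussian_density(p[3], p[4]),
                          gaussian_density(p[1], p[2]))
    xd <- rnorm(1e7, p[1], p[2])
    xn <- rnorm(1e7, p[3], p[4])
    mc <- mean(xd < xn)   # diseased volumes are the smaller
    expect_equal(closed, mc, tolerance = 1e-3)
  }
})

test_that("empirical AUC converges to binormal Az on Gaussian classes", {
  set.seed(77)
  dn <- gaussian_density(17943.8, 2052.8)
  dd <- gaussian_density(14697.2, 2511.1)
  s <- c(-rnorm(20000, dd$mu, dd$sigma), -rnorm(20000, dn$mu, dn$sigma))
  lab <- rep(c("AD", "NC"), each = 20000)
  expect_equal(empirical_roc(s, lab)$auc, binormal_az(dn, dd),
               tolerance = 0.005)
})

test_that("Hanley-McNeil intervals behave at the extremes", {
  mk <- function(auc_scores, labs) empirical_roc(auc_scores, labs)
  # symmetric about 0.5 for chance-level scores
  r <- structure(list(points = NULL, auc = 0.5, n_pos = 100, n_neg = 100),
                 class = "roc_curve")
  ci <- auc_confidence_interval(r)
  expect_equal(unname(0.5 - ci[["lower"]]), unname(ci[["upper"]] - 0.5))
  # clipping at a perfect AUC
  r$auc <- 1.0
  expect_equal(auc_confidence_interval(r)[["upper"]], 1.0)
  r$n_pos <- 1
  expect_error(auc_confidence_interval(r), "fewer than 2")
})

test_that("Hanley-McNeil upper bound matches a bootstrap oracle", {
  # test-sized problem: 46 diseased / 23 normal with AUC near 0.93
  set.seed(46)
  d <- rnorm(46, 2.1); n <- rnorm(23, 0)
  r <- empirical_roc(c(d, n), rep(c("AD", "NC"), c(46, 23)))
  ci <- auc_confidence_interval(r)

  boot <- replicate(10000, {
    db <- sample(d, replace = TRUE); nb <- sample(n, replace = TRUE)
    pairwise_auc(db, nb)
  })
  boot_upper <- unname(stats::quantile(boot, 0.975))
  expect_lt(abs(ci[["upper"]] - min(boot_upper, 1)), 0.02)
})

test_that("the y = 0 report matches hand enumeration on a toy model", {
  m <- lr_observer_from_params(gaussian_density(10, 1),
                               gaussian_density(6, 1),
                               left_hippo_measure())
  co <- scores_cohort(ad_values = c(5, 7, 11), nc_values = c(9, 12))
  rep <- evaluate_at_zero_threshold(m, co)   # boundary at 8, x < 8 diseased
  expect_equal(rep$tp, 2L); expect_equal(rep$fn, 1L)
  expect_equal(rep$tn, 2L); expect_equal(rep$fp, 0L)
  expect_equal(rep$sensitivity, 2 / 3)
  expect_equal(rep$specificity, 1.0)
  expect_equal(rep$balanced_accuracy, (2 / 3 + 1) / 2)
})

test_that("perfect separation yields perfect rates", {
  m <- lr_observer_from_params(gaussian_density(100, 1),
                               gaussian_density(10, 1),
                               left_hippo_measure())
  co <- scores_cohort(ad_values = c(8, 10, 12), nc_values = c(98, 103))
  rep <- evaluate_at_zero_threshold(m, co)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$specificity, 1.0)
})

test_that("classification report arithmetic follows from the counts", {
  rep <- classification_report(tp = 7, fp = 2, tn = 8, fn = 3)
  expect_equal(rep$sensitivity, 0.7)
  expect_equal(rep$specificity, 0.8)
  expect_equal(rep$balanced_accuracy, 0.75)
  expect_error(classification_report(1, 0, 0, 0), "undefined")
  expect_error(classification_report(-1, 1, 1, 1), "non-negative")
})
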