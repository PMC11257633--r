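test_that("allelic ratio sums counts over SNPs before dividing", {
  one <- allelic_ratio(data.frame(sample = "s1", xi_count = 55,
                                  xa_count = 100))
  expect_equal(one$ar, 0.55)

  zero <- allelic_ratio(data.frame(sample = "s1", xi_count = 0,
                                   xa_count = 80))
  expect_equal(zero$ar, 0)

  # sum-then-ratio, not mean of per-SNP ratios
  two <- allelic_ratio(data.frame(sample = "s1", xi_count = c(10, 45),
                                  xa_count = c(20, 80)))
  expect_equal(two$ar, 55 / 100)
  expect_false(isTRUE(all.equal(two$ar, mean(c(10 / 20, 45 / 80)))))

  expect_warning(und <- allelic_ratio(data.frame(sample = "s1",
                                                 xi_count = 5,
                                                 xa_count = 0)),
                 "zero Xa")
  expect_true(is.na(und$ar))
})

test_that("allelic ratio is invariant to splitting counts across SNPs", {
  set.seed(66)
  for (i in 1:50) {
    xi <- sample(0:500, 1); xa <- sample(1:500, 1)
    k <- sample(1:5, 1)
    split_counts <- function(total, k) {
      cuts <- sort(sample(0:total, k - 1, replace = TRUE))
      diff(c(0, cuts, total))
    }
    df <- data.frame(sample = "s", xi_count = split_counts(xi, k),
                     xa_count = split_counts(xa, k))
    expect_equal(allelic_ratio(df)$ar, xi / xa)
  }
})

test_that("AR-vs-dEx test matches the closed-form t statistic", {
  set.seed(77)
  ar <- rnorm(20, 0.55, 0.05)
  res <- ar_vs_deltaEx_test(ar, 0.26)
  oracle <- oracle_one_sample_t(ar, 0.26)
  expect_equal(res$t, oracle$t)
  expect_equal(res$p, oracle$p)
  expect_equal(res$n, 20)
})

test_that("AR equal to dEx in every sample gives t = 0 only with variance", {
  expect_error(ar_vs_deltaEx_test(rep(0.26, 5), 0.26), "zero variance")
  set.seed(78)
  ar <- 0.26 + rnorm(10, 0, 0.05)
  res <- ar_vs_deltaEx_test(ar - (mean(ar) - 0.26), 0.26)
  expect_equal(res$t, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)
})

test_that("AR-vs-dEx test has power against the published gap", {
  rejections <- vapply(1:500, function(s) {
    set.seed(s)
    ar_vs_deltaEx_test(rnorm(20, 0.55, 0.05), 0.26)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.99)
})

test_that("AR-vs-dEx test keeps nominal type-I error under the null", {
  rejections <- vapply(1:2000, function(s) {
    set.seed(10000 + s)
    ar_vs_deltaEx_test(rnorm(20, 0.26, 0.05), 0.26)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

make_kd_expr <- function(x_ctrl, y_ctrl, x_kd, y_kd) {
  expr <- cbind(c(x_ctrl, y_ctrl), c(x_kd, y_kd))
  rownames(expr) <- c("DDX3X", "DDX3Y")
  colnames(expr) <- c("c1", "k1")
  meta <- data.frame(sample = c("c1", "k1"),
                     condition = c("control", "KD_target:DDX3Y"))
  list(expr = expr, meta = meta)
}

test_that("compensation indices reproduce worked examples", {
  # full compensation: Y knocked down 50 -> 10, X rises 100 -> 140
  d <- make_kd_expr(100, 50, 140, 10)
  res <- compensation_indices(d$expr, d$meta, target = "DDX3Y",
                              partner = "DDX3X")
  expect_equal(res$recovery_fraction, 1)
  expect_equal(res$summed_ratio, 1)

  # partial compensation after an X knockdown: X 100 -> 20, Y 50 -> 70
  d2 <- make_kd_expr(100, 50, 20, 70)
  d2$meta$condition[2] <- "KD_target:DDX3X"
  res2 <- compensation_indices(d2$expr, d2$meta, target = "DDX3X",
                               partner = "DDX3Y")
  expect_equal(res2$recovery_fraction, 20 / 80)
  expect_equal(res2$summed_ratio, 90 / 150)

  # target not reduced: recovery undefined
  d3 <- make_kd_expr(100, 50, 100, 60)
  expect_warning(res3 <- compensation_indices(d3$expr, d3$meta,
                                              target = "DDX3Y",
                                              partner = "DDX3X"),
                 "not reduced")
  expect_true(is.na(res3$recovery_fraction))
})

test_that("recovery fraction recovers the generative coupling coefficient", {
  for (kappa in c(0, 0.5, 1)) {
    recov <- vapply(1:200, function(s) {
      sim <- gen_knockdown_experiment(c(DDX3X = 100, DDX3Y = 50), "DDX3Y",
                                      kd_efficiency = 0.8, kappa = kappa,
                                      replicates = 6, cv = 0.1, seed = s)
      compensation_indices(sim$expr, sim$meta, "DDX3Y",
                           "DDX3X")$recovery_fraction
    }, numeric(1))
    mc_se <- sd(recov) / sqrt(length(recov))
    expect_lt(abs(mean(recov) - kappa), 2 * mc_se + 1e-12)
  }
})

test_that("ddCt folds follow the 2-fold-per-Ct rule", {
  qpcr <- data.frame(
    sample = sprintf("s%d", 1:6),
    group = rep(c("0uM", "10uM"), each = 3),
    ct_target = c(25.05, 24.95, 25.00, 24.05, 23.95, 24.00),
    ct_reference = 20)
  out <- ddct_fold(qpcr, control = "0uM")
  ctrl <- out$measurements$group == "0uM"
  expect_equal(out$measurements$ddct[ctrl], c(0.05, -0.05, 0))
  expect_equal(mean(out$measurements$ddct[ctrl]), 0)
  # a one-Ct drop in the treated group doubles the estimated abundance
  expect_equal(out$tests$mean_fold, 2)
  expect_lt(out$tests$p, 0.05)

  # fold is strictly decreasing in ddCt, 2-fold per unit
  dd <- out$measurements$ddct[order(out$measurements$ddct)]
  expect_true(all(diff(2^(-dd)) <= 0))
  expect_equal(out$measurements$fold[1] / out$measurements$fold[4], 0.5)
})

test_that("ddCt drops incomplete rows and needs a control group", {
  qpcr <- data.frame(sample = c("a", "b", "c", "d"),
                     group = c("0uM", "0uM", "2uM", "2uM"),
                     ct_target = c(25.1, 25, 24.1, 24),
                     ct_reference = c(20, NA, 20, 20))
  expect_warning(expect_warning(out <- ddct_fold(qpcr, "0uM"),
                                "missing Ct"),
                 "t-test skipped")
  expect_identical(nrow(out$measurements), 3L)
  expect_true(is.na(out$tests$p))
  expect_error(suppressWarnings(ddct_fold(qpcr, "DMSO")), "absent")
})

test_that("simulated treated/control Ct shift recovers the closed-form fold", {
  folds <- vapply(1:500, function(s) {
    set.seed(s)
    qpcr <- data.frame(
      sample = sprintf("s%d", 1:6),
      group = rep(c("0uM", "2uM"), each = 3),
      ct_target = c(rnorm(3, 25, 0.1), rnorm(3, 24.5, 0.1)),
      ct_reference = rnorm(6, 20, 0.1))
    ddct_fold(qpcr, "0uM")$tests$mean_fold
  }, numeric(1))
  expect_gt(median(folds), 1.3)
  expect_lt(median(folds), 1.6)  # truth 2^0.5 = 1.414
})
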