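seven_times <- c(0, 0.5, 1, 1.5, 2, 3.5, 7)

test_that("normalization divides out the spike-in and flags zero totals", {
  tc <- data.frame(time_h = c(0, 1, 2), nascent_tpm = c(0, 30, 60),
                   total_tpm = 60, spike_tpm = 50)
  norm <- normalize_timecourse(tc)
  expect_equal(norm$y, c(0, 0.5, 1))

  tc2 <- tc
  tc2$spike_tpm <- tc2$spike_tpm * 7.3
  expect_equal(normalize_timecourse(tc2)$y, norm$y)

  tc3 <- tc
  tc3$total_tpm[2] <- 0
  expect_warning(norm3 <- normalize_timecourse(tc3), "zero total")
  expect_identical(nrow(norm3), 2L)

  tc$spike_tpm[1] <- 0
  expect_error(normalize_timecourse(tc), "spike")
})

test_that("fully labeled steady-state input gives y identically 1", {
  tc <- data.frame(time_h = c(0, 1, 2), nascent_tpm = 60,
                   total_tpm = 60, spike_tpm = 5)
  expect_equal(normalize_timecourse(tc)$y, rep(1, 3))
})

test_that("generate-then-fit recovers half-lives exactly at zero noise", {
  for (hl in c(0.2, 0.5, 1.3, 5)) {
    y <- 1 - exp(-log(2) / hl * seven_times)
    fit <- fit_saturation(seven_times, y)
    expect_true(fit$converged)
    expect_equal(fit$half_life, hl, tolerance = 1e-6)
    expect_equal(fit$A, 1, tolerance = 1e-6)
  }
})

test_that("degenerate timecourses are flagged, never silently fit", {
  flat <- fit_saturation(seven_times, rep(0, 7))
  expect_false(flat$converged)
  expect_true(is.na(flat$half_life))

  decreasing <- fit_saturation(seven_times, c(1, 0.9, 0.75, 0.6, 0.5, 0.3, 0.1))
  expect_false(decreasing$converged)

  expect_error(fit_saturation(c(0, 1, 2), c(0, 0.5, 0.8)), "4 time points")
  expect_error(fit_saturation(seven_times, c(-0.1, 0.2, 0.4, 0.5, 0.6, 0.8, 1)),
               ">= 0")
})

test_that("fitted beta is invariant to time-unit rescaling", {
  y <- 1 - exp(-log(2) / 1.3 * seven_times)
  fit_h <- fit_saturation(seven_times, y)
  fit_min <- fit_saturation(seven_times * 60, y)
  expect_equal(fit_min$half_life / 60, fit_h$half_life, tolerance = 1e-6)
})

test_that("larger beta gives uniformly larger y at fixed plateau", {
  t_pos <- seven_times[seven_times > 0]
  y_slow <- 1 - exp(-0.3 * t_pos)
  y_fast <- 1 - exp(-1.5 * t_pos)
  expect_true(all(y_fast > y_slow))
})

test_that("spike-in rescaling leaves the fitted half-life unchanged", {
  for (s in 1:10) {
    tc <- gen_labeling_timecourse(beta = log(2) / 1.3, cv = 0.1, seed = s)
    fit1 <- with(normalize_timecourse(tc), fit_saturation(time_h, y))
    tc$spike_tpm <- tc$spike_tpm * runif(1, 0.01, 100)
    fit2 <- with(normalize_timecourse(tc), fit_saturation(time_h, y))
    expect_equal(fit2$half_life, fit1$half_life, tolerance = 1e-6)
  }
})

test_that("half-life recovery under noise stays within 15% median error", {
  rel_err <- vapply(1:500, function(s) {
    tc <- gen_labeling_timecourse(beta = log(2) / 1.3, cv = 0.1, seed = s)
    fit <- with(normalize_timecourse(tc), fit_saturation(time_h, y))
    abs(fit$half_life - 1.3) / 1.3
  }, numeric(1))
  expect_lt(median(rel_err, na.rm = TRUE), 0.15)
})

test_that("bootstrap is deterministic, degenerate on noiseless data", {
  y <- 1 - exp(-log(2) / 1.3 * seven_times)
  fit <- fit_saturation(seven_times, y)
  b <- bootstrap_halflife(fit, n_boot = 50, seed = 3)
  expect_lt(diff(b$ci), 1e-6)

  tc <- gen_labeling_timecourse(beta = log(2) / 1.3, cv = 0.1, seed = 4)
  fitn <- with(normalize_timecourse(tc), fit_saturation(time_h, y))
  b1 <- bootstrap_halflife(fitn, n_boot = 100, seed = 9)
  b2 <- bootstrap_halflife(fitn, n_boot = 100, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci[1] <= fitn$half_life && b1$ci[2] >= fitn$half_life)
})

test_that("bootstrap CI covers the true half-life in most simulations", {
  covered <- vapply(1:100, function(s) {
    tc <- gen_labeling_timecourse(beta = log(2) / 1.3, cv = 0.1,
                                  seed = 1000 + s)
    fit <- with(normalize_timecourse(tc), fit_saturation(time_h, y))
    if (!fit$converged) return(NA)
    ci <- bootstrap_halflife(fit, n_boot = 300, seed = s)$ci
    !anyNA(ci) && ci[1] <= 1.3 && ci[2] >= 1.3
  }, logical(1))
  expect_gte(mean(covered, na.rm = TRUE), 0.85)
})

test_that("condition comparison reports the half-life ratio with a CI", {
  y13 <- 1 - exp(-log(2) / 1.3 * seven_times)
  y05 <- 1 - exp(-log(2) / 0.5 * seven_times)
  fit_a <- fit_saturation(seven_times, y13)
  fit_b <- fit_saturation(seven_times, y05)
  cmp <- compare_conditions(fit_a, fit_b, n_boot = 50, seed = 2)
  expect_equal(cmp$ratio, 0.5 / 1.3, tolerance = 1e-5)

  same <- compare_conditions(fit_a, fit_a, n_boot = 50, seed = 2)
  expect_equal(same$ratio, 1, tolerance = 1e-10)

  bad <- fit_saturation(seven_times, rep(0, 7))
  expect_error(compare_conditions(fit_a, bad), "converged")
})

test_that("a 2.6-fold stability difference is detected at CV 0.1", {
  excludes_one <- vapply(1:40, function(s) {
    tc_a <- gen_labeling_timecourse(beta = log(2) / 1.3, cv = 0.1,
                                    seed = 3000 + s)
    tc_b <- gen_labeling_timecourse(beta = log(2) / 0.5, cv = 0.1,
                                    seed = 6000 + s)
    fit_a <- with(normalize_timecourse(tc_a), fit_saturation(time_h, y))
    fit_b <- with(normalize_timecourse(tc_b), fit_saturation(time_h, y))
    if (!fit_a$converged || !fit_b$converged) return(NA)
    ci <- compare_conditions(fit_a, fit_b, n_boot = 200, seed = s)$ci
    !anyNA(ci) && (ci[2] < 1 || ci[1] > 1)
  }, logical(1))
  expect_gte(mean(excludes_one, na.rm = TRUE), 0.9)
})

test_that("halflife_table fits every gene-condition series in long format", {
  tc <- rbind(
    gen_labeling_timecourse(beta = log(2) / 1.3, cv = 0, condition = "46,XY",
                            seed = 1),
    gen_labeling_timecourse(beta = log(2) / 0.5, cv = 0,
                            condition = "49,XYYYY", seed = 2))
  out <- halflife_table(tc)
  expect_identical(nrow(out), 2L)
  expect_equal(sort(out$half_life_h), c(0.5, 1.3), tolerance = 1e-6)
  expect_true(all(out$converged))
})
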