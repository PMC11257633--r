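# mRNA half-life estimation from 5-EU metabolic-labeling timecourses:
# spike-in normalization, saturation-kinetic fitting, residual bootstrap.

#' Normalize a labeling timecourse to nascent fraction
#'
#' Converts a metabolic-labeling timecourse to the nascent fraction
#' \deqn{y(t) = \frac{nascent(t)/spike(t)}{\overline{total/spike}},}
#' the spike-in-normalized nascent signal divided by the steady-state level,
#' estimated as the mean spike-normalized total across the timecourse's
#' points. Total mRNA sits at steady state throughout labeling, so pooling
#' its measurements gives a stable denominator instead of injecting each
#' point's total-library noise into the ratio. Multiplying every spike TPM
#' by a common factor cancels exactly. Under constant synthesis and
#' first-order decay, the noiseless fraction equals \eqn{A(1 - e^{-\beta t})}.
#'
#' @param tc data.frame with columns `time_h`, `nascent_tpm`, `total_tpm`,
#'   `spike_tpm` (long format; see [gen_labeling_timecourse()]). If a
#'   `replicate` column is present each replicate is normalized against its
#'   own steady-state mean, then fractions are averaged per time point.
#' @return data.frame with `time_h` and `y` (nascent fraction), sorted by
#'   time. Points with zero total TPM are dropped with a warning.
#' @export
normalize_timecourse <- function(tc) {
  stopifnot(all(c("time_h", "nascent_tpm", "total_tpm", "spike_tpm")
                %in% colnames(tc)))
  if (any(tc$spike_tpm <= 0)) stop("spike-in TPM must be > 0 at every point")
  zero_total <- tc$total_tpm == 0
  if (any(zero_total)) {
    warning("dropping ", sum(zero_total), " point(s) with zero total TPM")
    tc <- tc[!zero_total, , drop = FALSE]
  }
  rep_id <- if ("replicate" %in% colnames(tc)) tc$replicate else
    rep(1L, nrow(tc))
  y <- rep(NA_real_, nrow(tc))
  for (r in unique(rep_id)) {
    sel <- rep_id == r
    steady <- mean(tc$total_tpm[sel] / tc$spike_tpm[sel])
    y[sel] <- (tc$nascent_tpm[sel] / tc$spike_tpm[sel]) / steady
  }
  out <- data.frame(time_h = tc$time_h, y = y)
  agg <- stats::aggregate(y ~ time_h, data = out, FUN = mean)
  agg[order(agg$time_h), , drop = FALSE]
}

#' Fit the saturation (approach-to-steady-state) kinetic model
#'
#' Nonlinear least squares fit of \eqn{y(t) = A (1 - e^{-\beta t})} to a
#' nascent-fraction timecourse. With constant synthesis and first-order
#' decay at rate \eqn{\beta}, labeled RNA approaches its plateau along this
#' curve, so \eqn{\beta} is the decay rate and the mRNA half-life is
#' \eqn{\ln 2 / \beta}. The plateau A is free: it absorbs labeling
#' efficiency and the steady-state normalization constant.
#'
#' @param times Time points in hours (>= 4, including 0 recommended).
#' @param y Nascent fractions, same length as `times`, all >= 0.
#' @return Object of class `saturation_fit`: list with `A`, `beta`
#'   (1/h), `half_life` (h), `sse`, `converged`, plus the data and fitted
#'   values. A fit that cannot beat a constant mean (e.g. monotone-decreasing
#'   input) is flagged `converged = FALSE`; failures are never silent.
#' @details Initialization: A starts at 1.05 x max(y); beta starts at
#'   ln2 / (first time at which y exceeds half the starting plateau, falling
#'   back to the median positive time). Bounds: A in (0, 2 max(y)],
#'   beta > 0. Levenberg-Marquardt via [minpack.lm::nlsLM()], at most 500
#'   iterations.
#' @export
#' @examples
#' t <- c(0, 0.5, 1, 1.5, 2, 3.5, 7)
#' y <- 1 - exp(-log(2) / 1.3 * t)
#' fit_saturation(t, y)$half_life  # 1.3
fit_saturation <- function(times, y) {
  stopifnot(length(times) == length(y))
  keep <- is.finite(times) & is.finite(y)
  times <- times[keep]; y <- y[keep]
  if (length(times) < 4L) stop("need at least 4 time points")
  if (any(y < 0)) stop("nascent fractions must be >= 0")
  failed <- function() {
    structure(list(A = NA_real_, beta = NA_real_, half_life = NA_real_,
                   sse = NA_real_, converged = FALSE, times = times, y = y,
                   fitted = rep(NA_real_, length(y))),
              class = "saturation_fit")
  }
  ymax <- max(y)
  if (ymax <= 0) return(failed())

  a0 <- 1.05 * ymax
  above <- times[y > a0 / 2 & times > 0]
  t_half0 <- if (length(above)) min(above) else stats::median(times[times > 0])
  b0 <- log(2) / t_half0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-b * t)),
      data = data.frame(t = times, y = y),
      start = list(A = a0, b = b0),
      lower = c(A = 1e-9, b = 1e-9),
      upper = c(A = 2 * ymax, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed())
  est <- stats::coef(fit)
  fitted_y <- est[["A"]] * (1 - exp(-est[["b"]] * times))
  sse <- sum((y - fitted_y)^2)
  sst <- sum((y - mean(y))^2)
  # a saturation curve that cannot beat a flat mean carries no kinetic signal
  converged <- est[["b"]] > 1e-8 && est[["A"]] > 1e-8 &&
    (sst == 0 || sse < sst * (1 - 1e-8))
  if (!converged) return(failed())
  beta_hat <- unname(est[["b"]])
  se_beta <- tryCatch(sqrt(stats::vcov(fit)["b", "b"]),
                      error = function(e) NA_real_)
  # delta method: half-life = ln2/beta
  se_half_life <- log(2) / beta_hat^2 * se_beta
  structure(list(A = unname(est[["A"]]), beta = beta_hat,
                 half_life = log(2) / beta_hat,
                 se_beta = se_beta, se_half_life = se_half_life,
                 sse = sse, converged = TRUE, times = times, y = y,
                 fitted = fitted_y),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Saturation fit: DID NOT CONVERGE (", length(x$times),
        "points )\n")
  } else {
    cat(sprintf(
      "Saturation fit: A = %.4g, beta = %.4g /h, half-life = %.2g h (%d points)\n",
      x$A, x$beta, x$half_life, length(x$times)))
  }
  invisible(x)
}

#' Residual-resampling bootstrap CI for a fitted half-life
#'
#' Studentized (bootstrap-t) residual bootstrap: residuals of a converged
#' saturation fit are centred, inflated by \eqn{\sqrt{n/(n-p)}} to undo the
#' downward bias of least-squares residual variance, resampled with
#' replacement onto the fitted curve, and each resample refit. The 2.5-97.5%
#' interval is built from the bootstrap distribution of the studentized
#' statistic \eqn{(\hat h^* - \hat h)/\widehat{se}(\hat h^*)} with the
#' delta-method standard error of the half-life, which calibrates far better
#' than the raw percentile interval at the short timecourses (7 points)
#' typical of labeling experiments. Deterministic given the seed.
#'
#' @param fit A converged `saturation_fit`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `ci` (length-2 numeric, clipped to bracket the point
#'   estimate and floored at 0), `draws` (successful bootstrap half-lives),
#'   `n_fail`. If more than half the refits fail the CI is `NA` with a
#'   warning.
#' @export
bootstrap_halflife <- function(fit, n_boot = 500L, seed = 1L) {
  stopifnot(inherits(fit, "saturation_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit")
  set.seed(derive_seed(seed, "bootstrap"))
  n <- length(fit$y)
  resid <- fit$y - fit$fitted
  if (fit$sse < 1e-18) {
    # noiseless data: the CI degenerates to the point estimate
    return(list(ci = c(fit$half_life, fit$half_life),
                draws = rep(fit$half_life, n_boot), n_fail = 0L))
  }
  resid <- (resid - mean(resid)) * sqrt(n / max(1L, n - 2L))
  draws <- rep(NA_real_, n_boot)
  tstat <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    y_star <- pmax(0, fit$fitted + sample(resid, n, replace = TRUE))
    refit <- tryCatch(fit_saturation(fit$times, y_star),
                      error = function(e) NULL)
    if (!is.null(refit) && refit$converged) {
      draws[b] <- refit$half_life
      if (is.finite(refit$se_half_life) && refit$se_half_life > 0) {
        tstat[b] <- (refit$half_life - fit$half_life) / refit$se_half_life
      }
    }
  }
  n_fail <- sum(is.na(draws))
  draws <- draws[!is.na(draws)]
  if (n_fail > n_boot / 2) {
    warning("more than half of bootstrap refits failed; CI unavailable")
    ci <- c(NA_real_, NA_real_)
  } else if (is.finite(fit$se_half_life) && fit$se_half_life > 0 &&
             sum(is.finite(tstat)) >= n_boot / 2) {
    q <- stats::quantile(tstat, c(0.025, 0.975), na.rm = TRUE)
    ci <- c(fit$half_life - q[[2L]] * fit$se_half_life,
            fit$half_life - q[[1L]] * fit$se_half_life)
  } else {
    ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  if (!anyNA(ci)) {
    ci <- c(max(0, min(ci[1L], fit$half_life)), max(ci[2L], fit$half_life))
  }
  list(ci = ci, draws = draws, n_fail = n_fail)
}

#' Compare half-lives between two conditions
#'
#' Ratio of fitted half-lives (condition b over condition a) with a
#' percentile confidence interval from paired independent bootstrap draws of
#' the two fits.
#'
#' @param fit_a,fit_b Converged `saturation_fit` objects.
#' @param n_boot Bootstrap replicates per condition.
#' @param seed Integer seed (substreams derived per condition).
#' @return List with `ratio` (half-life b / half-life a), `ci`, and the two
#'   point estimates.
#' @export
compare_conditions <- function(fit_a, fit_b, n_boot = 500L, seed = 1L) {
  if (!fit_a$converged || !fit_b$converged) {
    stop("both fits must have converged")
  }
  ratio <- fit_b$half_life / fit_a$half_life
  ba <- bootstrap_halflife(fit_a, n_boot, derive_seed(seed, "cond_a"))
  bb <- bootstrap_halflife(fit_b, n_boot, derive_seed(seed, "cond_b"))
  n <- min(length(ba$draws), length(bb$draws))
  ci <- if (n < n_boot / 2 || anyNA(ba$ci) || anyNA(bb$ci)) {
    c(NA_real_, NA_real_)
  } else {
    unname(stats::quantile(bb$draws[seq_len(n)] / ba$draws[seq_len(n)],
                           c(0.025, 0.975)))
  }
  list(ratio = ratio, ci = ci,
       half_life_a = fit_a$half_life, half_life_b = fit_b$half_life)
}

#' Half-life table for a long-format labeling dataset
#'
#' Normalizes and fits every gene x condition timecourse in a long-format
#' table (columns `gene`, `condition`, `time_h`, `nascent_tpm`, `total_tpm`,
#' `spike_tpm`).
#'
#' @param tc Long-format labeling data.frame.
#' @param n_boot Bootstrap replicates for the CI (0 to skip).
#' @param seed Integer seed.
#' @return data.frame with one row per gene x condition: `A`, `beta`,
#'   `half_life_h`, `ci_lo`, `ci_hi`, `converged`.
#' @export
halflife_table <- function(tc, n_boot = 0L, seed = 1L) {
  stopifnot(all(c("gene", "condition") %in% colnames(tc)))
  key <- interaction(tc$gene, tc$condition, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- tc[key == k, , drop = FALSE]
    norm <- normalize_timecourse(sub)
    fit <- fit_saturation(norm$time_h, norm$y)
    ci <- c(NA_real_, NA_real_)
    if (fit$converged && n_boot > 0L) {
      ci <- bootstrap_halflife(fit, n_boot,
                               derive_seed(seed, paste0("hl_", k)))$ci
    }
    data.frame(gene = sub$gene[1L], condition = sub$condition[1L],
               A = fit$A, beta = fit$beta, half_life_h = fit$half_life,
               ci_lo = ci[1L], ci_hi = ci[2L], converged = fit$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
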