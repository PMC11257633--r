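# Allelic-ratio estimation, the AR-vs-dEx auto-regulation test, knockdown
# compensation indices, and delta-delta-Ct qPCR utilities.

#' Allelic ratio (Xi/Xa) per sample
#'
#' Sums allele-specific counts over informative SNPs within each sample and
#' takes the ratio of Xi- to Xa-derived counts. Summing before dividing
#' weights each SNP by its coverage; it is invariant to how counts are split
#' across SNPs, unlike a mean of per-SNP ratios.
#'
#' @param counts data.frame with columns `sample`, `xi_count`, `xa_count`
#'   (one row per SNP per sample, or already aggregated).
#' @return data.frame with `sample`, `xi_count`, `xa_count` (summed), and
#'   `ar = xi/xa`. A sample with zero Xa counts gets `NA` with a warning.
#' @export
#' @examples
#' allelic_ratio(data.frame(sample = "s1", xi_count = c(10, 45),
#'                          xa_count = c(20, 80)))$ar  # 55/100 = 0.55
allelic_ratio <- function(counts) {
  stopifnot(all(c("sample", "xi_count", "xa_count") %in% colnames(counts)),
            all(counts$xi_count >= 0), all(counts$xa_count >= 0))
  xi <- tapply(counts$xi_count, counts$sample, sum)
  xa <- tapply(counts$xa_count, counts$sample, sum)
  samples <- names(xi)
  ar <- ifelse(xa > 0, xi / xa, NA_real_)
  if (anyNA(ar)) {
    warning("sample(s) with zero Xa counts: allelic ratio undefined for ",
            paste(samples[is.na(ar)], collapse = ", "))
  }
  data.frame(sample = samples, xi_count = as.integer(xi),
             xa_count = as.integer(xa), ar = as.numeric(ar),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test whether allelic ratios exceed the dosage increment
#'
#' One-sample t-test of per-sample allelic ratios against a fixed reference
#' \eqn{\Delta E_X}. If expression from Xi and Xa were independent and
#' additive, AR should approximate \eqn{\Delta E_X}; a mean AR significantly
#' above it indicates that added-X dosage is buffered downstream of Xi
#' transcription (negative auto-regulation).
#'
#' @param ar_values Numeric vector of per-sample allelic ratios (>= 2).
#' @param delta_ex Reference dosage increment to test against.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return List with `mean_ar`, `delta_ex`, `t`, `p`, `n`.
#' @export
ar_vs_deltaEx_test <- function(ar_values, delta_ex,
                               alternative = "two.sided") {
  ar_values <- ar_values[!is.na(ar_values)]
  if (length(ar_values) < 2L) stop("need at least 2 allelic-ratio values")
  if (stats::var(ar_values) == 0) {
    stop("zero variance in allelic ratios; t-test undefined")
  }
  tt <- stats::t.test(ar_values, mu = delta_ex, alternative = alternative)
  list(mean_ar = mean(ar_values), delta_ex = delta_ex,
       t = unname(tt$statistic), p = tt$p.value, n = length(ar_values))
}

#' Compensation indices for a homolog-pair knockdown
#'
#' Quantifies how completely the partner homolog buffers a knockdown of the
#' target. On replicate means:
#' `summed_ratio = (target_kd + partner_kd) / (target_control +
#' partner_control)` (1 = summed pair expression fully maintained) and
#' `recovery_fraction = (partner_kd - partner_control) / (target_control -
#' target_kd)` (the fraction of absolute target loss recovered by the
#' partner's rise; equals the generative cross-coupling coefficient in
#' expectation).
#'
#' @param expr Gene x sample TPM matrix containing both homologs.
#' @param meta Sample annotation with `sample` and `condition`
#'   (`"control"` vs anything else for the knockdown arm).
#' @param target Knocked-down gene.
#' @param partner Homologous partner gene.
#' @param kd_condition Condition label of the knockdown arm; defaults to the
#'   single non-control condition present.
#' @return List of class `compensation_result` with per-gene control/KD
#'   means, `control_sum`, `kd_sum`, `summed_ratio`, `recovery_fraction`,
#'   and replicate counts.
#' @details If the target is not reduced in the knockdown arm the recovery
#'   fraction is undefined and returned as `NA` with a warning.
#' @export
compensation_indices <- function(expr, meta, target, partner,
                                 kd_condition = NULL) {
  stopifnot(target %in% rownames(expr), partner %in% rownames(expr))
  idx <- match(colnames(expr), meta$sample)
  if (anyNA(idx)) stop("samples in expression table missing from annotation")
  cond <- meta$condition[idx]
  if (is.null(kd_condition)) {
    kd_condition <- setdiff(unique(cond), "control")
    if (length(kd_condition) != 1L) {
      stop("specify kd_condition: found ", length(kd_condition),
           " non-control conditions")
    }
  }
  ctrl <- cond == "control"
  kd <- cond == kd_condition
  if (!any(ctrl) || !any(kd)) stop("need replicates in both conditions")

  m <- function(gene, sel) mean(expr[gene, sel])
  target_control <- m(target, ctrl); target_kd <- m(target, kd)
  partner_control <- m(partner, ctrl); partner_kd <- m(partner, kd)
  control_sum <- target_control + partner_control
  kd_sum <- target_kd + partner_kd
  loss <- target_control - target_kd
  if (loss <= 0) {
    warning("target '", target, "' not reduced in knockdown arm; ",
            "recovery fraction undefined")
    recovery <- NA_real_
  } else {
    recovery <- (partner_kd - partner_control) / loss
  }
  structure(list(target = target, partner = partner,
                 kd_condition = kd_condition,
                 target_control = target_control, target_kd = target_kd,
                 partner_control = partner_control, partner_kd = partner_kd,
                 control_sum = control_sum, kd_sum = kd_sum,
                 summed_ratio = kd_sum / control_sum,
                 recovery_fraction = recovery,
                 n_control = sum(ctrl), n_kd = sum(kd)),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat("Knockdown compensation:", x$target, "KD, partner", x$partner, "\n")
  cat(sprintf("  summed pair TPM: %.2f (control) -> %.2f (KD), ratio %.3f\n",
              x$control_sum, x$kd_sum, x$summed_ratio))
  cat(sprintf("  recovery fraction: %s\n",
              if (is.na(x$recovery_fraction)) "undefined"
              else sprintf("%.3f", x$recovery_fraction)))
  invisible(x)
}

#' Delta-delta-Ct fold changes with per-group t-tests
#'
#' Computes per-sample \eqn{\Delta Ct = Ct_{target} - Ct_{reference}},
#' centres each sample on the control-group mean \eqn{\Delta Ct} to obtain
#' \eqn{\Delta\Delta Ct}, and reports fold change \eqn{2^{-\Delta\Delta Ct}}
#' (each unit drop in Ct doubles estimated abundance). Each non-control
#' group is compared with the control by a one-sided Welch t-test on
#' \eqn{\Delta Ct} values in the direction of increased target expression
#' (treated \eqn{\Delta Ct} below control), with Benjamini-Hochberg
#' adjustment across groups.
#'
#' @param qpcr data.frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param control Label of the control group in `group`.
#' @return List with `measurements` (per-sample dCt, ddCt, fold) and
#'   `tests` (per non-control group: mean fold, t, one-sided p, BH-adjusted
#'   p). Rows with missing Ct values are dropped with a warning.
#' @export
ddct_fold <- function(qpcr, control) {
  stopifnot(all(c("sample", "group", "ct_target", "ct_reference")
                %in% colnames(qpcr)))
  drop <- is.na(qpcr$ct_target) | is.na(qpcr$ct_reference)
  if (any(drop)) {
    warning("dropping ", sum(drop), " row(s) with missing Ct values")
    qpcr <- qpcr[!drop, , drop = FALSE]
  }
  if (!control %in% qpcr$group) stop("control group '", control, "' absent")
  qpcr$dct <- qpcr$ct_target - qpcr$ct_reference
  ctrl_mean <- mean(qpcr$dct[qpcr$group == control])
  qpcr$ddct <- qpcr$dct - ctrl_mean
  qpcr$fold <- 2^(-qpcr$ddct)

  groups <- setdiff(unique(qpcr$group), control)
  tests <- do.call(rbind, lapply(groups, function(g) {
    a <- qpcr$dct[qpcr$group == g]
    b <- qpcr$dct[qpcr$group == control]
    if (length(a) < 2L || length(b) < 2L) {
      warning("fewer than 2 replicates in group '", g,
              "' or control; t-test skipped")
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- stats::t.test(a, b, alternative = "less")
    }
    data.frame(group = g, mean_fold = 2^(-(mean(a) - ctrl_mean)),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(tests)) tests$p_adj <- stats::p.adjust(tests$p, "BH")
  list(measurements = qpcr, tests = tests)
}
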