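# Per-gene dose-response estimation across sex-chromosome copy-number
# series, Pearson dose correlations, and the XY karyotype-retention filter
# for cancer cell line panels.

#' Fit a linear dose-response of expression on chromosome copy number
#'
#' Ordinary least squares of TPM on centred copy-number predictors:
#' `(nX - 1)`, `nY`, and `(n21 - 2)` when requested. The intercept is the
#' expected expression in a 45,X-like baseline (one X, no Y, disomy 21), so
#' each slope is the TPM increment per added chromosome and the relative
#' increments \eqn{\Delta E_X = \beta_X/\beta_0} and
#' \eqn{\Delta E_Y = \beta_Y/\beta_0} express that change relative to the
#' single-active-X baseline.
#'
#' @param expr Gene x sample TPM matrix (see [read_expression_table()]).
#' @param meta Sample annotation data.frame with `sample`, `nX`, `nY`, `n21`
#'   matching `colnames(expr)`.
#' @param gene Gene identifier (row of `expr`).
#' @param predictors Subset of `c("X", "Y", "21")` to include.
#' @return An object of class `dose_response_fit`: list with `gene`,
#'   `coefficients` (data.frame of estimate, std. error, p-value per term),
#'   `beta0`, `betaX`, `betaY`, `beta21`, `dEx`, `dEy`, and `n`.
#' @details A constant predictor makes the design rank-deficient and raises
#'   an error naming the predictor. Relative increments are `NA` with a
#'   warning when the fitted baseline is non-positive.
#' @export
fit_dose_response <- function(expr, meta, gene,
                              predictors = c("X", "Y")) {
  stopifnot(all(predictors %in% c("X", "Y", "21")), length(predictors) >= 1L)
  if (!gene %in% rownames(expr)) stop("gene not in expression table: ", gene)
  idx <- match(colnames(expr), meta$sample)
  if (anyNA(idx)) stop("samples in expression table missing from annotation")
  meta <- meta[idx, , drop = FALSE]

  df <- data.frame(tpm = expr[gene, ])
  pred_cols <- c(X = "xX", Y = "xY", `21` = "x21")[predictors]
  if ("X" %in% predictors) df$xX <- meta$nX - 1
  if ("Y" %in% predictors) df$xY <- meta$nY
  if ("21" %in% predictors) df$x21 <- meta$n21 - 2
  for (p in predictors) {
    v <- df[[pred_cols[[p]]]]
    if (length(unique(v)) < 2L) {
      stop("rank-deficient design: predictor '", p, "' is constant")
    }
  }
  if (nrow(df) < length(predictors) + 2L) {
    stop("too few samples for ", length(predictors), " predictor(s)")
  }
  fit <- stats::lm(stats::reformulate(unname(pred_cols), response = "tpm"),
                   data = df)
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1L],
                      std_error = cf[, 2L], p_value = cf[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  beta0 <- cf["(Intercept)", 1L]
  getb <- function(term) if (term %in% rownames(cf)) cf[term, 1L] else NA_real_
  betaX <- getb("xX"); betaY <- getb("xY"); beta21 <- getb("x21")
  if (beta0 <= 0) {
    warning("fitted baseline expression <= 0; relative increments undefined")
    dEx <- dEy <- NA_real_
  } else {
    dEx <- betaX / beta0
    dEy <- betaY / beta0
  }
  structure(list(gene = gene, coefficients = coefs, beta0 = beta0,
                 betaX = betaX, betaY = betaY, beta21 = beta21,
                 dEx = dEx, dEy = dEy, n = nrow(df)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response fit for", x$gene, "(n =", x$n, "samples)\n")
  cat(sprintf("  baseline (1X, 0Y): %.3f TPM\n", x$beta0))
  if (!is.na(x$betaX)) {
    cat(sprintf("  per added X: %+.3f TPM (dEx = %.3f)\n", x$betaX, x$dEx))
  }
  if (!is.na(x$betaY)) {
    cat(sprintf("  per added Y: %+.3f TPM (dEy = %.3f)\n", x$betaY, x$dEy))
  }
  if (!is.na(x$beta21)) {
    cat(sprintf("  per added chr21: %+.3f TPM\n", x$beta21))
  }
  invisible(x)
}

#' Pearson correlation between expression and chromosome copy number
#'
#' @param expr Gene x sample TPM matrix.
#' @param meta Sample annotation matching `colnames(expr)`.
#' @param gene Gene identifier.
#' @param axis Which copy number to correlate against: `"X"`, `"Y"`, or
#'   `"21"`.
#' @return List with `r` (Pearson product-moment correlation), `p`
#'   (two-sided), and `n`.
#' @export
dose_correlation <- function(expr, meta, gene, axis = c("X", "Y", "21")) {
  axis <- match.arg(axis)
  if (!gene %in% rownames(expr)) stop("gene not in expression table: ", gene)
  idx <- match(colnames(expr), meta$sample)
  if (anyNA(idx)) stop("samples in expression table missing from annotation")
  meta <- meta[idx, , drop = FALSE]
  x <- switch(axis, X = meta$nX, Y = meta$nY, `21` = meta$n21)
  y <- expr[gene, ]
  if (length(y) < 3L) stop("need at least 3 samples")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in ", if (stats::var(x) == 0) "copy number" else
      "expression", "; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(y))
}

#' Classify cell lines as XY-karyotype-retained
#'
#' Restricts a cancer-cell-line panel to lines behaving as 46,XY by
#' expression: retained iff log2TPM(DDX3Y) > 0.2 and log2TPM(RPS4Y) > 0.2
#' and log2TPM(XIST) < 2, all strict inequalities. Lines with any missing
#' value are called not-retained and flagged.
#'
#' @param log2tpm_ddx3y,log2tpm_rps4y,log2tpm_xist Numeric vectors of
#'   log2TPM values (recycled to common length).
#' @param line Optional cell line identifiers.
#' @return data.frame with `line`, the three inputs, `is_xy_retained`, and
#'   `missing_input`.
#' @export
#' @examples
#' classify_xy_retained(3.0, 2.5, 0.1)$is_xy_retained  # TRUE
#' classify_xy_retained(0.2, 2.5, 0.1)$is_xy_retained  # FALSE: boundary
classify_xy_retained <- function(log2tpm_ddx3y, log2tpm_rps4y, log2tpm_xist,
                                 line = NULL) {
  n <- max(length(log2tpm_ddx3y), length(log2tpm_rps4y), length(log2tpm_xist))
  d <- rep_len(log2tpm_ddx3y, n)
  r <- rep_len(log2tpm_rps4y, n)
  x <- rep_len(log2tpm_xist, n)
  if (is.null(line)) line <- sprintf("line_%03d", seq_len(n))
  miss <- is.na(d) | is.na(r) | is.na(x)
  retained <- !miss & d > 0.2 & r > 0.2 & x < 2
  data.frame(line = line, log2tpm_ddx3y = d, log2tpm_rps4y = r,
             log2tpm_xist = x, is_xy_retained = retained,
             missing_input = miss, stringsAsFactors = FALSE)
}
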