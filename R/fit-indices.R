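#' Independence (baseline) model fit
#'
#' The baseline for incremental fit indices frees every variance and fixes
#' every covariance at zero.  Its ML discrepancy has the closed form
#' `F_b = -log|R|` with `R` the sample correlation matrix, so
#' `chi2_b = (N - 1) * F_b` and `df_b = p(p - 1)/2`.
#'
#' @param moments a [sample_moments()].
#' @return list with `chi_square`, `df`, `F_min`.
#' @export
baseline_fit <- function(moments) {
  stopifnot(inherits(moments, "sample_moments"))
  R <- stats::cov2cor(moments$S)
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0) stop("sample correlation matrix is not positive definite")
  Fb <- -as.numeric(ld$modulus)
  p <- moments$p
  list(chi_square = (moments$n - 1) * Fb,
       df = p * (p - 1) / 2,
       F_min = Fb)
}

# 90% noncentrality interval for the noncentral chi-square family:
# lambda_lo solves P(X_{df,lambda} <= chi2) = 0.95 (0 if central prob < .95),
# lambda_hi solves P(X_{df,lambda} <= chi2) = 0.05.
noncentrality_interval <- function(chi2, df, level = 0.90) {
  a <- (1 - level) / 2
  pr <- function(lambda) stats::pchisq(chi2, df, ncp = lambda)
  upper_root <- function(target) {
    if (pr(0) <= target) return(0)
    hi <- max(chi2, 1)
    while (pr(hi) > target) hi <- hi * 2
    stats::uniroot(function(l) pr(l) - target, c(0, hi),
                   tol = 1e-9)$root
  }
  c(lo = upper_root(1 - a), hi = upper_root(a))
}

#' Goodness-of-fit index battery for a fitted path model
#'
#' Computes the absolute, incremental, parsimony and noncentrality-based
#' indices conventionally reported for covariance-structure models:
#' chi-square and its p-value, chi-square/df, RMR, SRMR, GFI, AGFI, PGFI,
#' NFI, RFI, IFI, TLI, CFI, PNFI, PCFI, RMSEA with a 90% confidence interval
#' and PCLOSE, ECVI with a 90% confidence interval, and Hoelter's critical N
#' at alpha = 0.05 (and 0.01).
#'
#' Formulas: `RMR = sqrt(sum_{i<=j} (s_ij - sigma_ij)^2 / (p(p+1)/2))`;
#' SRMR the same on residuals divided by `sd_i * sd_j` (sample);
#' `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`;
#' `AGFI = 1 - [p(p+1)/(2 df)] (1 - GFI)`; `PGFI = GFI * df / (p(p+1)/2)`;
#' `NFI = (chi2_b - chi2)/chi2_b`; `RFI = 1 - (chi2/df)/(chi2_b/df_b)`;
#' `IFI = (chi2_b - chi2)/(chi2_b - df)`;
#' `TLI = [(chi2_b/df_b) - (chi2/df)] / [(chi2_b/df_b) - 1]`;
#' `CFI = 1 - max(chi2 - df, 0)/max(chi2_b - df_b, chi2 - df, 0)`;
#' `PNFI = (df/df_b) NFI`; `PCFI = (df/df_b) CFI`;
#' `RMSEA = sqrt(max(chi2 - df, 0)/(df (N - 1)))` with interval bounds
#' `sqrt(lambda/(df (N - 1)))` from the 90% noncentrality interval and
#' `PCLOSE = P[chi2_{df, lambda0} > chi2]` at `lambda0 = (N-1) df 0.05^2`;
#' `ECVI = (chi2 + 2q)/(N - 1)` with bounds `(lambda + df + 2q)/(N - 1)`;
#' `Hoelter(alpha) = floor(chi2_crit(df, alpha) / (chi2/(N - 1))) + 1`.
#'
#' @param fit a [fit_ml()] result.
#' @param baseline optional [baseline_fit()] result (computed from the fit's
#'   moments when omitted).
#' @return an object of class `fit_index_report` (a list of scalars; degrees-
#'   of-freedom-based indices are `NA` for a saturated model).
#' @export
#' @examples
#' m <- triticale_gpre_model()
#' fit <- fit_ml(m, reconstruct_covariance(n = 37, divisor = "n"))
#' rep <- fit_indices(fit)
#' rep$ecvi; rep$hoelter_05
fit_indices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  moments <- fit$moments
  if (is.null(baseline)) baseline <- baseline_fit(moments)
  S <- moments$S[fit$ram$variables, fit$ram$variables]
  sigma <- fit$implied
  p <- fit$ram$p
  q <- fit$ram$q
  df <- fit$df
  n <- moments$n
  chi2 <- fit$chi_square
  chi2_b <- baseline$chi_square
  df_b <- baseline$df
  m_unique <- p * (p + 1) / 2

  res <- S - sigma
  lower <- lower.tri(res, diag = TRUE)
  rmr <- sqrt(sum(res[lower]^2) / m_unique)
  sds <- sqrt(diag(S))
  std_res <- res / tcrossprod(sds)
  srmr <- sqrt(sum(std_res[lower]^2) / m_unique)

  Wsig <- solve(sigma)
  WS <- Wsig %*% S
  gfi <- 1 - sum(diag((WS - diag(p)) %*% (WS - diag(p)))) /
             sum(diag(WS %*% WS))
  has_df <- df > 0
  agfi <- if (has_df) 1 - (m_unique / df) * (1 - gfi) else NA_real_
  pgfi <- gfi * df / m_unique

  nfi <- (chi2_b - chi2) / chi2_b
  rfi <- if (has_df) 1 - (chi2 / df) / (chi2_b / df_b) else NA_real_
  ifi <- (chi2_b - chi2) / (chi2_b - df)
  tli <- if (has_df) ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
         else NA_real_
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)
  pnfi <- (df / df_b) * nfi
  pcfi <- (df / df_b) * cfi

  if (has_df) {
    rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
    lam <- noncentrality_interval(chi2, df)
    rmsea_lo <- sqrt(lam[["lo"]] / (df * (n - 1)))
    rmsea_hi <- sqrt(lam[["hi"]] / (df * (n - 1)))
    lambda0 <- (n - 1) * df * 0.05^2
    pclose <- stats::pchisq(chi2, df, ncp = lambda0, lower.tail = FALSE)
    ecvi_lo <- (lam[["lo"]] + df + 2 * q) / (n - 1)
    ecvi_hi <- (lam[["hi"]] + df + 2 * q) / (n - 1)
    hoelter_05 <- floor(stats::qchisq(0.95, df) / (chi2 / (n - 1))) + 1
    hoelter_01 <- floor(stats::qchisq(0.99, df) / (chi2 / (n - 1))) + 1
  } else {
    rmsea <- rmsea_lo <- rmsea_hi <- pclose <- NA_real_
    ecvi_lo <- ecvi_hi <- NA_real_
    hoelter_05 <- hoelter_01 <- NA_integer_
  }
  ecvi <- (chi2 + 2 * q) / (n - 1)

  structure(list(
    chi_square = chi2,
    p_value = fit$p_value_model,
    chi_square_over_df = if (has_df) chi2 / df else NA_real_,
    df = df,
    rmr = rmr, srmr = srmr,
    gfi = gfi, agfi = agfi, pgfi = pgfi,
    nfi = nfi, rfi = rfi, ifi = ifi, tli = tli, cfi = cfi,
    pnfi = pnfi, pcfi = pcfi,
    rmsea = rmsea, rmsea_lo90 = rmsea_lo, rmsea_hi90 = rmsea_hi,
    pclose = pclose,
    ecvi = ecvi, ecvi_lo90 = ecvi_lo, ecvi_hi90 = ecvi_hi,
    hoelter_05 = hoelter_05, hoelter_01 = hoelter_01,
    baseline_chi_square = chi2_b, baseline_df = df_b,
    n = n, q = q), class = "fit_index_report")
}

#' @export
print.fit_index_report <- function(x, digits = 4, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", format(round(v, digits),
                                                  nsmall = digits))
  lines <- c(
    sprintf("Chi-squared            %s", fmt(x$chi_square)),
    sprintf("p                      %s", fmt(x$p_value)),
    sprintf("Chi-squared/df         %s", fmt(x$chi_square_over_df)),
    sprintf("RMR                    %s", fmt(x$rmr)),
    sprintf("GFI                    %s", fmt(x$gfi)),
    sprintf("AGFI                   %s", fmt(x$agfi)),
    sprintf("PGFI                   %s", fmt(x$pgfi)),
    sprintf("NFI                    %s", fmt(x$nfi)),
    sprintf("RFI                    %s", fmt(x$rfi)),
    sprintf("IFI                    %s", fmt(x$ifi)),
    sprintf("TLI                    %s", fmt(x$tli)),
    sprintf("CFI                    %s", fmt(x$cfi)),
    sprintf("PNFI                   %s", fmt(x$pnfi)),
    sprintf("PCFI                   %s", fmt(x$pcfi)),
    sprintf("RMSEA [90%% CI]         %s [%s, %s]",
            fmt(x$rmsea), fmt(x$rmsea_lo90), fmt(x$rmsea_hi90)),
    sprintf("PCLOSE                 %s", fmt(x$pclose)),
    sprintf("ECVI [90%% CI]          %s [%s, %s]",
            fmt(x$ecvi), fmt(x$ecvi_lo90), fmt(x$ecvi_hi90)),
    sprintf("Hoelter N (.05)        %s", x$hoelter_05),
    sprintf("Hoelter N (.01)        %s", x$hoelter_01))
  cat("Model fit summary\n")
  cat(paste0("  ", lines, collapse = "\n"), "\n")
  invisible(x)
}
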